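make_rows <- function(n, seed = 1, informative = TRUE) {
  set.seed(seed)
  label <- rep(0:1, length.out = n)
  shift <- if (informative) 2 * label else 0
  tibble::tibble(
    symptom = sprintf("s%02d", seq_len(n)), plaque = "calcified",
    topo_dist = rnorm(n) + shift, topo_euclid = rnorm(n) + shift,
    lift = rnorm(n) + shift, cnn_score = runif(n), semsim = runif(n),
    label = label
  )
}

test_that("model configuration validates and names the ablations", {
  expect_error(model_config(k_neighbors = 0), "k_neighbors")
  expect_error(model_config(folds = 1), "folds")
  expect_error(model_config(channels = "nope"), "arg")
  expect_setequal(ablation_config("A")$channels, c("topo", "assoc", "semsim"))
  expect_setequal(ablation_config("B")$channels, c("topo", "assoc"))
  expect_equal(ablation_config("C")$channels, "semsim")
})

test_that("KNN scoring follows hand-rankable cases", {
  # k = 1: a query equal to a training row returns that row's label
  rows <- make_rows(10)
  cfg <- model_config(k_neighbors = 1, folds = 2)
  model <- knn_fit(rows, cfg)
  expect_equal(knn_predict(model, rows[3, ]), rows$label[3])
  expect_equal(knn_predict(model, rows[4, ]), rows$label[4])

  # 1-D geometry: positives at 1.0..1.5, negatives at 3.0..3.5, query 1.25
  rows1 <- tibble::tibble(
    symptom = sprintf("s%d", 1:12), plaque = "mixed",
    semsim = c(seq(1.0, 1.5, 0.1), seq(3.0, 3.5, 0.1)),
    label = rep(c(1L, 0L), each = 6)
  )
  cfg1 <- model_config(k_neighbors = 6, channels = "semsim", standardize = FALSE)
  m1 <- knn_fit(rows1, cfg1)
  q <- tibble::tibble(semsim = 1.25)
  expect_equal(knn_predict(m1, q), 1.0)

  expect_error(knn_fit(rows[1:3, ], model_config(k_neighbors = 6)), "< k")
})

test_that("KNN scores equal an exhaustive all-distances oracle", {
  for (seed in 1:3) {
    rows <- make_rows(sample(50:200, 1), seed = seed)
    cfg <- model_config(k_neighbors = 6, standardize = FALSE)
    model <- knn_fit(rows, cfg)
    queries <- make_rows(20, seed = seed + 100)
    got <- knn_predict(model, queries)
    X <- as.matrix(rows[, c("topo_dist", "topo_euclid", "lift", "cnn_score", "semsim")])
    Q <- as.matrix(queries[, c("topo_dist", "topo_euclid", "lift", "cnn_score", "semsim")])
    oracle <- apply(Q, 1, function(q) {
      d <- sqrt(rowSums(sweep(X, 2, q)^2))
      mean(rows$label[order(d, seq_along(d))[1:6]])
    })
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("rank AUC matches concordant-pair counting", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  # labels (1,1,0,0) scores (.9,.7,.8,.6): 3 of 4 pairs concordant
  expect_equal(auc_rank(c(0.9, 0.7, 0.8, 0.6), c(1, 1, 0, 0)), 0.75)

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:500, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_rank(scores, labels), brute, tolerance = 1e-12)
  }
})

test_that("cross-validation partitions rows and pools out-of-fold scores", {
  rows <- make_rows(60, seed = 2)
  cfg <- model_config(folds = 5, seed = 3)
  cv <- cross_validate(rows, cfg)
  expect_equal(sort(unique(cv$scores$fold)), 1:5)
  expect_equal(length(cv$scores$fold), 60)
  expect_true(all(table(cv$scores$fold, cv$scores$label) >= 1))
  expect_gte(cv$pooled_auc, 0.9)  # strongly informative features

  # ROC shape: starts (0,0), ends (1,1), monotone
  expect_equal(cv$roc$fpr[1], 0)
  expect_equal(cv$roc$tpr[1], 0)
  expect_equal(cv$roc$fpr[nrow(cv$roc)], 1)
  expect_equal(cv$roc$tpr[nrow(cv$roc)], 1)
  expect_true(all(diff(cv$roc$fpr) >= 0))
  expect_true(all(diff(cv$roc$tpr) >= -1e-12))

  expect_error(cross_validate(make_rows(8), model_config(folds = 10)), "fewer folds")
})

test_that("label shuffling calibrates the cross-validated AUC to one half", {
  rows <- make_rows(80, seed = 5)
  set.seed(99)
  aucs <- purrr::map_dbl(1:20, function(i) {
    rows$label <- sample(rows$label)
    cross_validate(rows, model_config(folds = 4, seed = i))$pooled_auc
  })
  # CLT bound: null AUC sd for n1 = n0 = 40 is roughly 0.066; 20 replicates
  expect_lt(abs(mean(aucs) - 0.5), 3 * 0.066 / sqrt(20))
})

test_that("the ablation study evaluates exactly A, B, C on shared folds", {
  rows <- make_rows(60, seed = 4)
  ab <- run_ablation(rows, folds = 5, seed = 1)
  expect_setequal(names(ab$reports), c("A", "B", "C"))
  expect_equal(ab$reports$A$scores$fold, ab$reports$C$scores$fold)
  # semsim is uninformative noise here: C should hover near chance
  expect_lt(ab$summary$pooled_auc[ab$summary$config == "C"], 0.7)
  expect_gt(ab$summary$pooled_auc[ab$summary$config == "A"], 0.8)
})

test_that("a constant feature channel scores near chance", {
  rows <- make_rows(80, seed = 6)
  rows$semsim <- 0.4
  cv <- cross_validate(rows, model_config(channels = "semsim", folds = 4))
  expect_lt(abs(cv$pooled_auc - 0.5), 0.2)
})

test_that("association selection respects the score cutoff", {
  rows <- make_rows(20, seed = 7)
  cv <- cross_validate(rows, model_config(folds = 4))
  sets <- list()
  all_sel <- select_associations(cv, sets, sets, score_cutoff = 0)
  expect_equal(nrow(all_sel$pairs), 20)
  if (any(cv$scores$score < 1)) {
    top_sel <- select_associations(cv, sets, sets, score_cutoff = 1)
    expect_lt(nrow(top_sel$pairs), 20)
  }

  # toy report with known scores {0.9, 0.4}: cutoff 0.5 keeps exactly one
  fake <- cv
  fake$scores <- tibble::tibble(
    symptom = c("s1", "s2"), plaque = "calcified",
    label = c(1L, 0L), score = c(0.9, 0.4)
  )
  sel <- select_associations(fake, list(s1 = c("gA", "gB")),
                             list(calcified = c("gB", "gC")), score_cutoff = 0.5)
  expect_equal(sel$pairs$symptom, "s1")
  expect_setequal(sel$genes, c("gA", "gB", "gC"))
  expect_warning(select_associations(fake, list(), list(), score_cutoff = 0.99),
                 "no pair")
})
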