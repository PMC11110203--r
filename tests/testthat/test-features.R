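test_that("shortest paths are exact on hand-enumerable graphs", {
  g <- mini_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
  d <- kg_shortest_paths(g, "a")
  expect_equal(unname(d["c"]), 2)
  expect_equal(unname(d["a"]), 0)

  # a longer direct edge does not shorten the two-step path
  g2 <- mini_graph(data.frame(from = c("a", "b", "a"), to = c("b", "c", "c")),
                   lengths = c(1, 1, 3))
  expect_equal(unname(kg_shortest_paths(g2, "a")["c"]), 2)

  expect_error(kg_shortest_paths(g, "zz"), "unknown source")
})

test_that("Dijkstra agrees with a Bellman-Ford oracle on random weighted graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(n:(3 * n), 1)
    edges <- cbind(sample(nodes, m, replace = TRUE), sample(nodes, m, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(edges)
    lengths <- runif(nrow(edges), 0.05, 2)
    g <- mini_graph(data.frame(from = edges[, 1], to = edges[, 2]), lengths)
    src <- sample(igraph::V(g)$name, 1)
    d <- kg_shortest_paths(g, src)
    oracle <- bellman_ford(edges, lengths, igraph::V(g)$name, src)
    expect_equal(d[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("point-to-network profiles reduce to centroid arithmetic", {
  # 2 symptoms, 1 plaque, profiles (1) and (3): centroid 2, euclids 1 and 1
  edges <- data.frame(from = c("s1", "p"), to = c("p", "s2"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$length <- c(1, 3)
  igraph::V(g)$kind <- c("symptom", "plaque", "symptom")
  igraph::V(g)$name <- c("sym:s1", "plq:p", "sym:s2")
  tf <- topo_features(g)
  expect_equal(tf$topo_dist[tf$symptom == "s1"], 1)
  expect_equal(tf$topo_dist[tf$symptom == "s2"], 3)
  expect_equal(unname(tf$topo_euclid), c(1, 1))

  # a symptom whose profile equals the centroid has zero euclid
  edges2 <- data.frame(from = c("s1", "s2"), to = c("p", "p"))
  g2 <- igraph::graph_from_data_frame(edges2, directed = FALSE)
  igraph::E(g2)$length <- c(2, 2)
  igraph::V(g2)$kind <- c("symptom", "symptom", "plaque")
  igraph::V(g2)$name <- c("sym:s1", "sym:s2", "plq:p")
  expect_equal(unname(topo_features(g2)$topo_euclid), c(0, 0))
})

test_that("lift matches direct counting and its edge cases", {
  rec <- tibble::tibble(
    patient_id = sprintf("p%d", 1:10),
    symptoms = c(rep(list("A"), 3), list("A"), rep(list(character(0)), 6)),
    plaques = c(rep(list("calcified"), 3), list(character(0)), list("calcified"), list("calcified"),
                rep(list(character(0)), 4))
  )
  # A in 4, B in 5, both in 3 -> lift 0.3/(0.4*0.5) = 1.5
  l <- pair_lift(rec, "A", "calcified")
  expect_equal(as.numeric(l), 1.5)
  expect_equal(attr(l, "confidence"), 0.75)

  # item in all records: lift 1
  rec2 <- tibble::tibble(patient_id = c("p1", "p2"),
                         symptoms = list("A", "A"),
                         plaques = list("mixed", character(0)))
  expect_equal(as.numeric(pair_lift(rec2, "A", "mixed")), 1)

  # never co-occurring items: lift 0
  rec3 <- tibble::tibble(patient_id = c("p1", "p2"),
                         symptoms = list("A", "B"),
                         plaques = list(character(0), "mixed"))
  expect_equal(as.numeric(pair_lift(rec3, "A", "mixed")), 0)

  expect_error(pair_lift(rec3, "ZZ", "mixed"), "zero support")

  # symmetry
  expect_equal(as.numeric(pair_lift(rec, "A", "calcified")),
               as.numeric(pair_lift(rec, "calcified", "A")))
})

test_that("lift table equals per-pair direct counting on random cohorts", {
  for (seed in 1:3) {
    cfg <- generator_config(n_patients = 100, n_symptoms = 6, n_genes = 30, seed = seed)
    rec <- generate_cohort(cfg)$records
    lt <- lift_table(rec)
    for (i in sample(nrow(lt), 6)) {
      row <- lt[i, ]
      if (is.na(row$lift)) next
      expect_equal(row$lift, as.numeric(pair_lift(rec, row$symptom, row$plaque)),
                   info = sprintf("seed %d %s/%s", seed, row$symptom, row$plaque))
    }
  }
})

test_that("shuffling plaque labels drives mean lift to one", {
  cfg <- generator_config(n_patients = 1000, n_symptoms = 10, n_genes = 50,
                          effect_size = 2, seed = 3)
  rec <- generate_cohort(cfg)$records
  set.seed(42)
  shuffled_means <- purrr::map_dbl(1:10, function(i) {
    rec$plaques <- rec$plaques[sample(nrow(rec))]
    mean(lift_table(rec)$lift, na.rm = TRUE)
  })
  expect_equal(mean(shuffled_means), 1, tolerance = 0.05)
})

test_that("patient matrices zero absent-symptom rows and share dimensions", {
  rec <- toy_records()
  lt <- lift_table(rec)
  pm <- build_patient_matrices(rec, lt)
  expect_equal(dim(pm$matrices), c(3, 2, 1))
  # p3 has symptoms {s2}: its s1 row must be zero, s2 row equals the lift
  expect_equal(pm$matrices["p3", "s1", ], 0)
  expect_equal(unname(pm$matrices["p3", "s2", "calcified"]),
               lt$lift[lt$symptom == "s2" & lt$plaque == "calcified"])
  # identical symptom sets give identical matrices
  rec2 <- tibble::tibble(patient_id = c("a", "b"),
                         symptoms = list(c("s1", "s2"), c("s2", "s1")),
                         plaques = list("calcified", character(0)))
  pm2 <- build_patient_matrices(rec2, lt)
  expect_equal(pm2$matrices["a", , ], pm2$matrices["b", , ])
  # a patient with no symptoms gets an all-zero matrix
  rec3 <- tibble::tibble(patient_id = "z", symptoms = list(character(0)),
                         plaques = list("calcified"))
  expect_true(all(build_patient_matrices(rec3, lt)$matrices == 0))
})

test_that("the convolutional model overfits a small cohort and is well-behaved", {
  cfg <- generator_config(n_patients = 40, n_symptoms = 20, seed = 7)
  co <- generate_cohort(cfg)
  lt <- lift_table(co$records, symptoms = co$truth$symptoms, plaques = co$truth$plaques)
  pm <- build_patient_matrices(co$records, lt)
  Y <- plaque_label_matrix(co$records, pm)
  model <- train_cnn(pm, Y, cnn_train_config(epochs = 200, seed = 7))
  pr <- cnn_predict(model, pm)
  expect_gte(mean((pr > 0.5) == Y), 0.9)
  expect_true(all(pr > 0 & pr < 1))

  # training is deterministic given the seed
  model2 <- train_cnn(pm, Y, cnn_train_config(epochs = 200, seed = 7))
  expect_identical(model$par, model2$par)

  # a zeroed final layer predicts sigmoid(0) = 0.5 everywhere
  model$par$W3[] <- 0
  model$par$b3[] <- 0
  expect_true(all(cnn_predict(model, pm) == 0.5))

  # pair scores stay in [0,1]
  sc <- cnn_pair_scores(model2, pm, co$records)
  expect_true(all(sc$cnn_score >= 0 & sc$cnn_score <= 1))

  # single-class labels are refused with the class named
  Y1 <- Y
  Y1[, "mixed"] <- 1L
  expect_error(train_cnn(pm, Y1, cnn_train_config(epochs = 1)), "mixed")
})

test_that("convolution gradients match numerical differentiation", {
  set.seed(1)
  arr <- array(rnorm(4 * 5 * 3), dim = c(4, 5, 3),
               dimnames = list(sprintf("p%d", 1:4), sprintf("s%d", 1:5),
                               c("calcified", "mixed", "noncalcified")))
  pm <- structure(list(matrices = arr, symptoms = sprintf("s%d", 1:5),
                       plaques = c("calcified", "mixed", "noncalcified"),
                       patient_id = sprintf("p%d", 1:4)), class = "patient_matrices")
  Y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  Y[1, ] <- c(0L, 1L, 0L); Y[2, ] <- c(1L, 0L, 1L)  # ensure both classes per column
  # one Adam step must reduce nothing in particular, but the analytic loss
  # gradient wrt W3 should match finite differences through the forward pass
  model <- train_cnn(pm, Y, cnn_train_config(epochs = 1, lr = 0, seed = 3))
  par <- model$par
  n <- 4; S <- 5; W <- 3; P <- S * W
  idxM <- plaquekg:::conv_gather(S, W, n)
  X1 <- plaquekg:::cnn_im2col1(plaquekg:::cnn_input_cols(arr), idxM)
  loss_of <- function(p) {
    fw <- plaquekg:::cnn_forward(p, X1, idxM, n, P)
    yh <- pmin(pmax(fw$Yhat, 1e-12), 1 - 1e-12)
    -mean(Y * log(yh) + (1 - Y) * log(1 - yh))
  }
  fw <- plaquekg:::cnn_forward(par, X1, idxM, n, P)
  g <- plaquekg:::cnn_gradients(par, fw, X1, idxM, Y, n, P)
  for (probe in list(c("W1", 3, 2), c("W2", 10, 5), c("W3", 7, 2), c("W2", 19, 12))) {
    nm <- probe[1]; i <- as.integer(probe[2]); j <- as.integer(probe[3])
    eps <- 1e-5
    pp <- par; pp[[nm]][i, j] <- pp[[nm]][i, j] + eps
    pm_ <- par; pm_[[nm]][i, j] <- pm_[[nm]][i, j] - eps
    num <- (loss_of(pp) - loss_of(pm_)) / (2 * eps)
    expect_equal(g[[nm]][i, j], num, tolerance = 1e-4,
                 info = sprintf("gradient of %s[%d,%d]", nm, i, j))
  }
})
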