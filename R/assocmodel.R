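#' Configuration for the KNN association model
#'
#' The three channel groups map to feature columns: `topo` to
#' `topo_dist` + `topo_euclid`, `assoc` to `lift` + `cnn_score`, `semsim`
#' to `semsim`.  The named ablation configurations are A (all three
#' channels), B (topology + association) and C (semantic similarity only).
#'
#' @param k_neighbors Neighbourhood size (default 6).
#' @param folds Cross-validation folds (default 10).
#' @param channels Subset of `c("topo", "assoc", "semsim")`.
#' @param standardize Z-score features inside each training fold.
#' @param seed Fold-assignment seed.
#' @return A `plaquekg_model_config`.
#' @export
model_config <- function(k_neighbors = 6, folds = 10,
                         channels = c("topo", "assoc", "semsim"),
                         standardize = TRUE, seed = 1L) {
  if (k_neighbors < 1) abort("input error: k_neighbors must be >= 1")
  if (folds < 2) abort("input error: folds must be >= 2")
  channels <- match.arg(channels, c("topo", "assoc", "semsim"), several.ok = TRUE)
  if (length(channels) == 0) abort("input error: at least one channel required")
  structure(list(k_neighbors = as.integer(k_neighbors), folds = as.integer(folds),
                 channels = channels, standardize = standardize, seed = as.integer(seed)),
            class = "plaquekg_model_config")
}

#' Named ablation configurations
#'
#' @param name One of "A", "B", "C".
#' @param ... Passed to [model_config()].
#' @return A `plaquekg_model_config` with the channels of that ablation.
#' @export
ablation_config <- function(name = c("A", "B", "C"), ...) {
  name <- match.arg(name)
  channels <- switch(name,
    A = c("topo", "assoc", "semsim"),
    B = c("topo", "assoc"),
    C = "semsim")
  model_config(channels = channels, ...)
}

channel_columns <- function(channels) {
  unlist(list(topo = c("topo_dist", "topo_euclid"),
              assoc = c("lift", "cnn_score"),
              semsim = "semsim")[channels], use.names = FALSE)
}

feature_matrix <- function(rows, cfg) {
  cols <- channel_columns(cfg$channels)
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0) {
    abort(sprintf("input error: feature column(s) missing: %s", paste(missing, collapse = ", ")))
  }
  as.matrix(rows[cols])
}

#' Fit the k-nearest-neighbour association model
#'
#' Stores the (optionally z-scored) training features and labels; a query
#' is scored by the fraction of its `k` nearest training rows (Euclidean
#' metric) with label 1.  Distance ties break by training-row index.
#'
#' @param rows Feature tibble with channel columns and a 0/1 `label`.
#' @param cfg A [model_config()].
#' @return A `plaquekg_knn` model.
#' @export
knn_fit <- function(rows, cfg = model_config()) {
  X <- feature_matrix(rows, cfg)
  y <- rows$label
  if (nrow(X) < cfg$k_neighbors) {
    abort(sprintf("input error: %d training rows < k = %d", nrow(X), cfg$k_neighbors))
  }
  if (length(unique(y)) < 2) abort("input error: training labels are single-class")
  center <- scale_ <- NULL
  if (cfg$standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  structure(list(X = X, y = y, center = center, scale = scale_, cfg = cfg),
            class = "plaquekg_knn")
}

#' @param model A fitted `plaquekg_knn`.
#' @param newrows Feature tibble to score.
#' @return Numeric vector of scores in [0,1].
#' @rdname knn_fit
#' @export
knn_predict <- function(model, newrows) {
  Q <- feature_matrix(newrows, model$cfg)
  if (model$cfg$standardize) {
    Q <- sweep(sweep(Q, 2, model$center), 2, model$scale, "/")
  }
  k <- model$cfg$k_neighbors
  apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(model$X) - q)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    mean(model$y[nn])
  })
}

#' Area under the ROC curve by the rank statistic
#'
#' Equivalent to the Wilcoxon-Mann-Whitney statistic; tied scores
#' contribute one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0,1].
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("input error: AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  ths <- unique(s)
  pts <- purrr::map_dfr(ths, function(th) {
    pred <- scores >= th
    tibble(threshold = th,
           fpr = sum(pred & labels == 0) / max(1, sum(labels == 0)),
           tpr = sum(pred & labels == 1) / max(1, sum(labels == 1)))
  })
  bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), pts) |>
    arrange(.data$fpr, .data$tpr)
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      abort(sprintf("fold error: class %s has %d members < %d folds; use fewer folds",
                    cl, length(idx), folds))
    }
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Stratified cross-validation of the KNN model
#'
#' Rows are split into stratified folds by the configuration seed; each
#' fold is scored by a model fit on the remainder (standardization
#' refitted inside each training fold), and the out-of-fold scores are
#' pooled for the ROC and AUC.
#'
#' @param rows Feature tibble with `label`.
#' @param cfg A [model_config()].
#' @param fold_assignment Optional precomputed fold vector (for ablations
#'   sharing folds).
#' @return A `plaquekg_cv` report: per-fold AUCs, pooled ROC points,
#'   pooled and mean AUC, and the per-row out-of-fold scores.
#' @export
cross_validate <- function(rows, cfg = model_config(), fold_assignment = NULL) {
  fold <- fold_assignment %||% stratified_folds(rows$label, cfg$folds, cfg$seed)
  scores <- numeric(nrow(rows))
  fold_auc <- numeric(cfg$folds)
  for (f in seq_len(cfg$folds)) {
    test <- fold == f
    model <- knn_fit(rows[!test, ], cfg)
    scores[test] <- knn_predict(model, rows[test, ])
    fold_auc[f] <- if (length(unique(rows$label[test])) == 2) {
      auc_rank(scores[test], rows$label[test])
    } else NA_real_
  }
  out <- rows
  out$score <- scores
  out$fold <- fold
  structure(list(
    fold_auc = fold_auc,
    mean_auc = mean(fold_auc, na.rm = TRUE),
    pooled_auc = auc_rank(scores, rows$label),
    roc = roc_points(scores, rows$label),
    scores = as_tibble(out),
    cfg = cfg
  ), class = "plaquekg_cv")
}

#' @export
print.plaquekg_cv <- function(x, ...) {
  cat(sprintf("<plaquekg_cv> channels {%s}: pooled AUC %.3f (mean fold AUC %.3f over %d folds)\n",
              paste(x$cfg$channels, collapse = ","), x$pooled_auc, x$mean_auc,
              x$cfg$folds))
  invisible(x)
}

#' Channel-ablation comparison of the KNN model
#'
#' Evaluates configurations A (all channels), B (topology + association)
#' and C (semantic similarity) on identical stratified folds.
#'
#' @param rows Feature tibble carrying all channel columns and `label`.
#' @param k_neighbors,folds,seed Shared settings, see [model_config()].
#' @return A `plaquekg_ablation`: list of the three `plaquekg_cv` reports
#'   plus a summary tibble ordered by AUC.
#' @export
run_ablation <- function(rows, k_neighbors = 6, folds = 10, seed = 1L) {
  fold <- stratified_folds(rows$label, folds, seed)
  reports <- lapply(setNames(nm = c("A", "B", "C")), function(nm) {
    cfg <- ablation_config(nm, k_neighbors = k_neighbors, folds = folds, seed = seed)
    cross_validate(rows, cfg, fold_assignment = fold)
  })
  summary <- tibble(
    config = names(reports),
    channels = map_chr(reports, ~ paste(.x$cfg$channels, collapse = "+")),
    pooled_auc = map_dbl(reports, "pooled_auc"),
    mean_fold_auc = map_dbl(reports, "mean_auc")
  )
  structure(list(reports = reports, summary = summary), class = "plaquekg_ablation")
}

#' @export
print.plaquekg_ablation <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Select associated pairs and their gene complement
#'
#' Retains pairs whose out-of-fold predicted score reaches the cutoff and
#' collects the union of annotation genes of the retained symptoms and
#' plaques.
#'
#' @param report A `plaquekg_cv` report.
#' @param symptom_sets,plaque_sets Named lists of gene-id vectors.
#' @param score_cutoff Minimum mean predicted score.
#' @return A list with `pairs` (tibble), `genes` (character) and `counts`.
#' @export
select_associations <- function(report, symptom_sets, plaque_sets, score_cutoff = 0.5) {
  sel <- filter(report$scores, .data$score >= score_cutoff)
  if (nrow(sel) == 0) {
    warn("no pair reaches the score cutoff; empty selection")
    return(list(pairs = sel, genes = character(0),
                counts = c(pairs = 0L, symptoms = 0L, plaques = 0L, genes = 0L)))
  }
  genes <- sort(unique(c(
    unlist(symptom_sets[intersect(unique(sel$symptom), names(symptom_sets))]),
    unlist(plaque_sets[intersect(unique(sel$plaque), names(plaque_sets))])
  )))
  list(pairs = select(sel, "symptom", "plaque", "label", "score"),
       genes = genes,
       counts = c(pairs = nrow(sel),
                  symptoms = length(unique(sel$symptom)),
                  plaques = length(unique(sel$plaque)),
                  genes = length(genes)))
}
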