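#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the out-of-fold scores of a cross-validated KNN report
#'
#' @param x A `plaquekg_cv`.
#' @param ... Unused.
#' @return Tibble of per-pair out-of-fold scores, labels and folds.
#' @export
tidy.plaquekg_cv <- function(x, ...) x$scores

#' One-row model summary of a cross-validated KNN report
#'
#' @param x A `plaquekg_cv`.
#' @param ... Unused.
#' @return One-row tibble with AUC summaries and settings.
#' @export
glance.plaquekg_cv <- function(x, ...) {
  tibble(channels = paste(x$cfg$channels, collapse = "+"),
         k_neighbors = x$cfg$k_neighbors, folds = x$cfg$folds,
         pooled_auc = x$pooled_auc, mean_fold_auc = x$mean_auc,
         sd_fold_auc = sd(x$fold_auc, na.rm = TRUE))
}

#' Tidy a module assignment into a gene-level table
#'
#' @param x A `plaquekg_modules`.
#' @param ... Unused.
#' @return Tibble with `gene`, `module`, `color`.
#' @export
tidy.plaquekg_modules <- function(x, ...) {
  tibble(gene = names(x$modules), module = unname(x$modules),
         color = unname(x$colors))
}

#' One-row summary of a module assignment
#'
#' @param x A `plaquekg_modules`.
#' @param ... Unused.
#' @return One-row tibble with power, module count and grey fraction.
#' @export
glance.plaquekg_modules <- function(x, ...) {
  tibble(beta = x$beta, n_modules = length(unique(x$modules[x$modules > 0])),
         n_genes = length(x$modules),
         grey_fraction = mean(x$modules == 0), cut_height = x$cut_height)
}

#' Tidy a ROC result
#'
#' @param x A `plaquekg_roc`.
#' @param ... Unused.
#' @return Tibble of ROC points.
#' @export
tidy.plaquekg_roc <- function(x, ...) x$roc

#' One-row summary of a ROC result
#'
#' @param x A `plaquekg_roc`.
#' @param ... Unused.
#' @return One-row tibble with the AUC and sizes.
#' @export
glance.plaquekg_roc <- function(x, ...) {
  tibble(auc = x$auc, n_samples = nrow(x$scores), n_genes = length(x$genes))
}
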