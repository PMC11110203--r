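#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_tile
#'   geom_text geom_step labs theme_minimal scale_fill_gradient2 geom_point
#' @export
ggplot2::autoplot

#' ROC curve of a validated signature
#'
#' @param object A `plaquekg_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plaquekg_roc <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("Signature ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Pooled ROC of a cross-validated KNN report
#'
#' @param object A `plaquekg_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plaquekg_cv <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("KNN {%s}: pooled AUC = %.3f",
                         paste(object$cfg$channels, collapse = ","), object$pooled_auc)) +
    theme_minimal()
}

#' Overlaid ROC curves of the channel ablations
#'
#' @param object A `plaquekg_ablation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plaquekg_ablation <- function(object, ...) {
  df <- purrr::imap_dfr(object$reports, ~ mutate(.x$roc, config = .y))
  ggplot(df, aes(x = .data$fpr, y = .data$tpr, colour = .data$config)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    labs(x = "False positive rate", y = "True positive rate",
         colour = "KNN config", title = "Channel-ablation ROC") +
    theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param mt Tibble from [module_trait()].
#' @return A ggplot.
#' @export
plot_module_trait <- function(mt) {
  ggplot(mt, aes(x = .data$trait, y = .data$module, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f\n(%.1g)", .data$r, .data$p)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = "Trait", y = "Module eigengene", fill = "Pearson r") +
    theme_minimal()
}

#' Scale-free fit diagnostics for candidate soft powers
#'
#' @param sft Result of [pick_soft_threshold()].
#' @return A ggplot of signed R-squared versus power.
#' @export
plot_soft_threshold <- function(sft) {
  df <- mutate(sft$fit, signed_rsq = .data$rsq * sign(-.data$slope))
  ggplot(df, aes(x = .data$beta, y = .data$signed_rsq)) +
    geom_point() + geom_line() +
    labs(x = "Soft-thresholding power", y = "Signed scale-free R²") +
    theme_minimal()
}
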