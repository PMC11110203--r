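#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` term members, the chance of an overlap
#' at least `k`.
#'
#' @param k Observed overlap.
#' @param K Term (annotation set) size.
#' @param n Query set size.
#' @param N Universe size.
#' @return Probability in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  ok <- all(is.finite(c(k, K, n, N))) && k >= 0 && K <= N && n <= N && k <= min(K, n)
  if (!ok) abort("input error: require 0 <= k <= min(K, n) and K, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each annotation term with an overlap of at least one gene
#' against the query, sorted by p-value.  Raw p-value thresholding at
#' `p_cut` is the default; multiple-testing correction is available but
#' off by default.
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param annotation Named list term -> gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Background gene ids.
#' @param p_cut Significance threshold on the (possibly adjusted) p.
#' @param correction `p.adjust` method; `"none"` (default) reproduces raw
#'   thresholding.
#' @return Tibble with `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`,
#'   `significant`, ordered by `p`.
#' @export
enrich <- function(query, annotation, universe, p_cut = 0.05, correction = "none") {
  if (length(universe) == 0) abort("input error: empty universe")
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    abort(sprintf("input error: query gene(s) outside the universe: %s",
                  paste(head(setdiff(query, universe), 3), collapse = ", ")))
  }
  query <- unique(query)
  n <- length(query); N <- length(universe)
  res <- purrr::imap_dfr(annotation, function(gs, term) {
    gs <- intersect(unique(gs), universe)
    k <- length(intersect(gs, query))
    if (k == 0) return(NULL)
    tibble(term = term, k = k, K = length(gs), n = n, N = N,
           p = hypergeom_p(k, length(gs), n, N))
  })
  if (nrow(res) == 0) return(mutate(res, p_adj = numeric(0), significant = logical(0)))
  res$p_adj <- stats::p.adjust(res$p, method = correction)
  res$significant <- res$p_adj < p_cut
  arrange(res, .data$p)
}

#' ROC validation of a gene-set signature on expression data
#'
#' The per-sample signature score is the mean z-scored expression over
#' the gene set; the ROC and AUC come from the rank statistic (ties
#' counted one half).
#'
#' @param expr Gene x sample numeric matrix.
#' @param labels Character/factor vector per sample; `positive` names the
#'   case level.
#' @param gene_set Character vector of gene ids.
#' @param positive Label treated as the positive class.
#' @return A `plaquekg_roc`: ROC points, AUC, per-sample scores.
#' @export
signature_roc <- function(expr, labels, gene_set, positive = "case") {
  genes <- intersect(gene_set, rownames(expr))
  if (length(genes) == 0) {
    abort(sprintf("input error: no signature gene present in the matrix (missing: %s%s)",
                  paste(head(gene_set, 5), collapse = ", "),
                  if (length(gene_set) > 5) ", ..." else ""))
  }
  y <- as.integer(labels == positive)
  if (length(unique(y)) < 2) abort("input error: both labels must be present")
  Z <- t(scale(t(expr[genes, , drop = FALSE])))
  Z[is.na(Z)] <- 0
  score <- colMeans(Z)
  structure(list(
    roc = roc_points(score, y),
    auc = auc_rank(score, y),
    scores = tibble(sample = colnames(expr), label = labels, score = unname(score)),
    genes = genes
  ), class = "plaquekg_roc")
}

#' @export
print.plaquekg_roc <- function(x, ...) {
  cat(sprintf("<plaquekg_roc> AUC %.3f over %d samples (%d signature genes)\n",
              x$auc, nrow(x$scores), length(x$genes)))
  invisible(x)
}
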