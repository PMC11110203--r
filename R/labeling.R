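#' Random walk with restart on the knowledge graph
#'
#' Edge affinities are the inverse traversal lengths; the transition
#' matrix is column-stochastic (each node spreads its mass over its
#' neighbours in proportion to affinity).  The walker iterates
#' `p <- (1 - r) W p + r p0` with `p0` uniform on the seed nodes until the
#' L1 residual falls below `tol`.  Nodes without edges restart fully.
#'
#' @param kg Fused igraph with positive edge `length`s.
#' @param seeds Bare node ids to restart at.
#' @param r Restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error that carries
#'   the residual.
#' @return A `plaquekg_rwr`: list with `scores` (named, sums to 1),
#'   `iterations`, `residual`, `converged`, `r`, `seeds`.
#' @export
rwr <- function(kg, seeds, r = 0.7, tol = 1e-10, max_iter = 10000) {
  if (length(seeds) == 0) abort("input error: empty seed set")
  if (!(r > 0 && r <= 1)) abort("input error: restart probability must be in (0,1]")
  nm <- igraph::V(kg)$name
  bare <- strip_id(nm)
  seed_idx <- match(seeds, bare)
  if (anyNA(seed_idx)) abort(sprintf("input error: unknown seed node '%s'", seeds[which(is.na(seed_idx))[1]]))

  A <- igraph::as_adjacency_matrix(kg, attr = "length", sparse = FALSE)
  aff <- ifelse(A > 0, 1 / A, 0)
  p0 <- numeric(length(nm))
  p0[seed_idx] <- 1 / length(seed_idx)
  colsum <- colSums(aff)
  W <- aff
  nz <- colsum > 0
  W[, nz] <- sweep(aff[, nz, drop = FALSE], 2, colsum[nz], "/")
  W[, !nz] <- p0  # dangling nodes restart entirely

  p <- p0
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p_new <- (1 - r) * as.vector(W %*% p) + r * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) break
  }
  if (res >= tol) {
    abort(sprintf("RWR failed to converge in %d iterations (residual %.3e)", max_iter, res),
          class = "plaquekg_rwr_nonconvergence", residual = res)
  }
  structure(list(scores = setNames(p, bare), iterations = it, residual = res,
                 converged = TRUE, r = r, seeds = seeds),
            class = "plaquekg_rwr")
}

#' @export
print.plaquekg_rwr <- function(x, ...) {
  cat(sprintf("<plaquekg_rwr> r = %.2f, %d iterations, residual %.2e\n",
              x$r, x$iterations, x$residual))
  invisible(x)
}

#' Label symptom-plaque pairs from RWR judgment values
#'
#' For each plaque the walk restarts at that plaque node and symptoms are
#' ranked by their stationary score; the top `ceiling(q * S)` symptoms
#' are labelled 1, the rest 0.  Score ties break lexicographically by
#' symptom id so labels are reproducible.
#'
#' @param kg Fused igraph.
#' @param plaque_ids Plaque nodes to seed; default all in the graph.
#' @param r Restart probability.
#' @param q Positive fraction per plaque, in (0, 1].
#' @param tol,max_iter Passed to [rwr()].
#' @return Tibble with `symptom`, `plaque`, `rwr_score`, `label`.
#' @export
label_pairs <- function(kg, plaque_ids = kg_plaques(kg), r = 0.7, q = 0.5,
                        tol = 1e-10, max_iter = 10000) {
  if (!(q > 0 && q <= 1)) abort("input error: positive fraction q must be in (0,1]")
  symptoms <- sort(kg_symptoms(kg))
  n_pos <- ceiling(q * length(symptoms))
  out <- purrr::map_dfr(plaque_ids, function(t) {
    res <- rwr(kg, seeds = t, r = r, tol = tol, max_iter = max_iter)
    sc <- res$scores[symptoms]
    lab <- integer(length(symptoms))
    if (all(sc == 0)) {
      warn(sprintf("plaque '%s' is disconnected from all symptoms; labels all 0", t))
    } else {
      ord <- order(-sc, symptoms)
      lab[ord[seq_len(n_pos)]] <- 1L
    }
    tibble(symptom = symptoms, plaque = t, rwr_score = unname(sc), label = lab)
  })
  arrange(out, .data$plaque, .data$symptom)
}
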