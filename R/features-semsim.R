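# Wang-measure term semantic similarity with best-match-average (BMA)
# combination over gene term sets and over gene sets.  Semantic
# contributions decay along ancestor edges: is_a 0.8, part_of 0.6 by
# default.

DEFAULT_SEM_WEIGHTS <- c(is_a = 0.8, part_of = 0.6)

#' Semantic-contribution values of a term's ancestor closure
#'
#' For term `A`, `S_A(A) = 1` and for any ancestor `t`,
#' `S_A(t) = max over child edges (w_e * S_A(child))` taken over children
#' of `t` inside the closure — the strongest weighted path down to `A`.
#'
#' @param ontology A `plaquekg_ontology`.
#' @param term Term id.
#' @param weights Named edge weights per relation.
#' @return Named numeric vector over the term and its ancestors.
#' @export
term_svalues <- function(ontology, term, weights = DEFAULT_SEM_WEIGHTS) {
  if (!term %in% ontology$terms) abort(sprintf("unknown term '%s'", term))
  closure <- ontology_ancestors(ontology, term, include_self = TRUE)
  e <- ontology$edges[ontology$edges$child %in% closure & ontology$edges$parent %in% closure, ]
  sv <- setNames(rep(0, length(closure)), closure)
  sv[term] <- 1
  # DAG: at most |closure| relaxation sweeps reach a fixed point
  if (nrow(e) > 0) {
    w <- unname(weights[e$relation])
    repeat {
      cand <- tapply(w * sv[e$child], e$parent, max)
      upd <- pmax(sv[names(cand)], cand)
      changed <- any(upd > sv[names(cand)] + 1e-15)
      sv[names(cand)] <- upd
      if (!changed) break
    }
  }
  sv
}

#' Wang similarity between two terms
#'
#' `sim(A,B) = sum over shared closure terms of (S_A(t) + S_B(t)) divided
#' by (SV(A) + SV(B))` where `SV` is the total semantic contribution.
#'
#' @param ontology A `plaquekg_ontology`.
#' @param a,b Term ids.
#' @param weights Named edge weights per relation.
#' @return Similarity in [0,1].
#' @export
term_sim <- function(ontology, a, b, weights = DEFAULT_SEM_WEIGHTS) {
  sa <- term_svalues(ontology, a, weights)
  sb <- term_svalues(ontology, b, weights)
  shared <- intersect(names(sa), names(sb))
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

bma <- function(M) {
  # best-match average over a similarity matrix
  (sum(apply(M, 1, max)) + sum(apply(M, 2, max))) / (nrow(M) + ncol(M))
}

# Cache of pairwise term similarities shared across many set comparisons.
semsim_cache <- function(ontology, weights = DEFAULT_SEM_WEIGHTS) {
  env <- new.env(parent = emptyenv())
  env$sv <- new.env(parent = emptyenv())
  get_sv <- function(t) {
    got <- get0(t, env$sv)
    if (is.null(got)) {
      got <- term_svalues(ontology, t, weights)
      assign(t, got, env$sv)
    }
    got
  }
  env$pair <- new.env(parent = emptyenv())
  env$term_sim <- function(a, b) {
    key <- if (a <= b) paste(a, b) else paste(b, a)
    got <- get0(key, env$pair)
    if (is.null(got)) {
      sa <- get_sv(a); sb <- get_sv(b)
      shared <- intersect(names(sa), names(sb))
      got <- (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
      assign(key, got, env$pair)
    }
    got
  }
  env
}

gene_sim_cached <- function(terms_a, terms_b, cache) {
  M <- matrix(0, length(terms_a), length(terms_b))
  for (i in seq_along(terms_a)) for (j in seq_along(terms_b)) {
    M[i, j] <- cache$term_sim(terms_a[i], terms_b[j])
  }
  bma(M)
}

#' Semantic similarity between two gene sets
#'
#' Gene-pair similarity is the best-match average over the two genes' term
#' sets (Wang term similarity); set similarity is the best-match average
#' over all gene pairs.  Genes without annotations are dropped with a
#' warning.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param ontology A `plaquekg_ontology` carrying gene annotations.
#' @param weights Named edge weights per relation.
#' @param cache Optional shared [semsim_cache()] for repeated calls.
#' @return Similarity in [0,1].
#' @export
semsim <- function(set_a, set_b, ontology, weights = DEFAULT_SEM_WEIGHTS, cache = NULL) {
  ann <- ontology$annotations
  keep_a <- set_a[set_a %in% names(ann) & lengths(ann[set_a]) > 0]
  keep_b <- set_b[set_b %in% names(ann) & lengths(ann[set_b]) > 0]
  dropped <- length(set_a) - length(keep_a) + length(set_b) - length(keep_b)
  if (dropped > 0) warn(sprintf("semsim: dropped %d unannotated gene(s)", dropped))
  if (length(keep_a) == 0 || length(keep_b) == 0) {
    abort("undefined similarity: a gene set has no annotated members")
  }
  cache <- cache %||% semsim_cache(ontology, weights)
  M <- matrix(0, length(keep_a), length(keep_b))
  for (i in seq_along(keep_a)) for (j in seq_along(keep_b)) {
    M[i, j] <- gene_sim_cached(ann[[keep_a[i]]], ann[[keep_b[j]]], cache)
  }
  bma(M)
}

#' Semantic-similarity table over all symptom-plaque pairs
#'
#' @param symptom_sets,plaque_sets Named lists of gene-id vectors.
#' @param ontology A `plaquekg_ontology` with annotations.
#' @param weights Named edge weights per relation.
#' @return Tibble with `symptom`, `plaque`, `semsim`.
#' @export
semsim_table <- function(symptom_sets, plaque_sets, ontology, weights = DEFAULT_SEM_WEIGHTS) {
  cache <- semsim_cache(ontology, weights)
  grid <- tidyr::expand_grid(symptom = names(symptom_sets), plaque = names(plaque_sets))
  grid$semsim <- map_dbl(seq_len(nrow(grid)), function(r) {
    suppressWarnings(semsim(symptom_sets[[grid$symptom[r]]],
                            plaque_sets[[grid$plaque[r]]],
                            ontology, weights, cache))
  })
  grid
}
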