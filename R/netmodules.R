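#' Patient-by-gene coefficient matrix from the association model
#'
#' Each gene's relevance to a symptom is the mean out-of-fold predicted
#' score of the symptom's pairs whose annotation union contains the gene;
#' a patient's entry for a gene is the sum of relevances over the
#' patient's symptoms.  Traits are the 0/1 plaque flags plus any numeric
#' covariates.
#'
#' @param records Record tibble.
#' @param report A `plaquekg_cv` report with out-of-fold scores.
#' @param symptom_sets,plaque_sets Named lists of gene-id vectors.
#' @return A list with `M` (patients x genes matrix) and `traits`
#'   (patients x traits tibble).
#' @export
coefficient_matrix <- function(records, report, symptom_sets, plaque_sets) {
  genes <- sort(unique(c(unlist(symptom_sets), unlist(plaque_sets))))
  scores <- report$scores
  symptoms <- unique(scores$symptom)
  rel <- matrix(0, length(symptoms), length(genes), dimnames = list(symptoms, genes))
  for (s in symptoms) {
    rows <- scores[scores$symptom == s, ]
    for (i in seq_len(nrow(rows))) {
      gs <- unique(c(symptom_sets[[s]], plaque_sets[[rows$plaque[i]]]))
      gs <- intersect(gs, genes)
      rel[s, gs] <- rel[s, gs] + rows$score[i]
    }
    rel[s, ] <- rel[s, ] / nrow(rows)
  }
  M <- matrix(0, nrow(records), length(genes),
              dimnames = list(records$patient_id, genes))
  for (i in seq_len(nrow(records))) {
    pres <- intersect(records$symptoms[[i]], symptoms)
    if (length(pres) > 0) M[i, ] <- colSums(rel[pres, , drop = FALSE])
  }
  traits <- tibble(patient_id = records$patient_id)
  for (p in sort(unique(unlist(records$plaques)))) {
    traits[[p]] <- map_int(records$plaques, ~ as.integer(p %in% .x))
  }
  covar <- names(records)[vapply(records, is.numeric, logical(1))]
  for (cv in covar) traits[[cv]] <- records[[cv]]
  list(M = M, traits = traits)
}

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the `|cor|^beta` adjacency, computes
#' node connectivity, and fits `log10 p(k)` against `log10 k` over
#' connectivity bins.  The signed fit index is `-sign(slope) * R^2`, so a
#' rising degree law can never qualify.  The chosen power is the smallest
#' candidate whose signed index reaches `rsq_cut`, else the argmax.
#'
#' @param M Sample x gene numeric matrix.
#' @param betas Candidate powers (default 1..20).
#' @param rsq_cut Scale-free fit threshold (default 0.8).
#' @param n_bins Connectivity histogram bins.
#' @param min_mean_k Smallest acceptable mean connectivity: powers that
#'   leave the network essentially empty are not considered (the fit index
#'   is meaningless there), unless every candidate falls below the floor.
#' @return A list with the chosen `beta` and a tibble `fit` of per-power
#'   signed R^2, slope and mean connectivity.
#' @export
pick_soft_threshold <- function(M, betas = 1:20, rsq_cut = 0.8, n_bins = 10,
                                min_mean_k = 1) {
  if (length(betas) == 0) abort("input error: empty candidate power list")
  check_matrix_columns(M)
  C <- abs(cor(M))
  fit <- purrr::map_dfr(betas, function(b) {
    A <- C^b
    k <- colSums(A) - 1
    tibble(beta = b, !!!scale_free_fit(k, n_bins), mean_k = mean(k))
  })
  signed <- fit$rsq * (fit$slope < 0)
  allowed <- fit$mean_k >= min_mean_k
  if (!any(allowed)) allowed <- rep(TRUE, nrow(fit))
  ok <- which(allowed & signed >= rsq_cut)
  if (length(ok) > 0) {
    beta <- fit$beta[ok[1]]
  } else if (any(signed[allowed] > 0)) {
    beta <- fit$beta[which(allowed)[which.max(signed[allowed])]]
  } else {
    # no power gives a decaying degree law at workable connectivity;
    # fall back to the conventional unsigned-network default
    beta <- fit$beta[which.min(abs(fit$beta - 6))]
    warn("no candidate power satisfies the scale-free criterion; using the conventional default")
  }
  list(beta = beta, fit = fit)
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(rsq = 0, slope = 0))
  brk <- seq(min(k), max(k), length.out = n_bins + 1)  # equal-width bins
  bin <- cut(k, brk, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.vector(table(bin)) / length(k)
  keep <- pk > 0 & !is.na(dk)
  if (sum(keep) < 3) return(list(rsq = 0, slope = 0))
  f <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  list(rsq = summary(f)$r.squared, slope = unname(coef(f)[2]))
}

check_matrix_columns <- function(M) {
  v <- apply(M, 2, sd)
  bad <- colnames(M)[v == 0 | is.na(v)]
  if (length(bad) > 0) {
    abort(sprintf("degenerate matrix: zero-variance column(s) %s%s",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else ""))
  }
  invisible(M)
}

#' Soft-thresholded correlation adjacency
#'
#' `a_ij = |cor(g_i, g_j)|^beta` — unsigned network, unit diagonal.
#'
#' @param M Sample x gene matrix with >= 3 rows.
#' @param beta Soft-thresholding power.
#' @return Symmetric gene x gene matrix in [0,1].
#' @export
adjacency_matrix <- function(M, beta) {
  if (nrow(M) < 3) abort("input error: adjacency needs >= 3 samples")
  check_matrix_columns(M)
  A <- abs(cor(M))^beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the connectivity.
#'
#' @param A Adjacency from [adjacency_matrix()].
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
tom_similarity <- function(A) {
  stopifnot(isSymmetric(unname(A)))
  k <- colSums(A) - diag(A)
  L <- A %*% A
  l <- L - outer(diag(A), rep(1, ncol(A))) * A - A * outer(rep(1, nrow(A)), diag(A))
  kmin <- outer(k, k, pmin)
  TOM <- (l + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  TOM
}

#' Detect gene modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage clustering on `1 - TOM`, a single static cut, and
#' small-cluster merging into module 0 (grey).  Surviving modules are
#' relabelled by decreasing size and given the conventional colour names;
#' each module's eigengene is the first principal component of its
#' standardized columns, sign-oriented to correlate positively with its
#' genes.
#'
#' @param M Sample x gene matrix (used for eigengenes).
#' @param beta Soft power; computed via [pick_soft_threshold()] if `NULL`.
#' @param min_size Smallest retained module.
#' @param cut_height Static cut on the dendrogram; `NULL` cuts at 0.99 of
#'   the tallest merge, which tracks the near-unit dissimilarity plateau
#'   that separates TOM modules.
#' @return A `plaquekg_modules`: gene -> module vector, colour map,
#'   eigengene matrix, the dendrogram and the chosen power.
#' @export
detect_modules <- function(M, beta = NULL, min_size = 10, cut_height = NULL) {
  if (is.null(beta)) beta <- pick_soft_threshold(M)$beta
  A <- adjacency_matrix(M, beta)
  TOM <- tom_similarity(A)
  d <- as.dist(1 - TOM)
  tree <- hclust(d, method = "average")
  # guard against floating-point jitter breaking cutree's monotonicity check
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  h <- cut_height %||% (0.99 * max(tree$height))
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  modules <- integer(length(raw))
  names(modules) <- colnames(M)
  kept_sorted <- keep[order(-sizes[keep])]
  for (i in seq_along(kept_sorted)) modules[raw == as.integer(kept_sorted[i])] <- i
  if (all(modules == 0)) warn("all genes fell into module 0 (grey); no modules detected")

  mods <- sort(unique(modules[modules > 0]))
  eig <- NULL
  if (length(mods) > 0) {
    eig <- sapply(mods, function(m) {
      X <- scale(M[, modules == m, drop = FALSE])
      pc <- prcomp(X, center = FALSE, scale. = FALSE)$x[, 1]
      if (mean(cor(pc, X)) < 0) pc <- -pc
      pc
    })
    colnames(eig) <- paste0("ME", mods)
    rownames(eig) <- rownames(M)
  }
  structure(list(modules = modules, colors = module_colors(modules),
                 eigengenes = eig, beta = beta, tree = tree,
                 cut_height = h, min_size = min_size),
            class = "plaquekg_modules")
}

MODULE_PALETTE <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple")

module_colors <- function(modules) {
  col <- rep("grey", length(modules))
  pos <- modules > 0
  col[pos] <- MODULE_PALETTE[pmin(modules[pos], length(MODULE_PALETTE))]
  setNames(col, names(modules))
}

#' @export
print.plaquekg_modules <- function(x, ...) {
  tab <- table(x$colors)
  cat(sprintf("<plaquekg_modules> beta = %d, %d module(s): %s\n",
              x$beta, length(unique(x$modules[x$modules > 0])),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Module-trait correlation
#'
#' Pearson correlation between every module eigengene and every numeric
#' trait, with two-sided p-values from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param assignment A `plaquekg_modules` with eigengenes.
#' @param traits Tibble or data frame of numeric traits (0/1 flags fine);
#'   a `patient_id` column is ignored.
#' @return Tibble with `module`, `trait`, `r`, `p`.
#' @export
module_trait <- function(assignment, traits) {
  eig <- assignment$eigengenes
  if (is.null(eig)) abort("input error: no modules, no eigengenes")
  tr <- as.data.frame(traits)
  tr$patient_id <- NULL
  tr <- tr[vapply(tr, is.numeric, logical(1))]
  n <- nrow(eig)
  if (n < 3) abort("input error: module-trait correlation needs n >= 3")
  if (nrow(tr) != n) abort("input error: trait rows must match eigengene rows")
  out <- tidyr::expand_grid(module = colnames(eig), trait = names(tr))
  out$r <- map_dbl(seq_len(nrow(out)), ~ cor(eig[, out$module[.x]], tr[[out$trait[.x]]]))
  out$p <- map_dbl(out$r, function(r) {
    if (is.na(r)) return(NA_real_)
    if (abs(r) >= 1) return(0)
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), n - 2)
  })
  out
}
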