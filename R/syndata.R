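#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data module: cohort size and symptom
#' vocabulary, per-type plaque prevalence, the logistic symptom model
#' (baseline log-odds plus a log-odds bump for planted symptom-plaque
#' associations), the scale-free interaction network, annotation set sizes,
#' the ontology shape, and the planted-module expression design.
#'
#' The generators are pure functions of the configuration: the same
#' `seed` always reproduces the same cohort, network, annotations and
#' expression matrix.  Each generation stage derives its own stream from
#' `seed` plus a fixed per-stage offset, so stages can be re-run
#' independently without disturbing one another.
#'
#' @param n_patients Number of patient records.
#' @param n_symptoms Size of the symptom vocabulary.
#' @param plaque_prevalence Named vector of per-type plaque probabilities in
#'   (0,1); types are drawn independently, so a patient may carry several
#'   plaque types or none.
#' @param base_symptom_logit Baseline log-odds of any symptom.
#' @param effect_size Log-odds increase per present plaque type truly
#'   associated with the symptom (>= 0).
#' @param true_pair_density Fraction of all symptom-plaque pairs planted as
#'   true associations, in (0,1).
#' @param n_genes Number of genes in the interaction network.
#' @param genes_per_symptom,genes_per_plaque Annotation set sizes.
#' @param ontology_depth,ontology_branching Shape of the generated term DAG.
#' @param n_expression_samples Total expression samples (half case, half
#'   control).
#' @param n_planted_modules Number of co-expressed gene modules planted in
#'   the expression matrix.
#' @param module_shift Case-minus-control mean shift on module-1 genes, in
#'   standard-deviation units.
#' @param seed Integer master seed.
#' @return A `plaquekg_config` list.
#' @examples
#' cfg <- generator_config(n_patients = 200, n_symptoms = 8, seed = 1)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$records)
#' @export
generator_config <- function(n_patients = 1498,
                             n_symptoms = 35,
                             plaque_prevalence = c(calcified = 0.3, noncalcified = 0.3, mixed = 0.3),
                             base_symptom_logit = -2,
                             effect_size = 2,
                             true_pair_density = 0.15,
                             n_genes = 300,
                             genes_per_symptom = 15,
                             genes_per_plaque = 20,
                             ontology_depth = 4,
                             ontology_branching = 3,
                             n_expression_samples = 100,
                             n_planted_modules = 3,
                             module_shift = 2,
                             seed = 1L) {
  cfg <- list(
    n_patients = n_patients, n_symptoms = n_symptoms,
    plaque_prevalence = plaque_prevalence,
    base_symptom_logit = base_symptom_logit, effect_size = effect_size,
    true_pair_density = true_pair_density,
    n_genes = n_genes, genes_per_symptom = genes_per_symptom,
    genes_per_plaque = genes_per_plaque,
    ontology_depth = ontology_depth, ontology_branching = ontology_branching,
    n_expression_samples = n_expression_samples,
    n_planted_modules = n_planted_modules, module_shift = module_shift,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "plaquekg_config")
}

validate_config <- function(cfg) {
  counts <- c("n_patients", "n_symptoms", "n_genes", "genes_per_symptom",
              "genes_per_plaque", "ontology_depth", "ontology_branching",
              "n_expression_samples", "n_planted_modules")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      abort(sprintf("configuration error: `%s` must be a count >= 1 (got %s)", f, deparse(v)))
    }
  }
  pp <- cfg$plaque_prevalence
  if (is.null(names(pp)) || !all(names(pp) %in% PLAQUE_LEVELS)) {
    abort("configuration error: `plaque_prevalence` must be named with plaque types")
  }
  probs <- c(pp, true_pair_density = cfg$true_pair_density)
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs >= 1)) {
    abort("configuration error: probabilities must lie strictly in (0,1)")
  }
  if (!is.finite(cfg$effect_size) || cfg$effect_size < 0) {
    abort("configuration error: `effect_size` must be >= 0")
  }
  invisible(cfg)
}

# Per-stage seed offsets: fixed so stages draw from disjoint RNG streams.
stage_seed <- function(cfg, stage) {
  off <- c(cohort = 101L, ppin = 202L, annotations = 303L, expression = 404L)
  cfg$seed + off[[stage]]
}

symptom_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_symptoms))
gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

#' Generate a synthetic patient cohort with planted symptom-plaque pairs
#'
#' Each patient draws each plaque type independently at its prevalence
#' (the empty set means "no plaque").  Symptom `s` is then present with
#' probability `plogis(alpha + beta * m)` where `m` counts the patient's
#' present plaque types truly associated with `s`: presence of an
#' associated plaque raises the symptom's log-odds additively.
#'
#' @param cfg A [generator_config()].
#' @return A list with `records` (a tibble with list-columns `symptoms` and
#'   `plaques` plus numeric covariates) and `truth` (the planted
#'   `true_pairs` tibble and id vocabularies).
#' @export
generate_cohort <- function(cfg) {
  validate_config(cfg)
  set.seed(stage_seed(cfg, "cohort"))
  syms <- symptom_ids(cfg)
  plqs <- names(cfg$plaque_prevalence)
  n_pairs <- length(syms) * length(plqs)
  n_true <- max(1L, ceiling(cfg$true_pair_density * n_pairs))
  all_pairs <- tidyr::expand_grid(symptom = syms, plaque = plqs)
  true_idx <- sample.int(n_pairs, n_true)
  true_pairs <- all_pairs[sort(true_idx), ]

  # plaque draws: n x P Bernoulli at prevalence
  P <- length(plqs)
  plq_mat <- matrix(rbinom(cfg$n_patients * P, 1, rep(cfg$plaque_prevalence, each = cfg$n_patients)),
                    nrow = cfg$n_patients, dimnames = list(NULL, plqs))
  # bump matrix: symptom x plaque indicator of true pairs
  bump <- matrix(0, length(syms), P, dimnames = list(syms, plqs))
  bump[cbind(match(true_pairs$symptom, syms), match(true_pairs$plaque, plqs))] <- 1
  # logits: n x S
  logits <- cfg$base_symptom_logit + cfg$effect_size * (plq_mat %*% t(bump))
  sym_mat <- matrix(rbinom(length(logits), 1, plogis(as.vector(logits))),
                    nrow = cfg$n_patients, dimnames = list(NULL, syms))

  records <- tibble(
    patient_id = sprintf("P%04d", seq_len(cfg$n_patients)),
    symptoms = map(seq_len(cfg$n_patients), ~ syms[sym_mat[.x, ] == 1]),
    plaques = map(seq_len(cfg$n_patients), ~ plqs[plq_mat[.x, ] == 1]),
    age = round(rnorm(cfg$n_patients, 62, 10), 1),
    ldl = round(rnorm(cfg$n_patients, 3.0, 0.9), 2)
  )
  truth <- list(true_pairs = true_pairs, symptoms = syms, plaques = plqs)
  list(records = records, truth = truth)
}

#' Generate a scale-free protein-protein interaction network
#'
#' Preferential-attachment growth yields the heavy-tailed degree
#' distribution typical of curated interactomes; every edge carries an
#' integer confidence score uniform in 400..1000, i.e. already above the
#' usual combined-score retention threshold.
#'
#' @param cfg A [generator_config()] with `n_genes >= 3`.
#' @return A tibble with columns `gene1`, `gene2`, `combined_score`.
#' @export
generate_ppin <- function(cfg) {
  validate_config(cfg)
  if (cfg$n_genes < 3) abort("configuration error: `n_genes` must be >= 3")
  set.seed(stage_seed(cfg, "ppin"))
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = 2, directed = FALSE)
  igraph::V(g)$name <- gene_ids(cfg)
  el <- igraph::as_edgelist(g)
  tibble(
    gene1 = el[, 1], gene2 = el[, 2],
    combined_score = sample(400:1000, nrow(el), replace = TRUE)
  )
}

#' Generate annotation gene sets and a term ontology
#'
#' Symptom sets are uniform draws from the interaction network.  For every
#' planted pair (s, t) the plaque set for t is drawn from the <= 2-hop
#' network neighbourhood of s's genes, preferring closer genes, so truly
#' associated pairs share genes, sit at shorter graph distances and end up
#' with overlapping ontology annotations.  The ontology is a rooted DAG of
#' the configured depth and branching with `is_a` tree edges plus sparse
#' extra `part_of` parents.
#'
#' @param cfg A [generator_config()].
#' @param ppin Interaction edge tibble from [generate_ppin()].
#' @param truth Truth list from [generate_cohort()].
#' @return A list with `symptom_sets`, `plaque_sets` (named lists of gene-id
#'   vectors) and `ontology` (a `plaquekg_ontology` carrying gene-to-term
#'   annotations).
#' @export
generate_annotations <- function(cfg, ppin, truth) {
  validate_config(cfg)
  set.seed(stage_seed(cfg, "annotations"))
  g <- igraph::graph_from_data_frame(ppin[, c("gene1", "gene2")], directed = FALSE)
  genes <- igraph::V(g)$name

  symptom_sets <- lapply(truth$symptoms, function(s) sort(sample(genes, min(cfg$genes_per_symptom, length(genes)))))
  names(symptom_sets) <- truth$symptoms

  hop_weight <- c(0.4, 0.4, 0.2)  # hop 0 / 1 / 2 preference
  plaque_sets <- lapply(truth$plaques, function(t) {
    true_syms <- truth$true_pairs$symptom[truth$true_pairs$plaque == t]
    if (length(true_syms) == 0) return(sort(sample(genes, min(cfg$genes_per_plaque, length(genes)))))
    seed_genes <- unique(unlist(symptom_sets[true_syms]))
    picked <- character(0)
    for (i in seq_len(cfg$genes_per_plaque)) {
      anchor <- sample(seed_genes, 1)
      hop <- sample(0:2, 1, prob = hop_weight)
      pool <- if (hop == 0) anchor else {
        nb <- igraph::ego(g, order = hop, nodes = anchor, mindist = hop)[[1]]$name
        if (length(nb) == 0) anchor else nb
      }
      cand <- setdiff(pool, picked)
      if (length(cand) == 0) cand <- setdiff(genes, picked)
      picked <- c(picked, sample(cand, 1))
    }
    if (length(picked) < cfg$genes_per_plaque) {
      warn(sprintf("neighbourhood of plaque '%s' too small; topping up uniformly", t))
      picked <- c(picked, sample(setdiff(genes, picked), cfg$genes_per_plaque - length(picked)))
    }
    sort(picked)
  })
  names(plaque_sets) <- truth$plaques

  ont <- make_ontology(cfg$ontology_depth, cfg$ontology_branching)
  leaves <- ontology_leaves(ont)
  # annotation scheme: each symptom anchors one leaf term; its genes and
  # their 1-hop neighbours inherit that term, so network proximity implies
  # term sharing.  Remaining genes get random leaf terms.
  anno <- new.env(parent = emptyenv())
  add_term <- function(gs, term) for (gg in gs) assign(gg, union(get0(gg, anno, ifnotfound = character(0)), term), anno)
  for (s in truth$symptoms) {
    home <- sample(leaves, 1)
    gs <- symptom_sets[[s]]
    nb <- unique(unlist(igraph::ego(g, order = 1, nodes = gs)))
    add_term(c(gs, igraph::V(g)$name[nb]), home)
  }
  for (gg in genes) {
    extra <- sample(leaves, sample(1:2, 1))
    add_term(gg, extra)
  }
  ont$annotations <- lapply(setNames(nm = genes), function(gg) sort(get0(gg, anno, ifnotfound = character(0))))
  list(symptom_sets = symptom_sets, plaque_sets = plaque_sets, ontology = ont)
}

make_ontology <- function(depth, branching) {
  terms <- "T0001"
  edges <- tibble(child = character(0), parent = character(0), relation = character(0))
  level <- terms
  counter <- 1L
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("T%04d", counter)
        edges <- bind_rows(edges, tibble(child = id, parent = p, relation = "is_a"))
        nxt <- c(nxt, id)
      }
    }
    # sparse extra part_of parents within the previous level keep it a DAG
    if (length(level) > 1) {
      for (id in nxt) {
        if (runif(1) < 0.2) {
          p2 <- sample(setdiff(level, edges$parent[edges$child == id]), 1)
          edges <- bind_rows(edges, tibble(child = id, parent = p2, relation = "part_of"))
        }
      }
    }
    level <- nxt
    terms <- c(terms, nxt)
  }
  new_ontology(terms = terms, edges = edges, root = "T0001")
}

#' Generate a planted-module expression matrix
#'
#' Genes of a module share a latent factor (within-module correlation
#' exceeds between-module), background genes are pure noise, and case
#' samples are shifted by `module_shift` standard deviations on module-1
#' genes.
#'
#' @param cfg A [generator_config()].
#' @param truth Truth list from [generate_cohort()] (gene ids are taken
#'   from the configured gene vocabulary).
#' @param module_size Genes per planted module; defaults to 40 or what
#'   the gene pool allows.
#' @param n_background Unstructured background genes (assigned module 0);
#'   defaults to one module's worth.
#' @return A list with `expr` (gene x sample matrix), `labels` (tibble of
#'   sample ids and case/control labels) and `modules` (named integer
#'   vector gene -> planted module, 0 = background).
#' @export
generate_expression <- function(cfg, truth, module_size = NULL, n_background = NULL) {
  validate_config(cfg)
  set.seed(stage_seed(cfg, "expression"))
  M <- cfg$n_planted_modules
  module_size <- module_size %||% max(5L, min(40L, cfg$n_genes %/% (M + 1L)))
  n_background <- n_background %||% module_size
  need <- M * module_size + n_background
  genes <- gene_ids(cfg)
  if (need > length(genes)) abort("configuration error: not enough genes for the planted modules")
  chosen <- sample(genes, need)
  modules <- rep(c(seq_len(M), 0L), times = c(rep(module_size, M), n_background))
  names(modules) <- chosen

  n <- cfg$n_expression_samples
  n_case <- ceiling(n / 2)
  labels <- tibble(
    sample = sprintf("E%03d", seq_len(n)),
    label = rep(c("case", "control"), c(n_case, n - n_case))
  )
  rho <- 0.5
  factors <- matrix(rnorm(M * n), M, n)
  expr <- matrix(rnorm(need * n), need, n, dimnames = list(chosen, labels$sample))
  for (m in seq_len(M)) {
    rows <- modules == m
    expr[rows, ] <- sqrt(rho) * matrix(factors[m, ], sum(rows), n, byrow = TRUE) +
      sqrt(1 - rho) * expr[rows, ]
  }
  expr[modules == 1L, labels$label == "case"] <- expr[modules == 1L, labels$label == "case"] + cfg$module_shift
  list(expr = expr, labels = labels, modules = modules)
}

#' Run every generator and assemble the complete synthetic study
#'
#' @param cfg A [generator_config()].
#' @return A list with `records`, `ppin`, `symptom_sets`, `plaque_sets`,
#'   `ontology`, `expression` and `truth` (planted pairs, gene sets and
#'   module memberships).
#' @export
simulate_study <- function(cfg = generator_config()) {
  cohort <- generate_cohort(cfg)
  ppin <- generate_ppin(cfg)
  anno <- generate_annotations(cfg, ppin, cohort$truth)
  expr <- generate_expression(cfg, cohort$truth)
  truth <- c(cohort$truth, list(
    symptom_gene_sets = anno$symptom_sets,
    plaque_gene_sets = anno$plaque_sets,
    planted_modules = expr$modules
  ))
  list(records = cohort$records, ppin = ppin,
       symptom_sets = anno$symptom_sets, plaque_sets = anno$plaque_sets,
       ontology = anno$ontology, expression = expr, truth = truth)
}

#' Write a simulated study to a directory of plain-text files
#'
#' Emits `records.tsv`, `ppin.tsv`, `symptoms.gmt`, `plaques.gmt`,
#' `ontology.obo`, `annotations.tsv`, `expression.tsv`,
#' `expression_labels.tsv` and `truth.json`, all readable by the package's
#' own parsers.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the simulated study list.
#' @export
simulate_to_dir <- function(cfg, dir) {
  study <- simulate_study(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_records(study$records, file.path(dir, "records.tsv"))
  write_ppin(study$ppin, file.path(dir, "ppin.tsv"))
  write_gmt(study$symptom_sets, file.path(dir, "symptoms.gmt"))
  write_gmt(study$plaque_sets, file.path(dir, "plaques.gmt"))
  write_obo(study$ontology, file.path(dir, "ontology.obo"))
  write_gene2term(study$ontology$annotations, file.path(dir, "annotations.tsv"))
  expr_df <- as.data.frame(study$expression$expr)
  expr_df <- cbind(gene = rownames(study$expression$expr), expr_df)
  readr::write_tsv(expr_df, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$expression$labels, file.path(dir, "expression_labels.tsv"))
  truth_json <- list(
    true_pairs = study$truth$true_pairs,
    planted_modules = as.list(study$truth$planted_modules),
    symptom_gene_sets = study$truth$symptom_gene_sets,
    plaque_gene_sets = study$truth$plaque_gene_sets
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(study)
}
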