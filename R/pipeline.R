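#' Run the full association-mining pipeline on a synthetic study
#'
#' Executes every stage in order: simulate, build and fuse the graphs,
#' compute the three feature channels, label pairs by random walk with
#' restart, cross-validate the KNN ablations, select associations, build
#' the coefficient matrix and detect modules, run enrichment on module
#' genes, and validate detected-module signatures on the expression data.
#'
#' The positive fraction `label_q` defaults to the configured
#' `true_pair_density`: the share of pairs labelled positive should match
#' the association rate the analyst expects, and for the synthetic study
#' that rate is known by construction.
#'
#' @param cfg A [generator_config()].
#' @param label_q Positive fraction per plaque for [label_pairs()];
#'   `NULL` uses `cfg$true_pair_density`.
#' @param rwr_r Restart probability.
#' @param cnn_cfg A [cnn_train_config()] (or `NULL` to skip the CNN).
#' @param k_neighbors,folds KNN settings.
#' @param score_cutoff Selection cutoff on out-of-fold scores.
#' @param run_modules Run the module-detection and downstream stages.
#' @return A `plaquekg_run` with every stage output plus a `manifest` of
#'   configuration, seeds and per-stage counts.
#' @export
run_pipeline <- function(cfg = generator_config(),
                         label_q = NULL,
                         rwr_r = 0.7,
                         cnn_cfg = cnn_train_config(epochs = 150, lr = 0.02, seed = cfg$seed),
                         k_neighbors = 6, folds = 10,
                         score_cutoff = 0.5,
                         run_modules = TRUE) {
  label_q <- label_q %||% cfg$true_pair_density
  study <- simulate_study(cfg)

  clinical <- build_clinical_network(study$records)
  kg <- fuse_graph(clinical, study$symptom_sets, study$plaque_sets, study$ppin)

  rows <- pair_features(kg, study$records, study$symptom_sets, study$plaque_sets,
                        study$ontology, cnn_cfg = cnn_cfg)
  labels <- label_pairs(kg, r = rwr_r, q = label_q)
  rows <- left_join(rows, select(labels, "symptom", "plaque", "rwr_score", "label"),
                    by = c("symptom", "plaque"))

  ablation <- run_ablation(rows, k_neighbors = k_neighbors, folds = folds, seed = cfg$seed)
  selection <- select_associations(ablation$reports$A, study$symptom_sets,
                                   study$plaque_sets, score_cutoff = score_cutoff)

  modules <- traits <- mt <- enrichment <- validation <- NULL
  if (run_modules) {
    cm <- coefficient_matrix(study$records, ablation$reports$A,
                             study$symptom_sets, study$plaque_sets)
    # screen uninformative genes: constant columns carry no coexpression signal
    keep <- apply(cm$M, 2, sd) > 0
    if (any(!keep)) inform(sprintf("module stage: screening out %d constant gene column(s)", sum(!keep)))
    cm$M <- cm$M[, keep, drop = FALSE]
    modules <- detect_modules(cm$M)
    traits <- cm$traits
    if (!is.null(modules$eigengenes)) mt <- module_trait(modules, traits)
    term2gene <- invert_annotations(study$ontology$annotations)
    universe <- names(study$ontology$annotations)
    enrichment <- lapply(split(names(modules$modules), modules$modules), function(gs) {
      gs <- intersect(gs, universe)
      if (length(gs) == 0) return(NULL)
      enrich(gs, term2gene, universe)
    })
    expr <- study$expression
    validation <- lapply(sort(unique(modules$modules[modules$modules > 0])), function(m) {
      gs <- intersect(names(modules$modules)[modules$modules == m], rownames(expr$expr))
      if (length(gs) == 0) return(NULL)
      signature_roc(expr$expr, expr$labels$label, gs)
    })
  }

  manifest <- list(
    config = unclass(cfg),
    label_q = label_q, rwr_r = rwr_r,
    k_neighbors = k_neighbors, folds = folds, score_cutoff = score_cutoff,
    counts = list(
      patients = nrow(study$records),
      clinical_nodes = nrow(clinical$nodes), clinical_edges = nrow(clinical$edges),
      kg_nodes = igraph::vcount(kg), kg_edges = igraph::ecount(kg),
      pairs = nrow(rows), positives = sum(rows$label),
      selected = unname(selection$counts["pairs"]),
      hub_genes = unname(selection$counts["genes"]),
      modules = if (!is.null(modules)) sum(unique(modules$modules) > 0) else NA
    )
  )
  structure(list(study = study, clinical = clinical, kg = kg, features = rows,
                 ablation = ablation, selection = selection,
                 modules = modules, traits = traits, module_trait = mt,
                 enrichment = enrichment, validation = validation,
                 manifest = manifest),
            class = "plaquekg_run")
}

invert_annotations <- function(annotations) {
  df <- tibble(gene = rep(names(annotations), lengths(annotations)),
               term = unlist(annotations, use.names = FALSE))
  lapply(split(df$gene, df$term), unique)
}

#' @export
print.plaquekg_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<plaquekg_run>\n")
  cat(sprintf("  cohort: %d patients; clinical network %d nodes / %d edges\n",
              cnt$patients, cnt$clinical_nodes, cnt$clinical_edges))
  cat(sprintf("  knowledge graph: %d nodes / %d edges\n", cnt$kg_nodes, cnt$kg_edges))
  cat(sprintf("  pairs: %d (%d positive); selected %d with %d hub genes\n",
              cnt$pairs, cnt$positives, cnt$selected, cnt$hub_genes))
  print(x$ablation$summary)
  invisible(x)
}
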