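#' Assemble the full feature table for every symptom-plaque pair
#'
#' Joins the three channels: network topology (`topo_dist`, `topo_euclid`),
#' association rules (`lift`, `cnn_score`) and biological-process semantic
#' similarity (`semsim`).
#'
#' @param kg Fused knowledge graph.
#' @param records Record tibble.
#' @param symptom_sets,plaque_sets Named lists of gene-id vectors.
#' @param ontology A `plaquekg_ontology` with annotations.
#' @param cnn_cfg A [cnn_train_config()]; set `NULL` to skip the
#'   convolutional correction (cnn_score = 0.5 for all pairs).
#' @param cnn_max_train Largest patient subsample used to fit the
#'   convolutional model (all patients are still scored); the subsample is
#'   drawn deterministically from the training seed.
#' @return Tibble with one row per (symptom, plaque) and the five channel
#'   columns.
#' @export
pair_features <- function(kg, records, symptom_sets, plaque_sets, ontology,
                          cnn_cfg = cnn_train_config(), cnn_max_train = 600) {
  symptoms <- kg_symptoms(kg)
  plaques <- kg_plaques(kg)
  topo <- topo_features(kg, symptoms, plaques)
  lifts <- lift_table(records, symptoms = symptoms, plaques = plaques)
  if (!is.null(cnn_cfg)) {
    pm <- build_patient_matrices(records, lifts)
    labels <- plaque_label_matrix(records, pm)
    n <- nrow(records)
    if (n > cnn_max_train) {
      set.seed(cnn_cfg$seed)
      idx <- sort(sample.int(n, cnn_max_train))
      model <- train_cnn(pm_subset(pm, idx), labels[idx, , drop = FALSE], cnn_cfg)
    } else {
      model <- train_cnn(pm, labels, cnn_cfg)
    }
    cnn <- cnn_pair_scores(model, pm, records)
  } else {
    cnn <- tidyr::expand_grid(symptom = symptoms, plaque = plaques) |>
      mutate(cnn_score = 0.5)
  }
  sem <- semsim_table(symptom_sets[intersect(names(symptom_sets), symptoms)],
                      plaque_sets[intersect(names(plaque_sets), plaques)],
                      ontology)
  topo |>
    left_join(select(lifts, "symptom", "plaque", "lift"), by = c("symptom", "plaque")) |>
    left_join(cnn, by = c("symptom", "plaque")) |>
    left_join(sem, by = c("symptom", "plaque")) |>
    mutate(
      lift = ifelse(is.na(.data$lift), 0, .data$lift),
      semsim = ifelse(is.na(.data$semsim), 0, .data$semsim)
    )
}
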