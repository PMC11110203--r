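#' Association-rule lift between two items
#'
#' Treats each patient record as one transaction over its symptoms and
#' plaque types.  `lift = supp(A & B) / (supp(A) * supp(B))` with supports
#' as fractions of all records; support and confidence are returned as
#' attributes.
#'
#' @param records Record tibble.
#' @param item_a,item_b Symptom or plaque ids.
#' @return The lift value, with attributes `support_a`, `support_b`,
#'   `support_ab` and `confidence` (of A => B).
#' @export
pair_lift <- function(records, item_a, item_b) {
  items <- map2(records$symptoms, records$plaques, c)
  n <- length(items)
  in_a <- map_dbl(items, ~ item_a %in% .x)
  in_b <- map_dbl(items, ~ item_b %in% .x)
  sa <- sum(in_a) / n
  sb <- sum(in_b) / n
  if (sa == 0 || sb == 0) {
    abort(sprintf("lift undefined: item '%s' has zero support",
                  if (sa == 0) item_a else item_b))
  }
  sab <- sum(in_a * in_b) / n
  structure(sab / (sa * sb),
            support_a = sa, support_b = sb, support_ab = sab,
            confidence = sab / sa)
}

#' Lift table over all symptom-plaque pairs
#'
#' @param records Record tibble.
#' @param symptoms,plaques Item vocabularies; default everything observed.
#' @return Tibble with per-pair support, confidence and lift.  Pairs whose
#'   symptom or plaque never occurs get `NA` lift.
#' @export
lift_table <- function(records, symptoms = NULL, plaques = NULL) {
  symptoms <- symptoms %||% sort(unique(unlist(records$symptoms)))
  plaques <- plaques %||% sort(unique(unlist(records$plaques)))
  n <- nrow(records)
  S <- matrix(0L, n, length(symptoms), dimnames = list(NULL, symptoms))
  P <- matrix(0L, n, length(plaques), dimnames = list(NULL, plaques))
  for (i in seq_len(n)) {
    S[i, intersect(records$symptoms[[i]], symptoms)] <- 1L
    P[i, intersect(records$plaques[[i]], plaques)] <- 1L
  }
  co <- crossprod(S, P) / n          # supp(A & B)
  sa <- colMeans(S)
  sb <- colMeans(P)
  denom <- outer(sa, sb)
  lift <- ifelse(denom > 0, co / denom, NA_real_)
  tidyr::expand_grid(symptom = symptoms, plaque = plaques) |>
    mutate(
      support_a = sa[.data$symptom],
      support_b = sb[.data$plaque],
      support_ab = co[cbind(.data$symptom, .data$plaque)],
      confidence = ifelse(.data$support_a > 0, .data$support_ab / .data$support_a, NA_real_),
      lift = lift[cbind(.data$symptom, .data$plaque)]
    )
}

#' Per-patient symptom-by-plaque lift matrices
#'
#' Every patient gets the same full symptom-by-plaque grid of lift values,
#' with the rows of symptoms the patient does not exhibit zeroed out, so
#' each matrix encodes which associations are "active" in that patient.
#'
#' @param records Record tibble.
#' @param lifts Lift table from [lift_table()] covering all pairs.
#' @return A `patient_matrices` object: a 3-d array (patient, symptom,
#'   plaque) plus the id vocabularies.
#' @export
build_patient_matrices <- function(records, lifts) {
  symptoms <- sort(unique(lifts$symptom))
  plaques <- sort(unique(lifts$plaque))
  L <- matrix(0, length(symptoms), length(plaques), dimnames = list(symptoms, plaques))
  L[cbind(lifts$symptom, lifts$plaque)] <- ifelse(is.na(lifts$lift), 0, lifts$lift)
  n <- nrow(records)
  arr <- array(0, dim = c(n, length(symptoms), length(plaques)),
               dimnames = list(records$patient_id, symptoms, plaques))
  for (i in seq_len(n)) {
    present <- intersect(records$symptoms[[i]], symptoms)
    if (length(present) > 0) arr[i, present, ] <- L[present, , drop = FALSE]
  }
  structure(list(matrices = arr, symptoms = symptoms, plaques = plaques,
                 patient_id = records$patient_id),
            class = "patient_matrices")
}

#' Subset a `patient_matrices` object by patient index
#'
#' @param pm A `patient_matrices` object.
#' @param idx Integer patient indices.
#' @return A `patient_matrices` over the selected patients.
#' @export
pm_subset <- function(pm, idx) {
  structure(list(matrices = pm$matrices[idx, , , drop = FALSE],
                 symptoms = pm$symptoms, plaques = pm$plaques,
                 patient_id = pm$patient_id[idx]),
            class = "patient_matrices")
}

#' @export
print.patient_matrices <- function(x, ...) {
  cat(sprintf("<patient_matrices> %d patients, %d symptoms x %d plaques\n",
              dim(x$matrices)[1], dim(x$matrices)[2], dim(x$matrices)[3]))
  invisible(x)
}

#' Plaque label matrix aligned with a `patient_matrices` object
#'
#' @param records Record tibble (same order used to build the matrices).
#' @param pm A `patient_matrices` object.
#' @return 0/1 matrix patients x plaque types.
#' @export
plaque_label_matrix <- function(records, pm) {
  Y <- matrix(0L, nrow(records), length(pm$plaques),
              dimnames = list(records$patient_id, pm$plaques))
  for (i in seq_len(nrow(records))) {
    Y[i, intersect(records$plaques[[i]], pm$plaques)] <- 1L
  }
  Y
}
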