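test_that("generator configuration is validated", {
  expect_error(generator_config(n_patients = 0), "count")
  expect_error(generator_config(true_pair_density = 1.2), "probabilities")
  expect_error(generator_config(plaque_prevalence = c(calcified = 0)), "probabilities|named")
  expect_error(generator_config(effect_size = -1), "effect_size")
})

test_that("cohort generation is deterministic and plants the configured pairs", {
  cfg <- generator_config(n_patients = 300, n_symptoms = 10, n_genes = 50, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  n_pairs <- cfg$n_symptoms * length(cfg$plaque_prevalence)
  expect_equal(nrow(a$truth$true_pairs), ceiling(cfg$true_pair_density * n_pairs))
  expect_true(all(a$truth$true_pairs$symptom %in% a$truth$symptoms))
})

test_that("independence case: with zero effect size every pair's lift approaches 1", {
  cfg <- generator_config(n_patients = 4000, n_symptoms = 10, n_genes = 50,
                          effect_size = 0, seed = 2)
  rec <- generate_cohort(cfg)$records
  lt <- lift_table(rec)
  expect_equal(mean(lt$lift, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("planted pairs show higher empirical lift than unplanted ones", {
  cfg <- generator_config(n_patients = 2000, n_symptoms = 20, effect_size = 2.0,
                          true_pair_density = 0.15, seed = 7)
  co <- generate_cohort(cfg)
  lt <- lift_table(co$records, symptoms = co$truth$symptoms, plaques = co$truth$plaques)
  lt <- dplyr::left_join(lt, dplyr::mutate(co$truth$true_pairs, true = TRUE),
                         by = c("symptom", "plaque"))
  lt$true <- !is.na(lt$true)
  expect_gt(mean(lt$lift[lt$true]), mean(lt$lift[!lt$true]))
})

test_that("no-plaque patient count matches the binomial expectation", {
  cfg <- generator_config(n_patients = 1498, seed = 5)
  rec <- generate_cohort(cfg)$records
  none <- sum(lengths(rec$plaques) == 0)
  p0 <- prod(1 - cfg$plaque_prevalence)   # 0.7^3
  expect_equal(1498 * p0, 513.814, tolerance = 1e-3)
  ci <- qbinom(c(0.005, 0.995), 1498, p0)
  expect_gte(none, ci[1])
  expect_lte(none, ci[2])
})

test_that("interactome generator yields a connected heavy-tailed network with valid scores", {
  cfg3 <- generator_config(n_genes = 3, seed = 1)
  pp3 <- generate_ppin(cfg3)
  expect_true(nrow(pp3) %in% 2:3)
  expect_true(all(pp3$combined_score >= 400 & pp3$combined_score <= 1000))

  cfg <- generator_config(n_genes = 500, seed = 9)
  pp <- generate_ppin(cfg)
  expect_identical(pp, generate_ppin(cfg))
  g <- igraph::graph_from_data_frame(pp[, 1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))
  deg <- igraph::degree(g)
  expect_gt(max(deg), 5 * median(deg))
})

test_that("annotation sets of planted pairs sit closer in the interactome", {
  cfg <- generator_config(n_patients = 200, n_symptoms = 10, n_genes = 120, seed = 7)
  co <- generate_cohort(cfg)
  pp <- generate_ppin(cfg)
  an <- generate_annotations(cfg, pp, co$truth)
  g <- igraph::graph_from_data_frame(pp[, 1:2], directed = FALSE)
  D <- igraph::distances(g)
  set_dist <- function(s, t) {
    mean(D[an$symptom_sets[[s]], an$plaque_sets[[t]]])
  }
  grid <- tidyr::expand_grid(symptom = co$truth$symptoms, plaque = co$truth$plaques)
  grid <- dplyr::left_join(grid, dplyr::mutate(co$truth$true_pairs, true = TRUE),
                           by = c("symptom", "plaque"))
  grid$true <- !is.na(grid$true)
  grid$dist <- purrr::map2_dbl(grid$symptom, grid$plaque, set_dist)
  expect_lte(mean(grid$dist[grid$true]), mean(grid$dist[!grid$true]))

  # closure invariant: every annotated gene is an interactome node
  all_genes <- unique(unlist(c(an$symptom_sets, an$plaque_sets)))
  expect_true(all(all_genes %in% igraph::V(g)$name))
})

test_that("a depth-1 branching-1 ontology is a root plus one child", {
  ont <- plaquekg:::make_ontology(depth = 1, branching = 1)
  expect_equal(length(ont$terms), 2L)
  expect_equal(nrow(ont$edges), 1L)
  expect_equal(ont$edges$relation, "is_a")
})

test_that("expression generator plants correlated modules and a case shift", {
  cfg <- generator_config(n_genes = 200, module_shift = 2, n_expression_samples = 100, seed = 7)
  ex <- generate_expression(cfg, generate_cohort(cfg)$truth)
  expect_identical(ex$expr, generate_expression(cfg, generate_cohort(cfg)$truth)$expr)
  C <- cor(t(ex$expr))
  mods <- ex$modules
  same <- outer(mods, mods, "==") & outer(mods, mods, function(a, b) a > 0 & b > 0)
  diff <- outer(mods > 0, mods > 0, "&") & !same
  diag(same) <- FALSE
  expect_gt(mean(C[same]), mean(C[diff]))
})

test_that("generated files round-trip through the readers bit-exactly", {
  cfg <- generator_config(n_patients = 60, n_symptoms = 6, n_genes = 40,
                          ontology_depth = 2, ontology_branching = 2, seed = 13)
  dir <- withr::local_tempdir()
  study <- suppressWarnings(simulate_to_dir(cfg, dir))

  rec <- read_records(file.path(dir, "records.tsv"))
  expect_equal(rec$symptoms, study$records$symptoms)
  path2 <- file.path(dir, "records2.tsv")
  write_records(rec, path2)
  expect_identical(readr::read_file(file.path(dir, "records.tsv")), readr::read_file(path2))

  pp <- read_ppin(file.path(dir, "ppin.tsv"))
  expect_equal(as.data.frame(pp), as.data.frame(study$ppin), ignore_attr = TRUE)
  expect_equal(read_gmt(file.path(dir, "symptoms.gmt")), study$symptom_sets)
  expect_equal(read_gmt(file.path(dir, "plaques.gmt")), study$plaque_sets)
  ont <- read_obo(file.path(dir, "ontology.obo"))
  expect_setequal(ont$terms, study$ontology$terms)
  ann <- read_gene2term(file.path(dir, "annotations.tsv"))
  expect_equal(ann[order(names(ann))], study$ontology$annotations[order(names(study$ontology$annotations))])
})
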