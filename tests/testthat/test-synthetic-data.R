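test_that("config validation rejects malformed parameters", {
  expect_error(synthetic_config(penetrance = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_signal_genes = 50, n_pathway_genes = 40),
               "n_signal_genes")
  expect_error(synthetic_config(samples_per_type = 0), "count")
  expect_error(synthetic_config(expr_noise_sd = -1), ">= 0")
})

test_that("identical seeds reproduce bit-identical bundles", {
  cfg <- small_config(seed = 42L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(small_config(seed = 43L))))
})

test_that("activation only arises from pathogenic mutations or amplification", {
  b <- generate_cohort(small_config(seed = 2L))
  act <- names(b$latent_activation)[b$latent_activation > 0]
  patho_samples <- names(which(sample_true_pathogenic(b) == 1L))
  amp_samples <- unique(b$cnv$sample_id[b$cnv$category == "amplified"])
  expect_true(all(act %in% union(patho_samples, amp_samples)))
})

test_that("with full penetrance, no CNV and clean annotation, every activated sample carries a pathogenic mutation", {
  b <- generate_cohort(small_config(seed = 5L, penetrance = 1,
                                    annotation_error_rate = 0, cnv_rate = 0))
  act <- names(b$latent_activation)[b$latent_activation > 0]
  patho_samples <- names(which(sample_true_pathogenic(b) == 1L))
  expect_setequal(act, patho_samples)
})

test_that("null construction: zero signal shift leaves signal genes flat", {
  b <- generate_cohort(small_config(seed = 8L, signal_shift = 0,
                                    samples_per_type = 150L))
  sig_genes <- grep("^SIG", rownames(b$expression), value = TRUE)
  on <- b$latent_activation > 0
  cells_on <- as.vector(b$expression[sig_genes, on])
  cells_off <- as.vector(b$expression[sig_genes, !on])
  delta <- mean(cells_on) - mean(cells_off)
  se <- sqrt(stats::var(cells_on) / length(cells_on) +
               stats::var(cells_off) / length(cells_off))
  expect_lt(abs(delta), 3 * se)
})

test_that("signal genes shift by about signal_shift when the program is active", {
  b <- generate_cohort(small_config(seed = 9L, samples_per_type = 150L,
                                    signal_shift = 1.5))
  sig_genes <- grep("^SIG", rownames(b$expression), value = TRUE)
  on <- b$latent_activation > 0
  delta <- mean(b$expression[sig_genes, on]) - mean(b$expression[sig_genes, !on])
  n_on <- sum(on) * length(sig_genes)
  n_off <- sum(!on) * length(sig_genes)
  se <- sqrt(1 / n_on + 1 / n_off)
  expect_lt(abs(delta - 1.5), 3 * se)
})

test_that("pooled alteration rate sits inside binomial 99% bounds of the configured mix", {
  cfg <- synthetic_config(seed = 1L, n_cancer_types = 4L,
                          samples_per_type = 250L,
                          alteration_rate_per_type = c(0.10, 0.20, 0.30, 0.04))
  b <- generate_cohort(cfg)
  altered <- sum(bundle_labels(b)$any_mutation)
  bounds <- stats::qbinom(c(0.005, 0.995), 1000L, 0.16)
  expect_gte(altered, bounds[1])
  expect_lte(altered, bounds[2])
})

test_that("every expression sample has an activation label and drug records", {
  b <- generate_cohort(small_config(seed = 3L))
  ids <- colnames(b$expression)
  expect_identical(names(b$latent_activation), ids)
  expect_setequal(unique(b$drug_response$sample_id), ids)
  expect_identical(nrow(b$mutations), length(b$true_pathogenic))
})

test_that("routing drug response through mutation makes on-target drugs track the label", {
  cfg <- small_config(seed = 12L, response_driver = "mutation",
                      n_drugs = 2L, on_target_fraction = 0.5,
                      drug_effect = 2, response_noise_sd = 0.5,
                      samples_per_type = 100L)
  b <- generate_cohort(cfg)
  lab <- setNames(bundle_labels(b)$any_mutation, bundle_labels(b)$sample_id)
  on_drug <- b$drug_info$drug_id[b$drug_info$on_target][1]
  sub <- b$drug_response[b$drug_response$drug_id == on_drug, ]
  gap <- mean(sub$value[lab[sub$sample_id] == 0]) -
    mean(sub$value[lab[sub$sample_id] == 1])
  expect_gt(gap, 1.5)
})

test_that("paired cohorts: selection strength 0 keeps both arms identical", {
  pair <- generate_paired_cohort(small_config(seed = 4L,
                                              treatment_selection_strength = 0))
  expect_identical(pair$pre$latent_activation, pair$post$latent_activation)
  expect_identical(dim(pair$pre$expression), dim(pair$post$expression))
})

test_that("paired cohorts: selection strength 1 removes every activated tumor", {
  pair <- generate_paired_cohort(small_config(seed = 4L,
                                              treatment_selection_strength = 1))
  expect_true(all(pair$post$latent_activation == 0))
  expect_lt(ncol(pair$post$expression), ncol(pair$pre$expression))
})

test_that("paired cohorts: post-arm rate matches the conditional-probability oracle", {
  # pre activation rate 0.4 by construction; selection 0.5 implies
  # post rate 0.5*0.4 / (1 - 0.5*0.4) = 0.25
  cfg <- synthetic_config(seed = 10L, n_cancer_types = 2L,
                          samples_per_type = 250L,
                          alteration_rate_per_type = 0.4,
                          pathogenic_fraction = 1, cnv_rate = 0,
                          penetrance = 1, treatment_selection_strength = 0.5)
  pair <- generate_paired_cohort(cfg)
  post_rate <- mean(pair$post$latent_activation > 0)
  n_post <- length(pair$post$latent_activation)
  bounds <- stats::qbinom(c(0.005, 0.995), n_post, 0.25) / n_post
  # the pre-arm rate is itself binomial, so allow a small widening on top of
  # the conditional binomial bounds
  expect_gt(post_rate, bounds[1] - 0.03)
  expect_lt(post_rate, bounds[2] + 0.03)
})

test_that("bundles round-trip through the on-disk TSV/GMT formats", {
  b <- generate_cohort(small_config(seed = 6L, samples_per_type = 20L))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(expr, b$expression, tolerance = 1e-8)
  mut <- read_mutation_tsv(file.path(dir, "mutations.tsv"))
  expect_identical(mut$sample_id, b$mutations$sample_id)
  expect_identical(mut$clinvar, b$mutations$clinvar)
  gmt <- read_gmt(file.path(dir, "pathway.gmt"))
  expect_identical(gmt[[b$pathway$name]], b$pathway$feature_genes)
})
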