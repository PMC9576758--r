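# small, fast training setup reused across blocks: labels coincide with
# activation so the classes are clean
train_fixture <- function(seed = 1L, samples_per_type = 80L, ...) {
  b <- generate_cohort(small_config(
    seed = seed, samples_per_type = samples_per_type,
    pathogenic_fraction = 1, penetrance = 1, cnv_rate = 0,
    annotation_error_rate = 0, signal_shift = 2,
    alteration_rate_per_type = c(0.3, 0.4, 0.35, 0.25), ...))
  feats <- quiet(restrict_to_pathway(normalize_expression(b$expression),
                                     b$pathway))
  list(bundle = b, features = feats, labels = bundle_labels(b))
}

small_grid <- expand.grid(max_depth = c(2L, 3L), n_trees = c(20L, 50L))

test_that("module AUC equals the pairwise-concordance oracle, ties included", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    labels <- c(0L, 1L, stats::rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.1), n, TRUE)  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("degenerate label configurations are rejected up front", {
  fix <- train_fixture()
  expect_error(train_signature(fix$features, rep(1L, ncol(fix$features)),
                               grid = small_grid),
               "single-class")
  y <- c(1L, rep(0L, ncol(fix$features) - 1L))
  expect_error(train_signature(fix$features, y, grid = small_grid, folds = 10L),
               "fold count")
})

test_that("training recovers a clean synthetic signal and locks the signature", {
  fix <- train_fixture()
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 1L, pathway_name = "SYNTH_PATHWAY")
  expect_s3_class(sig, "phenocopy_signature")
  expect_gt(sig$cv_auc, 0.85)
  expect_true(sig$locked)
  expect_identical(sig$feature_genes, rownames(fix$features))
  expect_true(all(c("max_depth", "n_trees", "cv_auc") %in% names(sig$cv_grid)))
})

test_that("permuted labels give chance-level cross-validated AUC", {
  fix <- train_fixture()
  set.seed(99)
  perm <- sample(as.integer(fix$labels$any_mutation))
  sig <- train_signature(fix$features, perm,
                         grid = data.frame(max_depth = 2L, n_trees = 20L),
                         folds = 5L, seed = 2L)
  expect_gt(sig$cv_auc, 0.35)
  expect_lt(sig$cv_auc, 0.65)
})

test_that("identical seeds and inputs give byte-identical serialized signatures", {
  fix <- train_fixture()
  sig1 <- train_signature(fix$features, fix$labels, grid = small_grid,
                          folds = 5L, seed = 7L)
  sig2 <- train_signature(fix$features, fix$labels, grid = small_grid,
                          folds = 5L, seed = 7L)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  save_signature(sig1, d1)
  save_signature(sig2, d2)
  for (f in c("model.json", "signature.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
})

test_that("serialization round-trips metadata bit-exactly and predictions exactly", {
  fix <- train_fixture()
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 3L, pathway_name = "SYNTH_PATHWAY")
  dir <- file.path(withr::local_tempdir(), "sig")
  save_signature(sig, dir)
  back <- load_signature(dir)
  for (f in setdiff(names(sig), c("model", "cv_grid"))) {
    expect_identical(back[[f]], sig[[f]], label = f)
  }
  expect_equal(back$cv_grid, sig$cv_grid)
  expect_identical(predict_phenocopy(back, fix$features),
                   predict_phenocopy(sig, fix$features))
})

test_that("prediction is pure and never alters the serialized signature", {
  fix <- train_fixture()
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 4L)
  dir <- file.path(withr::local_tempdir(), "sig")
  save_signature(sig, dir)
  before <- tools::md5sum(list.files(dir, full.names = TRUE))
  p1 <- predict_phenocopy(sig, fix$features)
  p2 <- predict_phenocopy(sig, fix$features)
  expect_identical(p1, p2)
  expect_identical(tools::md5sum(list.files(dir, full.names = TRUE)), before)
})

test_that("held-out samples are called with high balanced accuracy", {
  fix <- train_fixture(seed = 1L)
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 5L)
  held <- train_fixture(seed = 2L)
  calls <- predict_phenocopy(sig, held$features)
  truth <- held$bundle$latent_activation[calls$sample_id]
  bal_acc <- mean(c(mean(calls$call[truth == 1] == 1),
                    mean(calls$call[truth == 0] == 0)))
  expect_gt(bal_acc, 0.85)
})

test_that("an all-constant matrix yields one decision for every sample", {
  fix <- train_fixture()
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 6L)
  flat <- matrix(0.5, nrow(fix$features), 10,
                 dimnames = list(rownames(fix$features), paste0("c", 1:10)))
  attr(flat, "normalization") <- "rank"
  calls <- predict_phenocopy(sig, flat)
  expect_identical(length(unique(calls$call)), 1L)
  expect_identical(length(unique(calls$margin)), 1L)
})

test_that("missing feature genes are imputed at mid-rank, with a hard ceiling", {
  fix <- train_fixture()
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 8L)
  partial <- fix$features[-(1:5), , drop = FALSE]
  attr(partial, "normalization") <- "rank"
  expect_message(calls <- predict_phenocopy(sig, partial), "imputing 5/")
  expect_identical(nrow(calls), ncol(partial))
  tiny <- fix$features[1:10, , drop = FALSE]
  attr(tiny, "normalization") <- "rank"
  expect_error(predict_phenocopy(sig, tiny), "missing")
})

test_that("a normalization-dialect mismatch is flagged at prediction", {
  fix <- train_fixture()
  sig <- train_signature(fix$features, fix$labels, grid = small_grid,
                         folds = 5L, seed = 9L)
  raw <- fix$features
  attr(raw, "normalization") <- NULL
  expect_warning(predict_phenocopy(sig, raw), "does not match")
})
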