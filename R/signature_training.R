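#' ROC AUC from scores and binary labels
#'
#' Computed by the rank (Mann-Whitney) formula: the probability that a random
#' positive scores above a random negative, counting ties as one half.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary labels (0/1), same length.
#' @return AUC in `[0, 1]`; both classes must be present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Default hyperparameter grid for signature training
#'
#' @return Data frame with columns `max_depth` and `n_trees`.
#' @export
default_tuning_grid <- function() {
  expand.grid(max_depth = c(2L, 3L, 4L, 6L), n_trees = c(50L, 100L, 200L, 400L),
              KEEP.OUT.ATTRS = FALSE)
}

# stratified fold assignment; error if folds exceed the minority class
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < folds) {
      stop(sprintf("fold count (%d) exceeds class %s count (%d)",
                   folds, cls, length(idx)), call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

.xgb_params <- function(depth, eta = 0.3) {
  list(objective = "binary:hinge", max_depth = depth, eta = eta, nthread = 1L)
}

#' Train and lock a phenocopy signature
#'
#' Fits gradient-boosted trees with a hinge loss to predict mutation status
#' from pathway-restricted, normalized expression. Tree depth and tree count
#' are tuned by stratified k-fold cross-validation: for each grid point the
#' out-of-fold margin scores are pooled across folds and scored by ROC AUC;
#' the best (ties broken toward fewer trees, then smaller depth) is refit on
#' all samples and the signature is locked. One fit per depth per fold covers
#' every tree-count grid point (margins are read at intermediate iterations).
#'
#' @param features Genes x samples matrix, already pathway-restricted and
#'   normalized (see [restrict_to_pathway()], [normalize_expression()]).
#' @param labels Binary vector (0/1) of mutation status, one per sample
#'   (column), or a label data frame from [build_labels()] whose
#'   `label_column` is used.
#' @param grid Hyperparameter grid, columns `max_depth` and `n_trees`;
#'   defaults to [default_tuning_grid()].
#' @param folds Number of CV folds (default 10); must not exceed the
#'   minority-class count.
#' @param seed Integer seed controlling fold assignment; with `nthread = 1`
#'   the whole procedure is deterministic.
#' @param eta Learning rate (default 0.3).
#' @param label_column Which label to train on when `labels` is a data
#'   frame; default `"any_mutation"`.
#' @param pathway_name Stored in the signature.
#' @return A locked `phenocopy_signature`: the fitted booster, ordered
#'   feature genes, normalization dialect, tuned depth and tree count,
#'   pooled out-of-fold `cv_auc`, the full CV AUC grid, and a fingerprint of
#'   the training inputs.
#' @export
train_signature <- function(features, labels, grid = default_tuning_grid(),
                            folds = 10L, seed = 1L, eta = 0.3,
                            label_column = "any_mutation",
                            pathway_name = "pathway") {
  stopifnot(is.matrix(features), nrow(features) >= 1L)
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", label_column) %in% names(labels)))
    labels <- setNames(labels[[label_column]], labels$sample_id)[colnames(features)]
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(features) || anyNA(labels)) {
    stop("`labels` must provide one 0/1 value per sample column", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training labels are single-class", call. = FALSE)
  }
  stopifnot(is.data.frame(grid), all(c("max_depth", "n_trees") %in% names(grid)))
  normalization <- attr(features, "normalization")
  if (is.null(normalization)) normalization <- "rank"

  x <- t(features)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fold <- .stratified_folds(labels, folds)

  depths <- sort(unique(grid$max_depth))
  tree_grid <- sort(unique(grid$n_trees))
  max_trees <- max(tree_grid)
  # pooled out-of-fold margins: [sample, depth, n_trees]
  margins <- array(NA_real_, c(length(labels), length(depths), length(tree_grid)))
  for (di in seq_along(depths)) {
    for (k in seq_len(folds)) {
      hold <- fold == k
      dtrain <- xgboost::xgb.DMatrix(x[!hold, , drop = FALSE],
                                     label = labels[!hold])
      booster <- xgboost::xgb.train(params = .xgb_params(depths[di], eta),
                                    data = dtrain, nrounds = max_trees,
                                    verbose = 0L)
      for (ti in seq_along(tree_grid)) {
        margins[hold, di, ti] <- predict(
          booster, x[hold, , drop = FALSE], outputmargin = TRUE,
          iterationrange = c(1L, tree_grid[ti]))
      }
    }
  }

  cv <- grid[, c("max_depth", "n_trees")]
  cv$cv_auc <- mapply(function(d, t) {
    roc_auc(margins[, match(d, depths), match(t, tree_grid)], labels)
  }, cv$max_depth, cv$n_trees)
  ord <- order(-cv$cv_auc, cv$n_trees, cv$max_depth)
  best <- cv[ord[1L], ]

  dall <- xgboost::xgb.DMatrix(x, label = labels)
  final <- xgboost::xgb.train(params = .xgb_params(best$max_depth, eta),
                              data = dall, nrounds = best$n_trees,
                              verbose = 0L)
  fingerprint <- .input_fingerprint(list(features, labels, grid, folds, seed, eta))
  structure(list(
    pathway_name = pathway_name,
    feature_genes = rownames(features),
    normalization_dialect = normalization,
    model = final,
    tuned_depth = as.integer(best$max_depth),
    tuned_n_trees = as.integer(best$n_trees),
    cv_auc = best$cv_auc,
    cv_grid = cv,
    cv_folds = as.integer(folds),
    cv_score_pooling = "pooled_out_of_fold",
    eta = eta,
    seed = as.integer(seed),
    training_fingerprint = fingerprint,
    locked = TRUE
  ), class = "phenocopy_signature")
}

# md5 of the serialized training inputs; identifies a signature's provenance
.input_fingerprint <- function(objects) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(objects, NULL, version = 2L), tmp)
  unname(tools::md5sum(tmp))
}

#' Apply a locked phenocopy signature to an expression matrix
#'
#' Scores each sample with the signature's booster and thresholds the hinge
#' margin at zero for the binary phenocopy call. Feature genes absent from
#' the matrix are imputed at the mid-rank value 0.5 (neutral under rank
#' normalization); the imputation rate is reported and an error is raised
#' when it exceeds `max_missing`. Prediction never mutates the signature.
#'
#' @param signature A locked `phenocopy_signature`.
#' @param matrix Genes x samples matrix, normalized with the signature's
#'   registered dialect (a mismatch in the `normalization` attribute warns).
#' @param max_missing Maximum tolerated fraction of missing feature genes
#'   (default 0.5).
#' @return Data frame (`sample_id`, `call`, `margin`), one row per sample.
#' @export
predict_phenocopy <- function(signature, matrix, max_missing = 0.5) {
  stopifnot(inherits(signature, "phenocopy_signature"), is.matrix(matrix))
  dialect <- attr(matrix, "normalization")
  if (is.null(dialect) || !identical(dialect, signature$normalization_dialect)) {
    warning(sprintf(
      "matrix normalization (%s) does not match the signature's dialect (%s)",
      if (is.null(dialect)) "unset" else dialect,
      signature$normalization_dialect), call. = FALSE)
  }
  feats <- signature$feature_genes
  missing <- setdiff(feats, rownames(matrix))
  frac <- length(missing) / length(feats)
  if (frac > max_missing) {
    stop(sprintf("%.0f%% of feature genes missing exceeds the %.0f%% limit",
                 100 * frac, 100 * max_missing), call. = FALSE)
  }
  if (length(missing) > 0L) {
    message(sprintf("predict_phenocopy: imputing %d/%d missing feature genes at 0.5",
                    length(missing), length(feats)))
    fill <- matrix(0.5, length(missing), ncol(matrix),
                   dimnames = list(missing, colnames(matrix)))
    matrix <- rbind(matrix, fill)
  }
  x <- t(matrix[feats, , drop = FALSE])
  margin <- predict(signature$model, x, outputmargin = TRUE)
  data.frame(sample_id = colnames(matrix), call = as.integer(margin > 0),
             margin = as.numeric(margin), stringsAsFactors = FALSE)
}

#' Serialize a locked signature to a directory of text files
#'
#' Writes the booster as a JSON model dump (`model.json`) plus a JSON
#' metadata sidecar (`signature.json`) carrying every metadata field
#' bit-exactly. Identical signatures serialize to byte-identical files.
#'
#' @param signature A `phenocopy_signature`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @seealso [load_signature()]
#' @export
save_signature <- function(signature, dir) {
  stopifnot(inherits(signature, "phenocopy_signature"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw_json <- xgboost::xgb.save.raw(signature$model, raw_format = "json")
  writeBin(raw_json, file.path(dir, "model.json"))
  meta <- signature[setdiff(names(signature), "model")]
  meta$cv_grid <- as.data.frame(meta$cv_grid)
  # I(17) significant digits: doubles survive the text round-trip bit-exactly
  jsonlite::write_json(meta, file.path(dir, "signature.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Load a signature serialized by [save_signature()]
#'
#' @param dir Directory containing `model.json` and `signature.json`.
#' @return A `phenocopy_signature`.
#' @export
load_signature <- function(dir) {
  meta_path <- file.path(dir, "signature.json")
  model_path <- file.path(dir, "model.json")
  stopifnot(file.exists(meta_path), file.exists(model_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  raw_json <- readBin(model_path, "raw", file.size(model_path))
  sig <- meta
  sig$feature_genes <- as.character(meta$feature_genes)
  sig$cv_grid <- as.data.frame(meta$cv_grid)
  sig$model <- xgboost::xgb.load.raw(raw_json)
  sig$tuned_depth <- as.integer(meta$tuned_depth)
  sig$tuned_n_trees <- as.integer(meta$tuned_n_trees)
  sig$cv_folds <- as.integer(meta$cv_folds)
  sig$seed <- as.integer(meta$seed)
  sig <- sig[c(setdiff(names(meta), "model"), "model")]
  structure(sig, class = "phenocopy_signature")
}

#' @export
print.phenocopy_signature <- function(x, ...) {
  cat(sprintf("<phenocopy_signature> %s: %d feature genes, %s normalization\n",
              x$pathway_name, length(x$feature_genes), x$normalization_dialect))
  cat(sprintf("  depth %d x %d trees (CV AUC %.3f over %d folds)%s\n",
              x$tuned_depth, x$tuned_n_trees, x$cv_auc, x$cv_folds,
              if (isTRUE(x$locked)) " [locked]" else ""))
  invisible(x)
}
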