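#' Intersect gene universes across expression matrices
#'
#' Cross-dataset application of a locked signature requires one shared gene
#' universe; each matrix is subsequently subset to the sorted intersection.
#'
#' @param matrices List of genes x samples matrices with gene rownames.
#' @return Sorted character vector of genes present in every matrix; empty
#'   intersection is an error.
#' @export
intersect_genes <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (length(genes) == 0L) {
    stop("gene intersection across matrices is empty", call. = FALSE)
  }
  sort(genes)
}

#' Rank-normalize an expression matrix per sample
#'
#' Replaces each sample's values by fractional ranks over the gene universe
#' (average ranks for ties, divided by the gene count), giving values in
#' (0, 1]. The transform is invariant to any strictly monotone per-sample
#' transformation of the input and idempotent, which is what lets one locked
#' signature be applied across sequencing- and array-derived datasets. The
#' dialect used is recorded in the `normalization` attribute and inside each
#' trained signature.
#'
#' @param matrix Genes x samples numeric matrix.
#' @param dialect `"rank"` (default), `"zscore"` (per-gene z-score), or
#'   `"none"`.
#' @return Matrix of the same shape with attribute `normalization` set.
#' @examples
#' m <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' normalize_expression(m)[, 1]
#' @export
normalize_expression <- function(matrix, dialect = c("rank", "zscore", "none")) {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(matrix), is.numeric(matrix), nrow(matrix) >= 1L)
  out <- switch(dialect,
    rank = {
      ng <- nrow(matrix)
      const <- apply(matrix, 2L, function(x) length(unique(x)) == 1L)
      if (any(const)) {
        warning(sprintf("%d constant sample(s) rank-normalized to uniform values",
                        sum(const)), call. = FALSE)
      }
      apply(matrix, 2L, function(x) rank(x, ties.method = "average") / ng)
    },
    zscore = t(scale(t(matrix))),
    none = matrix
  )
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(matrix))
  dimnames(out) <- dimnames(matrix)
  attr(out, "normalization") <- dialect
  out
}

#' Restrict an expression matrix to a pathway's feature genes
#'
#' @param matrix Genes x samples matrix.
#' @param pathway A [pathway_definition()].
#' @return The rows of `matrix` whose genes are feature genes, in the
#'   matrix's original row order; the missing-gene fraction is reported via
#'   `message()`. Zero overlap is an error naming the pathway.
#' @export
restrict_to_pathway <- function(matrix, pathway) {
  stopifnot(is.matrix(matrix), inherits(pathway, "pathway_definition"))
  keep <- rownames(matrix) %in% pathway$feature_genes
  if (!any(keep)) {
    stop(sprintf("no feature genes of pathway '%s' present in the matrix",
                 pathway$name), call. = FALSE)
  }
  missing_frac <- 1 - sum(keep) / length(pathway$feature_genes)
  message(sprintf("restrict_to_pathway: %d/%d feature genes present (%.1f%% missing)",
                  sum(keep), length(pathway$feature_genes), 100 * missing_frac))
  out <- matrix[keep, , drop = FALSE]
  attr(out, "normalization") <- attr(matrix, "normalization")
  out
}

#' Drop cancer types with low alteration rates from a training cohort
#'
#' Cancer types whose `any_mutation` rate falls strictly below `min_rate`
#' (default 5\%) are removed before signature training: at very low
#' alteration rates a type contributes almost no positive examples while
#' diluting the signal. A type at exactly `min_rate` is retained. The rate
#' uses `any_mutation`, not the pathogenic-only label, matching training on
#' all protein-coding alterations.
#'
#' @param labels Label data frame from [build_labels()].
#' @param cancer_types Named character vector mapping sample_id to cancer
#'   type; must cover every labelled sample.
#' @param min_rate Minimum per-type alteration rate, default 0.05.
#' @return Character vector of retained sample IDs, in the order of
#'   `labels`; per-type rates are reported via `message()`. All types
#'   removed is an error.
#' @export
filter_training_cancer_types <- function(labels, cancer_types, min_rate = 0.05) {
  stopifnot(is.data.frame(labels),
            all(c("sample_id", "any_mutation") %in% names(labels)))
  ct <- cancer_types[labels$sample_id]
  if (anyNA(ct)) {
    stop("every labelled sample must have a cancer type", call. = FALSE)
  }
  rates <- tapply(labels$any_mutation, ct, mean)
  message(paste0("alteration rate by cancer type: ",
                 paste(sprintf("%s=%.3f", names(rates), rates), collapse = ", ")))
  keep_types <- names(rates)[rates >= min_rate]
  if (length(keep_types) == 0L) {
    stop(sprintf("all cancer types fall below the %.0f%% alteration-rate floor",
                 100 * min_rate), call. = FALSE)
  }
  labels$sample_id[ct %in% keep_types]
}
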