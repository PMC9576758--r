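#' Define responders as the most-sensitive quartile
#'
#' With the response oriented lower = sensitive, the cutoff is the k-th
#' smallest value with `k = ceiling(n/4)`; every sample at or below the
#' cutoff is a responder, so ties at the boundary are included. Responders
#' are defined per drug over all assayed samples, before any stratification.
#'
#' @param response Numeric oriented response values (length >= 4).
#' @return Integer 0/1 vector with attribute `cutoff`; an all-equal vector
#'   makes everyone a responder and raises a warning (degenerate).
#' @examples
#' define_responders(c(5, 1, 7, 3, 8, 2, 6, 4))
#' @export
define_responders <- function(response) {
  stopifnot(is.numeric(response))
  if (anyNA(response)) stop("`response` must be complete", call. = FALSE)
  n <- length(response)
  if (n < 4L) stop("need at least 4 samples to define a responder quartile",
                   call. = FALSE)
  cutoff <- sort(response)[ceiling(n / 4)]
  out <- as.integer(response <= cutoff)
  if (all(out == 1L)) {
    warning("all values share the quartile cutoff; every sample is a responder",
            call. = FALSE)
  }
  attr(out, "cutoff") <- cutoff
  out
}

#' Confusion-matrix metrics for one evaluation stratum
#'
#' Counts true/false positives/negatives of a binary predictor against
#' responder status within a stratum, and derives sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)` and NPV
#' `tn/(tn+fn)`. A zero denominator yields `NA` (undefined), never 0.
#'
#' @param responders Binary responder vector over the full cohort.
#' @param predictor Binary predictor vector (phenocopy call or mutation
#'   label) over the full cohort.
#' @param stratum_mask Logical/binary vector selecting the stratum; must
#'   select at least one sample.
#' @param condition Condition tag (see [stratum_conditions()]).
#' @param drug_id,pathway_name,dataset_tag Identifiers carried through.
#' @return One-row data frame with counts and metrics.
#' @export
compute_stratum_metrics <- function(responders, predictor, stratum_mask,
                                    condition, drug_id = NA_character_,
                                    pathway_name = NA_character_,
                                    dataset_tag = NA_character_) {
  stopifnot(length(predictor) == length(responders),
            length(stratum_mask) == length(responders))
  mask <- as.logical(stratum_mask)
  if (!any(mask)) stop("stratum mask selects no samples", call. = FALSE)
  r <- as.integer(responders[mask])
  p <- as.integer(predictor[mask])
  tp <- sum(p == 1L & r == 1L); fp <- sum(p == 1L & r == 0L)
  fn <- sum(p == 0L & r == 1L); tn <- sum(p == 0L & r == 0L)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  data.frame(
    condition = condition, drug_id = drug_id, pathway_name = pathway_name,
    dataset_tag = dataset_tag, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
    stringsAsFactors = FALSE
  )
}

#' The five mutation/phenocopy evaluation conditions
#'
#' Returns the masks and predictors for the five biomarker conditions:
#' phenocopy calls evaluated within (1) mutation-negative samples,
#' (2) pathogenic-mutation samples, (3) non-pathogenic-mutation samples;
#' and over all samples, (4) mutation status and (5) pathogenic-mutation
#' status as the predictor. Conditions 1-3 partition the cohort.
#'
#' @param mutation,pathogenic,phenocopy Binary vectors over the cohort;
#'   `pathogenic` must imply `mutation`.
#' @return Named list of `list(condition, mask, predictor)` entries.
#' @export
stratum_conditions <- function(mutation, pathogenic, phenocopy) {
  mutation <- as.integer(mutation)
  pathogenic <- as.integer(pathogenic)
  phenocopy <- as.integer(phenocopy)
  stopifnot(length(pathogenic) == length(mutation),
            length(phenocopy) == length(mutation))
  if (any(pathogenic == 1L & mutation == 0L)) {
    stop("`pathogenic` must imply `mutation`", call. = FALSE)
  }
  list(
    phenocopy_in_no_mutation = list(
      condition = "phenocopy_in_no_mutation",
      mask = mutation == 0L, predictor = phenocopy),
    phenocopy_in_pathogenic = list(
      condition = "phenocopy_in_pathogenic",
      mask = pathogenic == 1L, predictor = phenocopy),
    phenocopy_in_nonpathogenic = list(
      condition = "phenocopy_in_nonpathogenic",
      mask = mutation == 1L & pathogenic == 0L, predictor = phenocopy),
    mutation_in_all = list(
      condition = "mutation_in_all",
      mask = rep(TRUE, length(mutation)), predictor = mutation),
    pathogenic_in_all = list(
      condition = "pathogenic_in_all",
      mask = rep(TRUE, length(mutation)), predictor = pathogenic)
  )
}

#' Biomarker metrics for all five conditions of one drug
#'
#' Defines responders over all assayed samples with [define_responders()],
#' then computes [compute_stratum_metrics()] for each of the five
#' [stratum_conditions()]. Conditions whose stratum is empty are skipped
#' (e.g. no pathogenic mutations assayed for this drug).
#'
#' @param response Oriented response values for one drug.
#' @param mutation,pathogenic,phenocopy Binary vectors aligned with
#'   `response`.
#' @inheritParams compute_stratum_metrics
#' @return Data frame with up to five rows, one per condition.
#' @export
biomarker_panel <- function(response, mutation, pathogenic, phenocopy,
                            drug_id = NA_character_,
                            pathway_name = NA_character_,
                            dataset_tag = NA_character_) {
  responders <- define_responders(response)
  conds <- stratum_conditions(mutation, pathogenic, phenocopy)
  rows <- lapply(conds, function(cn) {
    if (!any(cn$mask)) return(NULL)
    compute_stratum_metrics(responders, cn$predictor, cn$mask, cn$condition,
                            drug_id, pathway_name, dataset_tag)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
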