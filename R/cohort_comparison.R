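# Degenerate-safe Pearson chi-square on a 2x2 of (positives, size) per group.
# Cells whose expected count is zero contribute nothing; a table whose
# observed counts equal expectation (e.g. all-zero positives) yields
# statistic 0 and p = 1, where stats::chisq.test would return NaN.
.two_prop_chisq <- function(pos_a, n_a, pos_b, n_b) {
  obs <- rbind(c(pos_a, n_a - pos_a), c(pos_b, n_b - pos_b))
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  cells <- (obs - expd)^2 / expd
  stat <- sum(cells[expd > 0])
  list(statistic = stat, p_value = pchisq(stat, 1L, lower.tail = FALSE))
}

.rate_comparison <- function(group_a, group_b, pos_a, n_a, pos_b, n_b,
                             statistic, p_value, test_name,
                             degenerate = FALSE) {
  data.frame(
    group_a = group_a, group_b = group_b,
    rate_a = if (n_a > 0L) pos_a / n_a else NA_real_,
    rate_b = if (n_b > 0L) pos_b / n_b else NA_real_,
    n_a = n_a, n_b = n_b, statistic = statistic, p_value = p_value,
    test_name = test_name, degenerate = degenerate, stringsAsFactors = FALSE
  )
}

#' Compare pathway CNV rates between phenocopy-only samples and the rest
#'
#' Tests the mechanistic reading of phenocopies without mutations: group A
#' (phenocopy call positive, mutation negative) should carry pathway
#' copy-number changes more often than everyone else (group B). A sample's
#' pathway-CNV flag is any non-neutral category in any pathway gene (driver
#' or feature). Rates are compared by a two-proportion Pearson chi-square
#' without continuity correction.
#'
#' @param phenocopy Named binary vector of phenocopy calls (names =
#'   sample IDs).
#' @param mutation Named binary vector of mutation status over the same
#'   samples.
#' @param cnv CNV table (`sample_id`, `gene`,
#'   `category` in amplified/neutral/deleted); samples without records are
#'   treated as CNV-negative with a warning.
#' @param pathway A [pathway_definition()].
#' @return One-row rate-comparison data frame (groups, rates, counts,
#'   statistic, p-value, test name). An empty group A is an error.
#' @export
compare_cnv_rates <- function(phenocopy, mutation, cnv, pathway) {
  stopifnot(!is.null(names(phenocopy)), !is.null(names(mutation)),
            inherits(pathway, "pathway_definition"),
            all(c("sample_id", "gene", "category") %in% names(cnv)))
  ids <- names(phenocopy)
  mutation <- mutation[ids]
  if (anyNA(mutation)) stop("`mutation` must cover all phenocopy samples",
                            call. = FALSE)
  pwy_genes <- union(pathway$driver_genes, pathway$feature_genes)
  changed <- cnv$sample_id[cnv$category != "neutral" & cnv$gene %in% pwy_genes]
  uncovered <- setdiff(ids, unique(cnv$sample_id))
  if (length(uncovered) > 0L) {
    warning(sprintf("%d sample(s) without CNV records treated as CNV-negative",
                    length(uncovered)), call. = FALSE)
  }
  cnv_flag <- as.integer(ids %in% changed)
  in_a <- phenocopy == 1L & mutation == 0L
  if (!any(in_a)) {
    stop("no phenocopy-positive mutation-negative samples to compare",
         call. = FALSE)
  }
  tst <- .two_prop_chisq(sum(cnv_flag[in_a]), sum(in_a),
                         sum(cnv_flag[!in_a]), sum(!in_a))
  .rate_comparison("phenocopy_no_mutation", "other",
                   sum(cnv_flag[in_a]), sum(in_a),
                   sum(cnv_flag[!in_a]), sum(!in_a),
                   tst$statistic, tst$p_value, "two_proportion_chisq")
}

#' Compare phenocopy-positive rates between two arms
#'
#' Used for pre- vs post-treatment cohort comparisons: under selective
#' pressure of an effective targeted therapy, the phenocopy rate is expected
#' to drop in the resistant (post-treatment) arm. Two-proportion Pearson
#' chi-square without continuity correction.
#'
#' @param calls_a,calls_b Binary phenocopy calls per arm (both non-empty).
#' @param name_a,name_b Arm names for the report.
#' @return One-row rate-comparison data frame.
#' @export
compare_phenocopy_rates <- function(calls_a, calls_b,
                                    name_a = "pre", name_b = "post") {
  calls_a <- as.integer(calls_a); calls_b <- as.integer(calls_b)
  if (length(calls_a) == 0L || length(calls_b) == 0L) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  tst <- .two_prop_chisq(sum(calls_a), length(calls_a),
                         sum(calls_b), length(calls_b))
  .rate_comparison(name_a, name_b, sum(calls_a), length(calls_a),
                   sum(calls_b), length(calls_b),
                   tst$statistic, tst$p_value, "two_proportion_chisq")
}

#' Response rates stratified by phenocopy call
#'
#' Compares the responder rate among phenocopy-positive versus
#' phenocopy-negative samples with Fisher's exact test (clinical cohorts are
#' small). If one call group is empty the comparison is returned one-sided
#' with the missing rate `NA` and flagged degenerate.
#'
#' @param calls Binary phenocopy calls.
#' @param responder Binary responder labels, same length, `NA` not allowed.
#' @return One-row rate-comparison data frame (`test_name = "fisher_exact"`).
#' @export
responder_stratified_rates <- function(calls, responder) {
  calls <- as.integer(calls); responder <- as.integer(responder)
  stopifnot(length(calls) == length(responder))
  if (length(responder) == 0L || anyNA(responder)) {
    stop("responder labels must be present and complete", call. = FALSE)
  }
  pos <- calls == 1L
  if (all(pos) || !any(pos)) {
    warning("all samples share one phenocopy call; comparison is one-sided",
            call. = FALSE)
    return(.rate_comparison(
      "phenocopy_positive", "phenocopy_negative",
      sum(responder[pos]), sum(pos), sum(responder[!pos]), sum(!pos),
      NA_real_, NA_real_, "fisher_exact", degenerate = TRUE))
  }
  tab <- rbind(c(sum(responder[pos]), sum(pos) - sum(responder[pos])),
               c(sum(responder[!pos]), sum(!pos) - sum(responder[!pos])))
  ft <- fisher.test(tab)
  .rate_comparison("phenocopy_positive", "phenocopy_negative",
                   sum(responder[pos]), sum(pos),
                   sum(responder[!pos]), sum(!pos),
                   unname(ft$estimate), ft$p.value, "fisher_exact")
}
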