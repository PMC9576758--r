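#' Orient drug-response values so lower means more sensitive
#'
#' IC50 z-scores and dose-response AUC are already "lower = sensitive";
#' activity area is the opposite (a larger ActArea means more killing), so
#' ActArea values are negated. The `oriented` attribute records that the
#' table has been processed, making the operation idempotent.
#'
#' @param table Data frame with columns `sample_id`, `drug_id`, `value`,
#'   `metric_kind` (one of `ic50_z`, `act_area`, `auc`), and optionally
#'   `dataset_tag`.
#' @return The table with all values in "lower = sensitive" orientation and
#'   attribute `oriented = TRUE`. Unknown metric kinds are an error.
#' @export
orient_response <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "drug_id", "value", "metric_kind") %in% names(table)))
  if (isTRUE(attr(table, "oriented"))) return(table)
  known <- c("ic50_z", "act_area", "auc")
  bad <- setdiff(unique(table$metric_kind), known)
  if (length(bad) > 0L) {
    stop("unknown metric_kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  flip <- table$metric_kind == "act_area"
  table$value[flip] <- -table$value[flip]
  attr(table, "oriented") <- TRUE
  table
}

# Gaussian-ML likelihood-ratio statistic for nested OLS fits
.lr_chi2 <- function(rss_reduced, rss_full, n) n * log(rss_reduced / rss_full)

.empty_result <- function(drug_id, pathway_name, dataset_tag, n, reason,
                          three = FALSE) {
  out <- data.frame(
    drug_id = drug_id, pathway_name = pathway_name, dataset_tag = dataset_tag,
    n = n, coef_mutation = NA_real_, p_mutation = NA_real_,
    coef_phenocopy = NA_real_, p_phenocopy = NA_real_,
    chi2 = NA_real_, df = NA_integer_, p_raw = NA_real_, q_bh = NA_real_,
    degenerate = TRUE, reason = reason, stringsAsFactors = FALSE
  )
  if (three) {
    out$coef_pathogenic <- NA_real_
    out$p_pathogenic <- NA_real_
  }
  out
}

#' Nested linear models: does phenocopy status add to mutation status?
#'
#' Fits, by ordinary least squares on complete cases, a reduced model
#' `response ~ mutation` and a full model `response ~ mutation + phenocopy`,
#' and compares them with the Gaussian likelihood-ratio statistic
#' `chi2 = n * ln(RSS_reduced / RSS_full)` on 1 degree of freedom. Negative
#' coefficients mean association with sensitivity (the response must be
#' oriented lower = sensitive, see [orient_response()]). Degenerate designs
#' (constant or collinear phenocopy, too few samples) are returned flagged
#' rather than failing, so panel runs can proceed; flagged rows are excluded
#' from the FDR family by [adjust_fdr()].
#'
#' @param response Numeric oriented response values.
#' @param mutation Binary mutation-status vector.
#' @param phenocopy Binary phenocopy-call vector.
#' @param drug_id,pathway_name,dataset_tag Identifiers carried into the
#'   result row.
#' @param n_min Minimum complete-case count (default 20).
#' @return One-row data frame: coefficients and per-term p-values from the
#'   full model, `chi2`, `df`, `p_raw`, `q_bh` (filled later), `degenerate`,
#'   `reason`.
#' @export
fit_nested_models <- function(response, mutation, phenocopy,
                              drug_id = NA_character_,
                              pathway_name = NA_character_,
                              dataset_tag = NA_character_, n_min = 20L) {
  stopifnot(length(mutation) == length(response),
            length(phenocopy) == length(response))
  cc <- complete.cases(response, mutation, phenocopy)
  y <- response[cc]; m <- as.numeric(mutation[cc]); ph <- as.numeric(phenocopy[cc])
  n <- length(y)
  if (n < n_min) {
    return(.empty_result(drug_id, pathway_name, dataset_tag, n, "too_few_samples"))
  }
  x_full <- cbind(1, m, ph)
  if (qr(x_full)$rank < 3L) {
    return(.empty_result(drug_id, pathway_name, dataset_tag, n,
                         "phenocopy_collinear_or_constant"))
  }
  fit0 <- lm(y ~ m)
  fit1 <- lm(y ~ m + ph)
  rss0 <- sum(residuals(fit0)^2)
  rss1 <- sum(residuals(fit1)^2)
  chi2 <- max(.lr_chi2(rss0, rss1, n), 0)
  coefs <- summary(fit1)$coefficients
  data.frame(
    drug_id = drug_id, pathway_name = pathway_name, dataset_tag = dataset_tag,
    n = n,
    coef_mutation = coefs["m", "Estimate"],
    p_mutation = coefs["m", "Pr(>|t|)"],
    coef_phenocopy = coefs["ph", "Estimate"],
    p_phenocopy = coefs["ph", "Pr(>|t|)"],
    chi2 = chi2, df = 1L,
    p_raw = pchisq(chi2, 1L, lower.tail = FALSE),
    q_bh = NA_real_, degenerate = FALSE, reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Three-predictor model: mutation, pathogenic mutation, phenocopy
#'
#' The volcano-style variant: the full model regresses oriented response on
#' mutation status, pathogenic-mutation status and the phenocopy call, and
#' reports each term's coefficient and p-value. The likelihood-ratio part
#' compares it to the reduced model with the DNA terms only
#' (`~ mutation + pathogenic`), so `chi2` still measures what phenocopy adds
#' beyond all DNA information (1 df). Pathogenic status must imply mutation;
#' when no pathogenic mutations are present the term is dropped and the row
#' flagged `pathogenic_dropped` (its chi2 then matches [fit_nested_models()]).
#'
#' @inheritParams fit_nested_models
#' @param pathogenic Binary pathogenic-mutation vector, coded only among
#'   mutated samples.
#' @return One-row data frame as in [fit_nested_models()], with
#'   `coef_pathogenic` and `p_pathogenic` added.
#' @export
fit_three_predictor_model <- function(response, mutation, pathogenic, phenocopy,
                                      drug_id = NA_character_,
                                      pathway_name = NA_character_,
                                      dataset_tag = NA_character_, n_min = 20L) {
  stopifnot(length(mutation) == length(response),
            length(pathogenic) == length(response),
            length(phenocopy) == length(response))
  if (any(pathogenic == 1 & mutation == 0, na.rm = TRUE)) {
    stop("`pathogenic` must imply `mutation` (pathogenic-only samples found)",
         call. = FALSE)
  }
  cc <- complete.cases(response, mutation, pathogenic, phenocopy)
  y <- response[cc]; m <- as.numeric(mutation[cc])
  pg <- as.numeric(pathogenic[cc]); ph <- as.numeric(phenocopy[cc])
  n <- length(y)
  if (all(m == 0) && all(pg == 0) && all(ph == 0)) {
    stop("all predictors are zero vectors", call. = FALSE)
  }
  if (n < n_min) {
    return(.empty_result(drug_id, pathway_name, dataset_tag, n,
                         "too_few_samples", three = TRUE))
  }
  if (all(pg == 0)) {
    out <- fit_nested_models(y, m, ph, drug_id, pathway_name, dataset_tag, n_min)
    out$coef_pathogenic <- NA_real_
    out$p_pathogenic <- NA_real_
    out$degenerate <- TRUE
    out$reason <- "pathogenic_dropped"
    return(out)
  }
  if (qr(cbind(1, m, pg, ph))$rank < 4L) {
    return(.empty_result(drug_id, pathway_name, dataset_tag, n,
                         "collinear_design", three = TRUE))
  }
  fit0 <- lm(y ~ m + pg)
  fit1 <- lm(y ~ m + pg + ph)
  rss0 <- sum(residuals(fit0)^2)
  rss1 <- sum(residuals(fit1)^2)
  chi2 <- max(.lr_chi2(rss0, rss1, n), 0)
  coefs <- summary(fit1)$coefficients
  data.frame(
    drug_id = drug_id, pathway_name = pathway_name, dataset_tag = dataset_tag,
    n = n,
    coef_mutation = coefs["m", "Estimate"],
    p_mutation = coefs["m", "Pr(>|t|)"],
    coef_phenocopy = coefs["ph", "Estimate"],
    p_phenocopy = coefs["ph", "Pr(>|t|)"],
    chi2 = chi2, df = 1L,
    p_raw = pchisq(chi2, 1L, lower.tail = FALSE),
    q_bh = NA_real_, degenerate = FALSE, reason = NA_character_,
    coef_pathogenic = coefs["pg", "Estimate"],
    p_pathogenic = coefs["pg", "Pr(>|t|)"],
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg FDR adjustment over a family of nested-model results
#'
#' Applies BH step-up to the raw likelihood-ratio p-values of all
#' non-degenerate results. The family is pooled across every
#' drug/pathway/dataset combination in the run by default; `"per-dataset"`
#' adjusts within each `dataset_tag` separately.
#'
#' @param results Data frame of rows from [fit_nested_models()] /
#'   [fit_three_predictor_model()].
#' @param family `"pooled"` (default) or `"per-dataset"`.
#' @return `results` with `q_bh` filled for non-degenerate rows (degenerate
#'   rows keep `NA`). An empty non-degenerate family is an error.
#' @export
adjust_fdr <- function(results, family = c("pooled", "per-dataset")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(results), all(c("p_raw", "degenerate") %in% names(results)))
  ok <- !results$degenerate
  if (!any(ok)) stop("no non-degenerate results to adjust", call. = FALSE)
  if (family == "pooled") {
    results$q_bh[ok] <- p.adjust(results$p_raw[ok], method = "BH")
  } else {
    for (tag in unique(results$dataset_tag[ok])) {
      idx <- ok & results$dataset_tag %in% tag
      results$q_bh[idx] <- p.adjust(results$p_raw[idx], method = "BH")
    }
  }
  results
}

#' Evaluate a drug panel: one nested model per drug and dataset
#'
#' Convenience wrapper running [orient_response()], then per
#' (drug, dataset) a complete-case nested-model fit against the supplied
#' labels and phenocopy calls, then [adjust_fdr()] over the family.
#'
#' @param response_table Drug-response table (see [orient_response()]).
#' @param labels Label data frame from [build_labels()].
#' @param calls Phenocopy calls from [predict_phenocopy()] (columns
#'   `sample_id`, `call`).
#' @param pathway_name Carried into the results.
#' @param model `"two"` (mutation + phenocopy) or `"three"` (adds the
#'   pathogenic term).
#' @param family FDR family, see [adjust_fdr()].
#' @param n_min Minimum complete-case count per fit.
#' @return Data frame of per-drug results with `q_bh` filled.
#' @export
evaluate_drug_panel <- function(response_table, labels, calls,
                                pathway_name = "pathway",
                                model = c("two", "three"),
                                family = c("pooled", "per-dataset"),
                                n_min = 20L) {
  model <- match.arg(model)
  family <- match.arg(family)
  stopifnot(all(c("sample_id", "any_mutation") %in% names(labels)),
            all(c("sample_id", "call") %in% names(calls)))
  oriented <- orient_response(response_table)
  if (!"dataset_tag" %in% names(oriented)) oriented$dataset_tag <- "dataset"
  mut <- setNames(labels$any_mutation, labels$sample_id)
  pg <- if ("pathogenic_mutation" %in% names(labels)) {
    setNames(labels$pathogenic_mutation, labels$sample_id)
  } else NULL
  phe <- setNames(calls$call, calls$sample_id)
  groups <- unique(oriented[, c("drug_id", "dataset_tag")])
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- oriented[oriented$drug_id == groups$drug_id[i] &
                      oriented$dataset_tag == groups$dataset_tag[i], ]
    ids <- sub$sample_id
    rows[[i]] <- if (model == "two") {
      fit_nested_models(sub$value, mut[ids], phe[ids],
                        drug_id = groups$drug_id[i],
                        pathway_name = pathway_name,
                        dataset_tag = groups$dataset_tag[i], n_min = n_min)
    } else {
      if (is.null(pg)) {
        stop("three-predictor model needs a `pathogenic_mutation` label column",
             call. = FALSE)
      }
      fit_three_predictor_model(sub$value, mut[ids], pg[ids], phe[ids],
                                drug_id = groups$drug_id[i],
                                pathway_name = pathway_name,
                                dataset_tag = groups$dataset_tag[i],
                                n_min = n_min)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$degenerate)) out <- adjust_fdr(out, family = family)
  out
}
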