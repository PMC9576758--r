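#' Configuration for synthetic cohort generation
#'
#' Builds and validates the parameter set of the synthetic-cohort generator.
#' The generator encodes the causal structure the downstream analysis assumes:
#' driver mutations are a mix of pathogenic and passenger events; pathogenic
#' mutations or pathway amplification activate a latent transcriptional
#' program with probability `penetrance`; activation shifts signal-gene
#' expression by `signal_shift` and shifts response to on-target drugs by
#' `-drug_effect` (lower = more sensitive).
#'
#' Defaults describe a pan-cancer training-style cohort: four cancer types of
#' 250 samples each with heterogeneous driver-alteration rates (one type below
#' the 5\% training cut so the cancer-type filter is exercised), a 60-gene
#' pathway of which half the genes carry signal, and a drug panel in which
#' half the drugs are on-target.
#'
#' @param seed Integer seed; identical seeds yield bit-identical bundles.
#' @param n_cancer_types Number of cancer types.
#' @param samples_per_type Samples per cancer type.
#' @param alteration_rate_per_type Per-type probability that a sample carries
#'   a driver-gene mutation; recycled to `n_cancer_types`.
#' @param pathogenic_fraction Fraction of driver mutations that are functional
#'   (pathogenic) rather than passengers.
#' @param cnv_rate Probability of pathway amplification per sample.
#' @param penetrance Probability that a functional lesion (pathogenic mutation
#'   or amplification) activates the latent program.
#' @param n_pathway_genes Number of pathway feature genes.
#' @param n_signal_genes Number of pathway genes whose expression responds to
#'   activation; must not exceed `n_pathway_genes`.
#' @param n_background_genes Genes outside the pathway (pure noise).
#' @param signal_shift Expression shift (z-units) of signal genes when the
#'   program is active.
#' @param expr_noise_sd Expression noise standard deviation (z-units).
#' @param n_drugs Number of drugs in the response panel.
#' @param on_target_fraction Fraction of drugs whose response depends on
#'   activation.
#' @param drug_effect Response shift per unit activation for on-target drugs,
#'   applied with negative sign (lower = sensitive).
#' @param response_noise_sd Response noise standard deviation.
#' @param annotation_error_rate Probability that a mutation's annotation
#'   strings contradict its true pathogenicity.
#' @param treatment_selection_strength Probability that an activation-positive
#'   tumor is eliminated from the post-treatment arm of a paired cohort.
#' @param response_driver What drives on-target drug response:
#'   `"activation"` (default, the latent program), or `"mutation"` (the raw
#'   mutation label, a null construction in which phenocopy status carries no
#'   information about response beyond mutation status).
#' @param continuous_activation If `TRUE`, activation is a continuous dose in
#'   `[0,1]` (the Bernoulli draw times a Uniform dose) instead of binary.
#'   Off by default, matching binary phenocopy calls.
#' @return A validated `synthetic_config` object (a named list).
#' @seealso [generate_cohort()], [generate_paired_cohort()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_cancer_types = 4L,
                             samples_per_type = 250L,
                             alteration_rate_per_type = c(0.10, 0.20, 0.30, 0.04),
                             pathogenic_fraction = 0.7,
                             cnv_rate = 0.15,
                             penetrance = 0.9,
                             n_pathway_genes = 60L,
                             n_signal_genes = 30L,
                             n_background_genes = 200L,
                             signal_shift = 1,
                             expr_noise_sd = 1,
                             n_drugs = 10L,
                             on_target_fraction = 0.5,
                             drug_effect = 1,
                             response_noise_sd = 1,
                             annotation_error_rate = 0.05,
                             treatment_selection_strength = 0.5,
                             response_driver = c("activation", "mutation"),
                             continuous_activation = FALSE) {
  response_driver <- match.arg(response_driver)
  cfg <- list(
    seed = as.integer(seed),
    n_cancer_types = as.integer(n_cancer_types),
    samples_per_type = as.integer(samples_per_type),
    alteration_rate_per_type = rep_len(alteration_rate_per_type, n_cancer_types),
    pathogenic_fraction = pathogenic_fraction,
    cnv_rate = cnv_rate,
    penetrance = penetrance,
    n_pathway_genes = as.integer(n_pathway_genes),
    n_signal_genes = as.integer(n_signal_genes),
    n_background_genes = as.integer(n_background_genes),
    signal_shift = signal_shift,
    expr_noise_sd = expr_noise_sd,
    n_drugs = as.integer(n_drugs),
    on_target_fraction = on_target_fraction,
    drug_effect = drug_effect,
    response_noise_sd = response_noise_sd,
    annotation_error_rate = annotation_error_rate,
    treatment_selection_strength = treatment_selection_strength,
    response_driver = response_driver,
    continuous_activation = isTRUE(continuous_activation)
  )
  fracs <- c("pathogenic_fraction", "cnv_rate", "penetrance",
             "on_target_fraction", "annotation_error_rate",
             "treatment_selection_strength")
  for (f in fracs) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L ||
        is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("`%s` must be a single value in [0, 1]", f), call. = FALSE)
    }
  }
  if (any(cfg$alteration_rate_per_type < 0 | cfg$alteration_rate_per_type > 1)) {
    stop("`alteration_rate_per_type` values must lie in [0, 1]", call. = FALSE)
  }
  counts <- c("n_cancer_types", "samples_per_type", "n_pathway_genes",
              "n_signal_genes", "n_background_genes", "n_drugs")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop(sprintf("`%s` must be a count >= 1", f), call. = FALSE)
    }
  }
  if (cfg$n_signal_genes > cfg$n_pathway_genes) {
    stop("`n_signal_genes` must not exceed `n_pathway_genes`", call. = FALSE)
  }
  for (f in c("expr_noise_sd", "response_noise_sd")) {
    if (cfg[[f]] < 0) stop(sprintf("`%s` must be >= 0", f), call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Define a pathway by its driver and feature genes
#'
#' Driver genes are the genes whose mutations define the alteration label
#' (e.g. PIK3CA/AKT1/AKT2 for the PI3K-AKT pathway); feature genes are the
#' pathway-membership genes whose expression feeds the phenocopy classifier.
#' The two sets play different roles and need not overlap.
#'
#' @param name Pathway identifier, unique within a run.
#' @param driver_genes Character vector of gene symbols defining the label.
#' @param feature_genes Character vector of expression feature gene symbols.
#' @return A `pathway_definition` object.
#' @export
pathway_definition <- function(name, driver_genes, feature_genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  driver_genes <- unique(as.character(driver_genes))
  feature_genes <- unique(as.character(feature_genes))
  if (length(driver_genes) == 0L || length(feature_genes) == 0L) {
    stop("`driver_genes` and `feature_genes` must be non-empty", call. = FALSE)
  }
  structure(list(name = name, driver_genes = driver_genes,
                 feature_genes = feature_genes),
            class = "pathway_definition")
}

# Annotation strings consistent with true pathogenicity, then flipped with
# probability error_rate. Guarantees: with error_rate = 0 the consensus call
# (any damaging tool OR ClinVar pathogenic/likely pathogenic) equals `truth`.
.make_annotations <- function(truth, error_rate) {
  m <- length(truth)
  ann <- data.frame(
    sift = rep(NA_character_, m), polyphen_hdiv = rep(NA_character_, m),
    polyphen_hvar = rep(NA_character_, m), fathmm = rep(NA_character_, m),
    clinvar = rep(NA_character_, m), stringsAsFactors = FALSE
  )
  if (m == 0L) return(ann)
  pat <- truth == 1L
  npat <- sum(pat)
  if (npat > 0L) {
    ann$sift[pat] <- sample(c("D", "T"), npat, TRUE, c(0.8, 0.2))
    ann$polyphen_hdiv[pat] <- sample(c("D", "P", "B"), npat, TRUE, c(0.6, 0.2, 0.2))
    ann$polyphen_hvar[pat] <- sample(c("D", "P", "B"), npat, TRUE, c(0.5, 0.3, 0.2))
    ann$fathmm[pat] <- sample(c("D", "T"), npat, TRUE, c(0.7, 0.3))
    ann$clinvar[pat] <- sample(c("Pathogenic", "Likely_pathogenic", "VUS"),
                               npat, TRUE, c(0.3, 0.2, 0.5))
    # consensus must see at least one damaging field for a true pathogenic record
    none <- pat & !(ann$sift %in% "D" | ann$polyphen_hdiv %in% c("D", "P") |
                      ann$polyphen_hvar %in% c("D", "P") | ann$fathmm %in% "D" |
                      ann$clinvar %in% c("Pathogenic", "Likely_pathogenic"))
    ann$sift[none] <- "D"
    # secondary tools occasionally unannotated
    drop_hdiv <- pat & runif(m) < 0.1
    drop_fathmm <- pat & runif(m) < 0.1
    ann$polyphen_hdiv[drop_hdiv] <- NA_character_
    ann$fathmm[drop_fathmm] <- NA_character_
  }
  ben <- !pat
  nben <- sum(ben)
  if (nben > 0L) {
    ann$sift[ben] <- sample(c("T", NA), nben, TRUE, c(0.85, 0.15))
    ann$polyphen_hdiv[ben] <- sample(c("B", NA), nben, TRUE, c(0.85, 0.15))
    ann$polyphen_hvar[ben] <- sample(c("B", NA), nben, TRUE, c(0.85, 0.15))
    ann$fathmm[ben] <- sample(c("T", NA), nben, TRUE, c(0.85, 0.15))
    ann$clinvar[ben] <- sample(c("Benign", "VUS", NA), nben, TRUE, c(0.4, 0.4, 0.2))
  }
  flip <- runif(m) < error_rate
  to_benign <- flip & pat
  ann$sift[to_benign] <- "T"
  ann$polyphen_hdiv[to_benign] <- "B"
  ann$polyphen_hvar[to_benign] <- "B"
  ann$fathmm[to_benign] <- "T"
  ann$clinvar[to_benign] <- "VUS"
  to_damaging <- flip & !pat
  ann$sift[to_damaging] <- "D"
  ann
}

# Core generator; assumes the RNG state has already been seeded.
.generate_cohort_impl <- function(config) {
  n <- config$n_cancer_types * config$samples_per_type
  sample_ids <- sprintf("S%05d", seq_len(n))
  cancer_type <- rep(sprintf("CT%02d", seq_len(config$n_cancer_types)),
                     each = config$samples_per_type)
  names(cancer_type) <- sample_ids

  n_sig <- config$n_signal_genes
  n_pwy <- config$n_pathway_genes
  signal_genes <- sprintf("SIG%03d", seq_len(n_sig))
  other_pwy <- if (n_pwy > n_sig) sprintf("PWY%03d", seq_len(n_pwy - n_sig)) else character()
  background_genes <- sprintf("BKG%03d", seq_len(config$n_background_genes))
  driver_genes <- c("DRV1", "DRV2", "DRV3")
  pathway <- pathway_definition("SYNTH_PATHWAY", driver_genes,
                                c(signal_genes, other_pwy))

  # causal chain, drawn in a fixed order: mutation -> pathogenicity -> CNV ->
  # activation
  rate <- config$alteration_rate_per_type[match(cancer_type,
            sprintf("CT%02d", seq_len(config$n_cancer_types)))]
  mutated <- rbinom(n, 1L, rate)
  pathogenic <- mutated * rbinom(n, 1L, config$pathogenic_fraction)
  amplified <- rbinom(n, 1L, config$cnv_rate)
  eligible <- as.integer(pathogenic == 1L | amplified == 1L)
  act_draw <- rbinom(n, 1L, config$penetrance)
  if (config$continuous_activation) {
    dose <- runif(n)
    activation <- eligible * act_draw * dose
  } else {
    activation <- eligible * act_draw
  }
  names(activation) <- sample_ids

  genes <- c(signal_genes, other_pwy, background_genes)
  expr <- matrix(rnorm(length(genes) * n, 0, config$expr_noise_sd),
                 nrow = length(genes), ncol = n,
                 dimnames = list(genes, sample_ids))
  expr[signal_genes, ] <- expr[signal_genes, , drop = FALSE] +
    rep(config$signal_shift * activation, each = n_sig)

  # one protein-altering driver record per mutated sample, plus occasional
  # silent driver records and passenger records in background genes
  mut_idx <- which(mutated == 1L)
  rec <- data.frame(
    sample_id = sample_ids[mut_idx],
    gene = sample(driver_genes, length(mut_idx), TRUE),
    variant_class = sample(c("missense", "nonsense", "frameshift"),
                           length(mut_idx), TRUE, c(0.7, 0.15, 0.15)),
    stringsAsFactors = FALSE
  )
  rec_truth <- pathogenic[mut_idx]

  silent_idx <- which(runif(n) < 0.10)
  if (length(silent_idx) > 0L) {
    rec <- rbind(rec, data.frame(
      sample_id = sample_ids[silent_idx],
      gene = sample(driver_genes, length(silent_idx), TRUE),
      variant_class = sample(c("silent", "intronic", "upstream", "downstream",
                               "splicing"), length(silent_idx), TRUE),
      stringsAsFactors = FALSE
    ))
    rec_truth <- c(rec_truth, rep(0L, length(silent_idx)))
  }
  pass_idx <- which(runif(n) < 0.10)
  if (length(pass_idx) > 0L) {
    rec <- rbind(rec, data.frame(
      sample_id = sample_ids[pass_idx],
      gene = sample(background_genes, length(pass_idx), TRUE),
      variant_class = "missense",
      stringsAsFactors = FALSE
    ))
    rec_truth <- c(rec_truth, rep(0L, length(pass_idx)))
  }
  mutations <- cbind(rec, .make_annotations(rec_truth, config$annotation_error_rate))

  # CNV: one pathway-gene record per sample; amplified samples get an
  # "amplified" call, others neutral with a low background deletion rate
  cnv_gene <- sample(pathway$feature_genes, n, TRUE)
  cnv_cat <- ifelse(amplified == 1L, "amplified",
                    ifelse(runif(n) < 0.02, "deleted", "neutral"))
  cnv <- data.frame(sample_id = sample_ids, gene = cnv_gene,
                    category = cnv_cat, stringsAsFactors = FALSE)

  n_on <- round(config$n_drugs * config$on_target_fraction)
  drug_ids <- sprintf("DRUG%02d", seq_len(config$n_drugs))
  on_target <- c(rep(TRUE, n_on), rep(FALSE, config$n_drugs - n_on))
  resp <- vector("list", config$n_drugs)
  driver <- switch(config$response_driver,
                   activation = activation, mutation = as.numeric(mutated))
  for (d in seq_len(config$n_drugs)) {
    eff <- if (on_target[d]) -config$drug_effect * driver else 0
    resp[[d]] <- data.frame(
      sample_id = sample_ids, drug_id = drug_ids[d],
      value = eff + rnorm(n, 0, config$response_noise_sd),
      metric_kind = "ic50_z", dataset_tag = "synthetic",
      stringsAsFactors = FALSE
    )
  }
  drug_response <- do.call(rbind, resp)
  rownames(drug_response) <- NULL

  structure(list(
    expression = expr,
    cancer_type = cancer_type,
    mutations = mutations,
    true_pathogenic = rec_truth,
    cnv = cnv,
    drug_response = drug_response,
    latent_activation = activation,
    pathway = pathway,
    drug_info = data.frame(drug_id = drug_ids, on_target = on_target,
                           stringsAsFactors = FALSE),
    config = config
  ), class = "synthetic_bundle")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws one cohort under the generator's causal model: per sample, a driver
#' mutation (per-cancer-type rate), its pathogenicity, pathway amplification,
#' then latent activation with probability `penetrance` given a pathogenic
#' mutation or amplification; signal-gene expression and on-target drug
#' response are shifted by activation, everything else is noise. Annotation
#' strings (SIFT/PolyPhen-2/FATHMM/ClinVar vocabularies) are consistent with
#' true pathogenicity except for a configurable error rate, and the mutation
#' table additionally carries silent/intronic driver records and passenger
#' records in background genes, so the filtering and consensus steps are
#' exercised realistically.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_bundle`: list with `expression` (genes x samples
#'   matrix), `cancer_type` (named vector), `mutations` (MAF-like data frame),
#'   `true_pathogenic` (per-mutation-record ground truth), `cnv`,
#'   `drug_response` (long table, lower = sensitive), `latent_activation`
#'   (named per-sample ground truth), `pathway` ([pathway_definition()]),
#'   `drug_info`, and the `config` used.
#' @examples
#' b <- generate_cohort(synthetic_config(seed = 7, samples_per_type = 50))
#' dim(b$expression)
#' table(b$latent_activation)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  .generate_cohort_impl(config)
}

.subset_bundle <- function(bundle, keep_ids) {
  keep_mut <- bundle$mutations$sample_id %in% keep_ids
  out <- bundle
  out$expression <- bundle$expression[, keep_ids, drop = FALSE]
  out$cancer_type <- bundle$cancer_type[keep_ids]
  out$mutations <- bundle$mutations[keep_mut, , drop = FALSE]
  rownames(out$mutations) <- NULL
  out$true_pathogenic <- bundle$true_pathogenic[keep_mut]
  out$cnv <- bundle$cnv[bundle$cnv$sample_id %in% keep_ids, , drop = FALSE]
  rownames(out$cnv) <- NULL
  out$drug_response <- bundle$drug_response[
    bundle$drug_response$sample_id %in% keep_ids, , drop = FALSE]
  rownames(out$drug_response) <- NULL
  out$latent_activation <- bundle$latent_activation[keep_ids]
  out
}

#' Generate a paired pre/post-treatment cohort
#'
#' Emulates clinical cohorts where pre-treatment (sensitive) and
#' post-treatment (resistant) samples come from the same patients and
#' treatment preferentially eliminates activation-positive tumors: the pre
#' arm is drawn as [generate_cohort()]; the post arm keeps each
#' activation-positive sample only with probability
#' `1 - treatment_selection_strength`, so the post-arm activation rate is
#' lower than the pre-arm rate in expectation.
#'
#' @param config A [synthetic_config()]; `treatment_selection_strength`
#'   controls the elimination probability.
#' @return A list with elements `pre` and `post`, each a `synthetic_bundle`.
#' @export
generate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$treatment_selection_strength
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  pre <- .generate_cohort_impl(config)
  eliminated <- pre$latent_activation > 0 &
    runif(length(pre$latent_activation)) < s
  keep_ids <- names(pre$latent_activation)[!eliminated]
  if (length(keep_ids) == 0L) {
    stop("treatment selection eliminated every sample; lower ",
         "`treatment_selection_strength` or the activation rate", call. = FALSE)
  }
  list(pre = pre, post = .subset_bundle(pre, keep_ids))
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d genes x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  activation rate: %.3f | mutation records: %d | drugs: %d\n",
              mean(x$latent_activation > 0), nrow(x$mutations),
              nrow(x$drug_info)))
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %s: %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write a synthetic bundle to disk in the formats the readers consume
#'
#' Emits the expression matrix as TSV, sample annotations, the MAF-like
#' mutation table, CNV and drug-response tables as TSV, and the pathway's
#' feature genes as a GMT file, so synthetic and real inputs flow through one
#' code path. Ground-truth latents are written to a separate
#' `truth_activation.tsv` for oracle use and are not part of the analysis
#' inputs.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write.table(
    data.frame(sample_id = names(bundle$cancer_type),
               cancer_type = unname(bundle$cancer_type)),
    file.path(dir, "sample_annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$mutations, file.path(dir, "mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write.table(bundle$cnv, file.path(dir, "cnv.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$drug_response, file.path(dir, "drug_response.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(setNames(list(bundle$pathway$feature_genes), bundle$pathway$name),
            file.path(dir, "pathway.gmt"))
  write.table(
    data.frame(sample_id = names(bundle$latent_activation),
               activation = unname(bundle$latent_activation)),
    file.path(dir, "truth_activation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
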