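# Independent oracles and small fixture builders shared across test files.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# compact generator config for unit tests
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, samples_per_type = 60L, n_background_genes = 40L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# labels rebuilt from a bundle through the package's own annotation path
bundle_labels <- function(bundle) {
  build_labels(quiet(filter_protein_altering(bundle$mutations)),
               bundle$pathway, colnames(bundle$expression))
}

# phenocopy calls from the generator's ground truth (a perfect classifier)
truth_calls <- function(bundle) {
  data.frame(sample_id = names(bundle$latent_activation),
             call = as.integer(bundle$latent_activation > 0),
             stringsAsFactors = FALSE)
}

# per-sample true pathogenic-mutation status from per-record ground truth
sample_true_pathogenic <- function(bundle) {
  ids <- colnames(bundle$expression)
  out <- setNames(rep(0L, length(ids)), ids)
  if (nrow(bundle$mutations) > 0L) {
    agg <- tapply(bundle$true_pathogenic, bundle$mutations$sample_id, max)
    out[names(agg)] <- as.integer(agg)
  }
  out
}

# O(n_pos * n_neg) pairwise-concordance AUC
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# literal Benjamini-Hochberg step-up from its definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (k in rev(seq_len(m - 1))) adj[k] <- min(adj[k], adj[k + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Pearson chi-square of a 2x2 table from the expected-count formula
pearson_2x2 <- function(tab) {
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(((tab - expd)^2 / expd)[expd > 0])
}

# exhaustive hypergeometric enumeration for the two-sided Fisher p-value
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Gaussian-ML likelihood-ratio oracle via stats::logLik on both fits
lr_loglik_oracle <- function(y, m, ph) {
  2 * (as.numeric(stats::logLik(stats::lm(y ~ m + ph))) -
         as.numeric(stats::logLik(stats::lm(y ~ m))))
}
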