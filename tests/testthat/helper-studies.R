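# Shared fixture builders. Everything is generated in code; no stored data.

# A deterministic noiseless study: known half-life, simple peptide layout.
noiseless_study <- function(half_life = 20, n_peptides = 3, n_leu = 3,
                            p_enrich = 0.5, time_points = c(3, 7, 12, 17),
                            seed = 101) {
  gt <- simulate_ground_truth(
    1, half_life_law = list(dist = "point", value = half_life), seed = seed)
  pep <- generate_peptides(
    gt,
    peptides_per_protein_law = list(dist = "point", value = n_peptides),
    leu_count_law = list(dist = "point", value = n_leu), seed = seed + 1)
  design <- study_design(time_points = time_points, noise_cv = 0,
                         missing_rate = 0, enrichment_max = p_enrich,
                         seed = seed + 2)
  env <- simulate_timecourse(gt, pep, design)
  list(ground_truth = gt, peptides = pep, design = design, envelopes = env,
       fraction_new = deconvolve_table(env, p = p_enrich))
}

# Many-protein study in one simulator call; per-protein noise is independent,
# so protein-level statistics act as independent Monte Carlo replicates.
batch_study <- function(n_proteins, half_life_law, noise_cv, seed,
                        n_peptides = 3, n_leu = 3, missing_rate = 0,
                        hl_change = list(n_longer = 0L, n_shorter = 0L)) {
  gt <- simulate_ground_truth(n_proteins, half_life_law = half_life_law,
                              hl_change = hl_change, seed = seed)
  pep <- generate_peptides(
    gt,
    peptides_per_protein_law = list(dist = "point", value = n_peptides),
    leu_count_law = list(dist = "point", value = n_leu), seed = seed + 1)
  design <- study_design(noise_cv = noise_cv, missing_rate = missing_rate,
                         seed = seed + 2)
  env <- simulate_timecourse(gt, pep, design)
  list(ground_truth = gt, peptides = pep, design = design, envelopes = env)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# One-sided hypergeometric tail P(X >= x) by explicit enumeration with
# binomial coefficients; independent of stats::fisher.test / dhyper.
hyper_tail_oracle <- function(x, K, n, N) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
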