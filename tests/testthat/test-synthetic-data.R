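test_that("ground truth generation validates inputs and honours laws", {
  expect_error(simulate_ground_truth(0), "n_proteins")
  expect_error(simulate_ground_truth(5, compartment_props = c(mito = 0.7,
                                                              cyto = 0.7)),
               "sum to 1")
  gt <- simulate_ground_truth(
    50, half_life_law = list(dist = "point", value = 25), seed = 1)
  expect_true(all(gt$true_half_life == 25))
  expect_true(all(gt$base_abundance > 0))
  expect_setequal(unique(gt$compartment), c("mito", "cyto", "other"))
})

test_that("identical seeds reproduce identical datasets", {
  a <- simulate_ground_truth(30, seed = 42)
  b <- simulate_ground_truth(30, seed = 42)
  expect_identical(a, b)
  pep_a <- generate_peptides(a, seed = 7)
  pep_b <- generate_peptides(b, seed = 7)
  expect_identical(pep_a, pep_b)
  d <- study_design(seed = 9, noise_cv = 0.2, missing_rate = 0.1)
  expect_identical(simulate_timecourse(a, pep_a, d),
                   simulate_timecourse(b, pep_b, d))
  expect_identical(simulate_abundances(a, pep_a, d),
                   simulate_abundances(b, pep_b, d))
})

test_that("age effects are assigned as configured", {
  gt <- simulate_ground_truth(
    100, da_fraction = 0.2, da_log2fc = 1, da_compartment = "mito",
    hl_change = list(n_longer = 10L, n_shorter = 5L,
                     longer_mult = 1.5, shorter_mult = 0.5), seed = 3)
  expect_true(all(gt$compartment[gt$group_log2_effect != 0] == "mito"))
  expect_equal(sum(gt$old_hl_multiplier == 1.5), 10)
  expect_equal(sum(gt$old_hl_multiplier == 0.5), 5)
})

test_that("peptides map uniquely to proteins under point-mass laws", {
  gt <- simulate_ground_truth(1, seed = 5)
  pep <- generate_peptides(
    gt, peptides_per_protein_law = list(dist = "point", value = 3),
    leu_count_law = list(dist = "point", value = 0), seed = 6)
  expect_equal(nrow(pep), 3)
  expect_true(all(pep$protein_id == gt$protein_id))
  expect_true(all(pep$n_leu == 0))
  expect_equal(anyDuplicated(pep$peptide_id), 0)
  expect_error(generate_peptides(gt[0, ]), "non-empty")
})

test_that("the forward model puts f = 0.5 after one half-life", {
  st <- noiseless_study(half_life = 10, time_points = c(5, 10, 20))
  fn <- st$fraction_new
  expect_equal(unique(round(fn$percent_new[fn$time_days == 10], 9)), 50)
  # strictly increasing in time
  means <- tapply(fn$percent_new, fn$time_days, mean)
  expect_true(all(diff(means) > 0))
})

test_that("fraction-new falls with half-life at fixed time", {
  slow <- noiseless_study(half_life = 60, time_points = c(7, 14))
  fast <- noiseless_study(half_life = 6, time_points = c(7, 14))
  f_slow <- mean(slow$fraction_new$percent_new[
    slow$fraction_new$time_days == 7])
  f_fast <- mean(fast$fraction_new$percent_new[
    fast$fraction_new$time_days == 7])
  expect_lt(f_slow, f_fast)
})

test_that("timecourse layout matches the design and the envelope dialect", {
  gt <- simulate_ground_truth(3, seed = 8)
  pep <- generate_peptides(gt, seed = 9)
  d <- study_design(noise_cv = 0, missing_rate = 0, seed = 10)
  env <- simulate_timecourse(gt, pep, d)
  expect_named(env, c("peptide_id", "protein_id", "sample_id", "group",
                      "time_days", "rt_minutes", "n_leu", "channel",
                      "intensity"))
  expect_equal(length(unique(env$sample_id)),
               length(d$time_points) * d$n_animals * length(d$groups))
  # channels per peptide = n_leu + 1
  one <- env[env$peptide_id == pep$peptide_id[1] &
               env$sample_id == env$sample_id[1], ]
  expect_equal(sort(one$channel), 0:pep$n_leu[1])
})

test_that("missingness drops whole envelopes at the configured rate", {
  gt <- simulate_ground_truth(40, seed = 12)
  pep <- generate_peptides(gt, seed = 13)
  d <- study_design(noise_cv = 0, missing_rate = 0.3, seed = 14)
  env <- simulate_timecourse(gt, pep, d)
  obs <- unique(env[, c("peptide_id", "sample_id")])
  n_expected <- nrow(pep) * length(unique(env$sample_id))
  expect_equal(nrow(obs) / n_expected, 0.7, tolerance = 0.05)
  # no partial envelopes
  sizes <- tapply(env$channel, paste(env$peptide_id, env$sample_id), length)
  nl <- pep$n_leu[match(sub(" .*", "", names(sizes)), pep$peptide_id)]
  expect_equal(as.numeric(sizes), nl + 1)
})

test_that("noiseless abundances double under a log2 effect of 1", {
  gt <- simulate_ground_truth(4, da_fraction = 1, da_log2fc = 1, seed = 15)
  pep <- generate_peptides(gt, seed = 16)
  d <- study_design(noise_cv = 0, missing_rate = 0, seed = 17)
  ab <- simulate_abundances(gt, pep, d)
  ratio <- tapply(ab$auc, list(ab$peptide_id, ab$group), mean)
  expect_equal(unname(ratio[, "old"] / ratio[, "young"]),
               rep(2, nrow(ratio)))
})

test_that("datasets roundtrip through the TSV dialect", {
  gt <- simulate_ground_truth(3, seed = 18)
  pep <- generate_peptides(gt, seed = 19)
  d <- study_design(noise_cv = 0.1, missing_rate = 0, seed = 20)
  env <- simulate_timecourse(gt, pep, d)
  ab <- simulate_abundances(gt, pep, d)
  out <- withr::local_tempdir()
  paths <- write_dataset(list(envelopes = env, abundances = ab,
                              ground_truth = gt), out)
  expect_setequal(basename(unname(paths)),
                  c("envelopes.tsv", "abundances.tsv", "ground_truth.tsv"))
  back <- read_tsv_table(file.path(out, "envelopes.tsv"))
  expect_equal(back, env, tolerance = 1e-12, ignore_attr = TRUE)
  gt_back <- read_tsv_table(file.path(out, "ground_truth.tsv"))
  expect_true("true_half_life_days" %in% names(gt_back))
  expect_equal(nrow(gt_back), nrow(gt))
  # header-only file for an empty table
  write_dataset(list(envelopes = env[0, ]), out)
  expect_equal(nrow(read_tsv_table(file.path(out, "envelopes.tsv"))), 0)
  expect_error(write_dataset(list(x = gt), "/dev/null/nope"), "")
})
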