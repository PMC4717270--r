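test_that("half-life follows first-order kinetics from the slope", {
  expect_equal(half_life_from_slope(-0.0693147), 10.0, tolerance = 1e-5)
  expect_equal(half_life_from_slope(-log(2)), 1.0)
  expect_equal(half_life_from_slope(-log(2) / 365), 365)
  expect_identical(half_life_from_slope(0), Inf)
})

test_that("noiseless fits recover the true half-life exactly", {
  st <- noiseless_study(half_life = 20)
  fn <- st$fraction_new[st$fraction_new$group == "young", ]
  fit <- suppressWarnings(fit_turnover(fn))
  expect_equal(fit$half_life_days, 20, tolerance = 1e-9)
  expect_equal(fit$alpha, -log(2) / 20, tolerance = 1e-9)
  # y(0) = 0 in the simulator, so beta1 = -100
  expect_equal(fit$beta1, -100, tolerance = 1e-6)
  expect_equal(fit$n_peptides, 3)
  expect_false(fit$excluded_flag)

  # the nonlinear cross-check agrees on noiseless data
  nls_fit <- fit_turnover_nls(fn[fn$peptide_id == fn$peptide_id[1], ])
  expect_equal(nls_fit$half_life_days, 20, tolerance = 1e-6)
})

test_that("peptide blocking recovers a common slope that pooling distorts", {
  # two peptides, same rate, different baseline offsets, observed over
  # disjoint time windows: pooling confounds offset with slope
  alpha <- -0.05
  t_a <- c(3, 7)
  t_b <- c(12, 17)
  y_a <- 100 - 90 * exp(alpha * t_a)   # b = ln(90)
  y_b <- 100 - 70 * exp(alpha * t_b)   # b = ln(70)
  m <- data.frame(peptide_id = rep(c("a", "b"), each = 2),
                  time_days = c(t_a, t_b),
                  percent_new = c(y_a, y_b))
  blocked <- suppressWarnings(fit_turnover(m))
  expect_equal(blocked$alpha, alpha, tolerance = 1e-9)
  pooled <- suppressWarnings(fit_turnover(transform(m, peptide_id = "one")))
  expect_gt(abs(pooled$alpha - alpha), 1e-3)
})

test_that("degenerate kinetics inputs are flagged or rejected", {
  m0 <- data.frame(peptide_id = "a", time_days = c(3, 7, 12),
                   percent_new = c(0, 0, 0))
  fit <- suppressWarnings(fit_turnover(m0))
  expect_equal(fit$alpha, 0)
  expect_identical(fit$half_life_days, Inf)
  expect_true(fit$excluded_flag)

  expect_error(fit_turnover(data.frame(peptide_id = "a", time_days = 3,
                                       percent_new = 10)),
               "rate not identifiable")
  # saturated observations are clipped, not fatal
  m100 <- data.frame(peptide_id = "a", time_days = c(3, 7),
                     percent_new = c(50, 100))
  expect_silent(suppressWarnings(fit_turnover(m100)))
})

test_that("fit_turnover_all covers every protein-group and records failures", {
  st <- batch_study(5, list(dist = "point", value = 20), noise_cv = 0.1,
                    seed = 30)
  fn <- deconvolve_table(st$envelopes, p = 0.5)
  fits <- fit_turnover_all(fn)
  expect_equal(nrow(fits), 10)
  expect_setequal(fits$group, c("young", "old"))
  # a protein with one usable time point yields a reasoned NA row
  fn_bad <- fn[!(fn$protein_id == fn$protein_id[1] & fn$time_days > 3), ]
  fits_bad <- fit_turnover_all(fn_bad)
  row <- fits_bad[fits_bad$protein_id == fn$protein_id[1], ]
  expect_true(all(is.na(row$alpha)))
  expect_match(row$exclusion_reason[1], "rate not identifiable")
})

test_that("ANCOVA detects equal slopes as unchanged in the noiseless limit", {
  st <- noiseless_study(half_life = 25)
  cmp <- suppressWarnings(compare_groups_ancova(st$fraction_new,
                                                "young", "old"))
  expect_equal(cmp$delta_alpha, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$half_life_a, cmp$half_life_b)
})

test_that("ANCOVA flags a true rate difference with the right sign", {
  gt <- simulate_ground_truth(
    1, half_life_law = list(dist = "point", value = 20),
    hl_change = list(n_longer = 1L, n_shorter = 0L, longer_mult = 1.5),
    seed = 33)
  pep <- generate_peptides(
    gt, peptides_per_protein_law = list(dist = "point", value = 3),
    leu_count_law = list(dist = "point", value = 3), seed = 34)
  d <- study_design(noise_cv = 0, missing_rate = 0, seed = 35)
  fn <- deconvolve_table(simulate_timecourse(gt, pep, d), p = 0.5)
  cmp <- suppressWarnings(compare_groups_ancova(fn, "young", "old"))
  expect_equal(cmp$half_life_a, 20, tolerance = 1e-9)
  expect_equal(cmp$half_life_b, 30, tolerance = 1e-9)
  expect_gt(cmp$delta_alpha, 0)  # slower turnover: alpha less negative
  expect_equal(cmp$p_value, 0)
})

test_that("ANCOVA rejects degenerate designs", {
  st <- noiseless_study()
  fn <- st$fraction_new
  expect_error(compare_groups_ancova(fn[fn$group == "young", ],
                                     "young", "old"),
               "contrast not estimable")
  fn_flat <- fn[fn$group == "old" | fn$time_days == 3, ]
  expect_error(compare_groups_ancova(fn_flat, "young", "old"),
               "not testable")
})

test_that("the half-life exclusion rule is a fixed point and order-free", {
  fits <- data.frame(
    protein_id = rep(sprintf("P%02d", 1:10), each = 2),
    group = rep(c("young", "old"), 10),
    half_life_days = c(rep(20, 8), 364, 20, 366, 20, rep(25, 4),
                       20, Inf, 30, 31))
  filt <- filter_fits(fits, max_half_life_days = 365)
  # P06 (366 in young) and P09 (Inf) go; 364 stays
  expect_equal(length(unique(filt$excluded$protein_id)), 2)
  expect_equal(length(unique(filt$kept$protein_id)), 8)
  expect_true("P05" %in% filt$kept$protein_id)   # 364 d kept
  expect_false("P06" %in% filt$kept$protein_id)  # 366 d excluded
  expect_true(all(filt$excluded$excluded_flag))
  # idempotent
  again <- filter_fits(filt$kept, max_half_life_days = 365)
  expect_identical(again$kept, filt$kept)
  # order-independent
  shuffled <- filter_fits(fits[sample(nrow(fits)), ], 365)
  expect_setequal(shuffled$kept$protein_id, filt$kept$protein_id)
})
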