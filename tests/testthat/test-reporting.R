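test_that("compartment annotation applies mito precedence", {
  ids <- c("A", "B", "C", "D")
  expect_message(
    ann <- annotate_compartments(ids, mito_list = c("A", "B"),
                                 cyto_list = c("B", "C")),
    "both reference lists")
  expect_equal(ann$compartment, c("mito", "mito", "cyto", "other"))
  expect_equal(attr(ann, "conflicts"), "B")
  expect_equal(nrow(annotate_compartments(character(0), "A")), 0)
})

test_that("identifier lists and GMT files parse", {
  tmp <- withr::local_tempfile()
  writeLines(c("# mito reference", "A", "", "B "), tmp)
  expect_equal(read_id_list(tmp), c("A", "B"))

  gmt <- withr::local_tempfile()
  writeLines(c("set1\tdesc\tA\tB\tC", "set2\tdesc\tB\tD"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(set1 = c("A", "B", "C"), set2 = c("B", "D")))
})

test_that("half-life summaries stratify by compartment and group", {
  fits <- data.frame(
    protein_id = c("A", "B", "C", "A", "B", "C"),
    group = rep(c("young", "old"), each = 3),
    half_life_days = c(10, 20, 30, 12, 22, 32))
  ann <- annotate_compartments(c("A", "B", "C"), mito_list = c("A", "B"),
                               cyto_list = "C")
  s <- summarize_half_lives(fits, ann)
  tot_y <- s[s$stratum == "total" & s$group == "young", ]
  expect_equal(tot_y$median_t_half, 20)
  expect_equal(tot_y$mean_t_half, 20)
  expect_equal(tot_y$n_proteins, 3)
  mito_o <- s[s$stratum == "mito" & s$group == "old", ]
  expect_equal(mito_o$median_t_half, 17)
  cyto_y <- s[s$stratum == "cyto" & s$group == "young", ]
  expect_equal(cyto_y$median_t_half, 30)  # single fit: median = value
  expect_equal(cyto_y$mean_t_half, 30)
  # invariant to protein ordering
  s2 <- summarize_half_lives(fits[sample(nrow(fits)), ], ann)
  expect_equal(s2$median_t_half, s$median_t_half)
  # empty stratum flagged with n = 0
  s3 <- summarize_half_lives(fits, annotate_compartments(c("A", "B", "C"),
                                                         character(0)))
  expect_equal(s3$n_proteins[s3$stratum == "mito"], c(0, 0))
  expect_true(all(is.na(s3$median_t_half[s3$stratum == "mito"])))
})

make_cmp <- function(ids, q, hl_b_over_a) {
  data.frame(protein_id = ids, p_value = q, q_value = q,
             half_life_a = 20, half_life_b = 20 * hl_b_over_a)
}

test_that("change classification counts and Venn overlaps are set algebra", {
  m1 <- make_cmp(c("A", "B", "C", "E"), c(0.01, 0.01, 0.01, 0.5),
                 c(2, 2, 2, 1))
  m2 <- make_cmp(c("A", "B", "C", "D", "E"), c(0.5, 0.01, 0.01, 0.01, 0.2),
                 c(1, 2, 2, 2, 1))
  cls <- classify_changes(list(m1 = m1, m2 = m2), q_threshold = 0.05)
  expect_equal(cls$counts$longer, c(3, 3))
  expect_equal(cls$counts$shorter, c(0, 0))
  # longer sets {A,B,C} vs {B,C,D}; D not tested in m1 -> restricted to both
  expect_equal(unname(cls$venn$longer), c(1, 2, 0))
  expect_equal(cls$n_tested_both, 4)
  # counts partition the tested set
  expect_equal(cls$counts$longer + cls$counts$shorter + cls$counts$unchanged,
               cls$counts$tested)
  # all insignificant -> all unchanged
  cls0 <- classify_changes(list(m1 = make_cmp("A", 0.9, 2),
                                m2 = make_cmp("A", 0.8, 2)))
  expect_equal(cls0$counts$longer, c(0, 0))
  expect_equal(cls0$counts$unchanged, c(1, 1))
})

test_that("abundance-turnover regression reports r-squared and degeneracy", {
  x <- c(0.1, 0.4, -0.2, 0.3)
  cc <- suppressWarnings(correlate_changes(x, 2 * x + 1))
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$slope, 2)
  expect_equal(cc$intercept, 1)
  expect_error(correlate_changes(c(1, 2), c(1, 2)), "insufficient pairs")
  expect_error(correlate_changes(rep(1, 5), rnorm(5)), "degenerate predictor")
})

test_that("independent remodeling axes give near-zero r-squared", {
  set.seed(31)
  r2 <- replicate(50, correlate_changes(rnorm(200, 0, 0.3),
                                        rnorm(200, 0, 0.3))$r_squared)
  expect_gte(mean(r2 < 0.05), 0.9)
})

test_that("Fisher enrichment matches the hypergeometric tail", {
  # table: 3 in-set hits, 7 in-set non-hits, 10 out-set hits, 80 out-set
  # non-hits -> universe 100, set 10, hits 13, overlap 3
  p <- fisher_greater_p(3, 7, 10, 80)
  expect_equal(p, hyper_tail_oracle(3, K = 10, n = 13, N = 100),
               tolerance = 1e-12)
})

test_that("gene-set enrichment applies the <4-hit rule and the ratio", {
  universe <- sprintf("G%03d", 1:100)
  sets <- list(big = universe[1:20],    # 10 hits
               small = universe[81:90], # 0 hits
               tiny = universe[c(1:3, 95)])  # 3 hits -> excluded
  hits <- universe[1:13]
  res <- enrich_gene_sets(hits, universe, sets)
  expect_equal(res$set_name, "big")
  expect_equal(res$overlap_ratio, 13 / 20)  # hits 1:13 all in big? no: 1:20
  expect_error(enrich_gene_sets(c("zzz"), universe, sets), "subset")
  expect_error(enrich_gene_sets(hits, character(0), sets), "non-empty")

  # hit_set = universe: every ratio is full coverage and p = 1
  res_all <- enrich_gene_sets(universe, universe, sets["big"])
  expect_equal(res_all$overlap_ratio, 1)
  expect_equal(res_all$fisher_p, 1)
})

test_that("the pipeline runs end to end, writes a manifest, and is seeded", {
  cfg <- default_pipeline_config(seed = 5, n_proteins = 40)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res1 <- suppressWarnings(run_pipeline(cfg, out_dir = out1))
  res2 <- suppressWarnings(run_pipeline(cfg, out_dir = out2))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$seed, 5)
  for (f in manifest$files) expect_true(file.exists(file.path(out1, f)))
  expect_true(file.exists(file.path(out1, "run_log.txt")))
  # determinism: identical seeds give identical result tables
  expect_equal(res1$half_life_summary, res2$half_life_summary)
  expect_identical(readLines(file.path(out1, "fits_EDL.tsv")),
                   readLines(file.path(out2, "fits_EDL.tsv")))
  # counts partition the tested sets
  cc <- res1$classification$counts
  expect_equal(cc$longer + cc$shorter + cc$unchanged, cc$tested)
})
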