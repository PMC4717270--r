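#' Default end-to-end pipeline configuration
#'
#' A two-muscle simulated study mirroring a diet-switch labeling design:
#' shared protein catalogue across muscles, longer-lived mitochondrial
#' proteins in the fast-twitch-like muscle, an aged-group mitochondrial
#' abundance increase concentrated there, and a majority-longer-lived aged
#' shift in the slow-twitch-like muscle.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param n_proteins proteins in the shared catalogue.
#' @param q_threshold,max_half_life_days,fdr_method analysis settings.
#' @param noise_cv,missing_rate simulator noise settings.
#' @param gmt optional path to a GMT file for gene-set enrichment of the
#'   abundance hits.
#' @return configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, n_proteins = 150L,
                                    q_threshold = 0.05,
                                    max_half_life_days = 365,
                                    fdr_method = "BH",
                                    noise_cv = 0.15, missing_rate = 0.05,
                                    gmt = NULL) {
  list(
    seed = as.integer(seed),
    n_proteins = as.integer(n_proteins),
    q_threshold = q_threshold,
    max_half_life_days = max_half_life_days,
    fdr_method = fdr_method,
    noise_cv = noise_cv,
    missing_rate = missing_rate,
    gmt = gmt,
    muscles = list(
      EDL = list(
        half_life_law = list(
          mito = list(dist = "lognormal", meanlog = log(25), sdlog = 0.35),
          cyto = list(dist = "lognormal", meanlog = log(20), sdlog = 0.45),
          other = list(dist = "lognormal", meanlog = log(22), sdlog = 0.45)),
        da_fraction = 0.6, da_log2fc = 0.5, da_compartment = "mito",
        hl_change = list(n_longer = round(0.27 * n_proteins),
                         n_shorter = round(0.17 * n_proteins),
                         longer_mult = 1.4, shorter_mult = 0.7)),
      SOL = list(
        half_life_law = list(
          mito = list(dist = "lognormal", meanlog = log(22), sdlog = 0.35),
          cyto = list(dist = "lognormal", meanlog = log(16), sdlog = 0.45),
          other = list(dist = "lognormal", meanlog = log(18), sdlog = 0.45)),
        da_fraction = 0.15, da_log2fc = 0.4, da_compartment = "mito",
        hl_change = list(n_longer = round(0.27 * n_proteins),
                         n_shorter = round(0.04 * n_proteins),
                         longer_mult = 1.4, shorter_mult = 0.7))
    )
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full turnover-and-abundance pipeline on a simulated study
#'
#' Executes simulate, deconvolve, kinetics, ANCOVA comparison, differential
#' abundance, and reporting for every muscle in the configuration, then the
#' cross-muscle summaries (half-life table, change classification with Venn
#' overlaps, abundance-turnover correlation, optional gene-set enrichment).
#' All result tables are written as TSV under `out_dir` together with a
#' machine-readable `manifest.json` (seed, package version, file list) and a
#' plain-text run log. Identical seeds give identical outputs.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with every intermediate and summary object plus
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = file.path(tempdir(), "turnover_run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste("turnoverMS pipeline, package version",
                       as.character(utils::packageVersion("turnoverMS"))),
                 paste("seed:", config$seed))
  muscles <- names(config$muscles)
  results <- list()
  files <- character(0)
  per_muscle_seed <- function(i, k) config$seed + 101L * i + k

  for (i in seq_along(muscles)) {
    m <- muscles[i]
    mc <- config$muscles[[m]]
    gt <- .stage(paste0("simulate:", m), simulate_ground_truth(
      n_proteins = config$n_proteins,
      half_life_law = mc$half_life_law %||%
        list(dist = "lognormal", meanlog = log(22), sdlog = 1.3),
      da_fraction = mc$da_fraction %||% 0,
      da_log2fc = mc$da_log2fc %||% 0,
      da_compartment = mc$da_compartment,
      hl_change = mc$hl_change %||% list(n_longer = 0L, n_shorter = 0L),
      protein_ids = sprintf("P%04d", seq_len(config$n_proteins)),
      seed = per_muscle_seed(i, 1L)))
    pep <- generate_peptides(gt, seed = per_muscle_seed(i, 2L))
    design <- study_design(muscle = m, noise_cv = config$noise_cv,
                           missing_rate = config$missing_rate,
                           seed = per_muscle_seed(i, 3L))
    env <- simulate_timecourse(gt, pep, design)
    ab <- simulate_abundances(gt, pep, design)
    files <- c(files, write_dataset(
      stats::setNames(list(env, ab, gt),
                      paste0(c("envelopes_", "abundances_", "ground_truth_"), m)),
      out_dir))

    fn <- .stage(paste0("deconvolve:", m), deconvolve_table(env))
    fits <- .stage(paste0("fit:", m), fit_turnover_all(fn))
    filt <- filter_fits(fits, config$max_half_life_days)
    kept_ids <- unique(filt$kept$protein_id)
    comps <- .stage(paste0("compare:", m), compare_all_proteins(
      fn[fn$protein_id %in% kept_ids, , drop = FALSE],
      group_a = design$groups[1], group_b = design$aged_group,
      q_method = config$fdr_method, q_threshold = config$q_threshold))
    abres <- .stage(paste0("abundance:", m), abundance_all(
      ab, group_a = design$groups[1], group_b = design$aged_group,
      q_method = config$fdr_method))
    annotation <- gt[, c("protein_id", "compartment")]
    aucfrac <- .stage(paste0("auc_fraction:", m),
                      mito_auc_fraction(ab, annotation,
                                        group_a = design$groups[1],
                                        group_b = design$aged_group))
    summary_m <- summarize_half_lives(filt$kept, annotation)
    summary_m$muscle <- m

    files <- c(files,
      write_tsv_table(fn, file.path(out_dir, paste0("fraction_new_", m, ".tsv"))),
      write_tsv_table(fits, file.path(out_dir, paste0("fits_", m, ".tsv"))),
      write_tsv_table(comps, file.path(out_dir, paste0("comparisons_", m, ".tsv"))),
      write_tsv_table(abres, file.path(out_dir, paste0("abundance_results_", m, ".tsv"))),
      write_tsv_table(aucfrac$fractions, file.path(out_dir, paste0("auc_fraction_", m, ".tsv"))))

    results[[m]] <- list(ground_truth = gt, peptides = pep, design = design,
                         fraction_new = fn, fits = fits, filtered = filt,
                         comparisons = comps, abundance = abres,
                         auc_fraction = aucfrac, half_life_summary = summary_m)
    log_lines <- c(log_lines, sprintf(
      "%s: %d proteins kept / %d excluded (> %g d); %d tested by ANCOVA",
      m, length(kept_ids), length(unique(filt$excluded$protein_id)),
      config$max_half_life_days, sum(!is.na(comps$p_value))))
  }

  half_life_summary <- do.call(rbind, lapply(results, `[[`, "half_life_summary"))
  rownames(half_life_summary) <- NULL
  files <- c(files, write_tsv_table(
    half_life_summary, file.path(out_dir, "half_life_summary.tsv")))

  classification <- classify_changes(
    lapply(results, `[[`, "comparisons"), q_threshold = config$q_threshold)
  files <- c(files, write_tsv_table(
    classification$counts, file.path(out_dir, "change_counts.tsv")))

  # Abundance vs turnover remodeling, per muscle, on shared kept proteins.
  correlations <- lapply(muscles, function(m) {
    r <- results[[m]]
    hl <- r$filtered$kept
    young <- hl[hl$group == r$design$groups[1],
                c("protein_id", "half_life_days")]
    old <- hl[hl$group == r$design$aged_group,
              c("protein_id", "half_life_days")]
    mm <- merge(young, old, by = "protein_id", suffixes = c("_y", "_o"))
    dhl <- log2(mm$half_life_days_o / mm$half_life_days_y)
    dab <- r$abundance$log2_fc_old_over_young[match(mm$protein_id,
                                                    r$abundance$protein_id)]
    cc <- tryCatch(correlate_changes(dab, dhl), error = function(e) NULL)
    if (is.null(cc)) NULL else
      data.frame(muscle = m, slope = cc$slope, intercept = cc$intercept,
                 r_squared = cc$r_squared, p_value = cc$p_value, n = cc$n,
                 stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, correlations)
  if (!is.null(correlations)) {
    files <- c(files, write_tsv_table(
      correlations, file.path(out_dir, "abundance_turnover_correlation.tsv")))
  }

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    enrichment <- do.call(rbind, lapply(muscles, function(m) {
      abres <- results[[m]]$abundance
      ok <- !is.na(abres$q_value)
      hits <- abres$protein_id[ok & abres$q_value < config$q_threshold]
      if (!length(hits)) return(NULL)
      e <- enrich_gene_sets(hits, abres$protein_id[ok], sets,
                            q_method = config$fdr_method)
      if (nrow(e)) cbind(muscle = m, e) else NULL
    }))
    if (!is.null(enrichment)) {
      files <- c(files, write_tsv_table(
        enrichment, file.path(out_dir, "gene_set_enrichment.tsv")))
    }
  }

  manifest <- list(
    package = "turnoverMS",
    version = as.character(utils::packageVersion("turnoverMS")),
    seed = config$seed,
    q_threshold = config$q_threshold,
    max_half_life_days = config$max_half_life_days,
    fdr_method = config$fdr_method,
    muscles = muscles,
    venn = classification$venn,
    n_tested_both = classification$n_tested_both,
    files = basename(unname(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(out_dir = out_dir, results = results,
                 half_life_summary = half_life_summary,
                 classification = classification,
                 correlations = correlations,
                 enrichment = enrichment,
                 manifest = manifest))
}
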