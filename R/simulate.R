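#' Simulate ground-truth proteins for an in-silico labeling study
#'
#' Draws a protein catalogue with known half-lives, subcellular compartments,
#' base abundances, and age effects on both abundance and turnover. This is
#' the ground truth against which every downstream estimate can be checked.
#'
#' Half-lives default to a log-normal law with median 22 days and a heavy
#' right tail (a small percentage beyond one year), emulating the range seen
#' in slow- and fast-twitch muscle mitochondrial fractions. `half_life_law`
#' may also be a named list of laws, one per compartment, to build studies
#' where e.g. mitochondrial proteins are longer lived by construction.
#'
#' Age effects: `da_fraction` of proteins (optionally restricted to
#' `da_compartment`) receive an abundance log2 fold change of `da_log2fc` in
#' the aged group; `hl_change` assigns `n_longer` proteins a half-life
#' multiplied by `longer_mult` (> 1, slower turnover) and `n_shorter` by
#' `shorter_mult` (< 1) in the aged group.
#'
#' @param n_proteins number of proteins, >= 1.
#' @param half_life_law distribution law (see [draw_law()]) or named list of
#'   laws keyed by compartment.
#' @param compartment_props named proportions over
#'   `c("mito", "cyto", "other")`; must sum to 1.
#' @param abundance_law law for base peptide areas.
#' @param da_fraction fraction of proteins with an abundance age effect.
#' @param da_log2fc log2 fold change (aged / young) for affected proteins.
#' @param da_compartment restrict abundance effects to one compartment,
#'   or `NULL` for all.
#' @param hl_change list with `n_longer`, `n_shorter`, `longer_mult`,
#'   `shorter_mult` describing age effects on half-life.
#' @param protein_ids optional identifiers to reuse (e.g. to share a
#'   catalogue between muscles); length must equal `n_proteins`.
#' @param seed integer seed; identical seeds give identical catalogues.
#' @return data frame with columns `protein_id`, `compartment`,
#'   `true_half_life`, `old_hl_multiplier`, `base_abundance`,
#'   `group_log2_effect`.
#' @export
simulate_ground_truth <- function(n_proteins,
                                  half_life_law = list(dist = "lognormal",
                                                       meanlog = log(22),
                                                       sdlog = 1.3),
                                  compartment_props = c(mito = 0.35,
                                                        cyto = 0.21,
                                                        other = 0.44),
                                  abundance_law = list(dist = "lognormal",
                                                       meanlog = log(1e6),
                                                       sdlog = 1),
                                  da_fraction = 0,
                                  da_log2fc = 0,
                                  da_compartment = NULL,
                                  hl_change = list(n_longer = 0L,
                                                   n_shorter = 0L,
                                                   longer_mult = 1.5,
                                                   shorter_mult = 2 / 3),
                                  protein_ids = NULL,
                                  seed = NULL) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (abs(sum(compartment_props) - 1) > 1e-8 || any(compartment_props < 0)) {
    stop("compartment_props must be nonnegative and sum to 1")
  }
  if (is.null(names(compartment_props))) {
    stop("compartment_props must be named")
  }
  if (!is.null(seed)) set.seed(seed)
  protein_ids <- protein_ids %||% sprintf("P%04d", seq_len(n_proteins))
  if (length(protein_ids) != n_proteins) {
    stop("protein_ids must have length n_proteins")
  }
  compartment <- sample(names(compartment_props), n_proteins,
                        replace = TRUE, prob = compartment_props)
  per_comp <- is.null(half_life_law$dist) &&
    all(vapply(half_life_law, is.list, TRUE))
  hl <- if (per_comp) {
    out <- numeric(n_proteins)
    for (cmp in unique(compartment)) {
      law <- half_life_law[[cmp]]
      if (is.null(law)) stop("no half_life_law for compartment '", cmp, "'")
      idx <- compartment == cmp
      out[idx] <- draw_law(sum(idx), law)
    }
    out
  } else {
    draw_law(n_proteins, half_life_law)
  }
  if (any(hl <= 0)) stop("half_life_law produced nonpositive half-lives")
  base_abundance <- draw_law(n_proteins, abundance_law)

  group_log2_effect <- rep(0, n_proteins)
  if (da_fraction > 0) {
    pool <- if (is.null(da_compartment)) seq_len(n_proteins) else
      which(compartment == da_compartment)
    n_da <- round(da_fraction * length(pool))
    if (n_da > 0) {
      hit <- sample(pool, n_da)
      group_log2_effect[hit] <- da_log2fc
    }
  }

  old_hl_multiplier <- rep(1, n_proteins)
  n_longer <- as.integer(hl_change$n_longer %||% 0L)
  n_shorter <- as.integer(hl_change$n_shorter %||% 0L)
  if (n_longer + n_shorter > n_proteins) {
    stop("hl_change assigns more proteins than exist")
  }
  if (n_longer + n_shorter > 0) {
    chosen <- sample(n_proteins, n_longer + n_shorter)
    if (n_longer > 0) {
      old_hl_multiplier[chosen[seq_len(n_longer)]] <-
        hl_change$longer_mult %||% 1.5
    }
    if (n_shorter > 0) {
      old_hl_multiplier[chosen[n_longer + seq_len(n_shorter)]] <-
        hl_change$shorter_mult %||% (2 / 3)
    }
  }

  data.frame(protein_id = protein_ids,
             compartment = compartment,
             true_half_life = hl,
             old_hl_multiplier = old_hl_multiplier,
             base_abundance = base_abundance,
             group_log2_effect = group_log2_effect,
             stringsAsFactors = FALSE)
}

#' Generate peptides for a protein catalogue
#'
#' Every peptide maps to exactly one protein (only uniquely mapping peptides
#' are usable downstream). The leucine count per peptide defaults to a
#' Poisson law: tryptic peptides carry few leucines, and peptides with zero
#' leucines are deliberately possible since downstream analysis must exclude
#' them as uninformative.
#'
#' @param proteins ground-truth protein table from [simulate_ground_truth()].
#' @param peptides_per_protein_law count law (see [draw_count_law()]);
#'   default truncated Poisson with mean 4, minimum 1.
#' @param leu_count_law count law for leucines per peptide; default
#'   Poisson(1.5), minimum 0.
#' @param rt_range retention-time range (minutes) peptides are spread over.
#' @param ionization_sdlog log-scale SD of the per-peptide ionization factor.
#' @param seed integer seed.
#' @return data frame with columns `peptide_id`, `protein_id`, `n_leu`,
#'   `rt_true`, `ionization_factor`.
#' @export
generate_peptides <- function(proteins,
                              peptides_per_protein_law = list(dist = "poisson",
                                                              lambda = 4,
                                                              min = 1),
                              leu_count_law = list(dist = "poisson",
                                                   lambda = 1.5),
                              rt_range = c(10, 110),
                              ionization_sdlog = 0.5,
                              seed = NULL) {
  .check_cols(proteins, "protein_id", "proteins")
  if (nrow(proteins) < 1) stop("proteins must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  n_pep <- draw_count_law(nrow(proteins), peptides_per_protein_law)
  protein_id <- rep(proteins$protein_id, times = n_pep)
  n <- length(protein_id)
  data.frame(
    peptide_id = sprintf("%s_pep%02d", protein_id,
                         unlist(lapply(n_pep, seq_len), use.names = FALSE)),
    protein_id = protein_id,
    n_leu = draw_count_law(n, leu_count_law),
    rt_true = stats::runif(n, rt_range[1], rt_range[2]),
    ionization_factor = stats::rlnorm(n, -ionization_sdlog^2 / 2,
                                      ionization_sdlog),
    stringsAsFactors = FALSE
  )
}

# Sample sheet for a cross-sectional design: each animal is sacrificed at one
# time point, so samples are group x time x animal.
.design_samples <- function(design) {
  s <- expand.grid(animal = seq_len(design$n_animals),
                   time_days = design$time_points,
                   group = design$groups,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  s$sample_id <- sprintf("%s_%s_d%02d_a%d", design$muscle, s$group,
                         as.integer(round(s$time_days)), s$animal)
  s
}

#' Simulate peptide isotopologue envelopes over the labeling time course
#'
#' Forward model. A protein with half-life \eqn{t_{1/2}} turns over with rate
#' \eqn{k = \ln 2 / t_{1/2}}; the true fraction of its molecules synthesized
#' since the diet switch at time \eqn{t} is \eqn{f(t) = 1 - e^{-kt}}.
#' Pre-existing molecules carry no label (all intensity in channel 0); newly
#' synthesized molecules draw each of their `n_leu` leucines heavy with
#' probability equal to the precursor-pool enrichment, giving a binomial
#' channel distribution. The observed envelope is the mixture, scaled by the
#' peptide's total signal, with multiplicative log-normal channel noise and
#' whole-envelope missingness completely at random.
#'
#' @param proteins,peptides ground-truth tables.
#' @param design a [study_design()]; its `seed` fixes the dataset.
#' @return long-format data frame, one row per channel, with columns
#'   `peptide_id`, `protein_id`, `sample_id`, `group`, `time_days`,
#'   `rt_minutes`, `n_leu`, `channel`, `intensity`.
#' @export
simulate_timecourse <- function(proteins, peptides, design) {
  stopifnot(inherits(design, "study_design"))
  .check_cols(proteins, c("protein_id", "true_half_life", "old_hl_multiplier",
                          "base_abundance"), "proteins")
  .check_cols(peptides, c("peptide_id", "protein_id", "n_leu", "rt_true",
                          "ionization_factor"), "peptides")
  if (!is.null(design$seed)) set.seed(design$seed)
  samples <- .design_samples(design)
  pep <- merge(peptides, proteins, by = "protein_id", sort = FALSE)

  np <- nrow(pep); ns <- nrow(samples)
  pi_ <- rep(seq_len(np), times = ns)
  si <- rep(seq_len(ns), each = np)
  hl <- pep$true_half_life[pi_] *
    ifelse(samples$group[si] == design$aged_group,
           pep$old_hl_multiplier[pi_], 1)
  t_d <- samples$time_days[si]
  f <- 1 - exp(-log(2) / hl * t_d)
  p <- precursor_enrichment(design, t_d, samples$group[si])
  total <- pep$base_abundance[pi_] * pep$ionization_factor[pi_]

  keep <- stats::runif(length(pi_)) >= design$missing_rate
  pi_ <- pi_[keep]; si <- si[keep]; f <- f[keep]; p <- p[keep]
  total <- total[keep]
  n_leu <- pep$n_leu[pi_]

  j <- rep(seq_along(pi_), times = n_leu + 1L)
  channel <- sequence(n_leu + 1L) - 1L
  prob <- f[j] * stats::dbinom(channel, n_leu[j], p[j]) +
    (1 - f[j]) * (channel == 0L)
  intensity <- total[j] * prob * mult_noise(length(j), design$noise_cv)

  data.frame(
    peptide_id = pep$peptide_id[pi_][j],
    protein_id = pep$protein_id[pi_][j],
    sample_id = samples$sample_id[si][j],
    group = samples$group[si][j],
    time_days = samples$time_days[si][j],
    rt_minutes = pep$rt_true[pi_][j],
    n_leu = n_leu[j],
    channel = channel,
    intensity = intensity,
    stringsAsFactors = FALSE
  )
}

#' Simulate peptide chromatographic areas (AUC) for abundance analysis
#'
#' Each peptide's area is its protein's base abundance times the peptide
#' ionization factor, times `2^group_log2_effect` in the aged group, under
#' multiplicative log-normal noise with the design's CV, with observations
#' missing completely at random. Uses a seed offset from the design seed so
#' area noise is independent of envelope noise.
#'
#' @inheritParams simulate_timecourse
#' @return data frame with columns `peptide_id`, `protein_id`, `sample_id`,
#'   `group`, `auc`.
#' @export
simulate_abundances <- function(proteins, peptides, design) {
  stopifnot(inherits(design, "study_design"))
  .check_cols(proteins, c("protein_id", "base_abundance", "group_log2_effect"),
              "proteins")
  .check_cols(peptides, c("peptide_id", "protein_id", "ionization_factor"),
              "peptides")
  if (!is.null(design$seed)) set.seed(design$seed + 1009L)
  samples <- .design_samples(design)
  pep <- merge(peptides, proteins, by = "protein_id", sort = FALSE)

  np <- nrow(pep); ns <- nrow(samples)
  pi_ <- rep(seq_len(np), times = ns)
  si <- rep(seq_len(ns), each = np)
  eff <- ifelse(samples$group[si] == design$aged_group,
                pep$group_log2_effect[pi_], 0)
  auc <- pep$base_abundance[pi_] * pep$ionization_factor[pi_] *
    2^eff * mult_noise(length(pi_), design$noise_cv)
  keep <- stats::runif(length(pi_)) >= design$missing_rate
  data.frame(
    peptide_id = pep$peptide_id[pi_],
    protein_id = pep$protein_id[pi_],
    sample_id = samples$sample_id[si],
    group = samples$group[si],
    auc = auc,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

#' Write a simulated dataset to disk
#'
#' Writes each table in `tables` as `<name>.tsv` under `out_dir`. The
#' conventional members are `envelopes`, `abundances` and `ground_truth`
#' (the ground-truth table is re-shaped to the exchange columns
#' `protein_id`, `compartment`, `true_half_life_days`, `old_hl_multiplier`,
#' `group_log2_effect`).
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if needed.
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  for (nm in grep("^ground_truth", names(tables), value = TRUE)) {
    gt <- tables[[nm]]
    if ("true_half_life" %in% names(gt)) {
      names(gt)[names(gt) == "true_half_life"] <- "true_half_life_days"
      gt$base_abundance <- NULL
      tables[[nm]] <- gt
    }
  }
  paths <- vapply(names(tables), function(nm) {
    write_tsv_table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }, character(1))
  invisible(paths)
}
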