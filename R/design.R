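#' Define a labeling study design
#'
#' Describes one muscle's diet-switch labeling experiment: which days animals
#' are sacrificed, how many animals per age group, and the precursor-pool
#' enrichment and noise model used by the simulator. The defaults mirror a
#' cross-sectional 2H3-leucine diet-switch study: sacrifice at days 3, 7, 12
#' and 17, four animals per age group, two age groups.
#'
#' Precursor enrichment is the fraction of free leucine available for protein
#' synthesis that is heavy-labeled. By default it is constant at
#' `enrichment_max` from the diet switch onward; supplying `enrichment_rate`
#' (per day) makes it rise as
#' `p(t) = enrichment_max * (1 - exp(-enrichment_rate * t))`.
#' `enrichment_max_by_group` (a named vector) lets groups differ in their
#' achieved pool enrichment, which downstream estimation must absorb.
#'
#' @param time_points labeling durations in days, strictly increasing, > 0.
#' @param n_animals animals sacrificed per group at each time point.
#' @param groups group labels; the last element is taken as the aged group
#'   unless `aged_group` says otherwise.
#' @param muscle muscle label attached to every sample identifier.
#' @param enrichment_max plateau precursor-pool enrichment, in (0, 1].
#' @param enrichment_rate per-day rise constant for the enrichment time
#'   course, or `NULL` for constant enrichment.
#' @param enrichment_max_by_group optional named vector of per-group plateau
#'   enrichments overriding `enrichment_max`.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   noise applied to channel intensities and peptide areas.
#' @param missing_rate probability, in [0, 1), that a peptide-by-sample
#'   observation is missing completely at random.
#' @param aged_group which group carries the age effects encoded in the
#'   ground truth.
#' @param seed integer seed making the simulated dataset reproducible.
#' @return an object of class `study_design`.
#' @export
study_design <- function(time_points = c(3, 7, 12, 17),
                         n_animals = 4L,
                         groups = c("young", "old"),
                         muscle = "EDL",
                         enrichment_max = 0.5,
                         enrichment_rate = NULL,
                         enrichment_max_by_group = NULL,
                         noise_cv = 0.15,
                         missing_rate = 0.05,
                         aged_group = NULL,
                         seed = 1L) {
  if (length(time_points) < 1 || any(time_points <= 0) ||
      is.unsorted(time_points, strictly = TRUE)) {
    stop("time_points must be strictly increasing and positive")
  }
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (length(groups) < 1 || anyDuplicated(groups)) {
    stop("groups must be distinct labels")
  }
  if (!(enrichment_max > 0 && enrichment_max <= 1)) {
    stop("enrichment_max must lie in (0, 1]")
  }
  if (!is.null(enrichment_rate) && enrichment_rate < 0) {
    stop("enrichment_rate must be >= 0")
  }
  if (!is.null(enrichment_max_by_group)) {
    if (!all(groups %in% names(enrichment_max_by_group))) {
      stop("enrichment_max_by_group must name every group")
    }
    if (any(enrichment_max_by_group <= 0 | enrichment_max_by_group > 1)) {
      stop("per-group enrichment_max must lie in (0, 1]")
    }
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  aged_group <- aged_group %||% groups[length(groups)]
  if (!aged_group %in% groups) stop("aged_group must be one of groups")
  structure(list(
    time_points = as.numeric(time_points),
    n_animals = as.integer(n_animals),
    groups = groups,
    muscle = muscle,
    enrichment_max = enrichment_max,
    enrichment_rate = enrichment_rate,
    enrichment_max_by_group = enrichment_max_by_group,
    noise_cv = noise_cv,
    missing_rate = missing_rate,
    aged_group = aged_group,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "study_design")
}

#' Precursor-pool enrichment at given times for given groups
#'
#' @param design a [study_design()].
#' @param time_days numeric vector of labeling times (days).
#' @param group character vector of group labels, recycled against
#'   `time_days`.
#' @return numeric vector of enrichments in (0, 1].
#' @export
precursor_enrichment <- function(design, time_days, group) {
  n <- max(length(time_days), length(group))
  time_days <- rep_len(time_days, n)
  group <- rep_len(group, n)
  pmax_g <- if (is.null(design$enrichment_max_by_group)) {
    rep(design$enrichment_max, n)
  } else {
    unname(design$enrichment_max_by_group[group])
  }
  if (is.null(design$enrichment_rate)) {
    pmax_g
  } else {
    pmax_g * (1 - exp(-design$enrichment_rate * time_days))
  }
}

#' @export
print.study_design <- function(x, ...) {
  cat("Labeling study design (", x$muscle, ")\n", sep = "")
  cat("  time points (d): ", paste(x$time_points, collapse = ", "), "\n", sep = "")
  cat("  groups: ", paste(x$groups, collapse = ", "),
      " (aged: ", x$aged_group, "); ", x$n_animals,
      " animals/group/time\n", sep = "")
  cat("  enrichment max: ",
      if (is.null(x$enrichment_max_by_group)) x$enrichment_max
      else paste(names(x$enrichment_max_by_group), x$enrichment_max_by_group,
                 sep = "=", collapse = ", "),
      if (is.null(x$enrichment_rate)) " (constant)"
      else paste0(" (rate ", x$enrichment_rate, "/d)"), "\n", sep = "")
  cat("  noise CV: ", x$noise_cv, "; missing rate: ", x$missing_rate,
      "; seed: ", x$seed %||% "none", "\n", sep = "")
  invisible(x)
}
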