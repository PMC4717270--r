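#' Half-life from a first-order turnover rate
#'
#' Under first-order kinetics the half-life is `ln(2) / |alpha|`, where
#' `alpha` is the slope of `ln(100 - percent_new)` against labeling time
#' (negative by construction). A zero rate gives an infinite half-life,
#' returned as `Inf` rather than thrown.
#'
#' @param alpha per-day rate(s).
#' @return half-life in days.
#' @export
half_life_from_slope <- function(alpha) {
  ifelse(alpha == 0, Inf, log(2) / abs(alpha))
}

# Clip percent-new upward of the transform's domain: ln(100 - y) requires
# y < 100, and a fully exchanged (or noise-saturated) peptide reports 100.
.log_remaining <- function(percent_new, clip_eps = 0.01) {
  if (any(percent_new < 0 | percent_new > 100 + 1e-9)) {
    stop("percent_new must lie in [0, 100]")
  }
  log(100 - pmin(percent_new, 100 - clip_eps))
}

#' Fit first-order turnover kinetics for one protein in one group
#'
#' Fits the exponential appearance model `y = 100 + beta1 * exp(alpha * t)`
#' (`y` = percent newly synthesized) through its log-linear transform:
#' `ln(100 - y) = b + alpha * t`, by ordinary least squares. When a protein
#' is represented by several peptides, each peptide receives its own
#' intercept (a fixed-effect blocking factor absorbing systematic
#' between-peptide offsets) while the slope `alpha` is common — the
#' peptide-blocked ANCOVA reading of the model. `beta1` is reported as
#' `-exp(mean(b))` over peptide blocks, and the half-life as
#' `ln(2) / |alpha|`.
#'
#' @param measurements data frame with columns `peptide_id`, `time_days`,
#'   `percent_new` for one protein in one group; needs >= 2 distinct time
#'   points.
#' @param clip_eps observations at `percent_new = 100` are clipped to
#'   `100 - clip_eps` before the log transform.
#' @return one-row data frame with `alpha`, `beta1`, `half_life_days`,
#'   `se_alpha`, `n_peptides`, `n_observations`, `r_squared`,
#'   `excluded_flag`, `exclusion_reason`.
#' @export
fit_turnover <- function(measurements, clip_eps = 0.01) {
  .check_cols(measurements, c("peptide_id", "time_days", "percent_new"),
              "measurements")
  if (length(unique(measurements$time_days)) < 2) {
    stop("rate not identifiable: need >= 2 distinct time points")
  }
  z <- .log_remaining(measurements$percent_new, clip_eps)
  t_d <- measurements$time_days
  pep <- factor(measurements$peptide_id)
  fit <- if (nlevels(pep) > 1) stats::lm(z ~ pep + t_d) else stats::lm(z ~ t_d)
  cf <- stats::coef(fit)
  smry <- summary(fit)
  alpha <- unname(cf["t_d"])
  if (abs(alpha) < 1e-12) alpha <- 0  # numerically flat time course
  se_alpha <- smry$coefficients["t_d", "Std. Error"]
  # Per-peptide intercepts under treatment contrasts: base + offsets.
  b <- unname(cf[1]) + c(0, unname(cf[grep("^pep", names(cf))]))
  hl <- half_life_from_slope(alpha)
  degenerate <- !is.finite(hl)
  data.frame(
    alpha = alpha,
    beta1 = -exp(mean(b)),
    half_life_days = hl,
    se_alpha = se_alpha,
    n_peptides = nlevels(pep),
    n_observations = nrow(measurements),
    r_squared = smry$r.squared,
    excluded_flag = degenerate,
    exclusion_reason = if (degenerate) "zero rate: infinite half-life"
                       else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Fit turnover kinetics for every protein-by-group combination
#'
#' @param fraction_new fraction-new table (see [deconvolve_table()]).
#' @param clip_eps passed to [fit_turnover()].
#' @return data frame with one row per protein x group; proteins whose fit
#'   fails its preconditions get `NA` estimates and the failure message as
#'   `exclusion_reason`.
#' @export
fit_turnover_all <- function(fraction_new, clip_eps = 0.01) {
  .check_cols(fraction_new, c("protein_id", "group", "peptide_id",
                              "time_days", "percent_new"), "fraction_new")
  key <- interaction(fraction_new$protein_id, fraction_new$group, drop = TRUE,
                     sep = "\r")
  parts <- split(fraction_new, key)
  rows <- lapply(parts, function(m) {
    res <- tryCatch(fit_turnover(m, clip_eps), error = function(e) {
      data.frame(alpha = NA_real_, beta1 = NA_real_,
                 half_life_days = NA_real_, se_alpha = NA_real_,
                 n_peptides = length(unique(m$peptide_id)),
                 n_observations = nrow(m), r_squared = NA_real_,
                 excluded_flag = TRUE, exclusion_reason = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    cbind(data.frame(protein_id = m$protein_id[1], group = m$group[1],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$protein_id, out$group), ]
}

#' Cross-check: direct nonlinear fit of the exponential appearance model
#'
#' Fits `y = 100 + beta1 * exp(alpha * t)` by nonlinear least squares on the
#' untransformed percent-new values (single curve, no peptide blocking),
#' started from the log-linear estimates. Offered as a cross-check on the
#' primary log-linear fit; agreement is exact on noiseless data.
#'
#' @inheritParams fit_turnover
#' @return list with `alpha`, `beta1`, `half_life_days`, `converged`.
#' @export
fit_turnover_nls <- function(measurements) {
  .check_cols(measurements, c("time_days", "percent_new"), "measurements")
  z <- .log_remaining(measurements$percent_new)
  start_fit <- stats::lm(z ~ measurements$time_days)
  start <- list(beta1 = -exp(unname(stats::coef(start_fit)[1])),
                alpha = unname(stats::coef(start_fit)[2]))
  fit <- try(stats::nls(percent_new ~ 100 + beta1 * exp(alpha * time_days),
                        data = measurements, start = start), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(alpha = start$alpha, beta1 = start$beta1,
                half_life_days = half_life_from_slope(start$alpha),
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(alpha = unname(cf["alpha"]), beta1 = unname(cf["beta1"]),
       half_life_days = half_life_from_slope(unname(cf["alpha"])),
       converged = TRUE)
}

#' Compare turnover rates between two groups by ANCOVA
#'
#' Fits the log-transformed turnover model to both groups jointly with one
#' intercept per peptide-within-group block, a common time slope, and a
#' group-by-time interaction. The interaction coefficient is the slope
#' difference `delta_alpha = alpha_b - alpha_a`; its t-test p-value tests
#' whether turnover rates differ between groups. In the degenerate noiseless
#' case with a zero residual the p-value is reported as 1 when the slopes
#' are identical and 0 otherwise.
#'
#' By default the t-test uses a heteroskedasticity-robust (HC3) covariance:
#' a roughly constant error in the fraction newly synthesized is amplified
#' by `1 / (1 - f)` under the log transform, so residual variance grows
#' with labeling time and the classical homoskedastic standard error
#' understates the slope-contrast uncertainty (an anti-conservative test).
#' The slope estimates themselves remain unweighted least squares;
#' `robust = FALSE` gives the classical ANCOVA covariance.
#'
#' @param measurements fraction-new rows for one protein covering both
#'   groups (columns `peptide_id`, `group`, `time_days`, `percent_new`).
#' @param group_a,group_b group labels; `delta_alpha` is B minus A.
#' @param clip_eps see [fit_turnover()].
#' @param robust use an HC3 covariance for the interaction t-test.
#' @return one-row data frame with `group_a`, `group_b`, `alpha_a`,
#'   `alpha_b`, `delta_alpha`, `half_life_a`, `half_life_b`, `p_value`.
#' @export
compare_groups_ancova <- function(measurements, group_a, group_b,
                                  clip_eps = 0.01, robust = TRUE) {
  .check_cols(measurements, c("peptide_id", "group", "time_days",
                              "percent_new"), "measurements")
  m <- measurements[measurements$group %in% c(group_a, group_b), , drop = FALSE]
  for (g in c(group_a, group_b)) {
    tg <- m$time_days[m$group == g]
    if (length(tg) == 0) stop("contrast not estimable: group '", g, "' absent")
    if (length(unique(tg)) < 2) {
      stop("not testable: no within-group time spread in '", g, "'")
    }
  }
  z <- .log_remaining(m$percent_new, clip_eps)
  t_d <- m$time_days
  grp <- factor(m$group, levels = c(group_a, group_b))
  block <- droplevels(interaction(m$peptide_id, m$group, sep = "\r"))
  fit <- if (nlevels(block) > 2) {
    stats::lm(z ~ block + t_d + t_d:grp)
  } else {
    stats::lm(z ~ grp + t_d + t_d:grp)
  }
  cf <- stats::coef(fit)
  iname <- intersect(c(paste0("t_d:grp", group_b),
                       paste0("grp", group_b, ":t_d")), names(cf))[1]
  delta <- unname(cf[iname])
  if (is.na(iname) || is.na(delta)) {
    stop("not testable: slope contrast is not estimable")
  }
  smry <- summary(fit)
  p_value <- if (robust) {
    se <- sqrt(diag(sandwich::vcovHC(fit, type = "HC3"))[iname])
    2 * stats::pt(-abs(delta / se), stats::df.residual(fit))
  } else {
    smry$coefficients[iname, "Pr(>|t|)"]
  }
  if (!is.finite(p_value) || smry$sigma < 1e-8) {  # zero-residual limit
    p_value <- if (abs(delta) < 1e-10) 1 else 0
  }
  alpha_a <- unname(cf["t_d"])
  alpha_b <- alpha_a + delta
  data.frame(group_a = group_a, group_b = group_b,
             alpha_a = alpha_a, alpha_b = alpha_b, delta_alpha = delta,
             half_life_a = half_life_from_slope(alpha_a),
             half_life_b = half_life_from_slope(alpha_b),
             p_value = p_value, stringsAsFactors = FALSE)
}

#' ANCOVA turnover comparison for every protein, with q-values
#'
#' Runs [compare_groups_ancova()] per protein, adjusts the p-value family
#' with [adjust_multiplicity()], and classifies each protein's direction of
#' half-life change: `longer_lived` / `shorter_lived` where
#' `q_value < q_threshold`, otherwise `unchanged`.
#'
#' @param fraction_new fraction-new table covering both groups.
#' @param group_a,group_b group labels (B vs A).
#' @param q_method `"BH"` or `"storey"`.
#' @param q_threshold significance threshold on the q-value.
#' @param robust passed to [compare_groups_ancova()].
#' @return data frame, one row per protein, with the comparison fields plus
#'   `q_value` and `direction`.
#' @export
compare_all_proteins <- function(fraction_new, group_a, group_b,
                                 q_method = "BH", q_threshold = 0.05,
                                 robust = TRUE) {
  .check_cols(fraction_new, c("protein_id", "peptide_id", "group",
                              "time_days", "percent_new"), "fraction_new")
  parts <- split(fraction_new, fraction_new$protein_id)
  rows <- lapply(parts, function(m) {
    res <- tryCatch(compare_groups_ancova(m, group_a, group_b,
                                          robust = robust),
                    error = function(e) {
      data.frame(group_a = group_a, group_b = group_b,
                 alpha_a = NA_real_, alpha_b = NA_real_,
                 delta_alpha = NA_real_, half_life_a = NA_real_,
                 half_life_b = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    })
    cbind(data.frame(protein_id = m$protein_id[1], stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- adjust_multiplicity(out$p_value[ok], method = q_method)
  out$direction <- "unchanged"
  sig <- ok & !is.na(out$q_value) & out$q_value < q_threshold
  out$direction[sig & out$half_life_b > out$half_life_a] <- "longer_lived"
  out$direction[sig & out$half_life_b < out$half_life_a] <- "shorter_lived"
  out
}

#' Exclude proteins with extreme half-lives
#'
#' A protein whose fitted half-life exceeds `max_half_life_days` in any group
#' (or is non-finite) is excluded from all summaries, with the reason
#' recorded. The rule is idempotent and does not depend on row order.
#'
#' @param fits output of [fit_turnover_all()].
#' @param max_half_life_days exclusion threshold; default one year.
#' @return list with `kept` and `excluded` data frames.
#' @export
filter_fits <- function(fits, max_half_life_days = 365) {
  .check_cols(fits, c("protein_id", "half_life_days"), "fits")
  over <- !is.finite(fits$half_life_days) |
    fits$half_life_days > max_half_life_days
  bad <- unique(fits$protein_id[over])
  excluded <- fits[fits$protein_id %in% bad, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$excluded_flag <- TRUE
    excluded$exclusion_reason <- sprintf(
      "half-life > %g d in at least one group", max_half_life_days)
  }
  kept <- fits[!fits$protein_id %in% bad, , drop = FALSE]
  list(kept = kept, excluded = excluded)
}
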