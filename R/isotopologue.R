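#' Channel distribution of a fully newly synthesized peptide
#'
#' A peptide with `n_leu` leucines synthesized from a precursor pool with
#' heavy-leucine enrichment `p` incorporates each leucine heavy independently,
#' so the number of heavy leucines (the label-count channel) is binomial:
#' channel `k` has probability `choose(n_leu, k) * p^k * (1-p)^(n_leu-k)`.
#'
#' @param n_leu number of leucines, >= 0.
#' @param p precursor-pool enrichment in [0, 1].
#' @return probability vector over channels `0..n_leu`; sums to 1.
#' @export
channel_distribution <- function(n_leu, p) {
  if (length(n_leu) != 1 || n_leu < 0 || n_leu != round(n_leu)) {
    stop("n_leu must be a single nonnegative integer")
  }
  .check_prob(p, "p")
  stats::dbinom(0:n_leu, n_leu, p)
}

#' Envelope of a partially turned-over peptide pool
#'
#' Pre-existing molecules (fraction `1 - f`) are unlabeled and sit entirely
#' in channel 0; newly synthesized molecules (fraction `f`) follow
#' [channel_distribution()]. The observable envelope is the mixture.
#'
#' @param f fraction newly synthesized, in [0, 1].
#' @inheritParams channel_distribution
#' @return probability vector over channels `0..n_leu`; sums to 1.
#' @export
mixture_envelope <- function(f, n_leu, p) {
  .check_prob(f, "f")
  e <- f * channel_distribution(n_leu, p)
  e[1] <- e[1] + (1 - f)
  e
}

# Deviation direction of the mixture from pure channel 0, for fixed (n_leu, p):
# mixture_envelope(f) = e0 + f * d with d = binom - e0. The least-squares f at
# fixed p is therefore a 1-D linear projection, clamped to [0, 1].
.mixture_direction <- function(n_leu, p) {
  d <- stats::dbinom(0:n_leu, n_leu, p)
  d[1] <- d[1] - 1
  d
}

#' Deconvolve the fraction newly synthesized from one envelope
#'
#' Inverts the mixture model by constrained least squares on the normalized
#' envelope: `f_hat` minimizes `||envelope/sum - mixture_envelope(f, n, p)||`
#' over `f` in [0, 1]. Because the mixture is linear in `f` the problem is
#' convex with a closed-form projection; envelopes lying exactly on the model
#' manifold are inverted with zero residual. The result is invariant to
#' scaling the intensities by any positive constant.
#'
#' @param intensities nonnegative intensity vector over channels
#'   `0..n_leu` (so `n_leu = length(intensities) - 1`).
#' @param p precursor-pool enrichment in (0, 1], typically from
#'   [estimate_enrichment()].
#' @return list with `f_hat` (in [0, 1]) and `residual_norm`.
#' @export
deconvolve_fraction_new <- function(intensities, p) {
  if (!(length(p) == 1 && p > 0 && p <= 1)) stop("p must lie in (0, 1]")
  n_leu <- length(intensities) - 1L
  if (n_leu < 1L) stop("uninformative peptide: no labeled channels (n_leu = 0)")
  tot <- sum(intensities)
  if (!is.finite(tot) || tot <= 0 || any(intensities < 0)) {
    stop("empty envelope: total intensity must be positive")
  }
  y <- intensities / tot
  d <- .mixture_direction(n_leu, p)
  y0 <- y
  y0[1] <- y0[1] - 1
  f <- sum(y0 * d) / sum(d * d)
  f <- min(max(f, 0), 1)
  r <- y0 - f * d
  list(f_hat = f, residual_norm = sqrt(sum(r * r)))
}

# Shared input normalization for enrichment estimation: a long envelope table
# for one sample, or a plain list of intensity vectors.
.envelope_list <- function(envelopes) {
  if (is.data.frame(envelopes)) {
    .check_cols(envelopes, c("peptide_id", "n_leu", "channel", "intensity"),
                "envelopes")
    if ("sample_id" %in% names(envelopes) &&
        length(unique(envelopes$sample_id)) > 1) {
      stop("estimate_enrichment expects envelopes from a single sample")
    }
    env <- envelopes[order(envelopes$peptide_id, envelopes$channel), ]
    split(env$intensity, factor(env$peptide_id, unique(env$peptide_id)))
  } else if (is.list(envelopes)) {
    envelopes
  } else {
    stop("envelopes must be a data frame or a list of intensity vectors")
  }
}

#' Estimate precursor-pool enrichment for one sample
#'
#' The enrichment `p` is shared by every peptide in a sample while each
#' peptide has its own fraction-new `f`, so `p` is estimated by profile least
#' squares: for a candidate `p`, each peptide's `f` is profiled out by the
#' closed-form projection of [deconvolve_fraction_new()], and `p_hat`
#' minimizes the summed squared residual over (0, 1]. Only peptides with at
#' least `min_leu` leucines contribute: with a single leucine the envelope
#' determines only the product `f * p`, so shape information beyond the
#' 0/full channels — present only for `n_leu >= 2` — is what identifies `p`.
#'
#' @param envelopes long envelope table for one sample (columns `peptide_id`,
#'   `n_leu`, `channel`, `intensity`) or a list of intensity vectors.
#' @param min_leu minimum leucine count for a peptide to inform `p`.
#' @return list with `p_hat`, `n_peptides_used`, `objective_value`.
#' @export
estimate_enrichment <- function(envelopes, min_leu = 2L) {
  ints <- .envelope_list(envelopes)
  n_leu <- lengths(ints) - 1L
  ok <- n_leu >= min_leu &
    vapply(ints, function(v) sum(v) > 0 && all(v >= 0), TRUE)
  if (!any(ok)) {
    stop("enrichment not identifiable: no peptides with n_leu >= ", min_leu)
  }
  ints <- ints[ok]
  n_leu <- n_leu[ok]

  # Normalized envelopes stacked per leucine count for vectorized profiling.
  groups <- lapply(split(seq_along(ints), n_leu), function(idx) {
    Y <- do.call(rbind, lapply(ints[idx], function(v) v / sum(v)))
    Y[, 1] <- Y[, 1] - 1  # store Y - e0 directly
    list(n = length(ints[[idx[1]]]) - 1L, Y0 = Y)
  })

  objective <- function(p) {
    tot <- 0
    for (g in groups) {
      d <- .mixture_direction(g$n, p)
      dd <- sum(d * d)
      f <- as.vector(g$Y0 %*% d) / dd
      f <- pmin(pmax(f, 0), 1)
      R <- g$Y0 - outer(f, d)
      tot <- tot + sum(R * R)
    }
    tot
  }

  # Coarse scan to bracket the global minimum, then golden-section refinement.
  grid <- seq(0.005, 1, length.out = 200)
  vals <- vapply(grid, objective, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(objective, c(lo, hi), tol = 1e-10)
  p_hat <- opt$minimum
  obj <- opt$objective
  # optimize() never lands exactly on the interval ends; check the boundary.
  if (objective(1) <= obj) {
    p_hat <- 1
    obj <- objective(1)
  }
  list(p_hat = p_hat, n_peptides_used = length(ints), objective_value = obj)
}

#' Deconvolve a long-format envelope table into fraction-new values
#'
#' Applies [deconvolve_fraction_new()] to every peptide-by-sample envelope in
#' a table in the simulator's long dialect. Peptides with `n_leu = 0` carry
#' no label information and are dropped. The enrichment used per sample is
#' taken from `p` (a single value or a named vector keyed by `sample_id`);
#' when `p` is `NULL` it is estimated per sample with [estimate_enrichment()].
#'
#' @param envelopes long envelope table (simulator dialect).
#' @param p enrichment: single number, named per-sample vector, or `NULL` to
#'   estimate.
#' @param min_leu passed to [estimate_enrichment()].
#' @return fraction-new table with columns `peptide_id`, `protein_id`,
#'   `sample_id`, `group`, `time_days`, `percent_new` (0-100),
#'   `residual_norm`, `p_hat_used`.
#' @export
deconvolve_table <- function(envelopes, p = NULL, min_leu = 2L) {
  .check_cols(envelopes, c("peptide_id", "protein_id", "sample_id", "group",
                           "time_days", "n_leu", "channel", "intensity"),
              "envelopes")
  env <- envelopes[envelopes$n_leu >= 1L, , drop = FALSE]
  out <- vector("list", 0L)
  for (s in unique(env$sample_id)) {
    es <- env[env$sample_id == s, , drop = FALSE]
    p_s <- if (is.null(p)) {
      estimate_enrichment(es, min_leu = min_leu)$p_hat
    } else if (length(p) > 1 || !is.null(names(p))) {
      if (!s %in% names(p)) stop("no enrichment supplied for sample ", s)
      unname(p[[s]])
    } else {
      p
    }
    for (nl in sort(unique(es$n_leu))) {
      en <- es[es$n_leu == nl, , drop = FALSE]
      en <- en[order(en$peptide_id, en$channel), , drop = FALSE]
      first <- !duplicated(en$peptide_id)
      n_pep <- sum(first)
      if (nrow(en) != n_pep * (nl + 1L)) {
        stop("incomplete envelope(s) for n_leu = ", nl, " in sample ", s)
      }
      M <- matrix(en$intensity, nrow = n_pep, ncol = nl + 1L, byrow = TRUE)
      tot <- rowSums(M)
      keep <- tot > 0
      Y0 <- M / tot
      Y0[, 1] <- Y0[, 1] - 1
      d <- .mixture_direction(nl, p_s)
      f <- as.vector(Y0 %*% d) / sum(d * d)
      f <- pmin(pmax(f, 0), 1)
      R <- Y0 - outer(f, d)
      res <- data.frame(
        en[first, c("peptide_id", "protein_id", "sample_id", "group",
                    "time_days")],
        percent_new = 100 * f,
        residual_norm = sqrt(rowSums(R * R)),
        p_hat_used = p_s,
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- res[keep, , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Align retention coordinates between two runs
#'
#' Ordinary least-squares line mapping run A's retention coordinate (time or
#' scan number) to run B's, from peptides identified in both runs. The
#' matching window for transferring a peptide quantified in one run to the
#' other is `window_k` residual standard deviations around the predicted
#' coordinate.
#'
#' @param rt_a,rt_b retention coordinates of shared peptides (same length,
#'   >= 3).
#' @param window_k window half-width multiplier on the residual SD.
#' @return list with `slope`, `intercept`, `residual_sd`,
#'   `window_halfwidth`, and `predict(x)`, a function mapping run A
#'   coordinates into run B.
#' @export
align_runs <- function(rt_a, rt_b, window_k = 3) {
  if (length(rt_a) != length(rt_b)) stop("rt_a and rt_b must have equal length")
  if (length(rt_a) < 3) stop("insufficient anchors: need >= 3 shared peptides")
  fit <- stats::lm(rt_b ~ rt_a)
  cf <- stats::coef(fit)
  # exactly collinear anchors give a legitimate zero residual SD
  sig <- suppressWarnings(summary(fit)$sigma)
  list(slope = unname(cf[2]),
       intercept = unname(cf[1]),
       residual_sd = sig,
       window_halfwidth = window_k * sig,
       predict = function(x) unname(cf[1] + cf[2] * x))
}
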