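#' Differential abundance of one protein from peptide areas
#'
#' Linear model on `log2(AUC)` with one intercept per peptide (a blocking
#' factor absorbing each peptide's ionization efficiency) and a group
#' effect; the group coefficient is the protein's log2 fold change
#' (aged / young) and its t-test gives the p-value — a blocked analogue of
#' a two-sample t-test. The estimate is invariant to rescaling any single
#' peptide's areas, since the scale is absorbed by that peptide's block
#' intercept.
#'
#' @param auc_rows peptide area rows for one protein: columns `peptide_id`,
#'   `group`, `auc` (positive).
#' @param group_a,group_b group labels; the fold change is B over A.
#' @return one-row data frame with `log2_fc_old_over_young`, `t_statistic`,
#'   `p_value`, `n_peptides`, `n_observations`.
#' @export
protein_fold_change <- function(auc_rows, group_a = "young",
                                group_b = "old") {
  .check_cols(auc_rows, c("peptide_id", "group", "auc"), "auc_rows")
  m <- auc_rows[!is.na(auc_rows$auc), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% m$group)) {
    stop("contrast not estimable: a group has no observations")
  }
  if (any(m$auc <= 0)) stop("auc must be positive")
  l2 <- log2(m$auc)
  pep <- factor(m$peptide_id)
  grp <- factor(m$group, levels = c(group_a, group_b))
  fit <- if (nlevels(pep) > 1) stats::lm(l2 ~ pep + grp) else
    stats::lm(l2 ~ grp)
  cname <- paste0("grp", group_b)
  est <- unname(stats::coef(fit)[cname])
  smry <- summary(fit)
  tstat <- smry$coefficients[cname, "t value"]
  pv <- smry$coefficients[cname, "Pr(>|t|)"]
  if (!is.finite(pv) || smry$sigma < 1e-8) {  # zero-residual limit
    if (abs(est) < 1e-12) {
      pv <- 1; tstat <- 0
    } else {
      pv <- 0; tstat <- sign(est) * Inf
    }
  }
  data.frame(log2_fc_old_over_young = est, t_statistic = unname(tstat),
             p_value = unname(pv), n_peptides = nlevels(pep),
             n_observations = nrow(m), stringsAsFactors = FALSE)
}

#' Differential abundance for every protein, with q-values
#'
#' @param abundances peptide area table (columns `protein_id`, `peptide_id`,
#'   `group`, `auc`).
#' @inheritParams protein_fold_change
#' @param q_method `"BH"` or `"storey"`.
#' @return data frame with one row per protein: fold change, test
#'   statistics, and `q_value`. Proteins whose contrast is not estimable get
#'   `NA` statistics.
#' @export
abundance_all <- function(abundances, group_a = "young", group_b = "old",
                          q_method = "BH") {
  .check_cols(abundances, c("protein_id", "peptide_id", "group", "auc"),
              "abundances")
  parts <- split(abundances, abundances$protein_id)
  rows <- lapply(parts, function(m) {
    res <- tryCatch(protein_fold_change(m, group_a, group_b),
                    error = function(e) {
      data.frame(log2_fc_old_over_young = NA_real_, t_statistic = NA_real_,
                 p_value = NA_real_,
                 n_peptides = length(unique(m$peptide_id)),
                 n_observations = nrow(m), stringsAsFactors = FALSE)
    })
    cbind(data.frame(protein_id = m$protein_id[1], stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- adjust_multiplicity(out$p_value[ok], method = q_method)
  out
}

# Storey q-values with a single-lambda pi0 estimate: pi0 = #{p > lambda} /
# (m * (1 - lambda)), capped at 1, then the usual step-up with pi0 * m * p / k.
.storey_q <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Adjust p-values for multiplicity into q-values
#'
#' Benjamini-Hochberg step-up by default (the deterministic core), or Storey
#' pi0-estimated q-values for closer fidelity to q-value-based FDR control.
#' Output order matches input order.
#'
#' @param p_values numeric vector in [0, 1].
#' @param method `"BH"` or `"storey"`.
#' @param lambda pi0 tuning parameter for the Storey method.
#' @return q-values in the input order.
#' @export
adjust_multiplicity <- function(p_values, method = c("BH", "storey"),
                                lambda = 0.5) {
  method <- match.arg(method)
  .check_prob(p_values, "p_values")
  if (length(p_values) == 0) return(numeric(0))
  switch(method,
         BH = stats::p.adjust(p_values, method = "BH"),
         storey = .storey_q(p_values, lambda))
}

#' Mitochondrial fraction of total chromatographic area per sample
#'
#' For each sample, sums the areas of peptides from annotated mitochondrial
#' proteins and divides by the total area over all peptides (unannotated
#' proteins count toward the total only). The per-sample fractions are
#' compared between age groups with a two-sided two-sample t-test.
#'
#' @param abundances peptide area table (columns `protein_id`, `sample_id`,
#'   `group`, `auc`).
#' @param annotation compartment table (columns `protein_id`,
#'   `compartment`), e.g. from [annotate_compartments()].
#' @param group_a,group_b the two groups compared.
#' @return list with `fractions` (per-sample data frame: `sample_id`,
#'   `group`, `mito_auc`, `total_auc`, `fraction`), `group_means` (named
#'   vector), and `p_value`.
#' @export
mito_auc_fraction <- function(abundances, annotation, group_a = "young",
                              group_b = "old") {
  .check_cols(abundances, c("protein_id", "sample_id", "group", "auc"),
              "abundances")
  .check_cols(annotation, c("protein_id", "compartment"), "annotation")
  comp <- annotation$compartment[match(abundances$protein_id,
                                       annotation$protein_id)]
  comp[is.na(comp)] <- "other"
  total <- tapply(abundances$auc, abundances$sample_id, sum)
  if (any(total <= 0)) {
    stop("empty sample: total AUC must be positive in every sample")
  }
  is_mito <- comp == "mito"
  mito <- tapply(abundances$auc * is_mito, abundances$sample_id, sum)
  sample_ids <- names(total)
  grp <- abundances$group[match(sample_ids, abundances$sample_id)]
  fractions <- data.frame(sample_id = sample_ids, group = grp,
                          mito_auc = as.numeric(mito),
                          total_auc = as.numeric(total),
                          fraction = as.numeric(mito / total),
                          stringsAsFactors = FALSE, row.names = NULL)
  sel <- fractions$group %in% c(group_a, group_b)
  gm <- tapply(fractions$fraction[sel], fractions$group[sel], mean)
  p_value <- if (all(table(fractions$group[sel]) >= 2) &&
                 length(unique(fractions$group[sel])) == 2) {
    fa <- fractions$fraction[fractions$group == group_a]
    fb <- fractions$fraction[fractions$group == group_b]
    if (stats::sd(fa) == 0 && stats::sd(fb) == 0) {
      if (mean(fa) == mean(fb)) 1 else 0
    } else {
      stats::t.test(fa, fb)$p.value
    }
  } else {
    NA_real_
  }
  list(fractions = fractions, group_means = gm, p_value = p_value)
}
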