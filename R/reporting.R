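#' Assign proteins to subcellular compartments from reference lists
#'
#' Proteins on the mitochondrial reference list are `mito`, those on the
#' cytosolic list are `cyto`, all others `other`. A protein on both lists is
#' assigned `mito` (the mitochondrial reference takes precedence) and the
#' conflict is reported via a message and the `"conflicts"` attribute.
#'
#' @param protein_ids character vector of identifiers.
#' @param mito_list,cyto_list reference identifier sets (same namespace as
#'   `protein_ids`).
#' @return data frame with `protein_id` and `compartment`; conflicting
#'   identifiers in `attr(, "conflicts")`.
#' @export
annotate_compartments <- function(protein_ids, mito_list,
                                  cyto_list = character(0)) {
  compartment <- rep("other", length(protein_ids))
  compartment[protein_ids %in% cyto_list] <- "cyto"
  compartment[protein_ids %in% mito_list] <- "mito"
  conflicts <- protein_ids[protein_ids %in% mito_list &
                             protein_ids %in% cyto_list]
  if (length(conflicts)) {
    message(length(conflicts),
            " protein(s) on both reference lists assigned to mito: ",
            paste(utils::head(conflicts, 5), collapse = ", "),
            if (length(conflicts) > 5) ", ..." else "")
  }
  out <- data.frame(protein_id = protein_ids, compartment = compartment,
                    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- conflicts
  out
}

#' Compartment-stratified half-life summary
#'
#' Median and mean half-life with protein counts, per group, for the total
#' set and for the mitochondrial and cytosolic strata — the layout of a
#' turnover study's headline half-life table. Expects fits that already
#' passed [filter_fits()]. Empty strata get `n_proteins = 0` and `NA`
#' summaries.
#'
#' @param kept_fits `kept` element of [filter_fits()].
#' @param annotations compartment table (see [annotate_compartments()]).
#' @return data frame with `stratum`, `group`, `median_t_half`,
#'   `mean_t_half`, `n_proteins`.
#' @export
summarize_half_lives <- function(kept_fits, annotations) {
  .check_cols(kept_fits, c("protein_id", "group", "half_life_days"),
              "kept_fits")
  comp <- annotations$compartment[match(kept_fits$protein_id,
                                        annotations$protein_id)]
  comp[is.na(comp)] <- "other"
  strata <- list(total = rep(TRUE, nrow(kept_fits)),
                 mito = comp == "mito",
                 cyto = comp == "cyto")
  groups <- unique(kept_fits$group)
  rows <- list()
  for (st in names(strata)) {
    for (g in groups) {
      hl <- kept_fits$half_life_days[strata[[st]] & kept_fits$group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, group = g,
        median_t_half = if (length(hl)) stats::median(hl) else NA_real_,
        mean_t_half = if (length(hl)) mean(hl) else NA_real_,
        n_proteins = length(hl), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Classify half-life changes and count overlaps between muscles
#'
#' Per muscle, counts proteins whose half-life significantly lengthened or
#' shortened with age (`q_value < q_threshold`, direction from the sign of
#' the half-life change) versus unchanged. With exactly two muscles, also
#' computes Venn overlap counts of the longer- and shorter-lived sets,
#' restricted to proteins tested in both muscles; both the per-muscle tested
#' counts and the tested-in-both denominator are reported since either can
#' serve as the Venn universe.
#'
#' @param comparisons named list of per-muscle comparison tables (from
#'   [compare_all_proteins()]), or one table with a `muscle` column.
#' @param q_threshold significance threshold.
#' @return list with `counts` (per-muscle data frame of
#'   longer/shorter/unchanged/tested), `venn` (per direction: only-first,
#'   both, only-second), and `n_tested_both`.
#' @export
classify_changes <- function(comparisons, q_threshold = 0.05) {
  if (is.data.frame(comparisons)) {
    .check_cols(comparisons, "muscle", "comparisons")
    comparisons <- split(comparisons, comparisons$muscle)
  }
  muscles <- names(comparisons)
  direction_of <- function(cmp) {
    .check_cols(cmp, c("protein_id", "q_value", "half_life_a", "half_life_b"),
                "comparisons")
    d <- rep("unchanged", nrow(cmp))
    sig <- !is.na(cmp$q_value) & cmp$q_value < q_threshold
    d[sig & cmp$half_life_b > cmp$half_life_a] <- "longer_lived"
    d[sig & cmp$half_life_b < cmp$half_life_a] <- "shorter_lived"
    d
  }
  dirs <- lapply(comparisons, direction_of)
  counts <- do.call(rbind, lapply(muscles, function(m) {
    ok <- !is.na(comparisons[[m]]$p_value)
    data.frame(muscle = m,
               longer = sum(dirs[[m]] == "longer_lived"),
               shorter = sum(dirs[[m]] == "shorter_lived"),
               unchanged = sum(dirs[[m]] == "unchanged" & ok),
               tested = sum(ok), stringsAsFactors = FALSE)
  }))
  venn <- NULL
  n_both <- NA_integer_
  if (length(muscles) == 2) {
    tested <- lapply(muscles, function(m) {
      comparisons[[m]]$protein_id[!is.na(comparisons[[m]]$p_value)]
    })
    both <- intersect(tested[[1]], tested[[2]])
    n_both <- length(both)
    venn <- lapply(c(longer = "longer_lived", shorter = "shorter_lived"),
                   function(dd) {
      s1 <- intersect(comparisons[[1]]$protein_id[dirs[[1]] == dd], both)
      s2 <- intersect(comparisons[[2]]$protein_id[dirs[[2]] == dd], both)
      c(only_first = length(setdiff(s1, s2)),
        both = length(intersect(s1, s2)),
        only_second = length(setdiff(s2, s1)))
    })
  }
  list(counts = counts, venn = venn, n_tested_both = n_both)
}

#' Regress half-life changes on abundance changes
#'
#' Ordinary least-squares regression of per-protein half-life change on
#' abundance change (both as aged/young log ratios), quantifying how much of
#' the proteome's turnover remodeling is explained by its abundance
#' remodeling (historically very little: r-squared of a few percent).
#'
#' @param delta_abundance per-protein abundance log-ratio (aged/young).
#' @param delta_half_life per-protein half-life log-ratio (aged/young),
#'   same length/order.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
correlate_changes <- function(delta_abundance, delta_half_life) {
  if (length(delta_abundance) != length(delta_half_life)) {
    stop("inputs must have equal length")
  }
  ok <- is.finite(delta_abundance) & is.finite(delta_half_life)
  x <- delta_abundance[ok]
  y <- delta_half_life[ok]
  if (length(x) < 3) stop("insufficient pairs: need >= 3")
  if (stats::sd(x) == 0) stop("degenerate predictor: constant abundance change")
  fit <- stats::lm(y ~ x)
  smry <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = smry$r.squared,
       p_value = smry$coefficients["x", "Pr(>|t|)"],
       n = length(x))
}

#' One-sided Fisher's exact p-value for a 2x2 enrichment table
#'
#' Probability, under the hypergeometric null, of an overlap at least as
#' large as observed, for the table (in-set hits, in-set non-hits, out-set
#' hits, out-set non-hits).
#'
#' @param in_hits,in_miss,out_hits,out_miss 2x2 table cells.
#' @return p-value.
#' @export
fisher_greater_p <- function(in_hits, in_miss, out_hits, out_miss) {
  tab <- matrix(c(in_hits, in_miss, out_hits, out_miss), nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each gene set (intersected with the universe), tabulates hit versus
#' non-hit against in-set versus out-of-set and computes the one-sided
#' Fisher's exact p-value, the overlap ratio (hits in set / set size within
#' the universe), and q-values over the retained sets. Sets with fewer than
#' `min_hits` hits are excluded from the output.
#'
#' @param hit_set identifiers of interest (must lie in `universe`).
#' @param universe all tested identifiers.
#' @param gene_sets named list of identifier vectors, e.g. from
#'   [read_gmt()].
#' @param min_hits minimum number of hits for a set to be reported.
#' @param q_method passed to [adjust_multiplicity()].
#' @return data frame with `set_name`, `n_set`, `n_hits`, `overlap_ratio`,
#'   `fisher_p`, `q_value`.
#' @export
enrich_gene_sets <- function(hit_set, universe, gene_sets, min_hits = 4L,
                             q_method = "BH") {
  if (length(universe) == 0) stop("universe must be non-empty")
  if (!all(hit_set %in% universe)) {
    stop("hit_set must be a subset of universe")
  }
  hit_set <- unique(hit_set)
  universe <- unique(universe)
  n_hit <- length(hit_set)
  n_uni <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(hit_set, members))
    if (a < min_hits) return(NULL)
    data.frame(set_name = nm, n_set = length(members), n_hits = a,
               overlap_ratio = a / length(members),
               fisher_p = fisher_greater_p(a, length(members) - a,
                                           n_hit - a,
                                           n_uni - length(members) -
                                             (n_hit - a)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set_name = character(0), n_set = integer(0),
                      n_hits = integer(0), overlap_ratio = numeric(0),
                      fisher_p = numeric(0), stringsAsFactors = FALSE)
  }
  out$q_value <- adjust_multiplicity(out$fisher_p, method = q_method)
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member identifiers.
#'
#' @param path GMT file path.
#' @return named list of identifier vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' Read a plain-text identifier list (one per line)
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return character vector of identifiers.
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
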