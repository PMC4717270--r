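`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw values from a simple distribution specification
#'
#' Distribution laws throughout the simulator are given as lists with a
#' `dist` element: `list(dist = "point", value = )`,
#' `list(dist = "lognormal", meanlog = , sdlog = )`, or
#' `list(dist = "uniform", min = , max = )`.
#'
#' @param n number of draws.
#' @param law distribution specification list.
#' @return numeric vector of length `n`.
#' @keywords internal
draw_law <- function(n, law) {
  if (!is.list(law) || is.null(law$dist)) {
    stop("distribution law must be a list with a 'dist' element")
  }
  switch(law$dist,
    point = rep(law$value, n),
    lognormal = stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    uniform = stats::runif(n, min = law$min, max = law$max),
    stop("unknown distribution: ", law$dist)
  )
}

# Counts, optionally truncated below at law$min (inverse-CDF truncation so the
# draw is a genuine truncated Poisson, not a clamped one).
draw_count_law <- function(n, law) {
  if (!is.list(law) || is.null(law$dist)) {
    stop("count law must be a list with a 'dist' element")
  }
  min_k <- as.integer(law$min %||% 0L)
  switch(law$dist,
    point = rep(as.integer(law$value), n),
    poisson = {
      lo <- stats::ppois(min_k - 1L, law$lambda)
      as.integer(stats::qpois(stats::runif(n, lo, 1), law$lambda))
    },
    stop("unknown count distribution: ", law$dist)
  )
}

# Multiplicative log-normal noise with unit mean and the given coefficient of
# variation on the natural scale.
mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

.check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop(name, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

#' Read and write tab-separated tables in the package dialect
#'
#' Plain TSV, no quoting, no row names; `read_tsv_table()` never converts
#' strings to factors.
#'
#' @param df data frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
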