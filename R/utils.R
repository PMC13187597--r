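# Shared helpers: rounding, chromosome naming, seeded evaluation, logging.

#' Round half away from zero
#'
#' Percentages reported by the pipeline are rounded half-away-from-zero
#' (so 20.05 -> 20.1, -20.05 -> -20.1), not to even as [round()] does.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, 2.345, -0.15), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator, one decimal
#' @param n Numerator count.
#' @param d Denominator count.
#' @return Percentage rounded half-away-from-zero to one decimal.
#' @export
percent_of <- function(n, d) {
  stopifnot(all(d > 0))
  round_half_up(100 * n / d, 1)
}

# Normalize chromosome labels: strip "chr", keep 1-22/X/Y, drop MT with warning.
# Returns a character vector; mitochondrial entries are NA (caller drops them).
normalize_chromosome <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  x[x %in% c("M", "MT", "Mt")] <- NA_character_
  ok <- x %in% c(as.character(1:22), "X", "Y") | is.na(x)
  if (!all(ok)) {
    abort(paste0("unrecognized chromosome label(s): ",
                 paste(unique(x[!ok]), collapse = ", ")))
  }
  x
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-unit sub-seed from a master seed so streams are independent of
# how many units follow (kept below 2^31 - 1).
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629) + 1L
}

# Leveled logging to stderr. Levels: DEBUG < INFO < WARN.
log_msg <- function(level, msg) {
  inform(sprintf("[%s] %s", level, msg))
}

# Canonical chromosome rank for sorting: 1..22, X, Y.
chromosome_rank <- function(chrom) {
  match(chrom, c(as.character(1:22), "X", "Y"))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
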