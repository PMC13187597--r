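# Mutational-signature exposure estimation: non-negative least squares
# decomposition of 96-channel catalogs onto a signature matrix, with a
# multinomial bootstrap for per-signature confidence intervals and the
# high-confidence call (95% CI excluding zero).

# Exact NNLS by exhaustive support enumeration, batched over catalogs.
#
# For each support set A the unconstrained least-squares solution on A that
# is non-negative is a feasible point of the NNLS problem, and the NNLS
# optimum restricted to its own support is exactly such a solution (KKT
# stationarity); hence the best feasible support solution is the global
# optimum. With K signatures there are 2^K supports, so for the small
# signature sets used here this is exact and fast, and whole bootstrap
# batches are solved with a handful of matrix products. Larger K falls back
# to Lawson-Hanson (pracma::lsqnonneg).
nnls_batch <- function(Y, S) {
  K <- ncol(S)
  B <- ncol(Y)
  best_res2 <- colSums(Y^2)       # empty support: all-zero exposures
  best_x <- matrix(0, nrow = K, ncol = B)
  subsets <- lapply(seq_len(2^K - 1), function(m) which(bitwAnd(m, 2^(0:(K - 1))) > 0))
  for (A in subsets) {
    SA <- S[, A, drop = FALSE]
    XA <- tryCatch(solve(crossprod(SA), crossprod(SA, Y)),
                   error = function(e) NULL)
    if (is.null(XA)) next
    feas <- colSums(XA < -1e-10) == 0
    if (!any(feas)) next
    res2 <- colSums((Y - SA %*% XA)^2)
    upd <- feas & res2 < best_res2 - 1e-12
    if (any(upd)) {
      best_res2[upd] <- res2[upd]
      best_x[, upd] <- 0
      best_x[A, upd] <- pmax(XA[, upd, drop = FALSE], 0)
    }
  }
  rownames(best_x) <- colnames(S)
  list(exposure = best_x, residual_norm = sqrt(pmax(best_res2, 0)))
}

# One NNLS solve: counts (length 96) onto S (96 x K). Returns exposures in
# mutation counts plus the Euclidean residual norm.
nnls_fit <- function(counts, S) {
  if (length(counts) != nrow(S)) {
    abort(sprintf("catalog must have %d channels, got %d", nrow(S), length(counts)))
  }
  if (ncol(S) == 0) abort("signature matrix has no columns")
  if (all(counts == 0)) {
    return(list(exposure = setNames(numeric(ncol(S)), colnames(S)),
                residual_norm = 0))
  }
  if (ncol(S) <= 10) {
    fit <- nnls_batch(matrix(as.numeric(counts), ncol = 1), S)
    return(list(exposure = setNames(fit$exposure[, 1], colnames(S)),
                residual_norm = fit$residual_norm[1]))
  }
  fit <- pracma::lsqnonneg(S, as.numeric(counts))
  x <- setNames(as.numeric(fit$x), colnames(S))
  list(exposure = x,
       residual_norm = sqrt(sum((as.numeric(counts) - S %*% x)^2)))
}

catalogs_as_matrix <- function(catalogs) {
  if (is.matrix(catalogs)) return(catalogs)
  if (is.numeric(catalogs)) {
    return(matrix(catalogs, ncol = 1, dimnames = list(NULL, "catalog")))
  }
  assert_columns(catalogs, c("sample", "context", "count"), "catalogs")
  catalog_matrix(catalogs)
}

#' Fit signature exposures by non-negative least squares
#'
#' Decomposes each catalog into non-negative signature exposures minimizing
#' the Euclidean distance between the observed 96-channel counts and the
#' signature-matrix reconstruction (Lawson-Hanson NNLS). Exposures are in
#' mutation counts; derive fractions by dividing by the catalog total.
#'
#' @param catalogs A long catalog tibble (`sample`, `context`, `count`), a
#'   96 x samples count matrix, or a length-96 numeric vector.
#' @param signatures 96 x K signature matrix, columns summing to 1
#'   (default [default_signature_matrix()]).
#' @return A tibble of class `signature_exposure`: one row per sample and
#'   signature with `exposure` and the per-sample `residual_norm`.
#' @export
#' @examples
#' S <- default_signature_matrix()
#' fit_exposures(round(1000 * S[, "SBS1"]), S)
fit_exposures <- function(catalogs, signatures = default_signature_matrix()) {
  m <- catalogs_as_matrix(catalogs)
  res <- purrr::map_dfr(colnames(m), function(s) {
    fit <- nnls_fit(m[, s], signatures)
    tibble(sample = s, signature = colnames(signatures),
           exposure = unname(fit$exposure),
           residual_norm = fit$residual_norm)
  })
  class(res) <- c("signature_exposure", class(res))
  res
}

#' Bootstrap confidence intervals for signature exposures
#'
#' Draws `B` multinomial resamples of each catalog (total count preserved),
#' refits the NNLS decomposition on each, and reports percentile confidence
#' intervals per signature. A signature is flagged `high_confidence` when the
#' lower percentile bound is strictly positive (i.e. the CI excludes zero).
#' Catalogs with zero total mutations get degenerate `[0, 0]` intervals and
#' `FALSE` flags. Deterministic given `seed`.
#'
#' @inheritParams fit_exposures
#' @param B Number of bootstrap resamples (default 1000, minimum 100).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling stream.
#' @return A `signature_exposure` tibble with `exposure`, `ci_lower`,
#'   `ci_upper`, `high_confidence` per sample and signature.
#' @export
bootstrap_exposures <- function(catalogs, signatures = default_signature_matrix(),
                                B = 1000, level = 0.95, seed = 1L) {
  if (B < 100) abort("B must be at least 100")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  m <- catalogs_as_matrix(catalogs)
  alpha <- (1 - level) / 2
  samples <- colnames(m)
  purrr::map_dfr(seq_along(samples), function(si) {
    s <- samples[si]
    counts <- m[, s]
    fit <- nnls_fit(counts, signatures)
    total <- sum(counts)
    if (total == 0) {
      return(tibble(sample = s, signature = colnames(signatures),
                    exposure = 0, ci_lower = 0, ci_upper = 0,
                    high_confidence = FALSE))
    }
    boot <- with_seed(sub_seed(seed, si), {
      draws <- rmultinom(B, total, counts / total)
      if (ncol(signatures) <= 10) {
        nnls_batch(draws, signatures)$exposure
      } else {
        apply(draws, 2, function(y) nnls_fit(y, signatures)$exposure)
      }
    })
    # boot is K x B
    lo <- apply(boot, 1, quantile, probs = alpha, names = FALSE)
    hi <- apply(boot, 1, quantile, probs = 1 - alpha, names = FALSE)
    tibble(sample = s, signature = colnames(signatures),
           exposure = unname(fit$exposure),
           ci_lower = unname(lo), ci_upper = unname(hi),
           high_confidence = unname(lo) > 0)
  }) -> res
  class(res) <- c("signature_exposure", class(res))
  res
}

#' Call signature-3 presence per sample
#'
#' Classifies each sample as `absent` (point exposure 0, or exposure
#' fraction below `min_fraction`), `present` (qualifying positive exposure)
#' or `present_high_confidence` (qualifying exposure whose bootstrap CI
#' excludes zero). The last level requires that the exposure table carries
#' bootstrap flags ([bootstrap_exposures()]). The default `min_fraction = 0`
#' reproduces the raw any-exposure rule; the pipeline applies the configured
#' relative-exposure floor (`sig3_min_fraction`) because flat signatures
#' attract spurious NNLS exposure in low-mutation-count catalogs.
#'
#' @param exposures A `signature_exposure` tibble.
#' @param signature Signature to call (default `"SBS3"`).
#' @param min_fraction Relative-exposure floor in `[0, 1]` (default 0).
#' @return Tibble: `sample`, `exposure`, `fraction`, `call` (factor with the
#'   three levels).
#' @export
detect_sig3 <- function(exposures, signature = "SBS3", min_fraction = 0) {
  if (!signature %in% exposures$signature) {
    abort(sprintf("signature '%s' was not among the fitted signatures", signature))
  }
  df <- exposure_fractions(exposures) |>
    filter(.data$signature == !!signature)
  hc <- if ("high_confidence" %in% names(df)) df$high_confidence
        else rep(FALSE, nrow(df))
  qualifying <- df$exposure > 0 & df$fraction >= min_fraction
  df |>
    mutate(call = factor(ifelse(!qualifying, "absent",
                                ifelse(hc, "present_high_confidence",
                                       "present")),
                         levels = c("absent", "present",
                                    "present_high_confidence"))) |>
    select("sample", "exposure", "fraction", "call")
}

#' @export
tidy.signature_exposure <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.signature_exposure <- function(x, ...) {
  x |>
    group_by(.data$sample) |>
    summarise(total_exposure = sum(.data$exposure),
              residual_norm = .data$residual_norm[1],
              n_signatures = dplyr::n(), .groups = "drop")
}

#' Exposure fractions from an exposure table
#' @param exposures A `signature_exposure` tibble.
#' @return The table with an added `fraction` column (exposure / sample total;
#'   0 where the sample total is 0).
#' @export
exposure_fractions <- function(exposures) {
  exposures |>
    group_by(.data$sample) |>
    mutate(fraction = .data$exposure /
             max(sum(.data$exposure), .Machine$double.xmin)) |>
    ungroup()
}
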