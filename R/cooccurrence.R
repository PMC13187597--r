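# Pairwise co-occurrence / mutual-exclusivity testing under a
# Poisson-binomial null with per-gene, per-sample background probabilities
# (DISCOVER/Rediscover-style marginal-matching background).

#' Estimate the gene-by-sample background alteration model
#'
#' Fits `p[g, j] = plogis(mu_g + lambda_j)` by alternating Newton updates so
#' that expected row sums match observed per-gene alteration counts and
#' expected column sums match observed per-sample alteration loads (both to
#' `tol`). Degenerate all-zero/all-one rows and columns are clipped to
#' `[1e-9, 1 - 1e-9]`.
#'
#' @param mat Binary `alteration_matrix` (genes x samples).
#' @param tol Marginal matching tolerance (default 1e-9).
#' @param max_iter Maximum alternating sweeps (default 2000).
#' @return A matrix of probabilities with the dimensions and dimnames of
#'   `mat`, of class `background_model`.
#' @export
estimate_background <- function(mat, tol = 1e-9, max_iter = 2000) {
  m <- unclass(mat)
  if (!all(m %in% c(0, 1))) abort("alteration matrix must be binary")
  G <- nrow(m); S <- ncol(m)
  rs <- rowSums(m); cs <- colSums(m)
  eps <- 1e-9
  if (G == 1 || S == 1) {
    # a single row (or column) makes every column (row) marginal binary and
    # the sample effects unidentifiable; the background degenerates to the
    # uniform marginal frequency
    p <- if (G == 1) matrix(rs / S, G, S) else matrix(cs / G, G, S)
    p <- pmin(pmax(p, eps), 1 - eps)
    dimnames(p) <- dimnames(m)
    return(structure(p, class = c("background_model", "matrix", "array")))
  }
  # homogeneous-column shortcut also covers the 1 x n case
  mu <- qlogis(pmin(pmax(rs / S, eps), 1 - eps))
  lam <- rep(0, S)
  for (it in seq_len(max_iter)) {
    p <- plogis(outer(mu, lam, "+"))
    # gene effects
    err_r <- rowSums(p) - rs
    w_r <- rowSums(p * (1 - p))
    mu <- mu - err_r / pmax(w_r, eps)
    p <- plogis(outer(mu, lam, "+"))
    err_c <- colSums(p) - cs
    w_c <- colSums(p * (1 - p))
    lam <- lam - err_c / pmax(w_c, eps)
    # identifiability: centre the sample effects
    shift <- mean(lam)
    lam <- lam - shift
    mu <- mu + shift
    p <- plogis(outer(mu, lam, "+"))
    if (max(abs(rowSums(p) - rs)) < tol && max(abs(colSums(p) - cs)) < tol) break
  }
  p <- pmin(pmax(plogis(outer(mu, lam, "+")), eps), 1 - eps)
  dimnames(p) <- dimnames(m)
  structure(p, class = c("background_model", "matrix", "array"))
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with heterogeneous probabilities, computed by iterative
#' convolution (dynamic programming, exact to machine precision).
#'
#' @param probs Vector of success probabilities in `[0, 1]`.
#' @return Numeric vector of length `length(probs) + 1`: P(X = 0..n).
#' @export
#' @examples
#' dpoisbinom(c(0.5, 0.5))  # 0.25 0.50 0.25
dpoisbinom <- function(probs) {
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  pmf <- 1
  for (p in probs) {
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  pmf
}

#' Poisson-binomial tail probabilities
#'
#' `P(X <= q)` (or `P(X >= q)` with `lower_tail = FALSE`, inclusive) for the
#' Poisson-binomial distribution. Uses the exact convolution up to
#' `exact_limit` trials and a moment-matched shifted-binomial approximation
#' (matching mean, variance and skewness) beyond.
#'
#' @param q Count at which to evaluate the tail (inclusive).
#' @param probs Success probabilities.
#' @param lower_tail If `TRUE` (default) return `P(X <= q)`, else `P(X >= q)`.
#' @param exact_limit Use the exact pmf up to this number of trials
#'   (default 500).
#' @return Tail probability.
#' @export
ppoisbinom <- function(q, probs, lower_tail = TRUE, exact_limit = 500) {
  n <- length(probs)
  if (n <= exact_limit) {
    pmf <- dpoisbinom(probs)
    idx <- if (lower_tail) seq_len(q + 1) else (q + 1):(n + 1)
    return(min(1, sum(pmf[idx])))
  }
  shifted_binomial_tail(q, probs, lower_tail)
}

# Moment-matched shifted binomial: choose integer size m, probability p and
# real shift s so the first three moments match the Poisson-binomial ones.
shifted_binomial_tail <- function(q, probs, lower_tail = TRUE) {
  mu <- sum(probs)
  v <- sum(probs * (1 - probs))
  if (v == 0) {
    return(if (lower_tail) as.numeric(q >= mu) else as.numeric(q <= mu))
  }
  skew <- sum(probs * (1 - probs) * (1 - 2 * probs)) / v^1.5
  p <- (1 - skew * sqrt(v)) / 2
  p <- min(max(p, 1e-12), 1 - 1e-12)
  m <- max(1, round(v / (p * (1 - p))))
  s <- mu - m * p
  # the shift is fractional; interpolate the binomial CDF between the two
  # adjacent lattice points (reduces the discretization error to ~1e-5)
  cdf <- function(x) {
    f <- floor(x); w <- x - f
    (1 - w) * pbinom(f, m, p) + w * pbinom(f + 1, m, p)
  }
  if (lower_tail) cdf(q - s) else 1 - cdf(q - 1 - s)
}

#' Test one gene pair for co-occurrence and mutual exclusivity
#'
#' The overlap-count null is Poisson-binomial with per-sample probabilities
#' `q_j = p_aj * p_bj` from the background model. `p_cooccurrence` is
#' `P(X >= observed)` and `p_exclusivity` is `P(X <= observed)` (both tails
#' include the observed value).
#'
#' @param gene_a,gene_b Row names in `mat`.
#' @param mat Binary `alteration_matrix`.
#' @param background Background model from [estimate_background()] (computed
#'   on the fly when `NULL`).
#' @return One-row tibble: `gene_a`, `gene_b`, `observed_overlap`,
#'   `expected_overlap`, `p_cooccurrence`, `p_exclusivity`.
#' @export
test_pair <- function(gene_a, gene_b, mat, background = NULL) {
  background <- background %||% estimate_background(mat)
  a <- mat[gene_a, ]; b <- mat[gene_b, ]
  q <- background[gene_a, ] * background[gene_b, ]
  obs <- sum(a == 1 & b == 1)
  tibble(
    gene_a = gene_a, gene_b = gene_b,
    observed_overlap = as.integer(obs),
    expected_overlap = sum(q),
    p_cooccurrence = ppoisbinom(obs, q, lower_tail = FALSE),
    p_exclusivity = ppoisbinom(obs, q, lower_tail = TRUE)
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] with input validation). Elementwise `q >= p` and
#' order-preserving.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Cohort-wide pairwise co-occurrence / exclusivity screen
#'
#' Tests every pair of matrix rows altered in at least `min_samples` samples
#' (the marginal floor applies per gene, not to the overlap). BH correction
#' is applied separately to the co-occurrence and exclusivity p-value
#' families. Rows failing the floor are reported in the `skipped` attribute.
#'
#' @param mat Binary `alteration_matrix`.
#' @param background Optional precomputed [estimate_background()] model.
#' @param min_samples Marginal floor (default 3).
#' @return Tibble of pair results with `q_cooccurrence`, `q_exclusivity`,
#'   sorted by the smaller q-value; attribute `skipped` lists excluded rows.
#' @export
cooccurrence_test <- function(mat, background = NULL, min_samples = 3) {
  marg <- rowSums(mat)
  keep <- names(marg)[marg >= min_samples]
  skipped <- setdiff(rownames(mat), keep)
  if (length(skipped) > 0) {
    log_msg("INFO", sprintf("skipping %d row(s) altered in fewer than %d samples",
                            length(skipped), min_samples))
  }
  if (length(keep) < 2) {
    out <- tibble(gene_a = character(), gene_b = character(),
                  observed_overlap = integer(), expected_overlap = numeric(),
                  p_cooccurrence = numeric(), p_exclusivity = numeric(),
                  q_cooccurrence = numeric(), q_exclusivity = numeric())
    attr(out, "skipped") <- skipped
    return(out)
  }
  background <- background %||% estimate_background(mat)
  pairs <- utils::combn(keep, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    test_pair(pairs[1, k], pairs[2, k], mat, background)
  })
  res <- res |>
    mutate(q_cooccurrence = adjust_bh(.data$p_cooccurrence),
           q_exclusivity = adjust_bh(.data$p_exclusivity)) |>
    arrange(pmin(.data$q_cooccurrence, .data$q_exclusivity))
  attr(res, "skipped") <- skipped
  res
}
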