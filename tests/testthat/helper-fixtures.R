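# Shared fixture builders. Everything is generated in code; no stored data.

# Segment tibble in the internal half-open 0-based convention.
seg <- function(chromosome, start_mb, end_mb, total_cn = 2L, minor_cn = 1L,
                sample = "S1") {
  tibble::tibble(sample = sample, chromosome = as.character(chromosome),
                 start = start_mb * 1e6, end = end_mb * 1e6,
                 total_cn = as.integer(total_cn),
                 minor_cn = as.integer(minor_cn))
}

variants_tbl <- function(sample, gene, classification,
                         origin = "somatic", copy_context = "unknown",
                         pathogenic = NA) {
  tibble::tibble(sample = sample, gene = gene,
                 classification = classification,
                 variant_type = "SNV", origin = origin, vaf = 0.3,
                 copy_context = copy_context, pathogenic = pathogenic)
}

# Write a minimal variant TSV and return its path.
write_variant_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# Exact Poisson-binomial pmf by exhaustive enumeration over all 2^n outcomes
# (independent oracle for the convolution implementation).
poisbinom_enum <- function(probs) {
  n <- length(probs)
  pmf <- numeric(n + 1)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(n)]
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    pmf[sum(bits) + 1] <- pmf[sum(bits) + 1] + pr
  }
  pmf
}

# Independent log-rank statistic (observed-minus-expected over event times).
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d1 <- sum(event == 1 & time == t & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
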