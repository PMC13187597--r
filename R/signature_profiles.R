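# 96-channel trinucleotide contexts and bundled signature profiles.
#
# The bundled profiles are SYNTHETIC: deterministic stand-ins with the
# qualitative character of the corresponding COSMIC v2 single-base-substitution
# signatures (SBS1 deamination peaks at NpCpG, SBS3 near-featureless "flat"
# HRD signature, SBS5 flat with a T>C tilt, SBS6 MMR-like C>T dominance,
# SBS17 T>G peaks at NpTpT). They are intended for simulation and testing;
# substitute the real COSMIC matrix via read_signature_matrix() for analysis
# of real catalogs.

#' Canonical 96 trinucleotide substitution contexts
#'
#' Labels in canonical COSMIC ordering: substitution type major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank A/C/G/T, then 3' flank
#' A/C/G/T, i.e. `A[C>A]A` first and `T[T>G]T` last.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs96_contexts())
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(f) paste0(f, "[", s, "]", bases)))
  }))
}

#' Bundled synthetic signature matrix
#'
#' A deterministic 96 x 5 matrix of synthetic single-base-substitution
#' signature profiles (columns `SBS1`, `SBS3`, `SBS5`, `SBS6`, `SBS17`,
#' each summing to 1), mimicking the qualitative shape of the corresponding
#' COSMIC v2 signatures. See the file-level note: these are simulation
#' stand-ins, not the COSMIC estimates.
#'
#' @param signatures Which signature columns to return (default all five).
#' @return Numeric matrix with rownames [sbs96_contexts()] and one column per
#'   signature; every column sums to 1.
#' @export
#' @examples
#' S <- default_signature_matrix()
#' colSums(S)
default_signature_matrix <- function(signatures = c("SBS1", "SBS3", "SBS5",
                                                    "SBS6", "SBS17")) {
  ctx <- sbs96_contexts()
  sub <- substr(ctx, 3, 5)
  five <- substr(ctx, 1, 1)
  three <- substr(ctx, 7, 7)
  i <- seq_len(96)

  w <- list()
  # SBS1: spontaneous 5mC deamination -> C>T at NpCpG
  w$SBS1 <- 0.05 + 28 * (sub == "C>T" & three == "G") +
    0.6 * (sub == "C>T")
  # SBS3: HRD-associated, near-uniform across channels (mild ripple keeps the
  # column distinguishable without adding sharp features)
  w$SBS3 <- 1 + 0.25 * cos(2 * pi * i / 96)
  # SBS5: clock-like, T>C dominated (kept well away from the flat SBS3
  # column so low-count catalogs do not split arbitrarily between the two)
  w$SBS5 <- 0.18 + 2.6 * (sub == "T>C") +
    0.8 * (sub == "C>T" & five %in% c("A", "C"))
  # SBS6: MMR-deficiency-like, C>T dominated, strongest at GpCpN
  w$SBS6 <- 0.12 + 3.2 * (sub == "C>T") + 4.5 * (sub == "C>T" & five == "G")
  # SBS17: T>G at NpTpT (and mild T>C at the same contexts)
  w$SBS17 <- 0.08 + 22 * (sub == "T>G" & three == "T") +
    2.0 * (sub == "T>C" & three == "T")

  unknown <- setdiff(signatures, names(w))
  if (length(unknown) > 0) {
    abort(paste0("no bundled profile for: ", paste(unknown, collapse = ", ")))
  }
  m <- vapply(signatures, function(s) w[[s]] / sum(w[[s]]), numeric(96))
  rownames(m) <- ctx
  m
}

#' Read a signature matrix from TSV
#'
#' Expects a tab-separated file with a context-label column (named `context`
#' or the first column) holding the 96 canonical trinucleotide labels and one
#' numeric column per signature. Rows may be in any order; they are
#' normalized to canonical ordering and columns rescaled to sum to 1.
#'
#' @param path Path to the TSV file.
#' @return Numeric 96 x K matrix, columns summing to 1.
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ctx_col <- if ("context" %in% names(df)) "context" else names(df)[1]
  ctx <- sbs96_contexts()
  if (nrow(df) != 96 || !setequal(df[[ctx_col]], ctx)) {
    abort("signature matrix must have exactly the 96 canonical context rows")
  }
  df <- df[match(ctx, df[[ctx_col]]), , drop = FALSE]
  m <- as.matrix(df[setdiff(names(df), ctx_col)])
  if (any(m < 0)) abort("signature profiles must be non-negative")
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- ctx
  m
}

#' Write a signature matrix to TSV
#' @param mat 96 x K signature matrix with context rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(mat, path) {
  df <- tibble::tibble(context = rownames(mat))
  for (s in colnames(mat)) df[[s]] <- mat[, s]
  readr::write_tsv(df, path)
  invisible(path)
}
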