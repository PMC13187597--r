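# Analysis configuration: documented defaults plus flat key-value overrides.

#' Default analysis configuration
#'
#' Returns the full set of tunable parameters with their documented defaults.
#' All downstream functions that take a `config` argument accept the result of
#' [default_config()] or [load_config()].
#'
#' Keys (units in parentheses):
#' \describe{
#'   \item{retained_classes}{Variant classifications kept by
#'     [filter_classified()] (maftools non-synonymous convention).}
#'   \item{tmb_denominator_mb}{TMB denominator (megabases), default 38.}
#'   \item{tmb_high_threshold}{Strict threshold for TMB-high (mutations/Mb),
#'     default 10.}
#'   \item{hrd_loh_min_mb}{Minimum LOH segment length counted by the HRD-LOH
#'     score (Mb), default 15.}
#'   \item{lst_min_segment_mb, lst_smooth_mb}{LST segment-size floor and
#'     small-segment smoothing width (Mb), defaults 10 and 3.}
#'   \item{instability_loh_cutoff, instability_lst_cutoff}{Scar-score cutoffs
#'     granting genomic-instability points, defaults 10 and 15.}
#'   \item{sig3_rule}{Rule granting the signature-3 point: `"present"`
#'     (exposure fraction at or above `sig3_min_fraction`, default) or
#'     `"high_confidence"` (bootstrap CI excluding zero).}
#'   \item{sig3_min_fraction}{Relative-exposure floor below which a fitted
#'     SBS3 exposure is treated as absent in the pipeline (default 0.10;
#'     flat signatures attract spurious NNLS exposure at low mutation
#'     counts).}
#'   \item{germline_weights, somatic_weights}{Points per lesion by HRR gene
#'     category; caps `germline_cap`/`somatic_cap` (default 2 each).}
#'   \item{positivity_min_total}{Minimum total TOP-ART score for positivity
#'     (default 3; positivity additionally requires detected patterns).}
#'   \item{signature_set}{Signatures fitted by default.}
#'   \item{delta}{PFS-ratio efficacy threshold, default 1.3.}
#'   \item{alpha}{Significance level, default 0.05.}
#'   \item{bootstrap_B, pfs_bootstrap_B}{Bootstrap replicates for exposure CIs
#'     (1000) and the PFS-ratio CI (2000).}
#'   \item{min_pair_samples}{Marginal floor for co-occurrence testing
#'     (default 3 samples per gene).}
#'   \item{seed}{Default RNG seed.}
#' }
#'
#' @return A named list of class `topart_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$delta
default_config <- function() {
  structure(list(
    retained_classes = c(
      "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
      "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
      "In_Frame_Del", "In_Frame_Ins", "Translation_Start_Site"
    ),
    tmb_denominator_mb = 38,
    tmb_high_threshold = 10,
    hrd_loh_min_mb = 15,
    lst_min_segment_mb = 10,
    lst_smooth_mb = 3,
    instability_loh_cutoff = 10,
    instability_lst_cutoff = 15,
    sig3_rule = "present",
    sig3_min_fraction = 0.10,
    germline_weights = c(core = 2, associated = 1, unknown_association = 0),
    somatic_weights = c(core = 2, associated = 1, unknown_association = 0),
    germline_cap = 2,
    somatic_cap = 2,
    positivity_min_total = 3,
    max_total = 7,
    signature_set = c("SBS1", "SBS3", "SBS5", "SBS6", "SBS17"),
    delta = 1.3,
    alpha = 0.05,
    bootstrap_B = 1000,
    pfs_bootstrap_B = 2000,
    min_pair_samples = 3,
    seed = 1L
  ), class = "topart_config")
}

#' Load configuration overrides from a flat key-value file
#'
#' The file format is one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Vector values are comma-separated; named
#' vectors use `name:value` entries (e.g. `germline_weights = core:2,associated:1`).
#' Unknown keys raise an error listing the valid keys. Values are coerced to
#' the type of the corresponding default.
#'
#' @param path Path to the configuration file; `NULL` returns the defaults.
#' @param defaults Base configuration to merge into (default [default_config()]).
#' @return A `topart_config` list: defaults with overrides applied.
#' @export
load_config <- function(path = NULL, defaults = default_config()) {
  if (is.null(path)) return(defaults)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("malformed config line (expected 'key = value'): '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) {
      abort(sprintf("unknown config key '%s'; valid keys: %s",
                    key, paste(names(cfg), collapse = ", ")))
    }
    cfg[[key]] <- coerce_config_value(val, cfg[[key]], key)
  }
  cfg
}

coerce_config_value <- function(val, default, key) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  if (grepl(":", val, fixed = TRUE)) {
    nm <- trimws(sub(":.*$", "", parts))
    vv <- trimws(sub("^[^:]*:", "", parts))
    out <- if (is.numeric(default)) as.numeric(vv) else vv
    if (anyNA(out)) abort(sprintf("could not parse value for config key '%s'", key))
    return(setNames(out, nm))
  }
  if (is.numeric(default)) {
    out <- suppressWarnings(as.numeric(parts))
    if (anyNA(out)) abort(sprintf("config key '%s' expects numeric value(s)", key))
    if (is.integer(default) && length(out) == 1) out <- as.integer(out)
    return(out)
  }
  parts
}

#' @export
print.topart_config <- function(x, ...) {
  cat("<topart_config> with", length(x), "keys\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k,
                paste(utils::head(format(v, trim = TRUE), 6), collapse = ", ")))
  }
  invisible(x)
}
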