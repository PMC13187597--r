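# Composite TOP-ART HRD assessment: HRR-impairment sub-score (germline and
# bi-allelic somatic lesions in HRR genes) plus genomic-pattern sub-score
# (scar-score instability and signature-3 exposure); positive when the total
# reaches 3 points AND genomic patterns are detected.

#' Default HRR gene panel
#'
#' Genes of the homologous recombination repair pathway grouped into the
#' three categories used by the scoring schema: `core` (BRCA1/2, PALB2),
#' `associated`, and `unknown_association`.
#'
#' @return Tibble with columns `gene`, `category`.
#' @export
default_hrr_panel <- function() {
  dplyr::bind_rows(
    tibble(gene = c("BRCA1", "BRCA2", "PALB2"), category = "core"),
    tibble(gene = c("ATM", "ATR", "BAP1", "BARD1", "BRIP1", "CHEK1", "CHEK2",
                    "FANCA", "FANCD2", "MRE11A", "NBN", "RAD50", "RAD51",
                    "RAD51B", "RAD51C", "RAD51D"),
           category = "associated"),
    tibble(gene = c("FANCL", "RAD54L", "XRCC2", "GEN1"),
           category = "unknown_association")
  )
}

variant_points <- function(genes, panel, weights) {
  cat <- panel$category[match(genes, panel$gene)]
  unname(weights[cat])
}

#' Score HRR-pathway impairment per sample
#'
#' Germline pathogenic lesions score by gene category (default core 2,
#' associated 1, unknown 0; summed and capped at `germline_cap`). Somatic
#' lesions affecting all gene copies (`copy_context == "all_copies"`,
#' corresponding to bi-allelic events) score analogously with the somatic
#' weights; mono-allelic somatic lesions score 0 but are counted. Variants in
#' genes outside the panel are ignored with a warning.
#'
#' @param germline_variants Germline variant tibble; rows with
#'   `pathogenic == TRUE` (or `NA` treated as non-pathogenic) are scored.
#' @param somatic_variants Somatic variant tibble with `copy_context`.
#' @param panel HRR panel ([default_hrr_panel()]).
#' @param config Scoring configuration ([default_config()]): keys
#'   `germline_weights`, `somatic_weights`, `germline_cap`, `somatic_cap`.
#' @param samples Optional sample vector so lesion-free samples appear with
#'   zero points.
#' @return Tibble: `sample`, `germline_points`, `somatic_points`,
#'   `impairment_score`, `n_monoallelic_somatic`.
#' @export
score_hrr_impairment <- function(germline_variants, somatic_variants,
                                 panel = default_hrr_panel(),
                                 config = default_config(),
                                 samples = NULL) {
  gv <- germline_variants |>
    filter(dplyr::coalesce(.data$pathogenic, FALSE))
  sv <- somatic_variants
  off_panel <- setdiff(unique(c(gv$gene, sv$gene)), panel$gene)
  if (length(off_panel) > 0) {
    log_msg("WARN", sprintf("ignoring variants in %d non-panel gene(s): %s",
                            length(off_panel),
                            paste(head(off_panel, 5), collapse = ", ")))
    gv <- filter(gv, .data$gene %in% panel$gene)
    sv <- filter(sv, .data$gene %in% panel$gene)
  }
  samples <- samples %||% sort(unique(c(germline_variants$sample,
                                        somatic_variants$sample)))
  g_pts <- gv |>
    mutate(points = variant_points(.data$gene, panel, config$germline_weights)) |>
    group_by(.data$sample) |>
    summarise(germline_points = min(sum(.data$points), config$germline_cap),
              .groups = "drop")
  biallelic <- filter(sv, .data$copy_context == "all_copies")
  s_pts <- biallelic |>
    mutate(points = variant_points(.data$gene, panel, config$somatic_weights)) |>
    group_by(.data$sample) |>
    summarise(somatic_points = min(sum(.data$points), config$somatic_cap),
              .groups = "drop")
  mono <- sv |>
    filter(.data$copy_context == "mono_allelic") |>
    count(.data$sample, name = "n_monoallelic_somatic")
  tibble(sample = samples) |>
    left_join(g_pts, by = "sample") |>
    left_join(s_pts, by = "sample") |>
    left_join(mono, by = "sample") |>
    mutate(
      germline_points = dplyr::coalesce(.data$germline_points, 0),
      somatic_points = dplyr::coalesce(.data$somatic_points, 0),
      impairment_score = .data$germline_points + .data$somatic_points,
      n_monoallelic_somatic = as.integer(dplyr::coalesce(.data$n_monoallelic_somatic, 0L))
    )
}

#' Score the genomic-pattern component per sample
#'
#' Genomic instability contributes 1 point when either scar score reaches its
#' cutoff (HRD-LOH >= 10 or LST >= 15 by default) and 2 points when both do.
#' Signature 3 contributes 1 point when its call satisfies the configured
#' rule (`sig3_rule = "present"`: any positive exposure, the default, or
#' `"high_confidence"`). Patterns are detected when the component score is
#' at least 1.
#'
#' @param scars Tibble from [scar_scores()] (`sample`, `hrd_loh`, `lst`).
#' @param sig3_calls Tibble from [detect_sig3()] (`sample`, `call`).
#' @param config Configuration ([default_config()]): keys
#'   `instability_loh_cutoff`, `instability_lst_cutoff`, `sig3_rule`.
#' @return Tibble: `sample`, `instability_points`, `sig3_points`,
#'   `pattern_score`, `patterns_detected`.
#' @export
score_genomic_pattern <- function(scars, sig3_calls,
                                  config = default_config()) {
  assert_columns(scars, c("sample", "hrd_loh", "lst"), "scars")
  assert_columns(sig3_calls, c("sample", "call"), "sig3_calls")
  ok_calls <- if (identical(config$sig3_rule, "high_confidence")) {
    "present_high_confidence"
  } else {
    c("present", "present_high_confidence")
  }
  scars |>
    left_join(select(sig3_calls, "sample", "call"), by = "sample") |>
    mutate(
      instability_points = (.data$hrd_loh >= config$instability_loh_cutoff) +
        (.data$lst >= config$instability_lst_cutoff),
      sig3_points = as.integer(!is.na(.data$call) & .data$call %in% ok_calls),
      pattern_score = .data$instability_points + .data$sig3_points,
      patterns_detected = .data$pattern_score >= 1
    ) |>
    select("sample", "instability_points", "sig3_points", "pattern_score",
           "patterns_detected")
}

#' Compose the TOP-ART assessment
#'
#' Joins the HRR-impairment and genomic-pattern sub-scores and applies the
#' positivity rule: positive iff the total score reaches
#' `config$positivity_min_total` (default 3) AND genomic patterns are
#' detected. With the default tables the maximum total is 7.
#'
#' @param impairment Tibble from [score_hrr_impairment()].
#' @param pattern Tibble from [score_genomic_pattern()].
#' @param config Configuration ([default_config()]).
#' @return A tibble of class `topart_assessment`: per-sample sub-scores,
#'   `total`, `patterns_detected`, `positive`.
#' @export
#' @examples
#' imp <- tibble::tibble(sample = "S1", germline_points = 2,
#'                       somatic_points = 0, impairment_score = 2,
#'                       n_monoallelic_somatic = 0L)
#' pat <- tibble::tibble(sample = "S1", instability_points = 1,
#'                       sig3_points = 0, pattern_score = 1,
#'                       patterns_detected = TRUE)
#' compose_topart(imp, pat)
compose_topart <- function(impairment, pattern, config = default_config()) {
  out <- impairment |>
    left_join(pattern, by = "sample") |>
    mutate(
      instability_points = dplyr::coalesce(.data$instability_points, 0L),
      sig3_points = dplyr::coalesce(.data$sig3_points, 0L),
      pattern_score = dplyr::coalesce(.data$pattern_score, 0L),
      patterns_detected = dplyr::coalesce(.data$patterns_detected, FALSE),
      total = .data$impairment_score + .data$pattern_score,
      positive = .data$total >= config$positivity_min_total &
        .data$patterns_detected
    )
  if (any(out$total > config$max_total)) {
    abort(sprintf("total score exceeds the configured maximum (%d)",
                  config$max_total))
  }
  class(out) <- c("topart_assessment", class(out))
  out
}

#' Full TOP-ART assessment for a cohort
#'
#' Convenience wrapper: computes scar scores from segments, signature-3 calls
#' from catalogs (bootstrap confidence at `config$bootstrap_B` resamples),
#' HRR-impairment from the variant tables, and composes the assessment.
#'
#' @param cohort A `btc_cohort` ([cohort_dataset()] / [generate_cohort()]).
#' @param config Configuration ([default_config()]).
#' @param panel HRR panel ([default_hrr_panel()]).
#' @param signatures Signature matrix for the exposure fit.
#' @param seed Seed for the exposure bootstrap (default `config$seed`).
#' @return A `topart_assessment` tibble.
#' @export
topart_score <- function(cohort, config = default_config(),
                         panel = default_hrr_panel(),
                         signatures = default_signature_matrix(config$signature_set),
                         seed = config$seed) {
  samples <- cohort$samples$sample
  scars <- scar_scores(
    cohort$segments,
    sample_sex = select(cohort$samples, "sample", "sex"),
    hrd_loh_min_mb = config$hrd_loh_min_mb,
    lst_min_segment_mb = config$lst_min_segment_mb,
    lst_smooth_mb = config$lst_smooth_mb
  )
  scars <- tibble(sample = samples) |>
    left_join(scars, by = "sample") |>
    mutate(hrd_loh = dplyr::coalesce(.data$hrd_loh, 0L),
           lst = dplyr::coalesce(.data$lst, 0L))
  exposures <- if (identical(config$sig3_rule, "high_confidence")) {
    bootstrap_exposures(cohort$catalogs, signatures,
                        B = config$bootstrap_B, seed = seed)
  } else {
    fit_exposures(cohort$catalogs, signatures)
  }
  sig3 <- detect_sig3(exposures, min_fraction = config$sig3_min_fraction)
  sig3 <- tibble(sample = samples) |>
    left_join(sig3, by = "sample") |>
    mutate(call = dplyr::coalesce(as.character(.data$call), "absent"))
  impairment <- score_hrr_impairment(
    cohort$germline_variants,
    filter(filter_classified(cohort$somatic_variants,
                             config$retained_classes),
           .data$gene %in% panel$gene),
    panel = panel, config = config, samples = samples
  )
  pattern <- score_genomic_pattern(scars, sig3, config)
  out <- compose_topart(impairment, pattern, config)
  left_join(out, scars, by = "sample")
}

#' @export
tidy.topart_assessment <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.topart_assessment <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_positive = sum(x$positive),
    percent_positive = percent_of(sum(x$positive), nrow(x)),
    median_total = median(x$total),
    max_total = max(x$total)
  )
}
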