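# End-to-end cohort analysis: one call running variant filtering, TMB,
# alteration matrix, signature exposures with bootstrap confidence, scar
# scores, the composite TOP-ART assessment, the pairwise
# co-occurrence/exclusivity screen, and the guided-therapy outcome analytics.

#' Run the full cohort analysis
#'
#' @param cohort A `btc_cohort` ([cohort_dataset()] or [generate_cohort()]).
#' @param config Analysis configuration ([default_config()]).
#' @param panel HRR gene panel for the impairment score.
#' @param gene_panel Gene panel for the alteration matrix.
#' @param signatures Signature matrix for the exposure fit.
#' @param seed Seed for all stochastic steps (default `config$seed`).
#' @return A list of class `cohort_report`:
#' \describe{
#'   \item{tmb}{Per-sample TMB table and `tmb_summary` (median, n high).}
#'   \item{alterations, alteration_frequencies}{Binary matrix and per-gene rates.}
#'   \item{exposures, sig3_calls, sig3_summary}{Bootstrap exposure table and
#'     signature-3 prevalence.}
#'   \item{scars, topart, topart_summary}{Scar scores and the composite
#'     assessment.}
#'   \item{cooccurrence}{Pairwise test results.}
#'   \item{guided_summary, pfs_ratio}{Outcome analytics for guided therapy.}
#'   \item{accounting}{Cohort flow counts (profiled vs guided).}
#' }
#' @export
run_cohort_analysis <- function(cohort, config = default_config(),
                                panel = default_hrr_panel(),
                                gene_panel = default_gene_panel(),
                                signatures = default_signature_matrix(config$signature_set),
                                seed = config$seed) {
  samples <- cohort$samples$sample

  tmb <- compute_tmb(cohort$somatic_variants,
                     denominator_mb = config$tmb_denominator_mb,
                     threshold = config$tmb_high_threshold,
                     samples = samples,
                     retained_classes = config$retained_classes)
  tmb_summary <- tibble(
    n = nrow(tmb),
    median_tmb = median(tmb$tmb),
    n_high = sum(tmb$high),
    percent_high = percent_of(sum(tmb$high), nrow(tmb))
  )

  mat <- build_alteration_matrix(cohort$somatic_variants, cna = cohort$cna,
                                 fusions = cohort$fusions, panel = gene_panel,
                                 samples = samples,
                                 retained_classes = config$retained_classes)

  exposures <- bootstrap_exposures(cohort$catalogs, signatures,
                                   B = config$bootstrap_B, seed = seed)
  sig3_calls <- detect_sig3(exposures, min_fraction = config$sig3_min_fraction)
  sig3_calls <- tibble(sample = samples) |>
    left_join(sig3_calls, by = "sample") |>
    mutate(call = factor(
      dplyr::coalesce(as.character(.data$call), "absent"),
      levels = levels(sig3_calls$call)),
      exposure = dplyr::coalesce(.data$exposure, 0))
  sig3_summary <- tibble(
    n = nrow(sig3_calls),
    n_present = sum(sig3_calls$call != "absent"),
    percent_present = percent_of(sum(sig3_calls$call != "absent"),
                                 nrow(sig3_calls)),
    n_high_confidence = sum(sig3_calls$call == "present_high_confidence"),
    percent_high_confidence = percent_of(
      sum(sig3_calls$call == "present_high_confidence"), nrow(sig3_calls))
  )

  scars <- scar_scores(cohort$segments,
                       sample_sex = select(cohort$samples, "sample", "sex"),
                       hrd_loh_min_mb = config$hrd_loh_min_mb,
                       lst_min_segment_mb = config$lst_min_segment_mb,
                       lst_smooth_mb = config$lst_smooth_mb)
  scars <- tibble(sample = samples) |>
    left_join(scars, by = "sample") |>
    mutate(hrd_loh = dplyr::coalesce(.data$hrd_loh, 0L),
           lst = dplyr::coalesce(.data$lst, 0L))

  somatic_panel <- filter_classified(cohort$somatic_variants,
                                     config$retained_classes) |>
    filter(.data$gene %in% panel$gene)
  impairment <- score_hrr_impairment(cohort$germline_variants, somatic_panel,
                                     panel = panel, config = config,
                                     samples = samples)
  pattern <- score_genomic_pattern(scars, sig3_calls, config)
  topart <- left_join(compose_topart(impairment, pattern, config),
                      scars, by = "sample")

  cooccur <- cooccurrence_test(mat, min_samples = config$min_pair_samples)

  guided <- filter(cohort$clinical,
                   dplyr::coalesce(.data$received_guided_therapy, FALSE))
  guided_summary <- guided_therapy_summary(cohort$clinical,
                                           delta = config$delta, seed = seed)
  pfs_ratio <- if (nrow(guided) > 0 &&
                   any(!is.na(guided$pfs1_months) & guided$pfs1_months > 0)) {
    pfs_ratio_analysis(guided, delta = config$delta,
                       B = config$pfs_bootstrap_B, seed = seed)
  } else NULL

  accounting <- cohort_accounting(list(
    profiled = cohort$samples$patient,
    guided_therapy = guided$patient
  ))

  structure(list(
    tmb = tmb, tmb_summary = tmb_summary,
    alterations = mat, alteration_frequencies = alteration_frequencies(mat),
    exposures = exposures, sig3_calls = sig3_calls,
    sig3_summary = sig3_summary,
    scars = scars, topart = topart, topart_summary = glance(topart),
    cooccurrence = cooccur,
    guided_summary = guided_summary, pfs_ratio = pfs_ratio,
    accounting = accounting,
    config = config, seed = seed
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  samples: %d; median TMB %.3f/Mb (%d high, %.1f%%)\n",
              x$tmb_summary$n, x$tmb_summary$median_tmb,
              x$tmb_summary$n_high, x$tmb_summary$percent_high))
  cat(sprintf("  signature 3: %.1f%% present, %.1f%% high-confidence\n",
              x$sig3_summary$percent_present,
              x$sig3_summary$percent_high_confidence))
  cat(sprintf("  TOP-ART positive: %d/%d (%.1f%%), median score %s\n",
              x$topart_summary$n_positive, x$topart_summary$n,
              x$topart_summary$percent_positive,
              format(x$topart_summary$median_total)))
  cat(sprintf("  co-occurrence pairs tested: %d\n", nrow(x$cooccurrence)))
  if (!is.null(x$pfs_ratio)) {
    cat(sprintf("  PFS-ratio benefit rate at delta=%.2f: %.3f\n",
                x$pfs_ratio$delta, x$pfs_ratio$benefit_rate))
  }
  invisible(x)
}
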