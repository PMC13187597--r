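# The cohort container: a list of tibbles covering every interchange table,
# with the cross-table invariants enforced at construction.

#' Assemble a cohort dataset
#'
#' Bundles the per-table tibbles into a validated `btc_cohort` object. One
#' analysis sample per patient is enforced (the patient/sample mapping in
#' `samples` must be one-to-one), every sample referenced by any table must
#' appear in `samples`, and at most one segment profile and one catalog may
#' exist per sample.
#'
#' @param samples Tibble with columns `sample`, `patient` and optionally `sex`.
#' @param somatic_variants,germline_variants Variant tibbles
#'   (see [read_variant_table()]).
#' @param segments Segment tibble (see [read_segment_table()]).
#' @param catalogs Long catalog tibble (see [read_catalog_table()]).
#' @param fusions Fusion tibble (see [read_fusion_table()]).
#' @param clinical Clinical tibble keyed by `patient`
#'   (see [read_clinical_table()]).
#' @param cna Gene-level copy-number calls: tibble with `sample`, `gene`,
#'   `type` (`"amplification"` or `"loss"`).
#' @param msi_status Tibble with `sample`, `msi` in `MSS`/`MSI-H`/`unknown`.
#' @return A `btc_cohort` list.
#' @export
cohort_dataset <- function(samples,
                           somatic_variants = empty_variants(),
                           germline_variants = empty_variants(),
                           segments = empty_segments(),
                           catalogs = empty_catalogs(),
                           fusions = empty_fusions(),
                           clinical = tibble(patient = character()),
                           cna = tibble(sample = character(),
                                        gene = character(),
                                        type = character()),
                           msi_status = tibble(sample = character(),
                                               msi = character())) {
  assert_columns(samples, c("sample", "patient"), "samples")
  if (!"sex" %in% names(samples)) samples$sex <- NA_character_
  if (anyDuplicated(samples$sample) || anyDuplicated(samples$patient)) {
    abort("patient/sample mapping must be one-to-one (one analysis sample per patient)")
  }
  segments <- as_tibble(segments) |>
    arrange(.data$sample, chromosome_rank(.data$chromosome), .data$start)
  x <- structure(list(
    samples = as_tibble(samples),
    somatic_variants = as_tibble(somatic_variants),
    germline_variants = as_tibble(germline_variants),
    segments = segments,
    catalogs = as_tibble(catalogs),
    fusions = as_tibble(fusions),
    clinical = as_tibble(clinical),
    cna = as_tibble(cna),
    msi_status = as_tibble(msi_status)
  ), class = "btc_cohort")
  validate_cohort(x)
}

validate_cohort <- function(x) {
  known <- x$samples$sample
  refs <- c(x$somatic_variants$sample, x$germline_variants$sample,
            x$segments$sample, x$catalogs$sample, x$fusions$sample,
            x$cna$sample, x$msi_status$sample)
  stray <- setdiff(unique(refs), known)
  if (length(stray) > 0) {
    abort(paste0("sample(s) referenced but not declared in samples table: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  per <- x$catalogs |> distinct(.data$sample, .data$context) |> count(.data$sample)
  if (any(per$n != 96)) abort("each catalog must have exactly 96 contexts")
  if (anyDuplicated(x$catalogs[c("sample", "context")])) {
    abort("at most one catalog per sample")
  }
  stray_pat <- setdiff(x$clinical$patient, x$samples$patient)
  if (length(stray_pat) > 0) {
    abort("clinical table references unknown patient(s)")
  }
  x
}

empty_variants <- function() {
  tibble(sample = character(), gene = character(),
         classification = character(), variant_type = character(),
         origin = character(), vaf = numeric(),
         copy_context = character(), pathogenic = logical())
}

empty_segments <- function() {
  tibble(sample = character(), chromosome = character(),
         start = numeric(), end = numeric(),
         total_cn = integer(), minor_cn = integer())
}

empty_catalogs <- function() {
  tibble(sample = character(), context = character(), count = integer())
}

empty_fusions <- function() {
  tibble(sample = character(), gene_5prime = character(),
         gene_3prime = character(), exon_5prime = integer(),
         exon_3prime = integer(), predicted_effect = character())
}

#' @export
print.btc_cohort <- function(x, ...) {
  cat("<btc_cohort>\n")
  cat(sprintf("  %d patients / samples\n", nrow(x$samples)))
  cat(sprintf("  somatic variants: %d  germline variants: %d\n",
              nrow(x$somatic_variants), nrow(x$germline_variants)))
  cat(sprintf("  segment rows: %d  catalog samples: %d  fusions: %d\n",
              nrow(x$segments), length(unique(x$catalogs$sample)),
              nrow(x$fusions)))
  cat(sprintf("  clinical records: %d\n", nrow(x$clinical)))
  invisible(x)
}

#' Write a cohort to a directory of interchange TSV files
#'
#' Writes `samples.tsv`, `somatic_variants.tsv`, `germline_variants.tsv`,
#' `segments.tsv` (1-based inclusive coordinates), `catalogs.tsv` (wide,
#' 96 context rows), `fusions.tsv`, `clinical.tsv`, `cna.tsv` and `msi.tsv`.
#'
#' @param cohort A `btc_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(cohort$samples, p("samples.tsv"))
  readr::write_tsv(cohort$somatic_variants, p("somatic_variants.tsv"))
  readr::write_tsv(cohort$germline_variants, p("germline_variants.tsv"))
  write_segment_table(cohort$segments, p("segments.tsv"))
  if (nrow(cohort$catalogs) > 0) {
    write_catalog_table(cohort$catalogs, p("catalogs.tsv"))
  }
  readr::write_tsv(cohort$fusions, p("fusions.tsv"))
  readr::write_tsv(cohort$clinical, p("clinical.tsv"))
  readr::write_tsv(cohort$cna, p("cna.tsv"))
  readr::write_tsv(cohort$msi_status, p("msi.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing the interchange files.
#' @return A `btc_cohort`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  rd <- function(f) read_tsv_quiet(p(f))
  samples <- rd("samples.tsv")
  somatic <- read_variant_table(p("somatic_variants.tsv"), "somatic")
  germline <- read_variant_table(p("germline_variants.tsv"), "germline")
  segments <- read_segment_table(p("segments.tsv"))
  catalogs <- if (file.exists(p("catalogs.tsv")))
    read_catalog_table(p("catalogs.tsv")) else empty_catalogs()
  cohort_dataset(
    samples = samples,
    somatic_variants = somatic,
    germline_variants = germline,
    segments = segments,
    catalogs = catalogs,
    fusions = read_fusion_table(p("fusions.tsv")),
    clinical = read_clinical_table(p("clinical.tsv")),
    cna = rd("cna.tsv"),
    msi_status = rd("msi.tsv")
  )
}
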