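# Readers/writers for the tabular interchange formats. All coordinate
# conversion between on-disk 1-based inclusive (SEG/IGV convention) and the
# internal 0-based half-open representation happens here and nowhere else.

maf_aliases <- c(
  Tumor_Sample_Barcode = "sample",
  Hugo_Symbol = "gene",
  Variant_Classification = "classification",
  Variant_Type = "variant_type",
  t_vaf = "vaf"
)

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_guess()))
}

#' Read a variant table (MAF-subset TSV)
#'
#' Accepts either MAF-style column names (`Tumor_Sample_Barcode`,
#' `Hugo_Symbol`, `Variant_Classification`, `Variant_Type`, `t_vaf`) or the
#' internal names (`sample`, `gene`, `classification`, `variant_type`, `vaf`).
#' Unknown classification strings are preserved verbatim; filtering is a
#' separate, explicit step ([filter_classified()]).
#'
#' @param path Path to a tab-separated file with a header.
#' @param origin `"somatic"` or `"germline"`; stamped on every record.
#' @return A tibble with columns `sample`, `gene`, `classification`,
#'   `variant_type`, `origin`, `vaf`, `copy_context`, `pathogenic`.
#' @export
read_variant_table <- function(path, origin = c("somatic", "germline")) {
  origin <- match.arg(origin)
  df <- read_tsv_quiet(path)
  hit <- intersect(names(maf_aliases), names(df))
  names(df)[match(hit, names(df))] <- maf_aliases[hit]
  for (col in c("sample", "gene", "classification")) {
    if (!col %in% names(df)) {
      abort(sprintf("variant table '%s' is missing mandatory column '%s'",
                    path, col))
    }
  }
  if (nrow(df) == 0) {
    warn(sprintf("variant table '%s' has no data rows", path))
  }
  tibble(
    sample = as.character(df$sample),
    gene = as.character(df$gene),
    classification = as.character(df$classification),
    variant_type = if ("variant_type" %in% names(df))
      as.character(df$variant_type) else NA_character_,
    origin = origin,
    vaf = if ("vaf" %in% names(df)) as.numeric(df$vaf) else NA_real_,
    copy_context = if ("copy_context" %in% names(df))
      as.character(df$copy_context) else "unknown",
    pathogenic = if ("pathogenic" %in% names(df))
      as.logical(df$pathogenic) else NA
  )
}

#' Write a variant table
#' @param variants Variant tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants[setdiff(names(variants), "origin")], path)
  invisible(path)
}

#' Read allele-specific copy-number segments (SEG-like TSV)
#'
#' On-disk coordinates are 1-based inclusive; the returned tibble uses the
#' internal 0-based half-open convention, so `end - start` is the segment
#' length in bases. Segments are sorted by sample, chromosome, start;
#' overlapping segments within a sample are rejected. `chr` prefixes are
#' stripped; mitochondrial segments are dropped with a logged warning.
#'
#' @param path Path to a TSV with columns `sample`, `chromosome`, `start`,
#'   `end`, `total_cn`, `minor_cn`.
#' @return A tibble with those columns (coordinates half-open 0-based).
#' @export
read_segment_table <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("sample", "chromosome", "start", "end",
                       "total_cn", "minor_cn"), sprintf("segment table '%s'", path))
  bad <- which(df$end < df$start)
  if (length(bad) > 0) {
    abort(sprintf("segment table '%s': end < start at data row %d",
                  path, bad[1]))
  }
  if (any(df$total_cn < 0, na.rm = TRUE) || any(df$minor_cn < 0, na.rm = TRUE)) {
    abort(sprintf("segment table '%s': negative copy number", path))
  }
  chrom <- normalize_chromosome(df$chromosome)
  if (anyNA(chrom)) {
    log_msg("WARN", sprintf("dropping %d mitochondrial segment(s)", sum(is.na(chrom))))
  }
  seg <- tibble(
    sample = as.character(df$sample),
    chromosome = chrom,
    start = as.numeric(df$start) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(df$end),
    total_cn = as.integer(df$total_cn),
    minor_cn = as.integer(df$minor_cn)
  ) |>
    filter(!is.na(.data$chromosome)) |>
    arrange(.data$sample, chromosome_rank(.data$chromosome), .data$start)
  ov <- seg |>
    group_by(.data$sample, .data$chromosome) |>
    summarise(overlap = any(.data$start < lag(.data$end), na.rm = TRUE),
              .groups = "drop")
  if (any(ov$overlap)) {
    first <- ov[ov$overlap, ][1, ]
    abort(sprintf("overlapping segments for sample '%s' on chromosome %s",
                  first$sample, first$chromosome))
  }
  seg
}

#' Write segments back to SEG-like TSV (1-based inclusive)
#' @param segments Segment tibble (internal 0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  out <- segments |>
    mutate(start = .data$start + 1) # back to 1-based inclusive
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read 96-channel mutation catalogs
#'
#' Expects a TSV with a `context` column (or the first column) holding the
#' 96 canonical trinucleotide labels and one non-negative integer column per
#' sample. Row order is normalized to canonical ordering regardless of input
#' order.
#'
#' @param path Path to the catalog TSV.
#' @return A long tibble with columns `sample`, `context`, `count`, rows in
#'   canonical context order within sample.
#' @export
read_catalog_table <- function(path) {
  df <- read_tsv_quiet(path)
  ctx_col <- if ("context" %in% names(df)) "context" else names(df)[1]
  ctx <- sbs96_contexts()
  if (nrow(df) != 96 || !setequal(df[[ctx_col]], ctx)) {
    abort(sprintf("catalog '%s' must have exactly the 96 canonical context rows (got %d rows)",
                  path, nrow(df)))
  }
  df <- df[match(ctx, df[[ctx_col]]), , drop = FALSE]
  samples <- setdiff(names(df), ctx_col)
  counts <- as.matrix(df[samples])
  if (any(counts < 0)) abort(sprintf("catalog '%s': negative count", path))
  if (any(counts != round(counts))) {
    abort(sprintf("catalog '%s': counts must be integers", path))
  }
  tidyr::expand_grid(sample = samples, context = ctx) |>
    mutate(count = as.integer(counts[cbind(
      match(.data$context, ctx), match(.data$sample, samples))])) |>
    arrange(.data$sample, match(.data$context, ctx))
}

#' Write mutation catalogs to wide TSV
#' @param catalogs Long catalog tibble (`sample`, `context`, `count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_table <- function(catalogs, path) {
  wide <- catalogs |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count") |>
    arrange(match(.data$context, sbs96_contexts()))
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Convert long catalogs to a 96 x samples count matrix
#' @param catalogs Long catalog tibble.
#' @return Integer matrix, rows in canonical context order.
#' @export
catalog_matrix <- function(catalogs) {
  ctx <- sbs96_contexts()
  samples <- unique(catalogs$sample)
  m <- matrix(0L, nrow = 96, ncol = length(samples),
              dimnames = list(ctx, samples))
  m[cbind(match(catalogs$context, ctx), match(catalogs$sample, samples))] <-
    as.integer(catalogs$count)
  m
}

#' Read a gene-fusion call table
#' @param path TSV with columns `sample`, `gene_5prime`, `gene_3prime` and
#'   optional `exon_5prime`, `exon_3prime`, `predicted_effect`.
#' @return A tibble of fusion records.
#' @export
read_fusion_table <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, c("sample", "gene_5prime", "gene_3prime"),
                 sprintf("fusion table '%s'", path))
  if (any(!nzchar(df$gene_5prime)) || any(!nzchar(df$gene_3prime))) {
    abort(sprintf("fusion table '%s': empty gene symbol", path))
  }
  out <- tibble(
    sample = as.character(df$sample),
    gene_5prime = as.character(df$gene_5prime),
    gene_3prime = as.character(df$gene_3prime),
    exon_5prime = if ("exon_5prime" %in% names(df))
      as.integer(df$exon_5prime) else NA_integer_,
    exon_3prime = if ("exon_3prime" %in% names(df))
      as.integer(df$exon_3prime) else NA_integer_,
    predicted_effect = if ("predicted_effect" %in% names(df))
      as.character(df$predicted_effect) else "unknown"
  )
  if (any(out$exon_5prime < 1, na.rm = TRUE) ||
      any(out$exon_3prime < 1, na.rm = TRUE)) {
    abort(sprintf("fusion table '%s': exon numbers must be >= 1", path))
  }
  out
}

#' Read a clinical outcome table
#'
#' @param path TSV with columns `patient` and any of `os_months`, `os_event`,
#'   `pfs1_months`, `pfs1_event`, `pfs2_months`, `pfs2_event`,
#'   `best_response`, `n_prior_lines`, `received_guided_therapy`, `basket`,
#'   `evidence_level`.
#' @return A tibble, event columns coerced to logical.
#' @export
read_clinical_table <- function(path) {
  df <- read_tsv_quiet(path)
  assert_columns(df, "patient", sprintf("clinical table '%s'", path))
  for (col in c("os_event", "pfs1_event", "pfs2_event",
                "received_guided_therapy")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  as_tibble(df)
}
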