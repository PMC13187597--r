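# Genomic scar scores from allele-specific copy-number segments.
#
# HRD-LOH (Abkevich-style convention): number of loss-of-heterozygosity
# regions (minor copy number 0) at least 15 Mb long that do not span the
# whole chromosome extent covered by the profile. Contiguous LOH segments
# (differing only in total copy number) are merged before measuring length.
#
# LST (Popova-style convention): after dropping segments shorter than the
# smoothing width (3 Mb) and re-merging flanking segments of equal
# allele-specific state, the number of chromosome-internal breakpoints
# between adjacent segments that each span at least 10 Mb and differ in
# (total, minor) copy number.
#
# Sex chromosomes: X is included only for female-annotated samples; Y is
# always excluded (minor-allele logic is undefined on hemizygous
# chromosomes). Coordinates are the internal half-open 0-based convention.

MB <- 1e6

filter_sex_chromosomes <- function(segments, sex = NA_character_) {
  keep_x <- !is.na(sex) && tolower(sex) %in% c("f", "female")
  segments |>
    filter(.data$chromosome != "Y",
           keep_x | .data$chromosome != "X")
}

# Merge abutting runs with a common predicate state; spans are summed.
merge_runs <- function(seg) {
  seg <- arrange(seg, .data$start)
  out <- seg[1, ]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- nrow(out)
      if (seg$start[i] <= out$end[last]) {
        out$end[last] <- max(out$end[last], seg$end[i])
      } else {
        out <- dplyr::bind_rows(out, seg[i, ])
      }
    }
  }
  out
}

#' HRD-LOH scar score
#'
#' Counts loss-of-heterozygosity regions (minor copy number 0, contiguous
#' segments merged) of length at least `min_mb` megabases that are shorter
#' than the full chromosome extent covered by the profile.
#'
#' @param segments Segment tibble for one sample (columns `chromosome`,
#'   `start`, `end`, `total_cn`, `minor_cn`; half-open 0-based coordinates).
#' @param min_mb Minimum qualifying LOH length in Mb (default 15).
#' @param sex Sample sex annotation; X is only scored for `"female"`.
#' @return Integer count.
#' @export
#' @examples
#' seg <- tibble::tibble(chromosome = "1", start = c(0, 40e6, 60e6),
#'                       end = c(40e6, 60e6, 100e6),
#'                       total_cn = 2L, minor_cn = c(1L, 0L, 1L))
#' compute_hrd_loh(seg)  # 20 Mb LOH inside a 100 Mb chromosome -> 1
compute_hrd_loh <- function(segments, min_mb = 15, sex = NA_character_) {
  if (nrow(segments) == 0) return(0L)
  assert_columns(segments, c("chromosome", "start", "end", "total_cn",
                             "minor_cn"), "segments")
  if (anyNA(segments$minor_cn)) {
    abort("HRD-LOH requires minor copy number on every segment")
  }
  seg <- filter_sex_chromosomes(segments, sex)
  if (nrow(seg) == 0) return(0L)
  n <- 0L
  for (chr in unique(seg$chromosome)) {
    s <- filter(seg, .data$chromosome == chr)
    extent <- max(s$end) - min(s$start)
    loh <- filter(s, .data$minor_cn == 0)
    if (nrow(loh) == 0) next
    runs <- merge_runs(loh)
    len <- runs$end - runs$start
    n <- n + sum(len >= min_mb * MB & len < extent)
  }
  as.integer(n)
}

#' Large-scale state transition (LST) scar score
#'
#' Smooths the profile by dropping segments shorter than `smooth_below_mb`
#' and merging flanking segments of equal allele-specific state, then counts
#' chromosome-internal breakpoints between adjacent segments that each span
#' at least `min_segment_mb` and differ in (total, minor) copy number.
#'
#' @param segments Segment tibble for one sample (half-open 0-based).
#' @param min_segment_mb Minimum flanking-segment span in Mb (default 10).
#' @param smooth_below_mb Segments shorter than this are smoothed away
#'   (default 3 Mb).
#' @param sex Sample sex annotation; X is only scored for `"female"`.
#' @return Integer count.
#' @export
compute_lst <- function(segments, min_segment_mb = 10, smooth_below_mb = 3,
                        sex = NA_character_) {
  if (nrow(segments) == 0) return(0L)
  assert_columns(segments, c("chromosome", "start", "end", "total_cn",
                             "minor_cn"), "segments")
  seg <- filter_sex_chromosomes(segments, sex)
  n <- 0L
  for (chr in unique(seg$chromosome)) {
    s <- seg |> filter(.data$chromosome == chr) |> arrange(.data$start)
    s <- filter(s, .data$end - .data$start >= smooth_below_mb * MB)
    if (nrow(s) < 2) next
    # re-merge equal-state neighbours exposed by the smoothing
    merged <- s[1, ]
    for (i in 2:nrow(s)) {
      last <- nrow(merged)
      if (s$total_cn[i] == merged$total_cn[last] &&
          s$minor_cn[i] == merged$minor_cn[last]) {
        merged$end[last] <- s$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, s[i, ])
      }
    }
    if (nrow(merged) < 2) next
    len <- merged$end - merged$start
    big <- len >= min_segment_mb * MB
    n <- n + sum(big[-length(big)] & big[-1])
  }
  as.integer(n)
}

#' Scar scores for every sample in a segment table
#'
#' @param segments Segment tibble covering one or more samples (a `sample`
#'   column is required).
#' @param sample_sex Optional tibble (`sample`, `sex`) controlling X-chromosome
#'   inclusion per sample.
#' @param hrd_loh_min_mb,lst_min_segment_mb,lst_smooth_mb Thresholds passed to
#'   [compute_hrd_loh()] and [compute_lst()].
#' @return Tibble: `sample`, `hrd_loh`, `lst`.
#' @export
scar_scores <- function(segments, sample_sex = NULL,
                        hrd_loh_min_mb = 15, lst_min_segment_mb = 10,
                        lst_smooth_mb = 3) {
  assert_columns(segments, "sample", "segments")
  samples <- unique(segments$sample)
  sex_of <- function(s) {
    if (is.null(sample_sex)) return(NA_character_)
    hit <- sample_sex$sex[match(s, sample_sex$sample)]
    if (length(hit) == 0) NA_character_ else hit
  }
  purrr::map_dfr(samples, function(s) {
    seg <- filter(segments, .data$sample == s)
    tibble(sample = s,
           hrd_loh = compute_hrd_loh(seg, hrd_loh_min_mb, sex = sex_of(s)),
           lst = compute_lst(seg, lst_min_segment_mb, lst_smooth_mb,
                             sex = sex_of(s)))
  })
}
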