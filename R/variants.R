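# Variant-classification filtering, alteration-matrix construction, TMB,
# cohort flow accounting, and basket/evidence-level annotation.

#' Keep non-synonymous variants (maftools convention)
#'
#' Retains exactly the non-synonymous classification strings of the maftools
#' convention (missense, nonsense, nonstop, splice site, frameshift and
#' in-frame indels, translation start site); silent/UTR/flank/intronic/IGR/RNA
#' classes are dropped. Classification strings outside both lists are dropped
#' with a logged count. The operation is idempotent.
#'
#' @param variants Variant tibble with a `classification` column.
#' @param retained_classes Character vector of classifications to keep
#'   (default: the maftools non-synonymous set, see [default_config()]).
#' @return The retained rows, same columns.
#' @export
#' @examples
#' v <- tibble::tibble(sample = "S1", gene = c("TP53", "TP53"),
#'                     classification = c("Missense_Mutation", "Silent"))
#' filter_classified(v)
filter_classified <- function(variants,
                              retained_classes = default_config()$retained_classes) {
  assert_columns(variants, "classification", "variants")
  known_dropped <- c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "RNA",
                     "3'Flank", "5'Flank")
  unknown <- setdiff(unique(variants$classification),
                     c(retained_classes, known_dropped))
  if (length(unknown) > 0) {
    n_unknown <- sum(variants$classification %in% unknown)
    log_msg("INFO", sprintf("dropping %d variant(s) with unrecognized classification(s): %s",
                            n_unknown, paste(head(unknown, 5), collapse = ", ")))
  }
  filter(variants, .data$classification %in% retained_classes)
}

#' Default gene panel for the alteration matrix
#'
#' A best-effort editable default assembled from genes recurrently altered in
#' biliary tract cancer, annotated with the alteration kind scored for each.
#'
#' @return Tibble with columns `gene`, `kind`
#'   (`snv_indel`/`amplification`/`loss`/`fusion`).
#' @export
default_gene_panel <- function() {
  dplyr::bind_rows(
    tibble(gene = c("TP53", "ARID1A", "IDH1", "IDH2", "BAP1", "KRAS", "BRAF",
                    "FGFR2", "TSC1", "PCDHA13", "FLG", "RAD51C", "BRCA1",
                    "BRCA2", "PALB2"),
           kind = "snv_indel"),
    tibble(gene = c("ERBB2", "MYC", "MCL1", "MET"), kind = "amplification"),
    tibble(gene = c("CDKN2A", "CDKN2B", "MTAP"), kind = "loss"),
    tibble(gene = c("FGFR2", "MET", "PTPRM"), kind = "fusion")
  )
}

#' Build the binary gene-by-sample alteration matrix
#'
#' One row per `(gene, kind)` panel entry, one column per sample; an entry is
#' 1 iff the sample carries at least one retained event of that kind in that
#' gene. Samples without events still appear as all-zero columns.
#'
#' @param variants Somatic variant tibble (already or not yet filtered;
#'   [filter_classified()] is applied internally).
#' @param cna Gene-level copy-number calls (`sample`, `gene`, `type` with
#'   `type` in `amplification`/`loss`), or `NULL`.
#' @param fusions Fusion tibble ([read_fusion_table()]), or `NULL`; both
#'   partner genes are scored.
#' @param panel Panel tibble (`gene`, `kind`); default [default_gene_panel()].
#' @param samples Character vector of sample columns (default: all samples
#'   seen in the inputs).
#' @param retained_classes Passed to [filter_classified()].
#' @return An integer matrix of class `alteration_matrix` with rownames
#'   `"GENE|kind"` and an attribute `panel`.
#' @export
build_alteration_matrix <- function(variants, cna = NULL, fusions = NULL,
                                    panel = default_gene_panel(),
                                    samples = NULL,
                                    retained_classes = default_config()$retained_classes) {
  if (nrow(panel) == 0) abort("gene panel is empty")
  assert_columns(panel, c("gene", "kind"), "panel")
  v <- filter_classified(variants, retained_classes)
  events <- dplyr::bind_rows(
    tibble(sample = v$sample, gene = v$gene, kind = "snv_indel"),
    if (!is.null(cna) && nrow(cna) > 0)
      tibble(sample = cna$sample, gene = cna$gene, kind = cna$type),
    if (!is.null(fusions) && nrow(fusions) > 0)
      tibble(sample = rep(fusions$sample, 2),
             gene = c(fusions$gene_5prime, fusions$gene_3prime),
             kind = "fusion")
  )
  samples <- samples %||% sort(unique(c(events$sample, variants$sample)))
  rows <- paste(panel$gene, panel$kind, sep = "|")
  m <- matrix(0L, nrow = nrow(panel), ncol = length(samples),
              dimnames = list(rows, samples))
  if (!is.null(events) && nrow(events) > 0) {
    hit <- events |>
      mutate(row = paste(.data$gene, .data$kind, sep = "|")) |>
      filter(.data$row %in% rows, .data$sample %in% samples) |>
      distinct(.data$row, .data$sample)
    m[cbind(match(hit$row, rows), match(hit$sample, samples))] <- 1L
  }
  structure(m, panel = panel, class = c("alteration_matrix", class(m)))
}

#' Per-gene alteration frequencies from an alteration matrix
#' @param mat An `alteration_matrix`.
#' @return Tibble with `gene`, `kind`, `n_altered`, `n_samples`, `frequency`,
#'   `percent` (one decimal).
#' @export
alteration_frequencies <- function(mat) {
  parts <- stringr::str_split_fixed(rownames(mat), stringr::fixed("|"), 2)
  tibble(
    gene = parts[, 1],
    kind = parts[, 2],
    n_altered = as.integer(rowSums(mat)),
    n_samples = ncol(mat)
  ) |>
    mutate(frequency = .data$n_altered / .data$n_samples,
           percent = percent_of(.data$n_altered, .data$n_samples))
}

#' Tumor mutational burden per sample
#'
#' Counts retained somatic SNVs and indels per sample and divides by the
#' interrogated footprint in megabases. The high-TMB call uses a strict
#' inequality (`tmb > threshold`).
#'
#' @param variants Somatic variant tibble; [filter_classified()] is applied.
#' @param denominator_mb Interrogated genome size in megabases (default 38,
#'   a conventional exome footprint).
#' @param threshold High-TMB threshold in mutations/Mb (default 10, strict).
#' @param samples Optional sample vector so that samples without retained
#'   variants appear with TMB 0.
#' @param retained_classes Passed to [filter_classified()].
#' @return Tibble: `sample`, `mutation_count`, `denominator_mb`, `tmb`, `high`.
#' @export
#' @examples
#' v <- tibble::tibble(sample = rep("S1", 38), gene = "TP53",
#'                     classification = "Missense_Mutation")
#' compute_tmb(v, denominator_mb = 38)
compute_tmb <- function(variants, denominator_mb = 38, threshold = 10,
                        samples = NULL,
                        retained_classes = default_config()$retained_classes) {
  if (denominator_mb <= 0) abort("TMB denominator must be positive")
  v <- filter_classified(variants, retained_classes)
  counts <- v |> count(.data$sample, name = "mutation_count")
  samples <- samples %||% sort(unique(variants$sample))
  tibble(sample = samples) |>
    left_join(counts, by = "sample") |>
    mutate(
      mutation_count = as.integer(dplyr::coalesce(.data$mutation_count, 0L)),
      denominator_mb = denominator_mb,
      tmb = .data$mutation_count / denominator_mb,
      high = .data$tmb > threshold
    )
}

#' Cohort flow accounting (CONSORT-style)
#'
#' Given an ordered set of study stages with their member identifiers,
#' emits counts and percentages for each declared numerator/denominator
#' stage pair. By default consecutive stages are paired; explicit pairs can
#' be supplied. Percentages are rounded half-away-from-zero to one decimal.
#'
#' @param flow Named list of member-identifier vectors, in stage order, or a
#'   data frame with columns `stage` and `member` (stage order of appearance).
#' @param pairs Optional two-column data frame (`numerator`, `denominator`)
#'   of stage labels; default pairs each stage with the one before it.
#' @return Tibble: `numerator_stage`, `denominator_stage`, `n`, `denominator`,
#'   `percent`.
#' @export
#' @examples
#' cohort_accounting(list(profiled = 1:115, treated = 1:23))
cohort_accounting <- function(flow, pairs = NULL) {
  if (is.data.frame(flow)) {
    assert_columns(flow, c("stage", "member"), "flow")
    flow <- split(flow$member, factor(flow$stage, levels = unique(flow$stage)))
  }
  if (length(flow) < 2 && is.null(pairs)) {
    abort("flow must declare at least two stages")
  }
  if (is.null(pairs)) {
    pairs <- tibble(numerator = names(flow)[-1],
                    denominator = names(flow)[-length(flow)])
  }
  purrr::pmap_dfr(pairs, function(numerator, denominator) {
    num <- flow[[numerator]]
    den <- flow[[denominator]]
    if (is.null(num) || is.null(den)) abort("pair references undeclared stage")
    if (!all(num %in% den)) {
      abort(sprintf("stage '%s' is not a subset of stage '%s'",
                    numerator, denominator))
    }
    tibble(numerator_stage = numerator, denominator_stage = denominator,
           n = length(unique(num)), denominator = length(unique(den)),
           percent = percent_of(length(unique(num)), length(unique(den))))
  })
}

#' Default actionability rule table
#'
#' Best-effort mapping from `(gene, kind)` to treatment basket (TK tyrosine
#' kinases, DDR DNA damage repair, CC cell cycle, IE immune evasion, OTH
#' other) and NCT/DKTK evidence level (m1A strongest ... m4). Editable; pass
#' your own table to [map_actionability()].
#'
#' @return Tibble: `gene`, `kind`, `basket`, `evidence_level`.
#' @export
default_actionability_rules <- function() {
  tribble_rows <- list(
    c("FGFR2", "fusion", "TK", "m1A"),
    c("IDH1", "snv_indel", "TK", "m1A"),
    c("ERBB2", "amplification", "TK", "m1B"),
    c("BRAF", "snv_indel", "TK", "m1C"),
    c("MET", "fusion", "TK", "m2B"),
    c("MET", "amplification", "TK", "m2B"),
    c("BRCA1", "snv_indel", "DDR", "m2A"),
    c("BRCA2", "snv_indel", "DDR", "m2A"),
    c("PALB2", "snv_indel", "DDR", "m2B"),
    c("RAD51C", "snv_indel", "DDR", "m2B"),
    c("BAP1", "snv_indel", "DDR", "m3"),
    c("CDKN2A", "loss", "CC", "m2C"),
    c("CDKN2B", "loss", "CC", "m2C"),
    c("MTAP", "loss", "CC", "m3"),
    c("KRAS", "snv_indel", "OTH", "m3"),
    c("TP53", "snv_indel", "OTH", "m4")
  )
  out <- do.call(rbind, tribble_rows)
  tibble(gene = out[, 1], kind = out[, 2], basket = out[, 3],
         evidence_level = out[, 4])
}

#' Map alterations to treatment baskets and evidence levels
#'
#' Deterministic lookup of `(gene, kind)` in a rule table; unmapped
#' alterations fall back to basket `OTH` with evidence level `unassigned`
#' (warned once with a count).
#'
#' @param alterations Tibble with columns `gene`, `kind` (other columns pass
#'   through).
#' @param rules Rule table (`gene`, `kind`, `basket`, `evidence_level`);
#'   default [default_actionability_rules()].
#' @return `alterations` with `basket` and `evidence_level` columns added.
#' @export
map_actionability <- function(alterations, rules = default_actionability_rules()) {
  if (is.null(rules) || nrow(rules) == 0) abort("actionability rule table is empty")
  assert_columns(rules, c("gene", "kind", "basket", "evidence_level"), "rules")
  assert_columns(alterations, c("gene", "kind"), "alterations")
  out <- left_join(alterations, rules, by = c("gene", "kind"))
  n_un <- sum(is.na(out$basket))
  if (n_un > 0) {
    log_msg("WARN", sprintf("%d alteration(s) not covered by the rule table; assigned OTH/unassigned", n_un))
  }
  out |>
    mutate(basket = dplyr::coalesce(.data$basket, "OTH"),
           evidence_level = dplyr::coalesce(.data$evidence_level, "unassigned"))
}
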