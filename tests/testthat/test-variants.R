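test_that("non-synonymous filtering keeps the maftools classes and is idempotent", {
  v <- variants_tbl(
    sample = "S1",
    gene = c("TP53", "TP53", "KRAS", "BRAF", "X1", "X2"),
    classification = c("Missense_Mutation", "Silent", "Frame_Shift_Del",
                       "Splice_Site", "3'UTR", "Intron")
  )
  kept <- filter_classified(v)
  expect_setequal(kept$classification,
                  c("Missense_Mutation", "Frame_Shift_Del", "Splice_Site"))
  expect_equal(filter_classified(kept), kept)
  expect_equal(nrow(filter_classified(v[0, ])), 0)

  # config can override the retained set entirely
  only_silent <- filter_classified(v, retained_classes = "Silent")
  expect_equal(only_silent$classification, "Silent")
})

test_that("alteration matrix separates alteration kinds and keeps zero columns", {
  panel <- tibble::tibble(gene = c("TP53", "FGFR2", "FGFR2"),
                          kind = c("snv_indel", "snv_indel", "fusion"))
  v <- variants_tbl("S1", c("TP53", "FGFR2"),
                    c("Missense_Mutation", "Missense_Mutation"))
  fus <- tibble::tibble(sample = "S1", gene_5prime = "AHCYL1",
                        gene_3prime = "FGFR2", exon_5prime = 5L,
                        exon_3prime = 17L, predicted_effect = "activating")
  m <- build_alteration_matrix(v, fusions = fus, panel = panel,
                               samples = c("S1", "S2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m["FGFR2|fusion", "S1"]), 1L)
  expect_equal(unname(m["FGFR2|snv_indel", "S1"]), 1L)
  expect_equal(unname(sum(m[, "S2"])), 0L)
  expect_error(build_alteration_matrix(v, panel = panel[0, ]), "empty")
})

test_that("TMB uses a strict >10 threshold and is linear in the count", {
  v38 <- variants_tbl("S1", rep("G", 38), rep("Missense_Mutation", 38))
  t38 <- compute_tmb(v38, denominator_mb = 38)
  expect_equal(t38$tmb, 1.0)
  expect_false(t38$high)

  v401 <- variants_tbl("S1", rep("G", 401), rep("Missense_Mutation", 401))
  t401 <- compute_tmb(v401, denominator_mb = 40)
  expect_equal(t401$tmb, 10.025)
  expect_true(t401$high)

  # exactly at the threshold is not high (strict inequality)
  v400 <- variants_tbl("S1", rep("G", 400), rep("Missense_Mutation", 400))
  expect_false(compute_tmb(v400, denominator_mb = 40)$high)

  t0 <- compute_tmb(v38[0, ], samples = "S1")
  expect_equal(t0$tmb, 0)

  expect_equal(compute_tmb(dplyr::bind_rows(v38, v38), denominator_mb = 38)$tmb,
               2 * t38$tmb)
  expect_error(compute_tmb(v38, denominator_mb = 0), "positive")
})

test_that("cohort accounting reproduces printed percentages", {
  acc <- cohort_accounting(list(profiled = 1:115, discussed = 1:109,
                                treated = 1:23))
  expect_equal(acc$percent, c(94.8, 21.1))
  direct <- cohort_accounting(list(profiled = 1:115, treated = 1:23),
                              pairs = tibble::tibble(numerator = "treated",
                                                     denominator = "profiled"))
  expect_equal(direct$percent, 20.0)
  same <- cohort_accounting(list(a = 1:10, b = 1:10))
  expect_equal(same$percent, 100.0)
  expect_error(cohort_accounting(list(a = 1:5, b = 6:7)), "subset")
})

test_that("actionability mapping is a deterministic lookup with OTH fallback", {
  alt <- tibble::tibble(gene = c("FGFR2", "NOVEL1"),
                        kind = c("fusion", "snv_indel"))
  mapped <- suppressMessages(map_actionability(alt))
  expect_equal(mapped$basket, c("TK", "OTH"))
  expect_equal(mapped$evidence_level[2], "unassigned")
  expect_error(map_actionability(alt, rules = tibble::tibble()), "empty")
})

test_that("alteration frequencies on a large synthetic cohort match generator
           parameters within three binomial standard errors", {
  n <- 4000
  co <- generate_cohort(cohort_params(n_patients = n, seed = 21))
  m <- suppressMessages(
    build_alteration_matrix(co$somatic_variants, cna = co$cna,
                            fusions = co$fusions,
                            samples = co$samples$sample))
  f <- alteration_frequencies(m)
  p <- attr(co, "params")
  checks <- list(c("TP53", "snv_indel", p$snv_probs[["TP53"]]),
                 c("ARID1A", "snv_indel", p$snv_probs[["ARID1A"]]),
                 c("FGFR2", "fusion", p$fusion_probs[["FGFR2"]]),
                 c("ERBB2", "amplification", p$amp_probs[["ERBB2"]]))
  for (ck in checks) {
    truth <- as.numeric(ck[3])
    obs <- f$frequency[f$gene == ck[1] & f$kind == ck[2]]
    se <- sqrt(truth * (1 - truth) / n)
    expect_lt(abs(obs - truth), 3 * se)
  }
})
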