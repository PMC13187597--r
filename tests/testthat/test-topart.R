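make_sig3_call <- function(sample, call) {
  tibble::tibble(sample = sample, exposure = ifelse(call == "absent", 0, 50),
                 fraction = ifelse(call == "absent", 0, 0.5),
                 call = factor(call, levels = c("absent", "present",
                                                "present_high_confidence")))
}

test_that("HRR impairment scoring follows the category weight table with caps", {
  none <- score_hrr_impairment(variants_tbl(character(), character(),
                                            character(), origin = "germline"),
                               variants_tbl(character(), character(),
                                            character()),
                               samples = "S1")
  expect_equal(none$impairment_score, 0)

  g_brca <- variants_tbl("S1", "BRCA1", "Nonsense_Mutation",
                         origin = "germline", pathogenic = TRUE)
  r <- score_hrr_impairment(g_brca, variants_tbl(character(), character(),
                                                 character()))
  expect_equal(r$germline_points, 2)

  # bi-allelic somatic lesion in an associated gene scores 1
  s_bap1 <- variants_tbl("S1", "BAP1", "Missense_Mutation",
                         copy_context = "all_copies")
  r2 <- score_hrr_impairment(g_brca[0, ], s_bap1)
  expect_equal(r2$somatic_points, 1)

  # mono-allelic somatic lesions score 0 but are recorded
  s_mono <- variants_tbl("S1", "RAD51C", "Missense_Mutation",
                         copy_context = "mono_allelic")
  r3 <- score_hrr_impairment(g_brca[0, ], s_mono)
  expect_equal(r3$somatic_points, 0)
  expect_equal(r3$n_monoallelic_somatic, 1L)

  # caps: two germline core lesions still cap at 2
  g2 <- dplyr::bind_rows(g_brca,
                         variants_tbl("S1", "BRCA2", "Frame_Shift_Del",
                                      origin = "germline", pathogenic = TRUE))
  expect_equal(score_hrr_impairment(g2, s_mono)$germline_points, 2)

  # non-panel genes are ignored with a warning
  off <- variants_tbl("S1", "NOTAGENE", "Missense_Mutation",
                      copy_context = "all_copies")
  expect_message(r4 <- score_hrr_impairment(g_brca[0, ], off), "non-panel")
  expect_equal(r4$somatic_points, 0)

  # germline lesions lacking the pathogenic flag do not score
  g_vus <- variants_tbl("S1", "BRCA1", "Missense_Mutation",
                        origin = "germline", pathogenic = NA)
  expect_equal(score_hrr_impairment(g_vus, s_mono)$germline_points, 0)
})

test_that("genomic pattern scoring grants instability and signature-3 points", {
  scars <- tibble::tibble(sample = c("A", "B", "C"),
                          hrd_loh = c(0L, 12L, 3L), lst = c(0L, 20L, 4L))
  sig3 <- dplyr::bind_rows(make_sig3_call("A", "absent"),
                           make_sig3_call("B", "present_high_confidence"),
                           make_sig3_call("C", "present_high_confidence"))
  p <- score_genomic_pattern(scars, sig3)
  expect_equal(p$instability_points, c(0L, 2L, 0L))
  expect_equal(p$sig3_points, c(0L, 1L, 1L))
  expect_equal(p$patterns_detected, c(FALSE, TRUE, TRUE))

  # one scar above threshold gives a single instability point
  one <- score_genomic_pattern(tibble::tibble(sample = "D", hrd_loh = 11L,
                                              lst = 3L),
                               make_sig3_call("D", "absent"))
  expect_equal(one$instability_points, 1L)

  # under the high-confidence rule a plain presence earns no point
  cfg <- default_config(); cfg$sig3_rule <- "high_confidence"
  hc <- score_genomic_pattern(tibble::tibble(sample = "E", hrd_loh = 0L,
                                             lst = 0L),
                              make_sig3_call("E", "present"), cfg)
  expect_equal(hc$sig3_points, 0L)
})

test_that("the positivity rule is the conjunction of total >= 3 and detected
           patterns, over the full sub-score grid up to the maximum of 7", {
  grid <- tidyr::expand_grid(g = 0:2, s = 0:2, inst = 0:2, m3 = 0:1)
  for (k in seq_len(nrow(grid))) {
    row <- grid[k, ]
    imp <- tibble::tibble(sample = "S", germline_points = row$g,
                          somatic_points = row$s,
                          impairment_score = row$g + row$s,
                          n_monoallelic_somatic = 0L)
    pat <- tibble::tibble(sample = "S", instability_points = row$inst,
                          sig3_points = row$m3,
                          pattern_score = row$inst + row$m3,
                          patterns_detected = (row$inst + row$m3) >= 1)
    out <- compose_topart(imp, pat)
    expect_equal(out$total, row$g + row$s + row$inst + row$m3)
    expect_lte(out$total, 7)
    expect_equal(out$positive,
                 out$total >= 3 && (row$inst + row$m3) >= 1)
  }
})

test_that("positivity is monotone: adding evidence never lowers the score", {
  imp <- tibble::tibble(sample = "S", germline_points = 0, somatic_points = 1,
                        impairment_score = 1, n_monoallelic_somatic = 0L)
  pat <- tibble::tibble(sample = "S", instability_points = 1L, sig3_points = 0L,
                        pattern_score = 1L, patterns_detected = TRUE)
  base <- compose_topart(imp, pat)
  more_g <- compose_topart(dplyr::mutate(imp, germline_points = 2,
                                         impairment_score = 3), pat)
  more_m <- compose_topart(imp, dplyr::mutate(pat, sig3_points = 1L,
                                              pattern_score = 2L))
  expect_gte(more_g$total, base$total)
  expect_gte(more_m$total, base$total)
  expect_true(more_g$positive)
  expect_false(base$positive)  # total 2
})

test_that("cohort positivity rises with the latent HRD prevalence and core
           lesions associate with stronger genomic patterns", {
  cfg <- default_config()
  prevalences <- c(0.1, 0.55, 0.9)
  rates <- vapply(prevalences, function(p) {
    co <- generate_cohort(cohort_params(n_patients = 150, seed = 31, p_hrd = p))
    tp <- suppressMessages(topart_score(co, cfg))
    mean(tp$positive)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))

  co <- generate_cohort(cohort_params(n_patients = 1000, seed = 33))
  tp <- suppressMessages(topart_score(co, cfg))
  lat <- attr(co, "latent")
  core <- default_hrr_panel()$gene[default_hrr_panel()$category == "core"]
  has_core <- lat$germline_gene %in% core | lat$biallelic_gene %in% core
  pat <- tp$pattern_score[match(lat$sample, tp$sample)]
  expect_lt(stats::wilcox.test(pat[has_core], pat[!has_core],
                               alternative = "greater")$p.value, 0.01)
})
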