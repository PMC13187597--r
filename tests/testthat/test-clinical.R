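test_that("Kaplan-Meier equals empirical survival without censoring and the
           hand-computed product limit with ties and censoring", {
  d <- tibble::tibble(t = c(1, 2, 3, 4), e = TRUE)
  km <- km_estimate(d, t, e)
  expect_equal(tidy(km)$estimate, c(0.75, 0.5, 0.25, 0))
  expect_equal(glance(km)$median, 2)  # smallest t with S(t) <= 0.5

  # censor at 1, deaths at 2 (x2) and 3: S(2) = 1 * (1 - 2/3) = 1/3
  d2 <- tibble::tibble(t = c(1, 2, 2, 3), e = c(FALSE, TRUE, TRUE, TRUE))
  km2 <- km_estimate(d2, t, e)
  st <- tidy(km2)
  expect_equal(st$estimate[st$time == 2], 1 / 3, tolerance = 1e-12)
  expect_equal(st$estimate[st$time == 3], 0, tolerance = 1e-12)

  single <- km_estimate(tibble::tibble(t = 5, e = FALSE), t, e)
  expect_true(is.na(glance(single)$median))  # median not reached
  expect_true(all(tidy(single)$estimate == 1))

  expect_equal(km_survival_at(km2, 2.5), 1 / 3)
  expect_equal(km_survival_at(km2, 0.5), 1)
})

test_that("log-rank behaves under symmetry, separation, and rescaling", {
  same <- tibble::tibble(t = rep(c(1, 2, 3, 4), 2), e = TRUE,
                         g = rep(c("a", "b"), each = 4))
  r <- logrank_test(same, t, e, g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  sep <- tibble::tibble(t = c(seq(1, 20), seq(31, 50)), e = TRUE,
                        g = rep(c("early", "late"), each = 20))
  r2 <- logrank_test(sep, t, e, g)
  expect_lt(r2$p_value, 0.01)
  expect_equal(r2$statistic,
               logrank_by_hand(sep$t, as.integer(sep$e), sep$g),
               tolerance = 1e-8)

  # invariant to a common rescaling of time
  r3 <- logrank_test(dplyr::mutate(sep, t = 12 * t), t, e, g)
  expect_equal(r3$statistic, r2$statistic, tolerance = 1e-12)

  expect_error(logrank_test(dplyr::mutate(same, g = "a"), t, e, g),
               "two groups")
})

test_that("response rates follow the RECIST definitions", {
  expect_equal(response_rates(tibble::tibble(best_response = c("PR", "SD", "PD"))),
               tibble::tibble(n = 3L, n_response = 1L, orr = 1 / 3,
                              n_control = 2L, dcr = 2 / 3))
  allcr <- response_rates(tibble::tibble(best_response = rep("CR", 4)))
  expect_equal(allcr$orr, 1); expect_equal(allcr$dcr, 1)

  ten <- tibble::tibble(best_response = c("PR", "PR", "PD", "SD", "NE", "PD",
                                          "PD", "SD", "PR", "CR"))
  r <- response_rates(ten)
  expect_equal(r$orr, 0.4)
  expect_equal(r$dcr, 0.6)
  r_ne <- response_rates(ten, include_ne = FALSE)
  expect_equal(r_ne$n, 9L)
  expect_error(response_rates(ten[0, ]), "no evaluable")
})

test_that("the unsmoothed PFS-ratio survival reduces to the empirical
           exceedance fraction and the KM median of ratios", {
  d <- tibble::tibble(pfs1_months = 1,
                      pfs2_months = c(2.0, 1.0, 0.5, 2.6, 1.4))
  r <- pfs_ratio_analysis(d, delta = 1.3, bandwidth = 0, B = 0)
  expect_equal(r$benefit_rate, 0.6)

  med <- tibble::tibble(pfs1_months = 1,
                        pfs2_months = c(0.5, 1.0, 2.22, 3.0, 4.0))
  g <- glance(pfs_ratio_analysis(med, bandwidth = 0, B = 0))
  expect_equal(g$median_ratio, 2.22)

  # smoothing vanishes as the bandwidth shrinks
  r_small <- pfs_ratio_analysis(d, delta = 1.3, bandwidth = 1e-6, B = 0)
  expect_equal(r_small$benefit_rate, 0.6, tolerance = 1e-9)

  # S(0) = 1 and the curve is non-increasing
  expect_equal(r$curve$survival[r$curve$delta == 0], 1)
  expect_true(all(diff(r$curve$survival) <= 1e-12))
})

test_that("censoring and exclusions are handled per the analysis rules", {
  # all ratios censored above delta: S(delta) = 1
  cens <- tibble::tibble(pfs1_months = 1, pfs2_months = c(2, 3, 4),
                         pfs2_event = FALSE)
  r <- pfs_ratio_analysis(cens, delta = 1.3, bandwidth = 0, B = 0)
  expect_equal(r$benefit_rate, 1)

  # all censored below delta: benefit undefined and flagged
  low <- tibble::tibble(pfs1_months = 1, pfs2_months = c(0.2, 0.5),
                        pfs2_event = FALSE)
  r2 <- pfs_ratio_analysis(low, delta = 1.3, bandwidth = 0, B = 0)
  expect_true(r2$benefit_undefined)
  expect_true(is.na(r2$benefit_rate))

  # missing and zero PFS1 are excluded and counted
  mix <- tibble::tibble(pfs1_months = c(NA, 0, 1, 1, 2),
                        pfs2_months = c(1, 1, 2, 0.5, 5))
  expect_message(r3 <- pfs_ratio_analysis(mix, bandwidth = 0, B = 0),
                 "PFS1 missing for 1")
  expect_equal(r3$n_used, 3)
  expect_equal(r3$n_zero_pfs1, 1)

  # explicitly censored PFS1 is excluded
  c1 <- tibble::tibble(pfs1_months = c(1, 1), pfs1_event = c(FALSE, TRUE),
                       pfs2_months = c(2, 2))
  r4 <- suppressMessages(pfs_ratio_analysis(c1, bandwidth = 0, B = 0))
  expect_equal(r4$n_used, 1)
})

test_that("the smoothed estimator recovers the configured exceedance truth on
           a large uncensored sample", {
  set.seed(23)
  n <- 2000
  meanlog <- log(2.22); sdlog <- 2.113
  truth <- pnorm((meanlog - log(1.3)) / sdlog)  # P(ratio > 1.3) = 0.60
  d <- tibble::tibble(pfs1_months = rexp(n, 1 / 3),
                      ratio = rlnorm(n, meanlog, sdlog)) |>
    dplyr::mutate(pfs2_months = pfs1_months * ratio)
  est <- pfs_ratio_analysis(d, delta = 1.3, B = 0)
  expect_lt(abs(est$benefit_rate - truth), 0.02)
})

test_that("bootstrap intervals achieve near-nominal coverage on uncensored
           samples", {
  set.seed(29)
  truth <- pnorm((log(2.22) - log(1.3)) / 2.113)
  hits <- replicate(200, {
    d <- tibble::tibble(pfs1_months = 1, pfs2_months = rlnorm(60, log(2.22), 2.113))
    r <- pfs_ratio_analysis(d, delta = 1.3, B = 200,
                            seed = sample.int(1e6, 1))
    r$ci_lower <= truth && truth <= r$ci_upper
  })
  cover <- mean(hits)
  expect_gte(cover, 0.92 - 3 * sqrt(0.95 * 0.05 / 200))
  expect_lte(cover, 1)
})

test_that("the guided-therapy summary reports per-stratum outcomes", {
  rec <- tibble::tibble(
    patient = sprintf("P%02d", 1:6),
    pfs1_months = c(2, 2, 4, NA, 3, 2),
    pfs2_months = c(4, 1, 9, 3, 6, 2),
    pfs2_event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    best_response = c("PR", "PD", "SD", "PD", "PR", "PD"),
    received_guided_therapy = TRUE,
    basket = c("TK", "TK", "DDR", "TK", "DDR", "TK"),
    evidence_level = "m2B"
  )
  s <- suppressMessages(guided_therapy_summary(rec))
  expect_equal(s$n[s$stratum == "overall"], 6L)
  expect_setequal(s$level[s$stratum == "basket"], c("TK", "DDR"))
  expect_equal(s$orr[s$stratum == "overall"], 2 / 6)

  one <- tibble::tibble(patient = "P1", pfs1_months = 1, pfs2_months = 2,
                        pfs2_event = TRUE, best_response = "PD",
                        received_guided_therapy = TRUE)
  s1 <- suppressMessages(guided_therapy_summary(one))
  expect_equal(s1$median_pfs2[1], 2)
  expect_equal(s1$orr[1], 0)

  none <- dplyr::mutate(one, received_guided_therapy = FALSE)
  expect_message(s0 <- guided_therapy_summary(none), "no patients")
  expect_equal(nrow(s0), 0)
})
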