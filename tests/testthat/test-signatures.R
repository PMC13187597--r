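test_that("exact mixtures are recovered exactly by the NNLS fit", {
  S <- default_signature_matrix()

  pure <- 100 * S[, "SBS3"]
  e <- fit_exposures(pure, S)
  expect_equal(e$exposure[e$signature == "SBS3"], 100, tolerance = 1e-8)
  expect_equal(sum(e$exposure[e$signature != "SBS3"]), 0, tolerance = 1e-8)
  expect_lt(e$residual_norm[1], 1e-8)

  mix <- 600 * S[, "SBS1"] + 400 * S[, "SBS5"]
  e2 <- fit_exposures(mix, S)
  expect_equal(e2$exposure[e2$signature == "SBS1"], 600, tolerance = 1e-6)
  expect_equal(e2$exposure[e2$signature == "SBS5"], 400, tolerance = 1e-6)

  zero <- fit_exposures(rep(0, 96), S)
  expect_true(all(zero$exposure == 0))
})

test_that("the support-enumeration solver agrees with Lawson-Hanson NNLS", {
  S <- default_signature_matrix()
  set.seed(31)
  for (i in 1:25) {
    y <- rpois(96, runif(1, 0.2, 8))
    mine <- topartr:::nnls_fit(y, S)
    ref <- pracma::lsqnonneg(S, as.numeric(y))
    expect_equal(unname(mine$exposure), as.numeric(ref$x), tolerance = 1e-6)
  }
})

test_that("fitted exposures are locally optimal and scale equivariant", {
  S <- default_signature_matrix()
  set.seed(8)
  y <- as.numeric(rmultinom(1, 500, S %*% c(0.4, 0.3, 0.3, 0, 0)))
  fit <- topartr:::nnls_fit(y, S)
  res0 <- sqrt(sum((y - S %*% fit$exposure)^2))
  eps <- 1e-4
  for (k in seq_len(ncol(S))) {
    for (sgn in c(-1, 1)) {
      x <- fit$exposure
      x[k] <- max(0, x[k] + sgn * eps)
      res <- sqrt(sum((y - S %*% x)^2))
      expect_gte(res, res0 - 1e-10)
    }
  }
  fit10 <- topartr:::nnls_fit(10 * y, S)
  expect_equal(unname(fit10$exposure), unname(10 * fit$exposure),
               tolerance = 1e-6)
})

test_that("exposure fractions are recovered on synthetic catalogs", {
  S <- default_signature_matrix()
  set.seed(12)
  n_mut <- 5000
  errs <- replicate(100, {
    w <- c(runif(3), 0, 0); w <- w / sum(w)
    y <- as.numeric(rmultinom(1, n_mut, S %*% w))
    e <- topartr:::nnls_fit(y, S)$exposure
    mean(abs(e / sum(e) - w))
  })
  expect_lt(mean(errs), 0.02)
})

test_that("bootstrap confidence calls follow the CI-excludes-zero rule", {
  S <- default_signature_matrix()
  pure3 <- as.numeric(round(1000 * S[, "SBS3"]))
  b <- bootstrap_exposures(pure3, S, B = 200, seed = 4)
  expect_true(b$high_confidence[b$signature == "SBS3"])
  expect_true(all(b$ci_lower <= b$exposure + 1e-9))
  expect_true(all(b$ci_upper >= b$exposure - 1e-9))

  zero <- bootstrap_exposures(rep(0, 96), S, B = 200, seed = 4)
  expect_true(all(!zero$high_confidence))
  expect_true(all(zero$ci_lower == 0 & zero$ci_upper == 0))

  # deterministic given the seed
  b2 <- bootstrap_exposures(pure3, S, B = 200, seed = 4)
  expect_equal(b, b2)
  expect_error(bootstrap_exposures(pure3, S, B = 10), "at least 100")
})

test_that("a large SBS1-only catalog rarely earns a high-confidence SBS3 flag", {
  S <- default_signature_matrix()
  set.seed(2)
  flags <- vapply(1:20, function(i) {
    y <- as.numeric(rmultinom(1, 2000, S[, "SBS1"]))
    b <- bootstrap_exposures(y, S, B = 200, seed = 100 + i)
    b$high_confidence[b$signature == "SBS3"]
  }, logical(1))
  expect_gte(mean(!flags), 0.9)
})

test_that("signature-3 calls apply the presence and confidence rules", {
  ex <- tibble::tibble(
    sample = c("A", "B", "C"),
    signature = "SBS3",
    exposure = c(0, 120, 15),
    residual_norm = 0,
    ci_lower = c(0, 30, 0), ci_upper = c(0, 210, 60),
    high_confidence = c(FALSE, TRUE, FALSE)
  )
  calls <- detect_sig3(ex)
  expect_equal(as.character(calls$call),
               c("absent", "present_high_confidence", "present"))
  expect_error(detect_sig3(dplyr::mutate(ex, signature = "SBS1")), "SBS3")

  # the relative-exposure floor reclassifies small exposures as absent
  multi <- dplyr::bind_rows(
    tibble::tibble(sample = "D", signature = c("SBS1", "SBS3"),
                   exposure = c(95, 5), residual_norm = 0),
    tibble::tibble(sample = "E", signature = c("SBS1", "SBS3"),
                   exposure = c(50, 50), residual_norm = 0))
  floored <- detect_sig3(multi, min_fraction = 0.10)
  expect_equal(as.character(floored$call), c("absent", "present"))
})

test_that("signature matrices round-trip through TSV", {
  S <- default_signature_matrix()
  p <- tempfile(fileext = ".tsv")
  write_signature_matrix(S, p)
  S2 <- read_signature_matrix(p)
  expect_equal(S2, S, tolerance = 1e-12)
})
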