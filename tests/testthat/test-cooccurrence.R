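test_that("the exact Poisson-binomial pmf matches closed forms and exhaustive
           enumeration", {
  expect_equal(dpoisbinom(c(0.5, 0.5)), c(0.25, 0.5, 0.25))

  # equal probabilities reduce to the binomial
  p <- 0.3; n <- 25
  expect_equal(dpoisbinom(rep(p, n)), dbinom(0:n, n, p), tolerance = 1e-12)

  # brute-force enumeration over all 2^12 outcomes
  set.seed(14)
  probs <- runif(12)
  expect_equal(dpoisbinom(probs), poisbinom_enum(probs), tolerance = 1e-12)

  pmf <- dpoisbinom(runif(40))
  expect_equal(sum(pmf), 1, tolerance = 1e-9)
  expect_error(dpoisbinom(c(0.5, 1.2)), "0, 1")
})

test_that("pmf mean equals the sum of probabilities", {
  set.seed(15)
  for (i in 1:5) {
    probs <- runif(sample(3:60, 1))
    pmf <- dpoisbinom(probs)
    expect_equal(sum(pmf * seq(0, length(probs))), sum(probs),
                 tolerance = 1e-9)
  }
})

test_that("the shifted-binomial approximation tracks exact tail probabilities", {
  set.seed(16)
  for (i in 1:25) {
    probs <- runif(1000, 0.01, 0.6)
    k <- sample(floor(sum(probs) * c(0.7, 1, 1.3)), 1)
    exact_lo <- ppoisbinom(k, probs, lower_tail = TRUE, exact_limit = 2000)
    appr_lo <- topartr:::shifted_binomial_tail(k, probs, lower_tail = TRUE)
    exact_hi <- ppoisbinom(k, probs, lower_tail = FALSE, exact_limit = 2000)
    appr_hi <- topartr:::shifted_binomial_tail(k, probs, lower_tail = FALSE)
    expect_lt(abs(exact_lo - appr_lo), 1e-3)
    expect_lt(abs(exact_hi - appr_hi), 1e-3)
  }
})

test_that("the background model reproduces both marginals", {
  # homogeneous samples: probabilities collapse to gene frequencies
  m <- matrix(rep(c(1, 1, 0, 0, 0), 4), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  m[3:4, ] <- 0; m[3, 1:2] <- 1; m[4, 1:2] <- 1
  bg <- estimate_background(m)
  expect_equal(rowSums(bg), rowSums(m), tolerance = 1e-6)
  expect_equal(colSums(bg), colSums(m), tolerance = 1e-6)

  # 1 x n matrix: uniform probability k/n
  one <- matrix(c(1, 1, 1, 0, 0, 0), nrow = 1,
                dimnames = list("g", paste0("s", 1:6)))
  bg1 <- estimate_background(one)
  expect_equal(as.numeric(bg1), rep(0.5, 6), tolerance = 1e-6)

  # heterogeneous loads
  set.seed(17)
  het <- matrix(rbinom(20 * 30, 1, runif(20 * 30, 0.05, 0.6)), nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
  bg2 <- estimate_background(het)
  expect_lt(max(abs(rowSums(bg2) - rowSums(het))), 1e-6)
  expect_lt(max(abs(colSums(bg2) - colSums(het))), 1e-6)
  expect_true(all(bg2 > 0 & bg2 < 1))

  expect_error(estimate_background(matrix(c(0, 2), 1)), "binary")
})

test_that("pair tests match an exhaustive independent-Bernoulli oracle", {
  # joint enumeration over both genes' alteration vectors under the fitted
  # background: the exact null distribution of the overlap
  overlap_null_enum <- function(pa, pb, obs) {
    n <- length(pa)
    p_ge <- 0; p_le <- 0; e <- sum(pa * pb)
    for (ma in 0:(2^n - 1)) {
      A <- as.integer(intToBits(ma))[seq_len(n)]
      prA <- prod(ifelse(A == 1, pa, 1 - pa))
      for (mb in 0:(2^n - 1)) {
        B <- as.integer(intToBits(mb))[seq_len(n)]
        prB <- prod(ifelse(B == 1, pb, 1 - pb))
        ov <- sum(A & B)
        if (ov >= obs) p_ge <- p_ge + prA * prB
        if (ov <= obs) p_le <- p_le + prA * prB
      }
    }
    list(p_co = p_ge, p_ex = p_le, expected = e)
  }

  set.seed(18)
  m <- matrix(0L, nrow = 4, ncol = 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  m[1, 1:3] <- 1L; m[2, 4:6] <- 1L         # disjoint pair
  m[3, 1:4] <- 1L; m[4, c(1, 2, 3, 4, 5)] <- 1L  # nested pair
  bg <- estimate_background(m)

  for (pair in list(c("g1", "g2"), c("g3", "g4"))) {
    res <- test_pair(pair[1], pair[2], m, bg)
    oracle <- overlap_null_enum(bg[pair[1], ], bg[pair[2], ],
                                res$observed_overlap)
    expect_equal(res$p_cooccurrence, oracle$p_co, tolerance = 1e-10)
    expect_equal(res$p_exclusivity, oracle$p_ex, tolerance = 1e-10)
    expect_equal(res$expected_overlap, oracle$expected, tolerance = 1e-10)
  }

  # disjoint genes: exclusivity p equals P(X <= 0) = P(X = 0) under the null
  r12 <- test_pair("g1", "g2", m, bg)
  expect_equal(r12$observed_overlap, 0L)
  q <- bg["g1", ] * bg["g2", ]
  expect_equal(r12$p_exclusivity, dpoisbinom(q)[1], tolerance = 1e-10)

  # degenerate self-pair keeps the probability contract
  self <- test_pair("g3", "g3", m, bg)
  expect_equal(self$observed_overlap, 4L)
  expect_lte(self$p_cooccurrence, 1)
  expect_gte(self$p_cooccurrence, 0)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.9)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("the cohort-wide screen enforces the three-sample marginal floor", {
  m <- matrix(0L, nrow = 3, ncol = 10,
              dimnames = list(c("common1", "common2", "rare"), paste0("s", 1:10)))
  m[1, 1:5] <- 1L; m[2, 3:8] <- 1L; m[3, 1:2] <- 1L
  res <- suppressMessages(cooccurrence_test(m, min_samples = 3))
  expect_equal(attr(res, "skipped"), "rare")
  expect_equal(nrow(res), 1)
  expect_true(all(c("q_cooccurrence", "q_exclusivity") %in% names(res)))
})
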