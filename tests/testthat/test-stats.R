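test_that("the published power calculation is reproduced", {
  ## 30% difference on a reference mean 3829 (SD 1106), 80% power,
  ## two-sided alpha 0.05 -> 16 per group
  expect_identical(sampleSizeTwoSample(3829, 1106, 0.30, 0.80, 0.05), 16L)
  ## the stock noncentral-t solver agrees after rounding up
  expect_identical(
    ceiling(stats::power.t.test(delta = 0.30 * 3829, sd = 1106,
                                power = 0.80, sig.level = 0.05)$n),
    16)
})

test_that("sample size is monotone in its inputs", {
  base <- sampleSizeTwoSample(3829, 1106, 0.30, 0.80, 0.05)
  expect_lt(sampleSizeTwoSample(3829, 1106, 0.60, 0.80, 0.05), base)
  expect_lte(sampleSizeTwoSample(5000, 1106, 0.30, 0.80, 0.05), base)
  expect_gte(sampleSizeTwoSample(3829, 1500, 0.30, 0.80, 0.05), base)
  expect_gte(sampleSizeTwoSample(3829, 1106, 0.30, 0.90, 0.05), base)
  expect_error(sampleSizeTwoSample(3829, 1106, 1e-5, 0.80, 0.05), "exceeds")
})

test_that("sample size matches a Monte-Carlo power sweep to +/- 1", {
  nImpl <- sampleSizeTwoSample(100, 10, 0.30, 0.80, 0.05)  # d = 3
  mcPower <- function(n, d, reps = 50000) {
    x <- matrix(rnorm(reps * n, d, 1), reps)
    y <- matrix(rnorm(reps * n, 0, 1), reps)
    mx <- rowMeans(x); my <- rowMeans(y)
    sp <- sqrt((rowSums((x - mx)^2) + rowSums((y - my)^2)) / (2 * n - 2))
    tstat <- (mx - my) / (sp * sqrt(2 / n))
    mean(abs(tstat) > qt(0.975, 2 * n - 2))
  }
  set.seed(42)
  pows <- vapply(2:8, function(n) mcPower(n, 3), 0)
  nMc <- (2:8)[which(pows >= 0.80)[1]]
  expect_lte(abs(nImpl - nMc), 1)
  expect_identical(nImpl, 4L)
})

test_that("Spearman rho hits the exact extremes and rejects constants", {
  expect_equal(spearmanRank(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearmanRank(1:8, -(1:8))$rho, -1)
  expect_error(spearmanRank(1:5, rep(2, 5)), "constant")
  expect_error(spearmanRank(1:2, 2:1), "at least 3")
})

test_that("exact permutation p matches brute-force enumeration and cor.test", {
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8)
  res <- spearmanRank(x, y)
  expect_identical(res$method, "exact permutation")
  expect_equal(res$p.value, bruteSpearmanP(x, y))
  ## cor.test's exact Spearman p as an independent library cross-check
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-12)
})

test_that("rank correlation is invariant under monotone transforms", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- spearmanRank(x, y)
  expect_equal(spearmanRank(exp(x), y)$rho, r0$rho)
  expect_equal(spearmanRank(x, y^3 + 5 * y)$rho, r0$rho)
  expect_equal(spearmanRank(rank(x), y)$p.value, r0$p.value)
})

test_that("t approximation tracks the exact p within 0.05 for n of 6 to 9", {
  ## representatives spanning the whole rho range; at n = 5 the t
  ## approximation deviates by up to 0.077 (verified by enumeration), so
  ## the 0.05 agreement band genuinely starts at n = 6
  for (n in 6:9) {
    base <- seq_len(n)
    P <- brutePerms(n)
    rhos <- apply(P, 1, function(p) cor(base, p))
    picks <- P[order(rhos)[round(seq(1, nrow(P), length.out = 9))], ,
               drop = FALSE]
    for (j in seq_len(nrow(picks))) {
      y <- as.numeric(picks[j, ])
      pe <- spearmanRank(base, y, method = "exact")$p.value
      pa <- spearmanRank(base, y, method = "approx")$p.value
      expect_lt(abs(pe - pa), 0.05)
    }
  }
})

test_that("mid-ranks make the correlation tie-aware", {
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6)
  res <- spearmanRank(x, y, method = "approx")
  expect_equal(res$rho, cor(rank(x), rank(y)))
  expect_equal(res$rho,
               suppressWarnings(cor.test(x, y, method = "spearman")$estimate),
               ignore_attr = TRUE)
})
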