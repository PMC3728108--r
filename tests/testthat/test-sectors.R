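
test_that("entropy closed forms match hand-evaluated values", {
  expect_equal(binaryRelativeEntropy(0.05, 0.05), 0)
  expect_equal(binaryRelativeEntropy(1, 0.05), log(20), tolerance = 1e-12)
  expect_equal(binaryRelativeEntropy(0.5, 0.05),
               0.5 * log(0.5 / 0.05) + 0.5 * log(0.5 / 0.95),
               tolerance = 1e-12)

  m <- workedAlignment()
  bg <- sectorBackground(m)
  expect_equal(bg$q[1], 0.05)
  expect_equal(bg$f[1], 0.5)
  expect_equal(siteEntropy(m, 1), 0.5 * log(10) + 0.5 * log(0.5 / 0.95),
               tolerance = 1e-12)

  # perfectly correlated pair: f_S = 0.5, q_S = 0.0025
  expect_equal(groupEntropy(m, c(1, 2)),
               0.5 * log(0.5 / 0.0025) + 0.5 * log(0.5 / 0.9975),
               tolerance = 1e-12)
  expect_equal(correlationEntropy(m, c(1, 2)),
               groupEntropy(m, c(1, 2)) - 2 * siteEntropy(m, 1),
               tolerance = 1e-12)

  # joint pattern absent: first term vanishes by the 0 ln 0 convention
  anti <- workedAlignment(overlap = 11:20)
  expect_equal(groupEntropy(anti, c(1, 2)), log(1 / 0.9975),
               tolerance = 1e-12)

  # correlated columns exceed margin-preserving shuffles in I_S
  half <- workedAlignment(overlap = 6:15)
  expect_gt(correlationEntropy(m, c(1, 2)),
            correlationEntropy(half, c(1, 2)))
})

test_that("group entropy reduces exactly to site entropy for singletons", {
  set.seed(33)
  m <- matrix(sample(c("A", "C", "D", "E", "-"), 40 * 60, replace = TRUE,
                     prob = c(0.3, 0.3, 0.2, 0.15, 0.05)), 40, 60)
  rownames(m) <- paste0("s", 1:40)
  bg <- sectorBackground(m)
  for (j in sample(60, 20))
    expect_identical(groupEntropy(m, j, bg), siteEntropy(m, j, background = bg))
  # and I_S of a singleton is exactly zero
  for (j in sample(60, 5))
    expect_identical(correlationEntropy(m, j, bg), 0)
  # D_i >= 0 everywhere
  expect_true(all(bg$Di >= 0, na.rm = TRUE))
})

test_that("destroying covariation by within-column shuffles lowers I_S", {
  tr <- simulateTree(25, 0.4, seed = 61)
  pl <- data.frame(site_i = c(1L, 3L), site_j = c(2L, 4L), rho = 1)
  m <- alignmentMatrix(evolveAlignment(tr, 30, planted = pl, seed = 62)$alignment)
  obs <- correlationEntropy(m, 1:4)
  set.seed(63)
  perm <- replicate(60, {
    mp <- m
    for (j in 1:4) mp[, j] <- sample(mp[, j])
    correlationEntropy(mp, 1:4)
  })
  expect_gt(obs, stats::quantile(perm, 0.9))
})

test_that("independence summaries give the normal-test z and p", {
  null <- as.numeric(scale(stats::rnorm(500)))  # exactly mean 0, sd 1
  atMean <- CoevNet:::independenceSummary(0, null)
  expect_equal(atMean$z, 0)
  expect_equal(atMean$p, 1)
  expect_true(atMean$independent)

  shifted <- CoevNet:::independenceSummary(2.5, null)
  expect_equal(shifted$z, 2.5, tolerance = 1e-12)
  expect_equal(shifted$p, 2 * stats::pnorm(-2.5), tolerance = 1e-12)
  expect_false(shifted$independent)

  expect_error(CoevNet:::independenceSummary(1, rep(0.3, 100)), "degenerate")
})

test_that("the independence test is symmetric and validates its inputs", {
  tr <- simulateTree(20, 0.4, seed = 64)
  m <- alignmentMatrix(evolveAlignment(tr, 50, seed = 65)$alignment)
  g1 <- c(2L, 5L, 9L); g2 <- c(11L, 20L, 33L)
  r12 <- independenceTest(m, g1, g2, pool = 1:50, nRandom = 150, seed = 66)
  r21 <- independenceTest(m, g2, g1, pool = 1:50, nRandom = 150, seed = 66)
  expect_equal(r12$theta, r21$theta)
  expect_equal(r12$p, r21$p)  # equal sizes: identical null draws
  expect_true(r12$p >= 0 && r12$p <= 1)

  expect_error(independenceTest(m, g1, g2, pool = 1:5, nRandom = 150),
               "pool")
  expect_error(independenceTest(m, g1, g2, pool = 1:50, nRandom = 10),
               "nRandom")
  expect_message(independenceTest(m, g1, c(2L, 40L, 44L), pool = 1:50,
                                  nRandom = 150, seed = 1), "overlap")
})

test_that("identical strongly covarying groups are called dependent", {
  # two duplicated columns with balanced composition against an iid
  # background: the shared group carries far more joint conservation than
  # random same-domain site sets
  set.seed(67)
  col <- sample(rep(c("A", "C", "D", "E"), each = 10))
  m <- matrix(sample(c("F", "G", "H", "I", "K", "L"), 40 * 60,
                     replace = TRUE), 40, 60)
  m[, 1] <- col; m[, 2] <- col
  rownames(m) <- paste0("s", 1:40)
  res <- suppressMessages(
    independenceTest(m, c(1L, 2L), c(1L, 2L), pool = 1:60,
                     nRandom = 300, seed = 69))
  expect_false(res$independent)
})
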