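test_that("divergence times cover patristic, Poisson and Li modes", {
  tr <- readTree(text = "(A:0.1,B:0.2);")
  aln <- aaSet(c(A = "ACDEFGHIKL", B = "ACDEFGHIKW"))
  tp <- divergenceTimes(aln, "patristic", tree = tr)
  expect_equal(tp["A", "B"], 0.3)
  expect_equal(diag(tp), c(A = 0, B = 0))

  # Poisson correction of p = 0.1
  tpp <- divergenceTimes(aln, "poisson_protein")
  expect_equal(tpp["A", "B"], -log(1 - 0.1), tolerance = 1e-9)

  # identical synonymous sites -> zero divergence floored at epsilon
  prot <- aaSet(c(A = "ACDEFGHIKL", B = "ACDEFGHIKL"))
  cds0 <- emitCDS(prot, synDivergence = 0, seed = 1)
  tks <- divergenceTimes(prot, "li_ks", cds = cds0)
  expect_equal(tks["A", "B"], 1e-4)

  # divergent synonymous codons give positive, symmetric times
  prot3 <- aaSet(c(a = strrep("ACDEFGHIKL", 4), b = strrep("ACDEFGHIKL", 4),
                   c = strrep("ACDEFGHIKL", 4)))
  cds <- emitCDS(prot3, synDivergence = 0.6, seed = 2)
  tks3 <- divergenceTimes(prot3, "li_ks", cds = cds)
  expect_true(isSymmetric(tks3))
  expect_true(all(tks3[upper.tri(tks3)] > 0))

  expect_error(divergenceTimes(aln, "li_ks"), "CDS")
  expect_error(divergenceTimes(aln, "patristic"), "tree")
})

test_that("site vectors are centered, corrected BLOSUM transition scores", {
  # 3 sequences (A, A, S): raw BLOSUM62 scores (4, 1, 1), mean 2,
  # centered (2, -1, -1), divided by unit times
  aln <- aaSet(c(s1 = "A", s2 = "A", s3 = "S"))
  v <- siteVector(aln, 1, unitTimes(names(aln)))
  expect_equal(unname(v), c(2, -1, -1))

  # invariant column centers to zero
  inv <- aaSet(c(s1 = "A", s2 = "A", s3 = "A"))
  expect_equal(unname(siteVector(inv, 1, unitTimes(names(inv)))), c(0, 0, 0))

  # a single sequence pair centers to zero
  two <- aaSet(c(s1 = "A", s2 = "A"))
  expect_equal(unname(siteVector(two, 1, unitTimes(names(two)))), 0)

  # gapped rows are masked
  gap <- aaSet(c(s1 = "A", s2 = "-", s3 = "S"))
  vg <- siteVector(gap, 1, unitTimes(names(gap)))
  expect_true(is.na(vg[1]) && is.na(vg[3]))  # pairs (1,2) and (2,3)
  expect_error(siteVector(aaSet(c(a = "-", b = "-")), 1,
                          unitTimes(c("a", "b"))), "gapped")
  expect_error(siteVector(aln, 9, unitTimes(names(aln))), "range")
})

test_that("pair correlation is Pearson with skip semantics", {
  vi <- c(2, -1, -1, 3)
  expect_equal(pairCorrelation(vi, vi), 1)
  expect_equal(pairCorrelation(vi, -vi), -1)
  expect_equal(pairCorrelation(c(2, -1, -1), c(-1, 2, -1)), -0.5)
  expect_equal(pairCorrelation(vi, 2 * vi + 5), 1)  # affine invariance

  # symmetry
  vj <- c(0.3, 1.2, -0.7, 0.1)
  expect_equal(pairCorrelation(vi, vj), pairCorrelation(vj, vi))

  short <- c(1, 2, NA, NA)
  expect_true(is.na(pairCorrelation(short, vi)))
  expect_equal(attr(pairCorrelation(short, vi), "reason"),
               "insufficient_overlap")
  flat <- c(1, 1, 1, 1)
  expect_equal(attr(pairCorrelation(flat, vi), "reason"), "zero_variance")
})

test_that("rescaling divergence times leaves correlations unchanged", {
  tr <- simulateTree(10, 0.4, seed = 3)
  aln <- evolveAlignment(tr, 30, seed = 4)$alignment
  times <- divergenceTimes(aln, "patristic", tree = tr)
  V1 <- siteVectors(aln, times)$V
  V2 <- siteVectors(aln, 3.7 * times)$V
  R1 <- suppressWarnings(stats::cor(V1, use = "pairwise.complete.obs"))
  R2 <- suppressWarnings(stats::cor(V2, use = "pairwise.complete.obs"))
  expect_equal(R1, R2, tolerance = 1e-12)
  expect_equal(V2, V1 / 3.7, tolerance = 1e-12)
})

test_that("null thresholds follow the empirical quantile convention", {
  s <- sort(c(rep(0, 999), 0.9))
  expect_equal(CoevNet:::nullQuantileThreshold(s, 0.001), 0.9)
  sym <- seq(-1, 1, length.out = 1001)
  expect_equal(CoevNet:::nullQuantileThreshold(sym, 0.5), 0)
})

test_that("null p-values are monotone, bounded mid-p exceedances", {
  null <- sort(c(-0.5, -0.2, 0, 0.2, 0.2, 0.5, 0.7, 0.9, 0.95, 1))
  p <- nullPValues(c(-1, 0.2, 0.6, 1, 2), null)
  expect_true(all(p > 0 & p <= 1))
  expect_true(all(diff(p) <= 0))
  # value above every null observation gets the smallest probability
  expect_equal(p[5], 1 / 11)
  # mid-p at an atom: #{> 0.2} = 5, #{>= 0.2} = 7 -> (6 + 1)/11
  expect_equal(p[2], 7 / 11)
  expect_true(is.na(nullPValues(NA_real_, null)))
})

test_that("null model construction is reproducible and validated", {
  tr <- simulateTree(8, 0.4, seed = 5)
  aln <- evolveAlignment(tr, 40, seed = 6)$alignment
  n1 <- buildNull(aln, tr, nSim = 3, nSamples = 1500, alpha = 0.05, seed = 9)
  n2 <- buildNull(aln, tr, nSim = 3, nSamples = 1500, alpha = 0.05, seed = 9)
  expect_identical(nullSample(n1), nullSample(n2))
  expect_identical(nullThreshold(n1), nullThreshold(n2))
  # threshold is monotone non-increasing in alpha
  expect_gte(CoevNet:::nullQuantileThreshold(nullSample(n1), 0.01),
             CoevNet:::nullQuantileThreshold(nullSample(n1), 0.10))
})

test_that("intra-protein detection flags planted pairs and records skips", {
  fx <- plantedFixture()
  null <- buildNull(fx$aln, fx$tree, nSim = 4, nSamples = 12000,
                    alpha = 0.001, seed = 11)
  det <- detectIntra(fx$aln, fx$tree, alpha = 0.001, null = null,
                     protein = "toy")
  tab <- pairTable(det)
  # all column pairs are present, sorted
  expect_equal(nrow(tab), choose(80, 2))
  expect_true(!is.unsorted(tab$site_a))
  expect_true(all(tab$site_a < tab$site_b))
  # every planted (duplicated-column) pair is significant
  sig <- significantPairs(det)
  for (k in seq_len(nrow(fx$planted)))
    expect_true(any(sig$site_a == fx$planted$site_i[k] &
                    sig$site_b == fx$planted$site_j[k]))
  # skipped pairs carry reasons, not silent drops
  skipped <- tab[!is.na(tab$skip_reason), ]
  expect_true(all(skipped$skip_reason %in%
                  c("zero_variance", "insufficient_overlap")))
  expect_true(all(is.na(skipped$r)))
})

test_that("an invariant column is skipped as zero variance", {
  fx <- plantedFixture()
  m <- alignmentMatrix(fx$aln)
  m[, 50] <- "A"
  null <- buildNull(m, fx$tree, nSim = 3, nSamples = 5000, alpha = 0.01,
                    seed = 12)
  det <- detectIntra(m, fx$tree, alpha = 0.01, null = null)
  tab <- pairTable(det)
  col50 <- tab[tab$site_a == 50 | tab$site_b == 50, ]
  expect_true(all(col50$skip_reason == "zero_variance"))
})

test_that("inter-protein detection needs organism-paired inputs and finds planted cross pairs", {
  tr <- simulateTree(24, 0.4, seed = 31)
  pp <- evolveProteinPair(tr, 40, 30,
                          crossPlanted = data.frame(site_i = 7L, site_j = 12L,
                                                    rho = 1),
                          seed = 32)
  null <- buildNull(pp$a, tr, nSim = 4, nSamples = 12000, alpha = 0.001,
                    seed = 33, crossLength = 30L)
  det <- detectInter(pp$a, pp$b, tr, alpha = 0.001, null = null,
                     proteins = c("pA", "pB"))
  tab <- pairTable(det)
  expect_equal(nrow(tab), 40L * 30L)
  sig <- significantPairs(det)
  expect_true(any(sig$site_a == 7 & sig$site_b == 12))

  unpaired <- aaSet(c(x = "ACDE", y = "ACDF", z = "ACDW"))
  expect_error(detectInter(pp$a, unpaired, tr, null = null),
               "organism-paired")
})
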