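test_that("deduplication keeps first representatives and is idempotent", {
  aln <- aaSet(c(a = "ACDE", b = "ACDF", c = "ACDE"))
  out <- deduplicate(aln)
  expect_equal(names(out), c("a", "b"))

  distinct <- aaSet(c(x = "AAAA", y = "CCCC"))
  expect_equal(as.character(deduplicate(distinct)), as.character(distinct))

  allSame <- aaSet(c(p = "AAAA", q = "AAAA", r = "AAAA"))
  one <- deduplicate(allSame)
  expect_equal(length(one), 1L)
  expect_error(meanDivergence(one), "at least 2")

  expect_identical(as.character(deduplicate(deduplicate(aln))),
                   as.character(deduplicate(aln)))
  expect_lte(length(deduplicate(aln)), length(aln))
})

test_that("within-species duplicates drop to one sequence per species", {
  aln <- aaSet(c(a = "AAAA", b = "CCCC", c = "DDDD", d = "EEEE"))
  sp <- c(a = "s1", b = "s1", c = "s2", d = "s3")
  expect_equal(names(dropWithinSpeciesDuplicates(aln, sp)), c("a", "c", "d"))

  spAll <- c(a = "s1", b = "s2", c = "s3", d = "s4")
  expect_equal(length(dropWithinSpeciesDuplicates(aln, spAll)), 4L)

  expect_error(dropWithinSpeciesDuplicates(aln, sp[-2]), "missing")
})

test_that("organism pairing restricts to the intersection in matched order", {
  A <- aaSet(c(a1 = "AAAA", a2 = "CCCC", a3 = "DDDD"))
  B <- aaSet(c(b1 = "EEEE", b2 = "FFFF", b3 = "GGGG"))
  org <- c(a1 = "x", a2 = "y", a3 = "z", b1 = "y", b2 = "z", b3 = "w")
  out <- pairByOrganism(A, B, org)
  expect_equal(out$organisms, c("y", "z"))
  expect_equal(names(out$a), c("a2", "a3"))
  expect_equal(names(out$b), c("b1", "b2"))

  orgDisjoint <- c(a1 = "x", a2 = "y", a3 = "z", b1 = "u", b2 = "v", b3 = "w")
  expect_error(pairByOrganism(A, B, orgDisjoint), "shared")

  orgSame <- c(a1 = "x", a2 = "y", a3 = "z", b1 = "x", b2 = "y", b3 = "z")
  same <- pairByOrganism(A, B, orgSame)
  expect_equal(length(same$a), 3L)
  expect_equal(length(same$b), 3L)
})

test_that("mean divergence implements pairwise-deletion p-distance", {
  two <- aaSet(c(a = "AAAAAAAAAA", b = "CCCAAAAAAA"))
  expect_equal(meanDivergence(two), 0.3)

  ident <- aaSet(c(a = "ACDE", b = "ACDE"))
  expect_equal(meanDivergence(ident), 0)

  # three sequences with pairwise p-distances 0.1, 0.2, 0.3 -> mean 0.2
  tri <- aaSet(c(A = "AAAAAAAAAA", B = "CAAAAAAAAA", C = "CDDAAAAAAA"))
  d <- pDistances(tri)
  expect_equal(sort(d[upper.tri(d)]), c(0.1, 0.2, 0.3))
  expect_equal(meanDivergence(tri), 0.2)

  # gapped columns are dropped per pair
  gapped <- aaSet(c(a = "AC-E", b = "AC-D"))
  expect_equal(meanDivergence(gapped), 1 / 3)

  # order invariance, range
  for (k in 1:5) {
    tr <- simulateTree(6, 0.4, seed = k)
    aln <- evolveAlignment(tr, 40, seed = k + 10)$alignment
    md <- meanDivergence(aln)
    expect_gte(md, 0); expect_lte(md, 1)
    perm <- withr::with_seed(k, sample(length(aln)))
    expect_equal(meanDivergence(aln[perm]), md)
  }
})

test_that("neighbor joining recovers additive trees from p-distances", {
  # 3 taxa: pairwise distances 0.2 / 0.3 / 0.3; unique additive solution
  # solved from the three-point equations
  tri <- aaSet(c(A = "CAAAAAAAAA", B = "ACAAAAAAAA", C = "AADDAAAAAA"))
  d <- pDistances(tri)
  expect_equal(d["A", "B"], 0.2)
  expect_equal(d["A", "C"], 0.3)
  expect_equal(d["B", "C"], 0.3)
  oracle <- c(
    A = (d["A", "B"] + d["A", "C"] - d["B", "C"]) / 2,
    B = (d["A", "B"] + d["B", "C"] - d["A", "C"]) / 2,
    C = (d["A", "C"] + d["B", "C"] - d["A", "B"]) / 2)
  tr <- njTree(tri)
  tip <- stats::setNames(
    tr$edge.length[match(seq_len(3L), tr$edge[, 2L])], tr$tip.label)
  expect_equal(tip[names(oracle)], oracle, tolerance = 1e-12)

  # 4 taxa with exactly additive distances: NJ reproduces the full metric,
  # hence the generating topology (checked against all three alternatives
  # via the four-point condition)
  quad <- aaSet(c(
    A = "CCWAAAAAAAAAAAAAAAAA",
    B = "CCAWAAAAAAAAAAAAAAAA",
    C = "DDAAWAAAAAAAAAAAAAAA",
    D = "DDAAAWAAAAAAAAAAAAAA"))
  d4 <- pDistances(quad)
  sums <- c(AB_CD = d4["A", "B"] + d4["C", "D"],
            AC_BD = d4["A", "C"] + d4["B", "D"],
            AD_BC = d4["A", "D"] + d4["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")  # generating split
  tr4 <- njTree(quad)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-12)

  expect_error(njTree(aaSet(c(a = "AA", b = "AC"))), "at least 3")

  # identical sequences give zero-length terminal branches, no error
  dup <- aaSet(c(a = "AAAA", b = "AAAA", c = "CCCC"))
  trd <- njTree(dup)
  expect_true(all(trd$edge.length >= 0))
})

test_that("column-to-residue mapping follows the gap-skip rule", {
  st <- makeStructure(c(5L, 6L, 7L), c("ALA", "CYS", "ASP"),
                      matrix(runif(9), 3))
  aln <- aaSet(c(ref = "A-CD", other = "AWCD"))
  map <- columnToResidueMap(aln, "ref", st)
  expect_equal(map, c(`1` = 5L, `3` = 6L, `4` = 7L),
               ignore_attr = "mismatches")
  expect_false("2" %in% names(map))
  expect_equal(attr(map, "mismatches"), integer(0))
  expect_true(all(diff(unname(map)) > 0))  # monotone
  # inverse composition is identity on mapped columns
  inv <- stats::setNames(as.integer(names(map)), map)
  expect_equal(unname(inv[as.character(map[names(map)])]),
               as.integer(names(map)))

  alnFull <- aaSet(c(ref = "ACD", other = "ACD"))
  expect_no_error(columnToResidueMap(alnFull, "ref", st))
  expect_error(columnToResidueMap(aaSet(c(ref = "ACDE", o = "ACDE")),
                                  "ref", st), "does not match")
  expect_error(columnToResidueMap(aln, "nope", st), "nope")
})
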