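carbonCoords <- function(structure, resno, caOnly = FALSE) {
  a <- structure@atoms
  sel <- a$resno == resno &
    (if (caOnly) a$elety == "CA" else a$elesy == "C")
  if (!any(sel))
    stop("residue ", resno, " has no ",
         if (caOnly) "alpha carbon" else "carbon atoms")
  as.matrix(a[sel, c("x", "y", "z"), drop = FALSE])
}

crossMinDistance <- function(A, B) {
  # min Euclidean distance over all rows of A x rows of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Minimum carbon-carbon distance between two residues
#'
#' The proximal-carbon distance: minimum Euclidean distance over all
#' (carbon, carbon) atom pairs of the two residues. A `proximal` attribute
#' flags whether the distance is strictly below `proximalCutoff` (default
#' 4 angstrom).
#'
#' @param structure a [StructureModel-class].
#' @param resA,resB residue numbers.
#' @param caOnly use only alpha carbons (sensitivity mode).
#' @param proximalCutoff cutoff for the `proximal` flag.
#' @return distance in angstrom, with attribute `proximal`.
#' @export
minCarbonDistance <- function(structure, resA, resB, caOnly = FALSE,
                              proximalCutoff = 4) {
  d <- crossMinDistance(carbonCoords(structure, resA, caOnly),
                        carbonCoords(structure, resB, caOnly))
  attr(d, "proximal") <- d < proximalCutoff
  d
}

#' Residue-pair minimum carbon distance matrix
#'
#' @param structure a [StructureModel-class].
#' @param residues residue numbers (default: all).
#' @param caOnly use only alpha carbons.
#' @return symmetric matrix of proximal-carbon distances.
#' @export
residueDistanceMatrix <- function(structure, residues = NULL, caOnly = FALSE) {
  if (is.null(residues)) residues <- residueNumbers(structure)
  missing <- setdiff(residues, residueNumbers(structure))
  if (length(missing))
    stop("residue(s) not in structure: ", paste(missing, collapse = ", "))
  coords <- lapply(residues, carbonCoords, structure = structure, caOnly = caOnly)
  n <- length(residues)
  D <- matrix(0, n, n, dimnames = list(residues, residues))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    D[i, j] <- D[j, i] <- crossMinDistance(coords[[i]], coords[[j]])
  D
}

#' Structural compactness of a residue group
#'
#' Mean pairwise proximal-carbon distance over all unordered residue pairs
#' of the group.
#'
#' @param structure a [StructureModel-class].
#' @param residues at least two residue numbers.
#' @param caOnly use only alpha carbons.
#' @return mean distance in angstrom.
#' @export
groupCompactness <- function(structure, residues, caOnly = FALSE) {
  if (length(residues) < 2L) stop("compactness needs at least 2 residues")
  D <- residueDistanceMatrix(structure, residues, caOnly)
  mean(D[upper.tri(D)])
}

#' Significance of structural clustering
#'
#' Compares the compactness of a residue group to random equal-size groups
#' drawn from a candidate pool: `p = (1 + #{random <= observed}) /
#' (nRandom + 1)` (add-one estimator).
#'
#' @param structure a [StructureModel-class].
#' @param residues the observed group (subset of `pool`).
#' @param pool candidate residue numbers (must contain the group).
#' @param nRandom number of random groups (>= 100).
#' @param seed integer seed.
#' @param caOnly use only alpha carbons.
#' @return p-value, with attributes `observed` (compactness) and
#'   `null_mean`.
#' @export
clusterSignificance <- function(structure, residues, pool, nRandom = 1000L,
                                seed = 1L, caOnly = FALSE) {
  if (nRandom < 100L) stop("nRandom must be at least 100")
  if (!all(residues %in% pool)) stop("pool must contain every group residue")
  if (length(pool) < length(residues) + 1L) stop("candidate pool too small")
  D <- residueDistanceMatrix(structure, pool, caOnly)
  idx <- match(residues, pool)
  comp <- function(ii) { S <- D[ii, ii]; mean(S[upper.tri(S)]) }
  obs <- comp(idx)
  k <- length(residues)
  nullComp <- withSeed(seed, vapply(seq_len(nRandom), function(r)
    comp(sample(length(pool), k)), numeric(1L)))
  p <- (1 + sum(nullComp <= obs)) / (nRandom + 1)
  attr(p, "observed") <- obs
  attr(p, "null_mean") <- mean(nullComp)
  p
}

#' Secondary-structure enrichment of a residue group
#'
#' Compares the observed distribution of the group over secondary-structure
#' classes (helix, strand, coil) to the expectation from the chain's class
#' composition, with a chi-square statistic (no continuity correction).
#' Classes absent from the chain (expected 0) are dropped and the degrees of
#' freedom reduced accordingly.
#'
#' @param structure a [StructureModel-class].
#' @param residues residue numbers of the group (n >= 1).
#' @return list: `table` (data.frame class, observed, expected, total),
#'   `chisq`, `df`, `p`.
#' @export
ssEnrichment <- function(structure, residues) {
  if (length(residues) == 0L) stop("empty residue group")
  ss <- secondaryStructure(structure)
  missing <- setdiff(residues, as.integer(names(ss)))
  if (length(missing))
    stop("residue(s) not in structure: ", paste(missing, collapse = ", "))
  classes <- c("helix", "strand", "coil")
  totals <- vapply(classes, function(k) sum(ss == k), numeric(1L))
  obs <- vapply(classes, function(k)
    sum(ss[as.character(residues)] == k), numeric(1L))
  n <- length(residues)
  keep <- totals > 0
  expd <- n * totals[keep] / sum(totals)
  obsK <- obs[keep]
  df <- sum(keep) - 1L
  if (df == 0L) stop("structure has a single secondary-structure class")
  chisq <- sum((obsK - expd)^2 / expd)
  list(table = data.frame(class = classes[keep], observed = obsK,
                          expected = expd, total = totals[keep],
                          row.names = NULL),
       chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Mean pairwise proximal-carbon distance over a residue set
#'
#' The chain-wide background distance scale coevolving clusters are compared
#' against (of order tens of angstrom for a globular chain).
#'
#' @param structure a [StructureModel-class].
#' @param residues residue numbers (default: all residues of the chain).
#' @param caOnly use only alpha carbons.
#' @return mean distance in angstrom.
#' @export
meanPairwiseDistance <- function(structure, residues = NULL, caOnly = FALSE) {
  if (is.null(residues)) residues <- residueNumbers(structure)
  groupCompactness(structure, residues, caOnly)
}
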