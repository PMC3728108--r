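AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosumMatrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Divergence times between sequences
#'
#' Builds the symmetric matrix of divergence times used to correct BLOSUM
#' transition scores. Three modes: `li_ks` (Li-type corrected synonymous
#' substitutions from a matched in-frame CDS alignment, the estimator used on
#' real data), `patristic` (sum of branch lengths on a tree) and
#' `poisson_protein` (Poisson-corrected p-distance, `-ln(1 - p)`).
#' Saturated or undefined estimates are replaced by the largest finite entry;
#' entries below `epsilon` are floored at `epsilon` so the matrix can be used
#' as a divisor.
#'
#' @param aln protein alignment (`XStringSet` or character matrix).
#' @param mode one of `"patristic"`, `"poisson_protein"`, `"li_ks"`.
#' @param tree [ape::phylo] tree (required for `patristic`).
#' @param cds in-frame CDS alignment matching `aln` ids, width 3x protein
#'   width (required for `li_ks`).
#' @param epsilon floor applied to off-diagonal entries (default `1e-4`).
#' @return symmetric numeric matrix over the alignment ids, zero diagonal,
#'   with attribute `mode`.
#' @export
divergenceTimes <- function(aln, mode = c("patristic", "poisson_protein", "li_ks"),
                            tree = NULL, cds = NULL, epsilon = 1e-4) {
  mode <- match.arg(mode)
  m <- alignmentMatrix(aln)
  ids <- rownames(m)
  t <- switch(mode,
    patristic = {
      if (is.null(tree)) stop("patristic mode requires a tree")
      missing <- setdiff(ids, tree$tip.label)
      if (length(missing))
        stop("alignment id(s) absent from tree: ", paste(missing, collapse = ", "))
      ape::cophenetic.phylo(tree)[ids, ids]
    },
    poisson_protein = {
      p <- pDistances(m)
      tt <- -log(1 - p)
      tt[!is.finite(tt)] <- NA
      tt
    },
    li_ks = {
      if (is.null(cds)) stop("li_ks mode requires a matched CDS alignment")
      liKsMatrix(m, cds)
    })
  # saturated / undefined estimates -> matrix maximum
  if (anyNA(t)) {
    mx <- max(t, na.rm = TRUE)
    if (!is.finite(mx)) stop("no finite divergence estimate available")
    t[is.na(t)] <- mx
  }
  t <- (t + base::t(t)) / 2
  t[t < epsilon] <- epsilon
  diag(t) <- 0
  dimnames(t) <- list(ids, ids)
  attr(t, "mode") <- mode
  t
}

liKsMatrix <- function(m, cds) {
  ids <- rownames(m)
  cm <- alignmentMatrix(cds)
  missing <- setdiff(ids, rownames(cm))
  if (length(missing))
    stop("CDS missing for id(s): ", paste(missing, collapse = ", "))
  cm <- cm[ids, , drop = FALSE]
  if (ncol(cm) != 3L * ncol(m))
    stop("CDS width (", ncol(cm), ") is not 3x the protein width (", ncol(m), ")")
  seqs <- tolower(apply(cm, 1L, paste, collapse = ""))
  sa <- seqinr::as.alignment(nb = length(ids), nam = ids, seq = unname(seqs))
  ks <- suppressWarnings(as.matrix(seqinr::kaks(sa)$ks))
  ks[!is.finite(ks) | ks < 0 | ks >= 9.99] <- NA  # kaks saturation sentinel
  ks <- ks[ids, ids]
  # identical coding sequences have zero synonymous divergence by definition
  rows <- apply(cm, 1L, paste, collapse = "")
  same <- outer(rows, rows, `==`)
  ks[same] <- 0
  ks
}

scoreablePairIndex <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) seq.int(k + 1L, n)))
  cbind(i = i, j = j)
}

#' Divergence-corrected BLOSUM transition vectors for all columns
#'
#' For every alignment column, computes the vector over unordered sequence
#' pairs of centered, divergence-corrected BLOSUM transition scores:
#' `(B(a_s, a_t) - mean_B) / t(s, t)`, where `B` is the substitution score of
#' the residue pair at that column, `mean_B` its mean over the pairs included
#' at the column, and `t(s, t)` the divergence time of the two sequences.
#' Pairs where either sequence is gapped at the column are `NA` (masked).
#'
#' @param aln alignment (`XStringSet` or character matrix).
#' @param times symmetric divergence-time matrix from [divergenceTimes()].
#' @param blosum substitution matrix (default BLOSUM62 from Biostrings).
#' @return list with `V` (numeric matrix, rows = sequence pairs, columns =
#'   alignment columns) and `pairs` (2-column index matrix of the sequence
#'   pairs).
#' @export
siteVectors <- function(aln, times, blosum = NULL) {
  m <- alignmentMatrix(aln)
  if (is.null(blosum)) blosum <- blosumMatrix()
  n <- nrow(m)
  ids <- rownames(m)
  if (!is.null(rownames(times))) times <- times[ids, ids]
  idx <- scoreablePairIndex(n)
  ok <- matrix(m %in% setdiff(rownames(blosum), "*"), nrow = n)
  A <- m[idx[, "i"], , drop = FALSE]
  B <- m[idx[, "j"], , drop = FALSE]
  incl <- ok[idx[, "i"], , drop = FALSE] & ok[idx[, "j"], , drop = FALSE]
  raw <- matrix(NA_real_, nrow(idx), ncol(m))
  raw[incl] <- blosum[cbind(A[incl], B[incl])]
  mu <- colMeans(raw, na.rm = TRUE)
  tvec <- times[idx]
  V <- sweep(raw, 2L, mu, `-`) / tvec
  list(V = V, pairs = idx, ids = ids)
}

#' Transition-score vector of a single column
#'
#' @inheritParams siteVectors
#' @param column 1-based alignment column.
#' @return numeric vector over unordered sequence pairs (`NA` = masked).
#' @export
siteVector <- function(aln, column, times, blosum = NULL) {
  m <- alignmentMatrix(aln)
  if (column < 1L || column > ncol(m)) stop("column out of range")
  v <- siteVectors(m[, column, drop = FALSE], times, blosum)$V[, 1L]
  if (all(is.na(v))) stop("column ", column, " is entirely gapped")
  v
}

#' Correlation of two site vectors
#'
#' Pearson correlation over the jointly unmasked entries. Pairs with fewer
#' than 3 shared entries, or where either vector is constant on the joint
#' mask, are not scored: the result is `NA` with a `reason` attribute
#' (`"insufficient_overlap"` or `"zero_variance"`).
#'
#' @param vi,vj numeric vectors of equal length (`NA` = masked).
#' @return correlation in \[-1, 1\], or `NA` with attribute `reason`.
#' @export
pairCorrelation <- function(vi, vj) {
  ok <- !is.na(vi) & !is.na(vj)
  if (sum(ok) < 3L)
    return(structure(NA_real_, reason = "insufficient_overlap"))
  x <- vi[ok]; y <- vj[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "zero_variance"))
  stats::cor(x, y)
}

nullQuantileThreshold <- function(sortedSample, alpha) {
  n <- length(sortedSample)
  sortedSample[min(n, ceiling((1 - alpha) * (n + 1)))]
}

#' Exceedance probabilities against a null sample
#'
#' One-tailed (high positive correlation indicates coevolution) add-one
#' exceedance probability with mid-p tie handling:
#' `p = (#\{null > r\} + #\{null = r\} / 2 + 1) / (n + 1)`.
#' The empirical null of this statistic is discrete (alignments on a shared
#' tree produce exact ties, e.g. at `r = 1`), and counting full atoms as
#' exceedances makes the plain add-one estimator conservative; the mid-p
#' correction restores calibration while still never returning 0.
#'
#' @param r numeric vector of observed correlations (`NA` passed through).
#' @param null a [CoevNull-class] or a numeric null sample.
#' @return numeric vector of p-values.
#' @export
nullPValues <- function(r, null) {
  s <- if (is(null, "CoevNull")) nullSample(null) else sort(null)
  n <- length(s)
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  kGT <- n - findInterval(r[ok], s)                   # #{null > r}
  kGE <- n - findInterval(r[ok], s, left.open = TRUE) # #{null >= r}
  p[ok] <- ((kGT + kGE) / 2 + 1) / (n + 1)
  p
}

#' Build the null distribution of the covariation statistic
#'
#' Simulates `nSim` neutrally evolving alignments on the tree (site
#' independent, stationary frequencies estimated from the real alignment so
#' the null shares its evolutionary features), scores all column pairs of
#' each with the same statistic as the real data, and pools the resulting
#' correlation coefficients. For inter-protein analyses (`crossLength`
#' given), each replicate simulates two alignments and pools the
#' cross-protein correlations.
#'
#' @param aln the real alignment the null should mimic.
#' @param tree [ape::phylo] tree over the alignment ids.
#' @param nSim number of simulated alignments (default 10).
#' @param nSamples maximum pooled null sample size (default 100000); if the
#'   simulations yield more values a deterministic subsample is kept.
#' @param alpha significance level used to derive the stored threshold.
#' @param seed integer seed.
#' @param crossLength if not `NULL`, the column count of the second protein:
#'   the null becomes a dedicated cross-protein null.
#' @param frequencies optional stationary residue frequencies (named, sums
#'   to 1); default: estimated from `aln`.
#' @return a [CoevNull-class].
#' @export
buildNull <- function(aln, tree, nSim = 10L, nSamples = 1e5L, alpha = 0.001,
                      seed = 1L, crossLength = NULL, frequencies = NULL) {
  m <- alignmentMatrix(aln)
  if (is.null(frequencies)) frequencies <- residueFrequencies(m)
  if (!setequal(tree$tip.label, rownames(m)))
    tree <- ape::keep.tip(tree, rownames(m))  # e.g. after deduplication
  times <- divergenceTimes(m, "patristic", tree = tree)
  L <- ncol(m)
  pool <- vector("list", nSim)
  for (s in seq_len(nSim)) {
    simSeed <- seed + s
    if (is.null(crossLength)) {
      sim <- evolveAlignment(tree, L, frequencies = frequencies, seed = simSeed)
      V <- siteVectors(sim$alignment, times)$V
      R <- suppressWarnings(stats::cor(V, use = "pairwise.complete.obs"))
      vals <- R[upper.tri(R)]
    } else {
      simA <- evolveAlignment(tree, L, frequencies = frequencies, seed = simSeed)
      simB <- evolveAlignment(tree, crossLength, frequencies = frequencies,
                              seed = simSeed + nSim + 1L)
      VA <- siteVectors(simA$alignment, times)$V
      VB <- siteVectors(simB$alignment, times)$V
      vals <- as.vector(suppressWarnings(
        stats::cor(VA, VB, use = "pairwise.complete.obs")))
    }
    pool[[s]] <- vals[is.finite(vals)]
  }
  pool <- unlist(pool)
  if (length(pool) < nSamples / 10)
    stop("too few valid null correlations (", length(pool),
         "); simulate longer alignments or more replicates")
  if (length(pool) > nSamples) {
    withSeed(seed, pool <- sample(pool, nSamples))
  }
  pool <- sort(pool)
  new("CoevNull", sample = pool,
      threshold = nullQuantileThreshold(pool, alpha),
      alpha = alpha, nSim = as.integer(nSim), seed = as.integer(seed),
      params = list(length = L, crossLength = crossLength,
                    frequencies = frequencies))
}

residueFrequencies <- function(m) {
  m <- alignmentMatrix(m)
  tab <- table(factor(m[m %in% AA20], levels = AA20))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- AA20
  if (any(f == 0)) {  # keep the simulator's state space complete
    f <- f + 1e-6
    f <- f / sum(f)
  }
  f
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  eval.parent(substitute(expr))
}

pairScoreTable <- function(R, overlap, siteA, siteB, proteinA, proteinB,
                           null, alpha, mapA = NULL, mapB = NULL) {
  r <- as.vector(R)
  nOver <- as.vector(overlap)
  skip <- rep(NA_character_, length(r))
  skip[is.na(r)] <- "zero_variance"
  skip[nOver < 3L] <- "insufficient_overlap"
  r[!is.na(skip)] <- NA
  p <- nullPValues(r, null)
  mapRes <- function(site, map) {
    if (is.null(map)) return(rep(NA_integer_, length(site)))
    unname(map[as.character(site)])
  }
  data.frame(
    protein_a = proteinA, site_a = siteA,
    residue_a = mapRes(siteA, mapA),
    protein_b = proteinB, site_b = siteB,
    residue_b = mapRes(siteB, mapB),
    r = r, p = p,
    significant = ifelse(is.na(p), NA, p < alpha),
    skip_reason = skip,
    stringsAsFactors = FALSE)
}

#' Detect intra-protein coevolving site pairs
#'
#' Scores every pair of alignment columns with the correlation of
#' divergence-corrected BLOSUM transition vectors and flags a pair as
#' coevolving when the null exceedance probability of its correlation is
#' below `alpha`. Skipped pairs (constant column on the joint mask, or fewer
#' than 3 shared sequence pairs) are recorded with a reason, never dropped.
#'
#' @param aln preprocessed protein alignment (deduplicated, paralogs
#'   removed).
#' @param tree [ape::phylo] tree over the alignment ids (used for patristic
#'   divergence times when `times` is not given).
#' @param alpha significance level (default 0.001).
#' @param null a [CoevNull-class] from [buildNull()].
#' @param times optional divergence-time matrix from [divergenceTimes()]
#'   (e.g. Li-type synonymous divergence); default: patristic from `tree`.
#' @param protein protein tag used in the output table.
#' @param siteMap optional column-to-residue map from
#'   [columnToResidueMap()].
#' @return a [CoevPairs-class], rows sorted by `(site_a, site_b)`.
#' @export
detectIntra <- function(aln, tree = NULL, alpha = 0.001, null,
                        times = NULL, protein = "protein", siteMap = NULL) {
  m <- alignmentMatrix(aln)
  if (is.null(times)) {
    if (is.null(tree)) stop("either a tree or a divergence-time matrix is required")
    times <- divergenceTimes(m, "patristic", tree = tree)
  }
  sv <- siteVectors(m, times)
  R <- suppressWarnings(stats::cor(sv$V, use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(sv$V))
  L <- ncol(m)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  tab <- pairScoreTable(R[ut], overlap[ut], ut[, 1L], ut[, 2L],
                        protein, protein, null, alpha,
                        mapA = siteMap, mapB = siteMap)
  new("CoevPairs", pairs = tab,
      params = list(alpha = alpha, mode = "intra",
                    nullSeed = if (is(null, "CoevNull")) null@seed else NA_integer_,
                    timesMode = attr(times, "mode")),
      proteins = protein)
}

#' Detect inter-protein coevolving site pairs
#'
#' Scores all cross-protein column pairs of two organism-paired alignments
#' (same row order, row i of each belonging to the same organism) with the
#' same statistic as [detectIntra()], against a dedicated cross-protein null.
#' Each site is annotated with whether it also appears among the significant
#' intra-protein pairs, supporting the check that inter-protein signals are
#' not indirect intra-protein dependencies.
#'
#' @param alnA,alnB organism-paired alignments (see [pairByOrganism()]).
#' @param tree tree over the ids of `alnA` (the shared organism tree).
#' @param alpha significance level.
#' @param null a cross-protein [CoevNull-class] (see `crossLength` in
#'   [buildNull()]).
#' @param times optional divergence-time matrix.
#' @param proteins length-2 character vector of protein tags.
#' @param intraA,intraB optional [CoevPairs-class] results of the
#'   intra-protein scans, used for the annotation columns.
#' @param siteMapA,siteMapB optional column-to-residue maps.
#' @return a [CoevPairs-class] with columns `site_a_in_intra`,
#'   `site_b_in_intra` added.
#' @export
detectInter <- function(alnA, alnB, tree = NULL, alpha = 0.001, null,
                        times = NULL, proteins = c("A", "B"),
                        intraA = NULL, intraB = NULL,
                        siteMapA = NULL, siteMapB = NULL) {
  mA <- alignmentMatrix(alnA)
  mB <- alignmentMatrix(alnB)
  if (nrow(mA) != nrow(mB))
    stop("alignments are not organism-paired: ", nrow(mA), " vs ", nrow(mB),
         " sequences")
  if (is.null(times)) {
    if (is.null(tree)) stop("either a tree or a divergence-time matrix is required")
    times <- divergenceTimes(mA, "patristic", tree = tree)
  }
  svA <- siteVectors(mA, times)
  # reuse A's pair indexing for B: rows are organism-matched
  rownames(mB) <- rownames(mA)
  svB <- siteVectors(mB, times)
  R <- suppressWarnings(stats::cor(svA$V, svB$V, use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(svA$V), !is.na(svB$V))
  grid <- expand.grid(a = seq_len(ncol(mA)), b = seq_len(ncol(mB)))
  grid <- grid[order(grid$a, grid$b), ]
  idx <- cbind(grid$a, grid$b)
  tab <- pairScoreTable(R[idx], overlap[idx], grid$a, grid$b,
                        proteins[1L], proteins[2L], null, alpha,
                        mapA = siteMapA, mapB = siteMapB)
  intraSites <- function(x) if (is.null(x)) integer(0) else
    unique(c(significantPairs(x)$site_a, significantPairs(x)$site_b))
  tab$site_a_in_intra <- tab$site_a %in% intraSites(intraA)
  tab$site_b_in_intra <- tab$site_b %in% intraSites(intraB)
  new("CoevPairs", pairs = tab,
      params = list(alpha = alpha, mode = "inter",
                    nullSeed = if (is(null, "CoevNull")) null@seed else NA_integer_,
                    timesMode = attr(times, "mode")),
      proteins = proteins)
}
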