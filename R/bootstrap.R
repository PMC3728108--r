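#' Random subsample of sequences and matching pruned tree
#'
#' Uniform sample without replacement of `ceiling(fraction * n)` sequences;
#' the tree is pruned to the sampled leaves with branch lengths preserved
#' (path lengths between retained leaves are unchanged).
#'
#' @param aln alignment (`XStringSet` or character matrix).
#' @param tree [ape::phylo] tree over the alignment ids.
#' @param fraction sampling fraction in (0, 1\].
#' @param seed integer seed.
#' @return list with `aln` (subset, original order), `tree` (pruned) and
#'   `ids`.
#' @export
resampleSequences <- function(aln, tree, fraction = 0.8, seed = 1L) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- min(n, ceiling(fraction * n))
  if (k < 4L) stop("subsample too small (", k, " sequences); need at least 4")
  ids <- rownames(m)
  keep <- withSeed(seed, sort(sample.int(n, k)))
  sub <- if (is.matrix(aln)) aln[keep, , drop = FALSE] else aln[keep]
  list(aln = sub, tree = ape::keep.tip(tree, ids[keep]), ids = ids[keep])
}

supportRecords <- function(keys, nDetected, nReps, threshold) {
  support <- nDetected / nReps
  rownames(keys) <- NULL
  cbind(keys,
        data.frame(n_reps = rep(as.integer(nReps), length(nDetected)),
                   n_detected = nDetected,
                   support = support,
                   retained = support > threshold))  # strictly more than
}

#' Phylogenetic bootstrap support of coevolving pairs
#'
#' The pair-level reliability filter: in each replicate a random subsample of
#' sequences (and the correspondingly pruned tree) is drawn, the null
#' threshold is re-derived on the subsample at reduced simulation effort, and
#' each base pair is re-scored at the same `alpha`. Support is the fraction
#' of replicates in which a pair is re-detected; pairs with support strictly
#' above `threshold` (default 0.70) are retained as consistently coevolving.
#' Only the base pairs' own correlations are evaluated per replicate: a
#' pair's detection depends solely on its own coefficient against the null,
#' so this equals a full rescan followed by intersection.
#'
#' Replicate failures (e.g. a column entirely gapped in a subsample) count as
#' non-detection and are tallied in the `failures` attribute.
#'
#' @param aln alignment the base pairs were detected on.
#' @param tree tree over the alignment ids.
#' @param basePairs a [CoevPairs-class] (its significant pairs are used) or a
#'   data.frame with columns `site_a`, `site_b` (plus `site_b` columns of a
#'   second protein for inter mode).
#' @param nReps number of bootstrap replicates (default 1000).
#' @param fraction per-replicate sampling fraction (default 0.8, without
#'   replacement).
#' @param threshold retention threshold on support (default 0.70, strict).
#' @param alpha detection significance level (same as the base scan).
#' @param seed master seed; replicate r uses `seed + r`.
#' @param nullSim simulated alignments per replicate null (reduced effort).
#' @param nullSamples pooled null sample cap per replicate.
#' @param aln2 second alignment for inter-protein pairs (organism-paired
#'   with `aln`).
#' @return data.frame: pair keys, `n_reps`, `n_detected`, `support`,
#'   `retained`.
#' @export
bootstrapPairs <- function(aln, tree, basePairs, nReps = 1000L,
                           fraction = 0.8, threshold = 0.70, alpha = 0.001,
                           seed = 1L, nullSim = 3L, nullSamples = 20000L,
                           aln2 = NULL) {
  if (is(basePairs, "CoevPairs")) basePairs <- significantPairs(basePairs)
  keys <- basePairs[, intersect(c("protein_a", "site_a", "protein_b", "site_b"),
                                names(basePairs)), drop = FALSE]
  nPairs <- nrow(basePairs)
  if (nPairs == 0L)
    return(supportRecords(keys, integer(0), nReps, threshold))
  m <- alignmentMatrix(aln)
  m2 <- if (!is.null(aln2)) alignmentMatrix(aln2) else NULL
  inter <- !is.null(m2)
  if (inter && nrow(m2) != nrow(m)) stop("aln2 is not organism-paired with aln")
  colsA <- unique(basePairs$site_a)
  colsB <- unique(basePairs$site_b)
  detected <- integer(nPairs)
  failures <- 0L
  for (r in seq_len(nReps)) {
    res <- tryCatch({
      rs <- resampleSequences(m, tree, fraction, seed = seed + r)
      keep <- match(rs$ids, rownames(m))
      nullR <- buildNull(rs$aln, rs$tree, nSim = nullSim,
                         nSamples = nullSamples, alpha = alpha,
                         seed = seed + nReps + r,
                         crossLength = if (inter) ncol(m2) else NULL)
      times <- divergenceTimes(rs$aln, "patristic", tree = rs$tree)
      VA <- siteVectors(rs$aln[, colsA, drop = FALSE], times)$V
      VB <- if (inter)
        siteVectors({mb <- m2[keep, colsB, drop = FALSE]
                     rownames(mb) <- rs$ids; mb}, times)$V
      else siteVectors(rs$aln[, colsB, drop = FALSE], times)$V
      rr <- vapply(seq_len(nPairs), function(k) {
        pairCorrelation(VA[, match(basePairs$site_a[k], colsA)],
                        VB[, match(basePairs$site_b[k], colsB)])
      }, numeric(1L))
      p <- nullPValues(rr, nullR)
      !is.na(p) & p < alpha
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L
    else detected <- detected + res
  }
  out <- supportRecords(keys, detected, nReps, threshold)
  attr(out, "failures") <- failures
  out
}
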