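#' Two-outcome relative entropy
#'
#' `f ln(f/q) + (1 - f) ln((1 - f)/(1 - q))`, the Kullback-Leibler divergence
#' of the observed modal-residue frequency `f` from its background
#' expectation `q`, with the `0 ln 0 = 0` convention. This is the building
#' block of the site, group and correlation entropies.
#'
#' @param f observed frequency in \[0, 1\].
#' @param q background frequency in (0, 1).
#' @return non-negative divergence (zero iff `f == q`).
#' @export
binaryRelativeEntropy <- function(f, q) {
  stopifnot(all(f >= 0 & f <= 1), all(q > 0 & q < 1))
  t1 <- ifelse(f == 0, 0, f * log(f / q))
  t2 <- ifelse(f == 1, 0, (1 - f) * log((1 - f) / (1 - q)))
  t1 + t2
}

#' Per-column conservation summaries of an alignment
#'
#' Computes, for every column: the modal residue (ties broken alphabetically
#' for determinism), its frequency `f` among ungapped rows, the background
#' frequency `q` of that residue over the whole alignment, and the site
#' conservation entropy `D_i`. Also returns the modal-indicator matrix used
#' by the group statistics.
#'
#' @param aln alignment (`XStringSet` or character matrix).
#' @return list with `modal`, `f`, `q`, `Di` (per-column vectors), `M`
#'   (logical sequence x column matrix, `NA` where gapped) and `freq`
#'   (overall residue frequencies).
#' @export
sectorBackground <- function(aln) {
  m <- alignmentMatrix(aln)
  ug <- m != "-" & m != "."
  res <- m[ug]
  freq <- table(res) / length(res)
  L <- ncol(m)
  modal <- character(L); f <- numeric(L); q <- numeric(L)
  for (j in seq_len(L)) {
    col <- m[ug[, j], j]
    if (length(col) == 0L) { modal[j] <- NA; f[j] <- NA; q[j] <- NA; next }
    tab <- table(col)
    a <- sort(names(tab)[tab == max(tab)])[1L]
    modal[j] <- a
    f[j] <- as.numeric(tab[a]) / length(col)
    q[j] <- as.numeric(freq[a])
  }
  M <- matrix(NA, nrow(m), L)
  M[ug] <- m[ug] == rep(modal, each = nrow(m))[ug]
  Di <- ifelse(is.na(f), NA, binaryRelativeEntropy(pmin(f, 1), pmax(pmin(q, 1 - 1e-12), 1e-12)))
  list(modal = modal, f = f, q = q, Di = Di, M = M, freq = freq)
}

#' Site conservation entropy
#'
#' `D_i = f ln(f/q) + (1 - f) ln((1 - f)/(1 - q))` with `f` the frequency of
#' the column's modal residue among ungapped rows and `q` that residue's
#' background frequency over the whole alignment (or a supplied value).
#'
#' @param aln alignment.
#' @param column 1-based column index.
#' @param q optional background frequency override.
#' @param background optional precomputed [sectorBackground()].
#' @return non-negative entropy value.
#' @export
siteEntropy <- function(aln, column, q = NULL, background = NULL) {
  if (is.null(background)) background <- sectorBackground(aln)
  f <- background$f[column]
  if (is.na(f)) stop("column ", column, " is entirely gapped")
  if (is.null(q)) q <- background$q[column]
  binaryRelativeEntropy(f, q)
}

groupJointFrequency <- function(background, sites) {
  M <- background$M[, sites, drop = FALSE]
  complete <- rowSums(is.na(M)) == 0L
  if (!any(complete))
    stop("no sequence is ungapped at every site of the group")
  mean(rowSums(M[complete, , drop = FALSE]) == length(sites))
}

#' Group conservation entropy
#'
#' Two-outcome relative entropy of the joint modal pattern of a site group:
#' `f_S` is the fraction of sequences carrying the modal residue at every
#' site of `S` simultaneously (sequences gapped at any site of `S` are
#' excluded), and the group background `q_S` is the product of the per-site
#' modal-residue background frequencies — the independence expectation of
#' the joint pattern. Reduces exactly to [siteEntropy()] for singletons.
#'
#' @param aln alignment.
#' @param sites integer vector of alignment columns (non-empty).
#' @param background optional precomputed [sectorBackground()].
#' @return group entropy `D_S`.
#' @export
groupEntropy <- function(aln, sites, background = NULL) {
  if (length(sites) == 0L) stop("empty site group")
  if (is.null(background)) background <- sectorBackground(aln)
  fS <- groupJointFrequency(background, sites)
  qS <- prod(background$q[sites])
  binaryRelativeEntropy(fS, min(qS, 1 - 1e-12))
}

#' Correlation entropy of a site group
#'
#' `I_S = D_S - sum_i D_i`: the excess of the group's joint conservation
#' over the sum of its sites' individual conservations. Positive values
#' indicate that the sites covary beyond what their individual conservation
#' explains; `I_S = 0` for singletons.
#'
#' @inheritParams groupEntropy
#' @return correlation entropy `I_S`.
#' @export
correlationEntropy <- function(aln, sites, background = NULL) {
  if (is.null(background)) background <- sectorBackground(aln)
  groupEntropy(aln, sites, background) - sum(background$Di[sites])
}

#' Statistical independence of two coevolving site groups
#'
#' Tests whether two site groups from the same protein domain are
#' statistically independent: the observed
#' `theta = I_S(g1 u g2) - (I_S(g1) + I_S(g2))` is compared to a null
#' distribution of `theta` from `nRandom` replicate pairs of disjoint random
#' site groups of the same sizes drawn from the domain site pool. A z-score
#' against the null mean/sd gives a two-sided normal p-value; the groups are
#' called independent when the difference is not significant (`p >= level`).
#'
#' @param aln alignment covering both clades under comparison (backgrounds
#'   are computed from it so both groups share a reference).
#' @param g1,g2 integer vectors of alignment columns (same protein domain;
#'   overlap is allowed and reported via a message).
#' @param pool integer vector of candidate columns of the domain.
#' @param nRandom number of null replicates (default 1000; >= 100).
#' @param seed integer seed.
#' @param level significance level of the verdict (default 0.05).
#' @return one-row data.frame: `n_g1`, `n_g2`, `theta`, `null_mean`,
#'   `null_sd`, `z`, `p`, `independent`.
#' @export
independenceTest <- function(aln, g1, g2, pool, nRandom = 1000L, seed = 1L,
                             level = 0.05) {
  if (nRandom < 100L) stop("nRandom must be at least 100")
  if (length(pool) < length(g1) + length(g2))
    stop("site pool smaller than the two group sizes combined")
  if (length(intersect(g1, g2)))
    message("groups overlap at ", length(intersect(g1, g2)),
            " site(s); union used for the joint entropy")
  bg <- sectorBackground(aln)
  theta <- function(a, b)
    correlationEntropy(aln, union(a, b), bg) -
      (correlationEntropy(aln, a, bg) + correlationEntropy(aln, b, bg))
  obs <- theta(g1, g2)
  n1 <- length(g1); n2 <- length(g2)
  nullTheta <- withSeed(seed, vapply(seq_len(nRandom), function(k) {
    s <- sample(pool, n1 + n2)
    theta(s[seq_len(n1)], s[n1 + seq_len(n2)])
  }, numeric(1L)))
  cbind(data.frame(n_g1 = n1, n_g2 = n2),
        independenceSummary(obs, nullTheta, level))
}

independenceSummary <- function(thetaObs, nullTheta, level = 0.05) {
  mu <- mean(nullTheta); sdv <- stats::sd(nullTheta)
  if (sdv == 0) stop("degenerate null: all replicate theta values identical")
  z <- (thetaObs - mu) / sdv
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(theta = thetaObs, null_mean = mu, null_sd = sdv, z = z, p = p,
             independent = p >= level)
}
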