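#' Simulate a pure-birth tree
#'
#' Pure-birth (Yule) tree with branch lengths rescaled so the mean
#' root-to-tip path length equals `depth` (substitutions per site), putting
#' simulated alignments in a chosen divergence regime.
#'
#' @param nTaxa number of leaves (>= 3).
#' @param depth target mean root-to-tip path length (default 0.3, which at
#'   the default stationary frequencies lands mean pairwise divergence in
#'   the 0.30-0.40 band typical of deep bacterial protein alignments).
#' @param seed integer seed.
#' @return an [ape::phylo] tree with `nTaxa` leaves.
#' @export
simulateTree <- function(nTaxa, depth = 0.3, seed = 1L) {
  if (nTaxa < 3L) stop("need at least 3 taxa")
  tr <- withSeed(seed, ape::rphylo(nTaxa, birth = 1, death = 0))
  tipDepth <- ape::node.depth.edgelength(tr)[seq_len(nTaxa)]
  tr$edge.length <- tr$edge.length * depth / mean(tipDepth)
  tr
}

# State pairing used by the coupling mechanism: the mirrored site adopts the
# same state. This is the identity bijection, so a fully coupled pair
# (rho = 1) is a duplicated column -- the strongest covariation signature the
# statistic can see -- and rho interpolates smoothly down to independence.
aaShift <- function(a) a
aaUnshift <- function(b) b

#' Evolve an alignment on a tree, optionally with planted covarying pairs
#'
#' Sites evolve independently down the tree under a continuous-time
#' exchange process with the given stationary frequencies (uniform
#' exchangeability: at each event the new state is drawn from the stationary
#' distribution; the event rate is normalized so branch lengths are expected
#' substitutions per site). For a planted pair with coupling `rho`, each
#' substitution event at one site of the pair is mirrored at the other with
#' probability `rho`, the mirrored state being given by a fixed bijection
#' between amino acids; `rho = 1` makes the two columns perfectly covarying
#' and `rho = 0` reduces to independent (neutral) evolution.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param length number of alignment columns.
#' @param frequencies stationary residue frequencies (named over the 20
#'   amino acids; default uniform).
#' @param planted data.frame with columns `site_i`, `site_j`, `rho`
#'   (planted covarying pairs; sites must be distinct and within `length`).
#' @param seed integer seed.
#' @return list: `alignment` ([Biostrings::AAStringSet] over the tree
#'   leaves) and `manifest` (the planted-pair data.frame).
#' @export
evolveAlignment <- function(tree, length, frequencies = NULL, planted = NULL,
                            seed = 1L) {
  if (is.null(frequencies))
    frequencies <- stats::setNames(rep(1 / 20, 20), AA20)
  stopifnot(all(AA20 %in% names(frequencies)))
  freq <- frequencies[AA20] / sum(frequencies[AA20])
  if (is.null(planted))
    planted <- data.frame(site_i = integer(0), site_j = integer(0),
                          rho = numeric(0))
  coupledSites <- c(planted$site_i, planted$site_j)
  if (anyDuplicated(coupledSites)) stop("planted sites must be distinct")
  if (length(coupledSites) && (max(coupledSites) > length || min(coupledSites) < 1))
    stop("planted sites out of range")
  if (any(planted$rho < 0 | planted$rho > 1)) stop("rho must be in [0, 1]")
  neutral <- setdiff(seq_len(length), coupledSites)
  mu <- 1 / (1 - sum(freq^2))  # events per unit branch length
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  root <- nTip + 1L
  states <- matrix(NA_character_, nNode, length)
  withSeed(seed, {
    states[root, ] <- sample(AA20, length, replace = TRUE, prob = freq)
    for (k in seq_len(nrow(planted)))
      if (planted$rho[k] > 0 && stats::runif(1) < planted$rho[k])
        states[root, planted$site_j[k]] <- aaShift(states[root, planted$site_i[k]])
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      len <- tree$edge.length[e]
      st <- states[par, ]
      nev <- stats::rpois(base::length(neutral), mu * len)
      hit <- neutral[nev > 0L]
      if (base::length(hit))
        st[hit] <- sample(AA20, base::length(hit), replace = TRUE, prob = freq)
      for (k in seq_len(nrow(planted))) {
        i <- planted$site_i[k]; j <- planted$site_j[k]; rho <- planted$rho[k]
        ki <- stats::rpois(1L, mu * len); kj <- stats::rpois(1L, mu * len)
        who <- sample(rep(c("i", "j"), c(ki, kj)))
        for (w in who) {
          if (w == "i") {
            a <- sample(AA20, 1L, prob = freq)
            st[i] <- a
            if (stats::runif(1) < rho) st[j] <- aaShift(a)
          } else {
            b <- sample(AA20, 1L, prob = freq)
            st[j] <- b
            if (stats::runif(1) < rho) st[i] <- aaUnshift(b)
          }
        }
      }
      states[child, ] <- st
    }
  })
  rows <- apply(states[seq_len(nTip), , drop = FALSE], 1L, paste, collapse = "")
  aln <- Biostrings::AAStringSet(stats::setNames(rows, tree$tip.label))
  list(alignment = aln, manifest = planted)
}

#' Evolve an organism-paired pair of alignments with cross-protein coupling
#'
#' Simulates a single alignment of `lengthA + lengthB` columns on the tree
#' (so both proteins share the organisms' evolutionary history) and splits
#' it into two alignments. `crossPlanted` pairs couple a column of protein A
#' (`site_i`, in A's coordinates) with a column of protein B (`site_j`, in
#' B's coordinates).
#'
#' @inheritParams evolveAlignment
#' @param lengthA,lengthB column counts of the two proteins.
#' @param crossPlanted data.frame with `site_i` (column of A), `site_j`
#'   (column of B), `rho`.
#' @return list: `a`, `b` (AAStringSet alignments over the tree leaves) and
#'   `manifest` (cross pairs in per-protein coordinates).
#' @export
evolveProteinPair <- function(tree, lengthA, lengthB, frequencies = NULL,
                              crossPlanted = NULL, seed = 1L) {
  planted <- if (is.null(crossPlanted)) NULL else
    data.frame(site_i = crossPlanted$site_i,
               site_j = crossPlanted$site_j + lengthA,
               rho = crossPlanted$rho)
  sim <- evolveAlignment(tree, lengthA + lengthB, frequencies = frequencies,
                         planted = planted, seed = seed)
  list(a = Biostrings::subseq(sim$alignment, 1L, lengthA),
       b = Biostrings::subseq(sim$alignment, lengthA + 1L, lengthA + lengthB),
       manifest = if (is.null(crossPlanted))
         data.frame(site_i = integer(0), site_j = integer(0), rho = numeric(0))
       else crossPlanted)
}

#' Reverse-translate a protein alignment into a coding alignment
#'
#' Emits an in-frame CDS alignment: each residue becomes a codon (gaps
#' become `---`). Per cell, with probability `synDivergence` a random
#' synonymous codon is used instead of the canonical codon of that residue,
#' giving tunable synonymous divergence between sequences while the protein
#' translation is unchanged.
#'
#' @param aln protein alignment (`XStringSet` or character matrix).
#' @param synDivergence probability of a non-canonical synonymous codon per
#'   cell (0 gives identical codons for identical residues).
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] of width 3x the protein width.
#' @export
emitCDS <- function(aln, synDivergence = 0.2, seed = 1L) {
  m <- alignmentMatrix(aln)
  gc <- Biostrings::GENETIC_CODE
  codonsOf <- split(names(gc), unname(gc))
  canonical <- vapply(codonsOf, `[`, "", 1L)
  bad <- setdiff(unique(as.vector(m)), c(AA20, "-", "."))
  if (base::length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  out <- withSeed(seed, {
    vapply(seq_len(nrow(m)), function(r) {
      cod <- character(ncol(m))
      for (j in seq_len(ncol(m))) {
        a <- m[r, j]
        if (a == "-" || a == ".") { cod[j] <- "---"; next }
        syn <- codonsOf[[a]]
        cod[j] <- if (base::length(syn) > 1L && stats::runif(1) < synDivergence)
          sample(syn, 1L) else canonical[[a]]
      }
      paste(cod, collapse = "")
    }, "")
  })
  Biostrings::DNAStringSet(stats::setNames(out, rownames(m)))
}

runifBall <- function(n, radius) {
  dir <- matrix(stats::rnorm(3L * n), n, 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  dir * radius * stats::runif(n)^(1 / 3)
}

#' Generate a toy structure with spatially compact residue groups
#'
#' Places `nResidues` single-carbon residues: background residues uniformly
#' in a cube sized so their mean pairwise distance is about `spread`
#' angstrom, and each designated group inside a ball of diameter just under
#' `clusterRadius`, so all its pairwise proximal-carbon distances are below
#' `clusterRadius` by construction.
#'
#' @param nResidues total residue count.
#' @param groups named list of disjoint integer vectors (residue numbers of
#'   each compact group).
#' @param clusterRadius upper bound on within-group pairwise distances
#'   (default 4 angstrom).
#' @param spread target mean pairwise distance of the background residues
#'   (default 40 angstrom; must exceed `clusterRadius`).
#' @param seed integer seed.
#' @param ss optional character vector of per-residue secondary-structure
#'   classes (`helix`, `strand`, `coil`); default all coil.
#' @return a [StructureModel-class] (chain "A", one CA carbon per residue).
#' @export
syntheticStructure <- function(nResidues, groups = list(), clusterRadius = 4,
                               spread = 40, seed = 1L, ss = NULL) {
  if (clusterRadius <= 0) stop("clusterRadius must be positive")
  if (clusterRadius >= spread) stop("clusterRadius must be below spread")
  gAll <- unlist(groups)
  if (anyDuplicated(gAll)) stop("groups must be disjoint")
  if (base::length(gAll) && (max(gAll) > nResidues || min(gAll) < 1))
    stop("group residue numbers out of range")
  side <- spread / 0.6617  # mean pairwise distance of a uniform cube
  xyz <- withSeed(seed, {
    co <- matrix(stats::runif(3L * nResidues, 0, side), nResidues, 3L)
    for (g in groups) {
      center <- stats::runif(3L, clusterRadius, side - clusterRadius)
      co[g, ] <- rep(center, each = base::length(g)) +
        runifBall(base::length(g), 0.475 * clusterRadius)
    }
    co
  })
  for (g in groups) {
    D <- as.matrix(stats::dist(xyz[g, , drop = FALSE]))
    if (any(D[upper.tri(D)] >= clusterRadius))
      stop("infeasible packing: group exceeds clusterRadius")
  }
  if (is.null(ss)) ss <- rep("coil", nResidues)
  stopifnot(base::length(ss) == nResidues,
            all(ss %in% c("helix", "strand", "coil")))
  atoms <- data.frame(resno = seq_len(nResidues), resid = "ALA",
                      elety = "CA", elesy = "C",
                      x = round(xyz[, 1L], 3), y = round(xyz[, 2L], 3),
                      z = round(xyz[, 3L], 3), stringsAsFactors = FALSE)
  new("StructureModel", chain = "A", atoms = atoms,
      ss = stats::setNames(ss, as.character(seq_len(nResidues))))
}
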