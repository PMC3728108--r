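aaSet <- function(...) {
  x <- c(...)
  Biostrings::AAStringSet(x)
}

writeFastaLines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# StructureModel from residue numbers / names, one CA carbon per residue at
# given coordinates (matrix n x 3)
makeStructure <- function(resno, resid, xyz, ss = NULL, chain = "A") {
  if (is.null(ss)) ss <- rep("coil", length(resno))
  atoms <- data.frame(resno = resno, resid = resid, elety = "CA",
                      elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  new("StructureModel", chain = chain, atoms = atoms,
      ss = stats::setNames(ss, as.character(resno)))
}

# hand-written PDB: 3 residues (GLY1, ALA2, CYS3) chain A, helix over 2-3
toyPDBFile <- function() {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HELIX    1  H1 ALA A    2  CYS A    3  1                                   2",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   2       4.500   1.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  CYS A   3       8.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  f
}

# uniform divergence-time matrix (off-diagonal 1) over n sequences
unitTimes <- function(ids) {
  n <- length(ids)
  t <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(t) <- 0
  t
}

# brute-force centralities by exhaustive simple-path enumeration (n <= ~7)
bruteCentrality <- function(adj) {
  n <- nrow(adj)
  allPaths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return() }
      for (w in which(adj[v, ] == 1)) if (!w %in% path) walk(c(path, w))
    }
    walk(s)
    out
  }
  degree <- rowSums(adj)
  between <- numeric(n)
  closeness <- numeric(n)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  D <- matrix(Inf, n, n)
  shortest <- vector("list", 0)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    if (comp[s] != comp[t]) next
    paths <- allPaths(s, t)
    lens <- vapply(paths, length, 1L) - 1L
    mn <- min(lens)
    D[s, t] <- D[t, s] <- mn
    sp <- paths[lens == mn]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      onpath <- vapply(sp, function(p) v %in% p, TRUE)
      between[v] <- between[v] + sum(onpath) / length(sp)
    }
  }
  for (v in seq_len(n)) {
    peers <- setdiff(which(comp == comp[v]), v)
    closeness[v] <- if (length(peers) == 0L) 0 else
      length(peers) / sum(D[v, peers])
  }
  list(degree = degree, closeness = closeness, betweenness = between)
}

# small planted-pair dataset reused by pipeline tests (built once per run)
plantedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- simulateTree(24, 0.4, seed = 71)
      pl <- data.frame(site_i = c(5L, 20L, 35L), site_j = c(10L, 25L, 40L),
                       rho = 1)
      sim <- evolveAlignment(tr, 80, planted = pl, seed = 72)
      cache <<- list(tree = tr, aln = sim$alignment, planted = pl)
    }
    cache
  }
})

# 20 x 21 alignment engineered so that columns 1 and 2 have modal residue A
# with frequency 0.5 and the alignment-wide background of A is exactly
# 21/420 = 0.05. `overlap` controls which rows of column 2 carry A.
workedAlignment <- function(overlap = 1:10) {
  others <- c("C", "D", "E", "F", "G", "H", "I", "K", "L", "M")
  m <- matrix("V", 20, 21)
  m[, 1] <- c(rep("A", 10), others)
  m[, 2] <- "V"
  m[overlap, 2] <- "A"
  m[setdiff(1:20, overlap), 2] <- others
  m[1, 3] <- "A"  # 21st A so q_A = 0.05 exactly
  rownames(m) <- paste0("s", 1:20)
  m
}
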