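#' Remove redundant (identical) sequences
#'
#' Drops sequences whose residue string is identical to an earlier sequence,
#' keeping the first occurrence as the representative.
#'
#' @param aln an `XStringSet` alignment.
#' @return the deduplicated alignment (same class, original order).
#' @export
deduplicate <- function(aln) {
  keep <- !duplicated(as.character(aln))
  aln[keep]
}

#' Keep one sequence per species
#'
#' Removes within-species gene duplicates: for every species only the first
#' sequence (input order) is retained.
#'
#' @param aln an `XStringSet` alignment.
#' @param speciesOfId named character vector mapping every sequence id to a
#'   species label.
#' @return the filtered alignment.
#' @export
dropWithinSpeciesDuplicates <- function(aln, speciesOfId) {
  ids <- names(aln)
  missing <- setdiff(ids, names(speciesOfId))
  if (length(missing))
    stop("id(s) missing from species mapping: ", paste(missing, collapse = ", "))
  sp <- speciesOfId[ids]
  aln[!duplicated(sp)]
}

#' Restrict two alignments to shared organisms, in matched row order
#'
#' Used to prepare inter-protein analyses: both alignments are restricted to
#' the organisms present in both, and rows are ordered identically (by sorted
#' organism label) so row i of each output belongs to the same organism.
#'
#' @param alnA,alnB `XStringSet` alignments.
#' @param organismOfId named character vector mapping every id of both
#'   alignments to an organism.
#' @return list with elements `a`, `b` (the paired alignments) and
#'   `organisms` (the common organism labels, in row order).
#' @export
pairByOrganism <- function(alnA, alnB, organismOfId) {
  missing <- setdiff(c(names(alnA), names(alnB)), names(organismOfId))
  if (length(missing))
    stop("id(s) missing from organism mapping: ", paste(missing, collapse = ", "))
  orgA <- organismOfId[names(alnA)]
  orgB <- organismOfId[names(alnB)]
  common <- sort(intersect(orgA, orgB))
  if (length(common) == 0L) stop("no organisms shared between the alignments")
  # first sequence per organism, then the common organisms in sorted order
  ia <- match(common, orgA)
  ib <- match(common, orgB)
  list(a = alnA[ia], b = alnB[ib], organisms = common)
}

#' Pairwise p-distance matrix
#'
#' Fraction of mismatching positions per sequence pair, computed over the
#' columns where both sequences are ungapped (pairwise deletion).
#'
#' @param aln alignment (`XStringSet` or character matrix).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistances <- function(aln) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("pairwise distances need at least 2 sequences")
  ug <- m != "-" & m != "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    both <- ug[i, ] & ug[j, ]
    nb <- sum(both)
    if (nb == 0L)
      stop("sequences ", rownames(m)[i], " and ", rownames(m)[j],
           " share no ungapped columns")
    d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / nb
  }
  d
}

#' Mean pairwise sequence divergence
#'
#' Mean over all unordered sequence pairs of the pairwise p-distance
#' (pairwise deletion of gapped columns).
#'
#' @param aln alignment (`XStringSet` or character matrix).
#' @return a fraction in \[0, 1\].
#' @export
meanDivergence <- function(aln) {
  d <- pDistances(aln)
  mean(d[upper.tri(d)])
}

#' Neighbor-joining tree from p-distances
#'
#' Builds a neighbor-joining tree from the pairwise p-distance matrix;
#' negative branch lengths (an NJ artifact) are clamped to zero.
#'
#' @param aln alignment with at least 3 sequences.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 sequences")
  tr <- ape::nj(pDistances(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Map alignment columns to structure residue numbers
#'
#' Maps the k-th ungapped column of the reference row to the k-th residue of
#' the structure chain; gap columns of the reference are unmapped. The
#' ungapped reference sequence must be the same length as the chain; residue
#' identity mismatches are reported as an attribute, not an error (the
#' alignment and the crystal sequence may legitimately differ at a few
#' positions).
#'
#' @param aln alignment containing the reference sequence.
#' @param refId identifier of the reference row.
#' @param structure a [StructureModel-class].
#' @return named integer vector: names are alignment columns (character),
#'   values structure residue numbers. Attribute `mismatches` lists columns
#'   whose reference residue differs from the structure residue name.
#' @export
columnToResidueMap <- function(aln, refId, structure) {
  m <- alignmentMatrix(aln)
  if (!refId %in% rownames(m)) stop("reference id not in alignment: ", refId)
  row <- m[refId, ]
  cols <- which(row != "-" & row != ".")
  resno <- residueNumbers(structure)
  if (length(cols) != length(resno))
    stop("ungapped reference length (", length(cols),
         ") does not match structure residue count (", length(resno), ")")
  map <- stats::setNames(resno, as.character(cols))
  aa3 <- structure@atoms$resid[match(resno, structure@atoms$resno)]
  aa1 <- threeToOne(aa3)
  mm <- cols[!is.na(aa1) & aa1 != row[cols]]
  attr(map, "mismatches") <- mm
  map
}

threeToOne <- function(x) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  unname(tab[toupper(x)])
}
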