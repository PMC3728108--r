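#' Read a multiple sequence alignment from FASTA
#'
#' Reads a gapped FASTA alignment. The sequence identifier is the first
#' whitespace-delimited token of the header; the remainder of the header is
#' ignored, which keeps identifiers joinable with trees and clade tables.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` (default) or `"dna"`.
#' @return an [Biostrings::AAStringSet] (or `DNAStringSet`) whose members all
#'   have equal width; the gap character is `-`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACD-", ">s2", "AC-E"), fa)
#' aln <- readAlignment(fa)
#' @export
readAlignment <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  aln <- if (alphabet == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  if (length(aln) == 0L) stop("empty alignment file: ", path)
  names(aln) <- vapply(strsplit(names(aln), "\\s+"), `[`, "", 1L)
  validateAlignment(aln)
  aln
}

validateAlignment <- function(aln) {
  if (length(aln) < 2L) stop("an alignment needs at least 2 sequences")
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("ragged alignment: sequences have unequal lengths (",
         paste(range(Biostrings::width(aln)), collapse = "-"), ")")
  dup <- unique(names(aln)[duplicated(names(aln))])
  if (length(dup))
    stop("duplicated sequence identifier(s): ", paste(dup, collapse = ", "))
  invisible(aln)
}

#' Alignment as a character matrix
#'
#' @param aln an `XStringSet` alignment or a character matrix (returned
#'   unchanged).
#' @return character matrix, rows = sequences (named), columns = alignment
#'   positions (1-based).
#' @export
alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  m <- as.matrix(aln)
  rownames(m) <- names(aln)
  m
}

#' Read a phylogenetic tree from Newick
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick text; overrides `path`.
#' @return an [ape::phylo] tree with non-negative branch lengths.
#' @export
readTree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else {
    if (!file.exists(path)) stop("tree file not found: ", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("unparsable Newick input")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tr
}

#' Read one chain of a PDB structure
#'
#' Parses ATOM records of the requested chain (first altLoc kept) and assigns
#' each residue a secondary-structure class from HELIX/SHEET records
#' (`coil` otherwise).
#'
#' @param path path to a PDB-format file.
#' @param chain chain identifier (default `"A"`).
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, chain = "A") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain)
  # keep first altLoc per (residue, atom name)
  at <- at[!duplicated(at[, c("resno", "elety")]), , drop = FALSE]
  atoms <- data.frame(resno = at$resno, resid = at$resid, elety = at$elety,
                      elesy = at$elesy, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  resno <- unique(atoms$resno)
  ss <- stats::setNames(rep("coil", length(resno)), as.character(resno))
  markRange <- function(tbl, cls) {
    if (is.null(tbl) || length(tbl$start) == 0L) return()
    for (k in seq_along(tbl$start)) {
      if (!is.null(tbl$chain) && !is.na(tbl$chain[k]) &&
          tbl$chain[k] != chain) next
      hit <- resno >= as.integer(tbl$start[k]) & resno <= as.integer(tbl$end[k])
      ss[hit] <<- cls
    }
  }
  markRange(pdb$helix, "helix")
  markRange(pdb$sheet, "strand")
  new("StructureModel", chain = chain, atoms = atoms, ss = ss)
}

#' Write a StructureModel as PDB text
#'
#' Emits HELIX/SHEET records for contiguous runs of the corresponding
#' secondary-structure class, followed by ATOM records. Output is
#' deterministic for a given object.
#'
#' @param structure a [StructureModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  lines <- character(0)
  resno <- residueNumbers(structure)
  ss <- structure@ss[as.character(resno)]
  at <- structure@atoms
  resName <- function(r) at$resid[match(r, at$resno)]
  runs <- function(cls) {
    inCls <- ss == cls
    if (!any(inCls)) return(NULL)
    r <- rle(inCls)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  h <- runs("helix")
  if (!is.null(h)) for (k in seq_len(nrow(h)))
    lines <- c(lines, sprintf(
      "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d %2d%30s%6d",
      k, sprintf("H%d", k), resName(resno[h[k, 1]]), structure@chain,
      resno[h[k, 1]], resName(resno[h[k, 2]]), structure@chain,
      resno[h[k, 2]], 1L, "", h[k, 2] - h[k, 1] + 1L))
  s <- runs("strand")
  if (!is.null(s)) for (k in seq_len(nrow(s)))
    lines <- c(lines, sprintf(
      "SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d  0",
      k, sprintf("S%d", k), 1L, resName(resno[s[k, 1]]), structure@chain,
      resno[s[k, 1]], resName(resno[s[k, 2]]), structure@chain,
      resno[s[k, 2]]))
  for (i in seq_len(nrow(at)))
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      i, paste0(" ", at$elety[i]), at$resid[i], structure@chain, at$resno[i],
      at$x[i], at$y[i], at$z[i], at$elesy[i]))
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read an organism/clade mapping table
#'
#' @param path TSV with a header; recognised columns: `id`, `organism`,
#'   `species`, `clade`.
#' @return data.frame.
#' @export
readCladeMap <- function(path) {
  if (!file.exists(path)) stop("clade map not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(m)) stop("clade map needs an 'id' column")
  m
}

#' Write a result bundle to disk
#'
#' Writes `pairs.tsv`, `support.tsv`, `edges.tsv`, `centrality.tsv`,
#' `sectors.tsv` and `provenance.json` into `outDir`. Tables are sorted by
#' their site-index key columns so reruns with identical inputs are
#' byte-identical.
#'
#' @param bundle a [ResultBundle-class].
#' @param outDir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writeResults <- function(bundle, outDir) {
  stopifnot(is(bundle, "ResultBundle"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  wt <- function(df, file, key = NULL) {
    if (!is.null(key) && nrow(df) > 0) {
      key <- intersect(key, names(df))
      if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
    }
    p <- file.path(outDir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(bundle@pairs, "pairs.tsv", c("protein_a", "site_a", "protein_b", "site_b")),
    wt(bundle@support, "support.tsv", c("site_a", "site_b")),
    wt(bundle@edges, "edges.tsv", c("node_a", "node_b")),
    wt(bundle@centrality, "centrality.tsv", "node"),
    wt(bundle@sectors, "sectors.tsv", c("clade_1", "clade_2", "domain")))
  pj <- file.path(outDir, "provenance.json")
  jsonlite::write_json(bundle@provenance, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, pj))
}
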