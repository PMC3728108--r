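#' @import methods
NULL

#' Protein structure model (one chain)
#'
#' Minimal structure container for a single chain: per-atom coordinates and a
#' per-residue secondary-structure class. Built by [readStructure()] from PDB
#' ATOM/HELIX/SHEET records or by [syntheticStructure()].
#'
#' @slot chain single chain identifier.
#' @slot atoms data.frame with columns `resno` (integer residue number),
#'   `resid` (3-letter residue name), `elety` (atom name), `elesy` (element
#'   symbol), `x`, `y`, `z` (angstrom).
#' @slot ss named character vector, one entry per residue (names are residue
#'   numbers), values in `helix`, `strand`, `coil`.
#'
#' @aliases StructureModel-class
#' @exportClass StructureModel
setClass("StructureModel",
  representation(chain = "character", atoms = "data.frame", ss = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("resno", "resid", "elety", "elesy", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  resno <- unique(a$resno)
  if (is.unsorted(resno, strictly = TRUE))
    return("residue numbers must be strictly increasing within the chain")
  if (!setequal(names(object@ss), as.character(resno)))
    return("ss must be named by every residue number")
  if (!all(object@ss %in% c("helix", "strand", "coil")))
    return("ss values must be helix, strand or coil")
  TRUE
})

#' @describeIn StructureModel residue numbers present in the chain
#' @param x,object a `StructureModel`
#' @export
residueNumbers <- function(x) unique(x@atoms$resno)

#' @describeIn StructureModel per-residue secondary-structure classes
#' @export
secondaryStructure <- function(x) x@ss

#' @describeIn StructureModel atom table (data.frame)
#' @export
atomTable <- function(x) x@atoms

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel: chain", object@chain, "-",
      length(residueNumbers(object)), "residues,",
      nrow(object@atoms), "atoms\n")
  cat("  secondary structure:",
      paste(sprintf("%s=%d", names(table(object@ss)), table(object@ss)),
            collapse = " "), "\n")
})

#' Null distribution of the covariation statistic
#'
#' Empirical null sample of pair correlations obtained from neutrally
#' evolving alignments simulated on the study tree, together with the derived
#' significance threshold. Built by [buildNull()].
#'
#' @slot sample sorted numeric vector of null correlation coefficients.
#' @slot threshold correlation threshold at the `1 - alpha` level.
#' @slot alpha significance level the threshold corresponds to.
#' @slot nSim number of simulated alignments pooled.
#' @slot seed integer seed the null was built from.
#' @slot params list of generator settings (alignment length, frequencies,
#'   cross-protein flag).
#'
#' @aliases CoevNull-class
#' @exportClass CoevNull
setClass("CoevNull",
  representation(sample = "numeric", threshold = "numeric", alpha = "numeric",
                 nSim = "integer", seed = "integer", params = "list"))

setValidity("CoevNull", function(object) {
  if (length(object@sample) < 10L) return("null sample too small")
  if (is.unsorted(object@sample)) return("null sample must be sorted")
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must be in (0,1)")
  TRUE
})

#' @describeIn CoevNull the `1 - alpha` null correlation threshold
#' @param x,object a `CoevNull`
#' @export
nullThreshold <- function(x) x@threshold

#' @describeIn CoevNull the pooled (sorted) null correlation sample
#' @export
nullSample <- function(x) x@sample

setMethod("show", "CoevNull", function(object) {
  cat("CoevNull:", length(object@sample), "pooled null correlations from",
      object@nSim, "simulated alignments\n")
  cat(sprintf("  threshold r* = %.4f at alpha = %g (seed %d)\n",
              object@threshold, object@alpha, object@seed))
})

#' Scored site pairs from a coevolution scan
#'
#' All scored column pairs of an intra- or inter-protein analysis, including
#' skipped pairs with their reason, plus the parameters that produced them.
#' Built by [detectIntra()] and [detectInter()].
#'
#' @slot pairs data.frame with columns `protein_a`, `site_a`, `residue_a`,
#'   `protein_b`, `site_b`, `residue_b`, `r`, `p`, `significant`,
#'   `skip_reason`, and for inter-protein scans `site_a_in_intra`,
#'   `site_b_in_intra`.
#' @slot params list of analysis parameters (alpha, null seed, mode, ...).
#' @slot proteins protein tag(s) of the scan.
#'
#' @aliases CoevPairs-class
#' @exportClass CoevPairs
setClass("CoevPairs",
  representation(pairs = "data.frame", params = "list", proteins = "character"))

setValidity("CoevPairs", function(object) {
  p <- object@pairs
  need <- c("protein_a", "site_a", "protein_b", "site_b", "r", "p",
            "significant", "skip_reason")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns", paste(need, collapse = ", ")))
  ok <- !is.na(p$p)
  if (any(p$p[ok] < 0 | p$p[ok] > 1)) return("p values must lie in [0,1]")
  intra <- p$protein_a == p$protein_b
  if (any(p$site_a[intra] >= p$site_b[intra]))
    return("within one protein site_a must be < site_b")
  TRUE
})

#' @describeIn CoevPairs full table of scored pairs
#' @param x,object a `CoevPairs`
#' @export
pairTable <- function(x) x@pairs

#' @describeIn CoevPairs subset of pairs flagged significant
#' @export
significantPairs <- function(x) {
  p <- x@pairs
  p[!is.na(p$significant) & p$significant, , drop = FALSE]
}

setMethod("show", "CoevPairs", function(object) {
  p <- object@pairs
  cat("CoevPairs:", paste(object@proteins, collapse = " x "), "-",
      nrow(p), "scored pairs,",
      sum(p$significant, na.rm = TRUE), "significant at alpha =",
      object@params$alpha, "\n")
})

#' Result bundle of a pipeline run
#'
#' Container for the tables produced by [runIntra()], [runInter()] and
#' [runCladeComparison()], with a provenance block recording the seed and
#' parameters. Serialized to TSV/JSON by [writeResults()].
#'
#' @slot pairs scored pair table (data.frame).
#' @slot support bootstrap support table (data.frame).
#' @slot centrality node centrality table (data.frame).
#' @slot edges network edge list (data.frame).
#' @slot sectors clade-comparison (independence test) table (data.frame).
#' @slot structure structure statistics (list; may be empty).
#' @slot provenance list: seed, parameters, input summaries.
#'
#' @aliases ResultBundle-class
#' @exportClass ResultBundle
setClass("ResultBundle",
  representation(pairs = "data.frame", support = "data.frame",
                 centrality = "data.frame", edges = "data.frame",
                 sectors = "data.frame", structure = "list",
                 provenance = "list"))

setMethod("show", "ResultBundle", function(object) {
  cat("ResultBundle:", nrow(object@pairs), "pairs,",
      nrow(object@support), "support records,",
      nrow(object@edges), "edges,",
      nrow(object@sectors), "sector comparisons\n")
})

#' @describeIn ResultBundle provenance block (seed, parameters)
#' @param x,object a `ResultBundle`
#' @export
provenance <- function(x) x@provenance
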