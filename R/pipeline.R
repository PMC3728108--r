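#' Conventional GroEL domain boundaries
#'
#' Residue ranges of the three GroEL domains in the E. coli numbering
#' commonly used with the GroES-GroEL crystal structure: equatorial
#' (1-133 and 409-548), intermediate (134-190 and 374-408) and apical
#' (191-373). These are configuration defaults for [runCladeComparison()]
#' and structure summaries; adjust them for other numberings.
#'
#' @return data.frame with columns `domain`, `start`, `end` (closed
#'   intervals).
#' @export
groELDomains <- function() {
  data.frame(
    domain = c("equatorial", "intermediate", "apical", "intermediate",
               "equatorial"),
    start = c(1L, 134L, 191L, 374L, 409L),
    end = c(133L, 190L, 373L, 408L, 548L))
}

#' Assemble a pipeline configuration
#'
#' Collects inputs and parameters for [runIntra()], [runInter()] and
#' [runCladeComparison()]. Inputs may be in-memory objects or file paths
#' (FASTA / Newick / PDB / TSV); paths are loaded lazily by the run
#' functions. Parameter defaults are the study-scale settings
#' (`alpha = 0.001`, 100000 pooled null samples, 1000 bootstrap replicates,
#' support threshold 0.70, 1000 random groups); scale `nullSim`,
#' `nullSamples` and `bootReps` down for exploratory runs.
#'
#' @param alignment protein alignment (`XStringSet`, matrix, or FASTA path).
#' @param tree optional [ape::phylo] or Newick path; built by [njTree()]
#'   when absent.
#' @param alignmentB second protein alignment for inter-protein runs.
#' @param organismOfId named vector mapping ids of both alignments to
#'   organisms (inter-protein runs).
#' @param speciesOfId optional named vector for within-species paralog
#'   removal.
#' @param structure optional [StructureModel-class] or PDB path.
#' @param chain chain to read when `structure` is a path.
#' @param refId alignment id of the structure's sequence (enables
#'   column-to-residue mapping).
#' @param proteins protein tag(s) used in outputs.
#' @param groups data.frame (`clade`, `domain`, `column`) of per-clade
#'   coevolving site groups for [runCladeComparison()].
#' @param domains data.frame (`domain`, `start`, `end`) of domain column
#'   ranges (closed intervals) supplying the random-group pools.
#' @param alpha significance level for pair detection.
#' @param nullSim simulated alignments pooled into the null.
#' @param nullSamples pooled null correlation sample cap.
#' @param bootReps bootstrap replicates.
#' @param bootFraction per-replicate sequence sampling fraction.
#' @param supportThreshold retention threshold on bootstrap support
#'   (strict).
#' @param nRandomGroups null replicates of the independence test.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param intraA,intraB optional [CoevPairs-class] intra results used to
#'   annotate inter-protein sites.
#' @param capsInternalResamples optional named vector of per-clade resample
#'   counts as used by the original CAPS program. Accepted and recorded in
#'   provenance for configuration compatibility, but semantically inert:
#'   the program's documentation does not define the quantity precisely
#'   enough to assert behaviour on it.
#' @return a `coevConfig` list.
#' @export
coevConfig <- function(alignment, tree = NULL, alignmentB = NULL,
                       organismOfId = NULL, speciesOfId = NULL,
                       structure = NULL, chain = "A", refId = NULL,
                       proteins = c("protA", "protB"),
                       groups = NULL, domains = NULL,
                       alpha = 0.001, nullSim = 10L, nullSamples = 1e5L,
                       bootReps = 1000L, bootFraction = 0.8,
                       supportThreshold = 0.70, nRandomGroups = 1000L,
                       seed = 1L, intraA = NULL, intraB = NULL,
                       capsInternalResamples = NULL) {
  stopifnot(alpha > 0, alpha < 1,
            bootFraction > 0, bootFraction <= 1,
            supportThreshold >= 0, supportThreshold <= 1,
            seed == as.integer(seed))
  cfg <- list(alignment = alignment, tree = tree, alignmentB = alignmentB,
              organismOfId = organismOfId, speciesOfId = speciesOfId,
              structure = structure, chain = chain, refId = refId,
              proteins = proteins, groups = groups, domains = domains,
              alpha = alpha, nullSim = as.integer(nullSim),
              nullSamples = as.integer(nullSamples),
              bootReps = as.integer(bootReps), bootFraction = bootFraction,
              supportThreshold = supportThreshold,
              nRandomGroups = as.integer(nRandomGroups),
              seed = as.integer(seed), intraA = intraA, intraB = intraB,
              capsInternalResamples = capsInternalResamples)
  class(cfg) <- "coevConfig"
  cfg
}

loadAlignment <- function(x, alphabet = "protein") {
  if (is.character(x) && length(x) == 1L) readAlignment(x, alphabet) else x
}

loadTree <- function(x) {
  if (is.character(x) && length(x) == 1L) readTree(x) else x
}

loadStructure <- function(x, chain) {
  if (is.character(x) && length(x) == 1L) readStructure(x, chain) else x
}

baseProvenance <- function(cfg, extra = list()) {
  c(list(seed = cfg$seed,
         parameters = list(alpha = cfg$alpha, nullSim = cfg$nullSim,
                           nullSamples = cfg$nullSamples,
                           bootReps = cfg$bootReps,
                           bootFraction = cfg$bootFraction,
                           supportThreshold = cfg$supportThreshold,
                           nRandomGroups = cfg$nRandomGroups,
                           capsInternalResamples = cfg$capsInternalResamples)),
    extra)
}

structureStats <- function(structure, siteMap, sites, seed) {
  res <- unname(siteMap[as.character(sites)])
  res <- res[!is.na(res)]
  if (length(res) < 2L) return(list())
  pool <- unname(siteMap)
  out <- list(
    residues = res,
    compactness = groupCompactness(structure, res),
    background = meanPairwiseDistance(structure, pool),
    cluster_p = as.numeric(clusterSignificance(structure, res, pool,
                                               nRandom = 1000L, seed = seed)))
  enr <- tryCatch(ssEnrichment(structure, res), error = function(e) NULL)
  if (!is.null(enr))
    out$enrichment <- c(enr[c("chisq", "df", "p")], list(table = enr$table))
  out
}

#' Run the intra-protein coevolution pipeline
#'
#' Preprocess (deduplicate, optional within-species paralog removal) ->
#' build/accept tree -> simulated-alignment null -> pair detection ->
#' phylogenetic bootstrap -> network and centralities -> optional structure
#' mapping with compactness and secondary-structure enrichment.
#'
#' @param config a [coevConfig()].
#' @return a [ResultBundle-class].
#' @export
runIntra <- function(config) {
  stopifnot(inherits(config, "coevConfig"))
  aln <- loadAlignment(config$alignment)
  aln <- deduplicate(aln)
  if (!is.null(config$speciesOfId))
    aln <- dropWithinSpeciesDuplicates(aln, config$speciesOfId)
  tree <- loadTree(config$tree)
  if (is.null(tree)) tree <- njTree(aln)
  structure <- loadStructure(config$structure, config$chain)
  siteMap <- if (!is.null(structure) && !is.null(config$refId))
    columnToResidueMap(aln, config$refId, structure) else NULL
  null <- buildNull(aln, tree, nSim = config$nullSim,
                    nSamples = config$nullSamples, alpha = config$alpha,
                    seed = config$seed)
  pairs <- detectIntra(aln, tree, alpha = config$alpha, null = null,
                       protein = config$proteins[1L], siteMap = siteMap)
  support <- bootstrapPairs(aln, tree, pairs, nReps = config$bootReps,
                            fraction = config$bootFraction,
                            threshold = config$supportThreshold,
                            alpha = config$alpha, seed = config$seed)
  retained <- support[support$retained, , drop = FALSE]
  net <- buildNetwork(retained)
  strStats <- if (!is.null(siteMap) && nrow(retained))
    structureStats(structure, siteMap,
                   unique(c(retained$site_a, retained$site_b)), config$seed)
  else list()
  new("ResultBundle", pairs = pairTable(pairs), support = support,
      centrality = centralityTable(net), edges = edgeTable(net),
      sectors = data.frame(), structure = strStats,
      provenance = baseProvenance(config, list(
        mode = "intra", protein = config$proteins[1L],
        nSequences = length(aln),
        nColumns = unique(Biostrings::width(aln))[1L],
        nullThreshold = nullThreshold(null),
        bootstrapFailures = attr(support, "failures"))))
}

#' Run the inter-protein coevolution pipeline
#'
#' Pairs the two alignments by organism, scores all cross-protein column
#' pairs against a dedicated cross-protein null, bootstraps the significant
#' pairs, and builds the cross-protein network. Sites also present in
#' supplied intra-protein results are flagged (candidate indirect
#' dependencies).
#'
#' @param config a [coevConfig()] with `alignmentB` and `organismOfId` set.
#' @return a [ResultBundle-class].
#' @export
runInter <- function(config) {
  stopifnot(inherits(config, "coevConfig"))
  alnA <- loadAlignment(config$alignment)
  alnB <- loadAlignment(config$alignmentB)
  if (is.null(config$organismOfId))
    stop("inter-protein runs need organismOfId")
  paired <- pairByOrganism(alnA, alnB, config$organismOfId)
  tree <- loadTree(config$tree)
  if (is.null(tree)) tree <- njTree(paired$a)
  null <- buildNull(paired$a, tree, nSim = config$nullSim,
                    nSamples = config$nullSamples, alpha = config$alpha,
                    seed = config$seed,
                    crossLength = unique(Biostrings::width(paired$b))[1L])
  pairs <- detectInter(paired$a, paired$b, tree, alpha = config$alpha,
                       null = null, proteins = config$proteins,
                       intraA = config$intraA, intraB = config$intraB)
  support <- bootstrapPairs(paired$a, tree, pairs, nReps = config$bootReps,
                            fraction = config$bootFraction,
                            threshold = config$supportThreshold,
                            alpha = config$alpha, seed = config$seed,
                            aln2 = paired$b)
  retained <- support[support$retained, , drop = FALSE]
  net <- buildNetwork(retained)
  new("ResultBundle", pairs = pairTable(pairs), support = support,
      centrality = centralityTable(net), edges = edgeTable(net),
      sectors = data.frame(), structure = list(),
      provenance = baseProvenance(config, list(
        mode = "inter", proteins = config$proteins,
        nOrganisms = length(paired$organisms),
        nullThreshold = nullThreshold(null),
        bootstrapFailures = attr(support, "failures"))))
}

#' Compare coevolving site groups between clades
#'
#' For every clade pair and protein domain with non-empty groups, runs the
#' entropy-based [independenceTest()] with the domain's column range as the
#' random-group pool. Clades with empty groups in a domain are skipped with
#' a notice.
#'
#' @param config a [coevConfig()] with `groups` and `domains` set.
#' @return a [ResultBundle-class] whose `sectors` slot holds the
#'   comparison table.
#' @export
runCladeComparison <- function(config) {
  stopifnot(inherits(config, "coevConfig"))
  aln <- loadAlignment(config$alignment)
  groups <- config$groups
  domains <- config$domains
  if (is.null(groups) || is.null(domains))
    stop("clade comparison needs groups and domains")
  rows <- list()
  counter <- 0L
  for (d in unique(domains$domain)) {
    dr <- domains[domains$domain == d, ][1L, ]
    pool <- seq.int(dr$start, dr$end)
    gd <- groups[groups$domain == d, , drop = FALSE]
    clades <- sort(unique(gd$clade))
    if (length(clades) < 2L) next
    for (a in seq_len(length(clades) - 1L)) for (b in seq.int(a + 1L, length(clades))) {
      g1 <- gd$column[gd$clade == clades[a]]
      g2 <- gd$column[gd$clade == clades[b]]
      if (length(g1) == 0L || length(g2) == 0L) {
        message("skipping ", clades[a], " vs ", clades[b], " in ", d,
                ": empty group")
        next
      }
      counter <- counter + 1L
      res <- independenceTest(aln, g1, g2, pool,
                              nRandom = config$nRandomGroups,
                              seed = config$seed + counter)
      rows[[counter]] <- cbind(data.frame(clade_1 = clades[a],
                                          clade_2 = clades[b], domain = d),
                               res)
    }
  }
  sectors <- if (length(rows)) do.call(rbind, rows) else data.frame()
  new("ResultBundle", pairs = data.frame(), support = data.frame(),
      centrality = data.frame(), edges = data.frame(), sectors = sectors,
      structure = list(),
      provenance = baseProvenance(config, list(mode = "clade_comparison")))
}
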