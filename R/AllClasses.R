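#' @import methods
NULL

#' Named gene sets over a gene universe
#'
#' A \code{GeneSetCollection} holds named gene sets (pathways, a disease
#' risk-gene list, ...) as character vectors of gene symbols. Symbols are
#' case-normalised to upper case by all readers and constructors; set ids are
#' unique and each set is deduplicated. The GMT description field is carried
#' along but never used in computation.
#'
#' @slot setIds character vector of unique set identifiers.
#' @slot descriptions character vector, parallel to \code{setIds}.
#' @slot members list of character vectors, parallel to \code{setIds}.
#'
#' @seealso [readGmt()], [restrictToUniverse()]
#' @export
setClass("GeneSetCollection",
  slots = c(setIds = "character", descriptions = "character",
            members = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  n <- length(object@setIds)
  if (length(object@descriptions) != n || length(object@members) != n)
    msg <- c(msg, "setIds, descriptions and members must have equal length")
  if (anyDuplicated(object@setIds))
    msg <- c(msg, "set ids must be unique")
  if (any(!nzchar(object@setIds)))
    msg <- c(msg, "set ids must be non-empty strings")
  bad <- vapply(object@members, function(m)
    !is.character(m) || any(!nzchar(m)) || anyDuplicated(m) > 0, logical(1))
  if (any(bad))
    msg <- c(msg, sprintf(
      "members must be deduplicated character vectors without empty strings (offending sets: %s)",
      paste(utils::head(object@setIds[bad], 3), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param members named list of character vectors (names become set ids).
#' @param descriptions optional character vector of per-set descriptions;
#'   recycled empty string by default.
#' @return A [GeneSetCollection-class] object. Members are upper-cased and
#'   deduplicated preserving first occurrence.
#' @examples
#' gsc <- GeneSetCollection(list(P1 = c("tp53", "BRCA1"), P2 = c("EGFR")))
#' setSizes(gsc)
#' @export
GeneSetCollection <- function(members, descriptions = NULL) {
  stopifnot(is.list(members), !is.null(names(members)))
  ids <- names(members)
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  members <- lapply(members, function(m) unique(toupper(as.character(m))))
  new("GeneSetCollection", setIds = ids,
      descriptions = as.character(descriptions),
      members = unname(members))
}

#' Regulator-to-target maps (miRNA or drug)
#'
#' A \code{TargetMap} stores the target gene sets of a single regulator class.
#' Gene symbols are upper-cased; miRNA identifiers are lower-cased so that
#' "hsa-miR-155-5p" and "hsa-mir-155-5p" collapse; drug identifiers are kept
#' verbatim. Duplicate (regulator, gene) pairs are collapsed.
#'
#' @slot targets named list of character vectors, one per regulator.
#' @slot regulatorClass either \code{"miRNA"} or \code{"drug"}.
#'
#' @seealso [readTargetMap()], [filterRegulators()]
#' @export
setClass("TargetMap",
  slots = c(targets = "list", regulatorClass = "character"))

setValidity("TargetMap", function(object) {
  msg <- character()
  if (length(object@regulatorClass) != 1L ||
      !object@regulatorClass %in% c("miRNA", "drug"))
    msg <- c(msg, "regulatorClass must be 'miRNA' or 'drug'")
  ids <- names(object@targets)
  if (length(object@targets) && (is.null(ids) || anyDuplicated(ids) ||
      any(!nzchar(ids))))
    msg <- c(msg, "regulator ids must be unique non-empty names")
  bad <- vapply(object@targets, function(m)
    !is.character(m) || anyDuplicated(m) > 0, logical(1))
  if (any(bad)) msg <- c(msg, "target sets must be deduplicated character vectors")
  if (length(msg)) msg else TRUE
})

#' Construct a TargetMap
#'
#' @param targets named list of character vectors (regulator id -> targets).
#' @param regulatorClass \code{"miRNA"} or \code{"drug"}.
#' @return A [TargetMap-class]. Genes are upper-cased and deduplicated;
#'   miRNA regulator ids are lower-cased.
#' @examples
#' tm <- TargetMap(list(`hsa-miR-1` = c("A", "a", "B")), "miRNA")
#' targetsOf(tm, "hsa-mir-1")
#' @export
TargetMap <- function(targets, regulatorClass = c("miRNA", "drug")) {
  regulatorClass <- match.arg(regulatorClass)
  stopifnot(is.list(targets))
  ids <- names(targets)
  if (regulatorClass == "miRNA" && length(ids)) ids <- tolower(ids)
  targets <- lapply(targets, function(m) unique(toupper(as.character(m))))
  if (anyDuplicated(ids)) {
    # case-collapsed ids can merge: union their targets
    targets <- lapply(split(targets, ids), function(x) unique(unlist(x)))
    ids <- names(targets)
  }
  names(targets) <- ids
  new("TargetMap", targets = targets, regulatorClass = regulatorClass)
}

#' Pathway over-representation result for one entity
#'
#' One row per pathway with at least one gene of the query in it (pathways
#' with zero overlap are omitted). \code{pathwayIds} records the full pathway
#' collection the table was computed against, which defines the label
#' universe for permutation of the profile.
#'
#' @slot entityId identifier of the query entity (disease, miRNA or drug).
#' @slot results data.frame with columns \code{pathway}, \code{N}, \code{K},
#'   \code{n}, \code{k}, \code{p_raw}, \code{p_adj}, \code{significant},
#'   sorted by ascending \code{p_raw} then pathway id.
#' @slot alpha significance threshold used for the \code{significant} flag.
#' @slot adjust \code{"none"} (flag on raw p) or \code{"BH"} (flag on
#'   Benjamini-Hochberg adjusted p).
#' @slot pathwayIds ids of every pathway in the collection tested.
#'
#' @seealso [enrich()], [permuteDiseaseProfile()]
#' @export
setClass("EnrichmentTable",
  slots = c(entityId = "character", results = "data.frame",
            alpha = "numeric", adjust = "character",
            pathwayIds = "character"))

setValidity("EnrichmentTable", function(object) {
  msg <- character()
  need <- c("pathway", "N", "K", "n", "k", "p_raw", "p_adj", "significant")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, paste("results must have columns:", paste(need, collapse = ", ")))
  else {
    r <- object@results
    if (anyDuplicated(r$pathway)) msg <- c(msg, "pathway ids must be unique")
    if (!all(r$pathway %in% object@pathwayIds))
      msg <- c(msg, "all result pathways must belong to pathwayIds")
    if (nrow(r)) {
      if (any(r$k < 0 | r$k > pmin(r$n, r$K)))
        msg <- c(msg, "k must satisfy 0 <= k <= min(n, K)")
      if (any(r$p_raw <= 0 | r$p_raw > 1)) msg <- c(msg, "p_raw must be in (0, 1]")
      ok <- is.na(r$p_adj) | r$p_adj >= r$p_raw - 1e-12
      if (!all(ok)) msg <- c(msg, "p_adj must be >= p_raw")
    }
  }
  if (!(length(object@alpha) == 1L && object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be a single value in (0, 1)")
  if (!(length(object@adjust) == 1L && object@adjust %in% c("none", "BH")))
    msg <- c(msg, "adjust must be 'none' or 'BH'")
  if (length(msg)) msg else TRUE
})

#' Tripartite miRNA-drug-pathway network (MDNG)
#'
#' An undirected simple graph whose nodes are pathways, miRNAs and drugs and
#' whose edges connect a regulator (miRNA or drug) to a pathway both it and
#' the disease gene set are significantly enriched in. Node names are
#' class-prefixed (\code{"pathway:"}, \code{"miRNA:"}, \code{"drug:"}) so ids
#' stay unique across classes; the unprefixed id is kept in the vertex
#' attribute \code{label}.
#'
#' @slot graph an \pkg{igraph} object with vertex attributes \code{name},
#'   \code{label} and \code{class}.
#' @slot partial logical; if \code{FALSE} (default) every pathway node is
#'   required to carry at least one miRNA and one drug edge.
#'
#' @seealso [buildMdng()], [degreeDistribution()], [topologicalCoefficient()]
#' @export
setClass("Mdng", slots = c(graph = "ANY", partial = "logical"))

setValidity("Mdng", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  msg <- character()
  cls <- igraph::V(g)$class
  if (is.null(cls) || !all(cls %in% c("pathway", "miRNA", "drug")))
    msg <- c(msg, "every node needs class 'pathway', 'miRNA' or 'drug'")
  if (anyDuplicated(igraph::V(g)$name)) msg <- c(msg, "node names must be unique")
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    c1 <- cls[ends[, 1]]; c2 <- cls[ends[, 2]]
    if (any((c1 == "pathway") == (c2 == "pathway")))
      msg <- c(msg, "edges must join exactly one pathway and one regulator")
  }
  deg <- igraph::degree(g)
  if (any(deg[cls != "pathway"] == 0))
    msg <- c(msg, "regulator nodes must have at least one edge")
  if (length(object@partial) != 1L)
    msg <- c(msg, "partial must be a single logical")
  else if (!object@partial && igraph::vcount(g)) {
    for (p in which(cls == "pathway")) {
      nb <- cls[igraph::neighbors(g, p)]
      if (!("miRNA" %in% nb) || !("drug" %in% nb)) {
        msg <- c(msg, "each pathway node must have both a miRNA and a drug edge")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Power-law fit of a degree distribution
#'
#' Parameters of \eqn{f(x) = a x^{b}} fitted by ordinary least squares of
#' \eqn{\log_{10}} count on \eqn{\log_{10}} degree, the convention used by
#' Cytoscape's NetworkAnalyzer.
#'
#' @slot a positive scale coefficient (\eqn{10^{\mathrm{intercept}}}).
#' @slot b exponent (slope on the log-log scale).
#' @slot rSquared coefficient of determination of the log-log regression.
#' @slot nPoints number of (degree, count) points used.
#'
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
  slots = c(a = "numeric", b = "numeric", rSquared = "numeric",
            nPoints = "integer"))

setValidity("PowerLawFit", function(object) {
  if (object@nPoints < 2L) return("a power-law fit needs at least 2 points")
  if (object@a <= 0) return("a must be positive")
  TRUE
})

#' Configuration of a synthetic study
#'
#' Parameters of the synthetic-study generator: a gene universe, overlapping
#' pathways, a disease gene set concentrated in designated risk pathways, and
#' miRNA/drug target maps in which "responsive" regulators draw a tunable
#' fraction of their targets from risk-pathway genes while "null" regulators
#' sample uniformly from the universe.
#'
#' @slot nGenes,nPathways,nRiskPathways,nDiseaseGenes,nMirnas,nDrugs,nResponsiveMirnas,nResponsiveDrugs integer scalars.
#' @slot pathwaySizeRange,targetsPerRegulatorRange integer ranges (min, max).
#' @slot diseaseSignal,regulatorSignal fractions in [0, 1] of members drawn
#'   from the risk-pathway union.
#' @slot seed integer seed; identical seeds give identical studies.
#'
#' @seealso [synthConfig()], [generateStudy()]
#' @export
setClass("SynthConfig",
  slots = c(nGenes = "integer", nPathways = "integer",
            pathwaySizeRange = "integer", nRiskPathways = "integer",
            nDiseaseGenes = "integer", diseaseSignal = "numeric",
            nMirnas = "integer", nDrugs = "integer",
            nResponsiveMirnas = "integer", nResponsiveDrugs = "integer",
            targetsPerRegulatorRange = "integer",
            regulatorSignal = "numeric", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  pos <- c(nGenes = object@nGenes, nPathways = object@nPathways)
  if (any(pos < 1L)) msg <- c(msg, "nGenes and nPathways must be >= 1")
  if (object@nRiskPathways < 0L || object@nRiskPathways > object@nPathways)
    msg <- c(msg, "nRiskPathways must lie in [0, nPathways]")
  if (object@nDiseaseGenes < 0L || object@nDiseaseGenes > object@nGenes)
    msg <- c(msg, "nDiseaseGenes must lie in [0, nGenes]")
  if (object@nResponsiveMirnas > object@nMirnas)
    msg <- c(msg, "nResponsiveMirnas must be <= nMirnas")
  if (object@nResponsiveDrugs > object@nDrugs)
    msg <- c(msg, "nResponsiveDrugs must be <= nDrugs")
  for (fr in c(object@diseaseSignal, object@regulatorSignal))
    if (is.na(fr) || fr < 0 || fr > 1)
      msg <- c(msg, "signal fractions must lie in [0, 1]")
  for (rg in list(object@pathwaySizeRange, object@targetsPerRegulatorRange))
    if (length(rg) != 2L || rg[1] > rg[2] || rg[1] < 1L)
      msg <- c(msg, "ranges must be ordered pairs of positive integers")
  if (object@pathwaySizeRange[2] > object@nGenes)
    msg <- c(msg, "pathway sizes cannot exceed the universe size")
  if (object@targetsPerRegulatorRange[2] > object@nGenes)
    msg <- c(msg, "target counts cannot exceed the universe size")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic study with ground truth
#'
#' Bundles everything the pipeline consumes — gene universe, pathway
#' collection, disease gene list, miRNA and drug target maps — together with
#' the planted truth (risk pathway ids, responsive regulator ids) and the
#' generating configuration.
#'
#' @slot universe character vector of gene symbols.
#' @slot pathways a [GeneSetCollection-class].
#' @slot diseaseGenes character vector of disease risk genes.
#' @slot mirnaTargets,drugTargets [TargetMap-class] objects.
#' @slot truth list with elements \code{riskPathwayIds},
#'   \code{responsiveMirnaIds}, \code{responsiveDrugIds}.
#' @slot config the generating [SynthConfig-class].
#'
#' @seealso [generateStudy()], [writeStudy()], [readStudy()]
#' @export
setClass("SynthStudy",
  slots = c(universe = "character", pathways = "GeneSetCollection",
            diseaseGenes = "character", mirnaTargets = "TargetMap",
            drugTargets = "TargetMap", truth = "list",
            config = "SynthConfig"))

setValidity("SynthStudy", function(object) {
  msg <- character()
  tr <- object@truth
  need <- c("riskPathwayIds", "responsiveMirnaIds", "responsiveDrugIds")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("truth must contain:", paste(need, collapse = ", ")))
  else {
    if (!all(tr$riskPathwayIds %in% object@pathways@setIds))
      msg <- c(msg, "risk pathway ids must exist in the pathway collection")
    if (!all(tr$responsiveMirnaIds %in% names(object@mirnaTargets@targets)))
      msg <- c(msg, "responsive miRNA ids must exist in the miRNA map")
    if (!all(tr$responsiveDrugIds %in% names(object@drugTargets@targets)))
      msg <- c(msg, "responsive drug ids must exist in the drug map")
  }
  if (anyDuplicated(object@universe)) msg <- c(msg, "universe must be duplicate-free")
  if (length(msg)) msg else TRUE
})
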