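#' @include AllClasses.R
NULL

#' Accessors for gene set collections
#'
#' @param x a [GeneSetCollection-class].
#' @param id a single set id (for [geneSet()]).
#' @return \code{setIds}: character vector of ids. \code{setDescriptions}:
#'   named character vector. \code{geneSet}: the member genes of one set.
#'   \code{geneSets}: named list of all member vectors. \code{setSizes}:
#'   named integer vector.
#' @examples
#' gsc <- GeneSetCollection(list(P1 = c("A", "B"), P2 = "C"))
#' setIds(gsc); setSizes(gsc); geneSet(gsc, "P2")
#' @name geneset-accessors
NULL

#' @rdname geneset-accessors
#' @export
setGeneric("setIds", function(x) standardGeneric("setIds"))
#' @rdname geneset-accessors
#' @export
setMethod("setIds", "GeneSetCollection", function(x) x@setIds)

#' @rdname geneset-accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))
#' @rdname geneset-accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x)
  stats::setNames(x@descriptions, x@setIds))

#' @rdname geneset-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname geneset-accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x)
  stats::setNames(x@members, x@setIds))

#' @rdname geneset-accessors
#' @export
setGeneric("geneSet", function(x, id) standardGeneric("geneSet"))
#' @rdname geneset-accessors
#' @export
setMethod("geneSet", "GeneSetCollection", function(x, id) {
  i <- match(id, x@setIds)
  if (is.na(i)) stop("unknown set id: ", id)
  x@members[[i]]
})

#' @rdname geneset-accessors
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))
#' @rdname geneset-accessors
#' @export
setMethod("setSizes", "GeneSetCollection", function(x)
  stats::setNames(lengths(x@members), x@setIds))

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setIds))

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@setIds)))
  if (length(object@setIds)) {
    sz <- lengths(object@members)
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sz), stats::median(sz), max(sz)))
    cat("  ids: ", paste(utils::head(object@setIds, 5), collapse = ", "),
        if (length(object@setIds) > 5) ", ..." else "", "\n", sep = "")
  }
})

#' Accessors for target maps
#'
#' @param x a [TargetMap-class].
#' @param id a single regulator id.
#' @return \code{regulators}: regulator ids. \code{targetsOf}: target genes of
#'   one regulator. \code{targetList}: named list of target sets.
#'   \code{regulatorClass}: \code{"miRNA"} or \code{"drug"}. \code{nTargets}:
#'   named integer vector of target-set sizes.
#' @examples
#' tm <- TargetMap(list(D1 = c("A", "B")), "drug")
#' regulators(tm); nTargets(tm)
#' @name targetmap-accessors
NULL

#' @rdname targetmap-accessors
#' @export
setGeneric("regulators", function(x) standardGeneric("regulators"))
#' @rdname targetmap-accessors
#' @export
setMethod("regulators", "TargetMap", function(x) names(x@targets))

#' @rdname targetmap-accessors
#' @export
setGeneric("targetsOf", function(x, id) standardGeneric("targetsOf"))
#' @rdname targetmap-accessors
#' @export
setMethod("targetsOf", "TargetMap", function(x, id) {
  if (!id %in% names(x@targets)) stop("unknown regulator id: ", id)
  x@targets[[id]]
})

#' @rdname targetmap-accessors
#' @export
setGeneric("targetList", function(x) standardGeneric("targetList"))
#' @rdname targetmap-accessors
#' @export
setMethod("targetList", "TargetMap", function(x) x@targets)

#' @rdname targetmap-accessors
#' @export
setGeneric("regulatorClass", function(x) standardGeneric("regulatorClass"))
#' @rdname targetmap-accessors
#' @export
setMethod("regulatorClass", "TargetMap", function(x) x@regulatorClass)

#' @rdname targetmap-accessors
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))
#' @rdname targetmap-accessors
#' @export
setMethod("nTargets", "TargetMap", function(x)
  stats::setNames(lengths(x@targets), names(x@targets)))

#' @export
setMethod("length", "TargetMap", function(x) length(x@targets))

#' @export
setMethod("show", "TargetMap", function(object) {
  cat(sprintf("TargetMap (%s) with %d regulator(s), %d pairs\n",
              object@regulatorClass, length(object@targets),
              sum(lengths(object@targets))))
})

#' Accessors for enrichment tables
#'
#' @param x an [EnrichmentTable-class].
#' @return \code{enrichResults}: the per-pathway data.frame.
#'   \code{entityId}: the query entity id. \code{pathwayUniverse}: ids of all
#'   pathways the table was computed against. \code{alphaLevel}: the
#'   significance threshold. \code{significantPathways}: ids of pathways
#'   flagged significant.
#' @name enrichment-accessors
NULL

#' @rdname enrichment-accessors
#' @export
setGeneric("enrichResults", function(x) standardGeneric("enrichResults"))
#' @rdname enrichment-accessors
#' @export
setMethod("enrichResults", "EnrichmentTable", function(x) x@results)

#' @rdname enrichment-accessors
#' @export
setGeneric("entityId", function(x) standardGeneric("entityId"))
#' @rdname enrichment-accessors
#' @export
setMethod("entityId", "EnrichmentTable", function(x) x@entityId)

#' @rdname enrichment-accessors
#' @export
setGeneric("pathwayUniverse", function(x) standardGeneric("pathwayUniverse"))
#' @rdname enrichment-accessors
#' @export
setMethod("pathwayUniverse", "EnrichmentTable", function(x) x@pathwayIds)

#' @rdname enrichment-accessors
#' @export
setGeneric("alphaLevel", function(x) standardGeneric("alphaLevel"))
#' @rdname enrichment-accessors
#' @export
setMethod("alphaLevel", "EnrichmentTable", function(x) x@alpha)

#' @rdname enrichment-accessors
#' @export
setGeneric("significantPathways",
           function(x) standardGeneric("significantPathways"))
#' @rdname enrichment-accessors
#' @export
setMethod("significantPathways", "EnrichmentTable", function(x)
  x@results$pathway[x@results$significant])

#' @export
setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf(
    "EnrichmentTable for '%s': %d/%d pathways overlapped, %d significant (alpha=%g, adjust=%s)\n",
    object@entityId, nrow(object@results), length(object@pathwayIds),
    sum(object@results$significant), object@alpha, object@adjust))
})

#' Accessors for MDNG networks
#'
#' @param x an [Mdng-class].
#' @param nodeClass optional class filter (\code{"pathway"}, \code{"miRNA"} or
#'   \code{"drug"}).
#' @return \code{mdngGraph}: the underlying \pkg{igraph} object.
#'   \code{nodeClasses}: named character vector of node classes (names are
#'   unprefixed labels). \code{nodeIds}: unprefixed node ids, optionally per
#'   class. \code{nodeCount}/\code{edgeCount}: integer counts.
#' @name mdng-accessors
NULL

#' @rdname mdng-accessors
#' @export
setGeneric("mdngGraph", function(x) standardGeneric("mdngGraph"))
#' @rdname mdng-accessors
#' @export
setMethod("mdngGraph", "Mdng", function(x) x@graph)

#' @rdname mdng-accessors
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))
#' @rdname mdng-accessors
#' @export
setMethod("nodeClasses", "Mdng", function(x) {
  g <- x@graph
  if (!igraph::vcount(g)) return(stats::setNames(character(), character()))
  stats::setNames(igraph::V(g)$class, igraph::V(g)$label)
})

#' @rdname mdng-accessors
#' @export
setGeneric("nodeIds", function(x, nodeClass = NULL) standardGeneric("nodeIds"))
#' @rdname mdng-accessors
#' @export
setMethod("nodeIds", "Mdng", function(x, nodeClass = NULL) {
  cl <- nodeClasses(x)
  if (is.null(nodeClass)) names(cl) else names(cl)[cl == nodeClass]
})

#' @rdname mdng-accessors
#' @export
setGeneric("nodeCount", function(x, nodeClass = NULL) standardGeneric("nodeCount"))
#' @rdname mdng-accessors
#' @export
setMethod("nodeCount", "Mdng", function(x, nodeClass = NULL)
  length(nodeIds(x, nodeClass)))

#' @rdname mdng-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname mdng-accessors
#' @export
setMethod("edgeCount", "Mdng", function(x) as.integer(igraph::ecount(x@graph)))

#' @export
setMethod("show", "Mdng", function(object) {
  cat(sprintf(
    "Mdng: %d nodes (%d pathways, %d miRNAs, %d drugs), %d edges\n",
    nodeCount(object), nodeCount(object, "pathway"),
    nodeCount(object, "miRNA"), nodeCount(object, "drug"),
    edgeCount(object)))
})

#' @export
setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: f(x) = %.4g * x^(%.4g), r^2 = %.4f (%d points)\n",
              object@a, object@b, object@rSquared, object@nPoints))
})

#' @export
setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    paste0("SynthConfig: %d genes, %d pathways (%d risk, sizes %d-%d), ",
           "%d disease genes (signal %.2f),\n  %d miRNAs (%d responsive), ",
           "%d drugs (%d responsive), targets %d-%d (signal %.2f), seed %d\n"),
    object@nGenes, object@nPathways, object@nRiskPathways,
    object@pathwaySizeRange[1], object@pathwaySizeRange[2],
    object@nDiseaseGenes, object@diseaseSignal,
    object@nMirnas, object@nResponsiveMirnas,
    object@nDrugs, object@nResponsiveDrugs,
    object@targetsPerRegulatorRange[1], object@targetsPerRegulatorRange[2],
    object@regulatorSignal, object@seed))
})

#' @export
setMethod("show", "SynthStudy", function(object) {
  cat(sprintf(
    "SynthStudy: %d genes, %d pathways, %d disease genes, %d miRNAs, %d drugs\n",
    length(object@universe), length(object@pathways@setIds),
    length(object@diseaseGenes), length(object@mirnaTargets@targets),
    length(object@drugTargets@targets)))
  cat(sprintf("  truth: %d risk pathways, %d responsive miRNAs, %d responsive drugs\n",
              length(object@truth$riskPathwayIds),
              length(object@truth$responsiveMirnaIds),
              length(object@truth$responsiveDrugIds)))
})

#' Accessors for synthetic studies
#'
#' @param x a [SynthStudy-class].
#' @return The corresponding component: gene universe (character), pathway
#'   [GeneSetCollection-class], disease gene vector, miRNA/drug
#'   [TargetMap-class], truth list, or [SynthConfig-class].
#' @name synthstudy-accessors
NULL

#' @rdname synthstudy-accessors
#' @export
setGeneric("studyUniverse", function(x) standardGeneric("studyUniverse"))
#' @rdname synthstudy-accessors
#' @export
setMethod("studyUniverse", "SynthStudy", function(x) x@universe)

#' @rdname synthstudy-accessors
#' @export
setGeneric("studyPathways", function(x) standardGeneric("studyPathways"))
#' @rdname synthstudy-accessors
#' @export
setMethod("studyPathways", "SynthStudy", function(x) x@pathways)

#' @rdname synthstudy-accessors
#' @export
setGeneric("diseaseGenes", function(x) standardGeneric("diseaseGenes"))
#' @rdname synthstudy-accessors
#' @export
setMethod("diseaseGenes", "SynthStudy", function(x) x@diseaseGenes)

#' @rdname synthstudy-accessors
#' @export
setGeneric("mirnaTargets", function(x) standardGeneric("mirnaTargets"))
#' @rdname synthstudy-accessors
#' @export
setMethod("mirnaTargets", "SynthStudy", function(x) x@mirnaTargets)

#' @rdname synthstudy-accessors
#' @export
setGeneric("drugTargets", function(x) standardGeneric("drugTargets"))
#' @rdname synthstudy-accessors
#' @export
setMethod("drugTargets", "SynthStudy", function(x) x@drugTargets)

#' @rdname synthstudy-accessors
#' @export
setGeneric("studyTruth", function(x) standardGeneric("studyTruth"))
#' @rdname synthstudy-accessors
#' @export
setMethod("studyTruth", "SynthStudy", function(x) x@truth)

#' @rdname synthstudy-accessors
#' @export
setGeneric("studyConfig", function(x) standardGeneric("studyConfig"))
#' @rdname synthstudy-accessors
#' @export
setMethod("studyConfig", "SynthStudy", function(x) x@config)
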