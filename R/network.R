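#' @include AllClasses.R accessors.R enrichment.R
NULL

emptyMdng <- function(partial = FALSE) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = character())
  g <- igraph::set_vertex_attr(g, "label", value = character())
  g <- igraph::set_vertex_attr(g, "class", value = character())
  new("Mdng", graph = g, partial = partial)
}

mdngFromEdges <- function(edges, partial = FALSE) {
  if (!nrow(edges)) return(emptyMdng(partial))
  regName <- paste0(edges$class, ":", edges$regulator)
  pwName <- paste0("pathway:", edges$pathway)
  verts <- unique(data.frame(
    name = c(regName, pwName),
    label = c(edges$regulator, edges$pathway),
    class = c(edges$class, rep("pathway", nrow(edges))),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = regName, to = pwName, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  g <- igraph::simplify(g)
  new("Mdng", graph = g, partial = partial)
}

#' Construct an MDNG from an explicit edge list
#'
#' Low-level constructor used when the regulator-pathway edges are already
#' known (e.g. when importing a network built elsewhere); [buildMdng()] is
#' the usual entry point.
#'
#' @param edges data.frame with columns \code{regulator}, \code{class}
#'   (\code{"miRNA"} or \code{"drug"}) and \code{pathway}; duplicate edges
#'   are collapsed.
#' @param partial if \code{TRUE}, pathway nodes need not carry both
#'   regulator classes.
#' @return an [Mdng-class].
#' @examples
#' Mdng(data.frame(regulator = c("m1", "d1"), class = c("miRNA", "drug"),
#'                 pathway = "P1"))
#' @export
Mdng <- function(edges, partial = FALSE) {
  stopifnot(is.data.frame(edges),
            all(c("regulator", "class", "pathway") %in% names(edges)),
            all(edges$class %in% c("miRNA", "drug")))
  mdngFromEdges(edges, partial = partial)
}

effectiveSignificant <- function(et, alpha = NULL) {
  r <- et@results
  if (is.null(alpha)) return(r$pathway[r$significant])
  p <- if (et@adjust == "BH") r$p_adj else r$p_raw
  r$pathway[p < alpha]
}

#' Build the tripartite miRNA-drug-pathway network
#'
#' Candidate pathways are those significantly enriched in the disease table.
#' A regulator (miRNA or drug) is linked to a candidate pathway when its own
#' enrichment table marks that pathway significant. Pathways lacking either a
#' miRNA or a drug edge are then pruned (both regulator classes are required
#' for a pathway to sit in the network), and regulators left without edges
#' are dropped. The result is a simple undirected graph.
#'
#' @param diseaseTable [EnrichmentTable-class] of the disease gene set.
#' @param mirnaTables named list of [EnrichmentTable-class], one per miRNA.
#' @param drugTables named list of [EnrichmentTable-class], one per drug.
#' @param alpha optional threshold overriding the tables' stored
#'   significance flags (applied to adjusted p for BH tables, raw p
#'   otherwise).
#' @param keepPartial if \code{TRUE}, retain pathways linked by only one
#'   regulator class.
#' @return an [Mdng-class]; empty (with a warning) when no pathway survives.
#' @export
buildMdng <- function(diseaseTable, mirnaTables, drugTables, alpha = NULL,
                      keepPartial = FALSE) {
  stopifnot(is(diseaseTable, "EnrichmentTable"))
  candidates <- effectiveSignificant(diseaseTable, alpha)
  edgeRows <- function(tables, cls) {
    if (!length(tables)) return(NULL)
    do.call(rbind, lapply(names(tables), function(id) {
      sig <- intersect(effectiveSignificant(tables[[id]], alpha), candidates)
      if (!length(sig)) return(NULL)
      data.frame(regulator = id, class = cls, pathway = sig,
                 stringsAsFactors = FALSE)
    }))
  }
  edges <- rbind(edgeRows(mirnaTables, "miRNA"), edgeRows(drugTables, "drug"))
  if (is.null(edges) || !nrow(edges)) {
    warning("no pathway shared by the disease and any regulator; empty network",
            call. = FALSE)
    return(emptyMdng(partial = keepPartial))
  }
  if (!keepPartial) {
    withMir <- unique(edges$pathway[edges$class == "miRNA"])
    withDrug <- unique(edges$pathway[edges$class == "drug"])
    keep <- intersect(withMir, withDrug)
    edges <- edges[edges$pathway %in% keep, , drop = FALSE]
    if (!nrow(edges)) {
      warning("no pathway carries both a miRNA and a drug edge; empty network",
              call. = FALSE)
      return(emptyMdng(partial = keepPartial))
    }
  }
  mdngFromEdges(edges, partial = keepPartial)
}

#' Degree distribution of a network
#'
#' Counts nodes by degree, optionally restricted to one node class (degrees
#' still count all incident edges). The counts sum to the number of
#' (selected) nodes.
#'
#' @param g an [Mdng-class] or \pkg{igraph} graph.
#' @param nodeClass optional class restriction (\code{"pathway"},
#'   \code{"miRNA"}, \code{"drug"}); ignored for plain igraph input.
#' @return named integer vector mapping degree to node count, ascending by
#'   degree.
#' @export
setGeneric("degreeDistribution",
           function(g, nodeClass = NULL) standardGeneric("degreeDistribution"))

degreeCounts <- function(deg) {
  if (!length(deg)) stop("degree distribution of an empty graph is undefined",
                         call. = FALSE)
  tab <- table(deg)
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname degreeDistribution
#' @export
setMethod("degreeDistribution", "Mdng", function(g, nodeClass = NULL) {
  deg <- igraph::degree(g@graph)
  if (!is.null(nodeClass)) deg <- deg[igraph::V(g@graph)$class == nodeClass]
  degreeCounts(deg)
})

#' @rdname degreeDistribution
#' @export
setMethod("degreeDistribution", "ANY", function(g, nodeClass = NULL) {
  stopifnot(igraph::is_igraph(g))
  degreeCounts(igraph::degree(g))
})

#' Fit a power law to a degree distribution
#'
#' Fits \eqn{f(x) = a x^{b}} by ordinary least squares of \eqn{\log_{10}}
#' node count on \eqn{\log_{10}} degree over degrees >= 1 with positive
#' count — the scale-free fit convention of Cytoscape's NetworkAnalyzer,
#' which reports the same functional form for degree distributions.
#'
#' @param dist named numeric vector mapping degree to count, as returned by
#'   [degreeDistribution()].
#' @return a [PowerLawFit-class] with \code{a} (\eqn{10^{intercept}}),
#'   \code{b} (slope) and the log-log \eqn{r^2}. A perfect fit (zero total
#'   variance or zero residual) reports \eqn{r^2 = 1}.
#' @examples
#' fitPowerLaw(stats::setNames(2 / (1:10), 1:10))  # a = 2, b = -1
#' @export
fitPowerLaw <- function(dist) {
  deg <- suppressWarnings(as.numeric(names(dist)))
  cnt <- as.numeric(dist)
  if (any(is.na(deg))) stop("dist must be named by numeric degrees", call. = FALSE)
  keep <- deg >= 1 & cnt > 0
  deg <- deg[keep]; cnt <- cnt[keep]
  if (length(unique(deg)) < 2)
    stop("power-law fit needs at least 2 distinct positive degrees",
         call. = FALSE)
  x <- log10(deg); y <- log10(cnt)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss <= .Machine$double.eps * length(y) || rss < 1e-20 * max(1, tss))
    1 else 1 - rss / tss
  new("PowerLawFit", a = 10^unname(stats::coef(fit)[1]),
      b = unname(stats::coef(fit)[2]), rSquared = r2,
      nPoints = length(deg))
}

tcVector <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  A[A > 1] <- 1
  diag(A) <- 0
  deg <- rowSums(A)
  S <- A %*% A                      # shared-neighbour counts
  J <- S + A                        # +1 for a direct edge
  tc <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    w <- setdiff(which(S[v, ] > 0), v)
    if (!length(w)) next
    tc[v] <- mean(J[v, w]) / deg[v]
  }
  names(tc) <- igraph::V(g)$name
  tc
}

#' Topological coefficient
#'
#' For a node \eqn{v} with degree at least 2, the topological coefficient is
#' the mean of \eqn{J(v, w) / \mathrm{deg}(v)} over all nodes \eqn{w \ne v}
#' sharing at least one neighbour with \eqn{v}, where \eqn{J(v, w)} is the
#' number of shared neighbours plus 1 if \eqn{v} and \eqn{w} are directly
#' linked (the NetworkAnalyzer convention). Nodes of degree < 2, or with no
#' neighbour-sharing partner, get \code{NA}.
#'
#' @param g an [Mdng-class] or \pkg{igraph} graph.
#' @param node optional node id (unprefixed label for an Mdng); if given,
#'   returns that node's coefficient alone and errors when the node is
#'   absent.
#' @return named numeric vector over all nodes, or a single value when
#'   \code{node} is given.
#' @export
setGeneric("topologicalCoefficient",
           function(g, node = NULL) standardGeneric("topologicalCoefficient"))

pickNode <- function(tc, node) {
  if (is.null(node)) return(tc)
  if (!node %in% names(tc)) stop("unknown node: ", node, call. = FALSE)
  tc[[node]]
}

#' @rdname topologicalCoefficient
#' @export
setMethod("topologicalCoefficient", "Mdng", function(g, node = NULL) {
  tc <- tcVector(g@graph)
  names(tc) <- igraph::V(g@graph)$label
  pickNode(tc, node)
})

#' @rdname topologicalCoefficient
#' @export
setMethod("topologicalCoefficient", "ANY", function(g, node = NULL) {
  stopifnot(igraph::is_igraph(g))
  pickNode(tcVector(g), node)
})

#' Per-node summary table of an MDNG
#'
#' @param network an [Mdng-class].
#' @return data.frame with columns \code{node} (unprefixed id),
#'   \code{class}, \code{degree} and \code{topological_coefficient}
#'   (\code{NA} where undefined), sorted by class then node id.
#' @export
nodeStats <- function(network) {
  stopifnot(is(network, "Mdng"))
  g <- network@graph
  if (!igraph::vcount(g))
    return(data.frame(node = character(), class = character(),
                      degree = integer(),
                      topological_coefficient = numeric()))
  out <- data.frame(node = igraph::V(g)$label, class = igraph::V(g)$class,
                    degree = as.integer(igraph::degree(g)),
                    topological_coefficient = unname(tcVector(g)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$class, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dissect one pathway into co-regulated disease genes
#'
#' For every disease gene inside the pathway, lists the miRNAs and drugs
#' whose target sets contain it. A gene is flagged co-regulated when both
#' lists are non-empty, i.e. the gene is a point where miRNA regulation and
#' drug action converge on the same disease pathway.
#'
#' @param pathwayId pathway to dissect (must exist in \code{pathways}).
#' @param pathways a [GeneSetCollection-class].
#' @param diseaseGenes character vector of disease risk genes.
#' @param mirnaTm,drugTm [TargetMap-class] objects.
#' @return data.frame with one row per disease gene in the pathway: columns
#'   \code{gene}, \code{mirnas} and \code{drugs} (comma-separated ids),
#'   \code{n_mirnas}, \code{n_drugs}, \code{co_regulated}.
#' @export
dissectPathway <- function(pathwayId, pathways, diseaseGenes, mirnaTm,
                           drugTm) {
  stopifnot(is(pathways, "GeneSetCollection"),
            is(mirnaTm, "TargetMap"), is(drugTm, "TargetMap"))
  pwGenes <- geneSet(pathways, pathwayId)
  genes <- intersect(toupper(diseaseGenes), pwGenes)
  hitters <- function(tm, gene)
    names(tm@targets)[vapply(tm@targets, function(t) gene %in% t, logical(1))]
  rows <- lapply(genes, function(gn) {
    m <- hitters(mirnaTm, gn); d <- hitters(drugTm, gn)
    data.frame(gene = gn, mirnas = paste(m, collapse = ","),
               drugs = paste(d, collapse = ","),
               n_mirnas = length(m), n_drugs = length(d),
               co_regulated = length(m) > 0 && length(d) > 0,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), mirnas = character(), drugs = character(),
               n_mirnas = integer(), n_drugs = integer(),
               co_regulated = logical())
  rownames(out) <- NULL
  out
}
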