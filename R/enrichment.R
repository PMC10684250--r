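#' @include AllClasses.R accessors.R
NULL

#' Upper tail of the hypergeometric distribution
#'
#' Probability of observing an overlap of at least \code{k} genes between a
#' query of size \code{n} and a gene set of size \code{K}, drawing without
#' replacement from a universe of size \code{N}: \eqn{P(X \ge k)} with
#' \eqn{X \sim \mathrm{Hypergeometric}(N, K, n)}. This is the one-sided
#' Fisher exact enrichment p-value.
#'
#' @param N universe size.
#' @param K gene-set (pathway) size within the universe.
#' @param n query size.
#' @param k observed overlap.
#' @return \eqn{P(X \ge k)}; exactly 1 for \code{k = 0}.
#' @examples
#' hypergeomTail(10, 4, 3, 3)  # 4/120
#' @export
hypergeomTail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (is.na(N) || is.na(K) || is.na(n) || is.na(k) ||
      K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K))
    stop("hypergeomTail: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)",
         call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output is order-preserving with
#' the input, elementwise no smaller than the input, and capped at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("bhAdjust: p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Pathway over-representation of a gene set
#'
#' Tests each pathway for over-representation of \code{entityGenes} with the
#' one-sided hypergeometric tail over the supplied gene universe. Pathways
#' with zero overlap are omitted. Significance is \code{p_raw < alpha}
#' (\code{adjust = "none"}, the convention for KEGG-style runs at p < .05) or
#' \code{p_adj < alpha} after Benjamini-Hochberg over the tested pathways
#' (\code{adjust = "BH"}, the FDR < 0.05 convention for GO-style runs).
#'
#' @param entityGenes character vector of query gene symbols.
#' @param pathways a [GeneSetCollection-class].
#' @param universe character vector defining the background population; both
#'   query and pathway members are restricted to it.
#' @param alpha significance threshold in (0, 1).
#' @param adjust \code{"none"} or \code{"BH"}.
#' @param ease if \code{TRUE}, compute the conservative EASE-style score:
#'   the overlap is decremented by one (floored at 0) before taking the tail.
#' @param entityName identifier recorded in the result table.
#' @return an [EnrichmentTable-class], rows sorted by ascending raw p then
#'   pathway id.
#' @examples
#' gsc <- GeneSetCollection(list(P1 = LETTERS[1:5], P2 = LETTERS[4:9]))
#' et <- enrich(LETTERS[1:5], gsc, LETTERS[1:20])
#' enrichResults(et)
#' @export
enrich <- function(entityGenes, pathways, universe, alpha = 0.05,
                   adjust = c("none", "BH"), ease = FALSE,
                   entityName = "query") {
  adjust <- match.arg(adjust)
  stopifnot(is(pathways, "GeneSetCollection"), length(universe) > 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  universe <- unique(toupper(universe))
  N <- length(universe)
  query <- intersect(unique(toupper(entityGenes)), universe)
  n <- length(query)
  empty <- function() new("EnrichmentTable", entityId = entityName,
    results = data.frame(pathway = character(), N = integer(),
      K = integer(), n = integer(), k = integer(), p_raw = numeric(),
      p_adj = numeric(), significant = logical()),
    alpha = alpha, adjust = adjust, pathwayIds = pathways@setIds)
  if (n == 0L) {
    warning("empty query after universe restriction for '", entityName, "'",
            call. = FALSE)
    return(empty())
  }
  Ks <- integer(length(pathways@setIds))
  ks <- integer(length(pathways@setIds))
  for (i in seq_along(pathways@setIds)) {
    mem <- pathways@members[[i]][pathways@members[[i]] %in% universe]
    Ks[i] <- length(mem)
    ks[i] <- sum(query %in% mem)
  }
  keep <- ks >= 1L
  if (!any(keep)) return(empty())
  ids <- pathways@setIds[keep]; Ks <- Ks[keep]; ks <- ks[keep]
  kEff <- if (ease) pmax(ks - 1L, 0L) else ks
  praw <- vapply(seq_along(ids), function(i)
    hypergeomTail(N, Ks[i], n, kEff[i]), numeric(1))
  padj <- if (adjust == "BH") bhAdjust(praw) else rep(NA_real_, length(praw))
  sig <- if (adjust == "BH") padj < alpha else praw < alpha
  res <- data.frame(pathway = ids, N = N, K = Ks, n = n, k = ks,
                    p_raw = praw, p_adj = padj, significant = sig,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  new("EnrichmentTable", entityId = entityName, results = res,
      alpha = alpha, adjust = adjust, pathwayIds = pathways@setIds)
}

#' Keep regulators with enough targets
#'
#' Retains regulators whose target set has at least \code{minTargets} genes.
#' The default of 6 implements the "more than 5 target genes" inclusion rule
#' used when compiling drug and miRNA target sets.
#'
#' @param tm a [TargetMap-class].
#' @param minTargets minimum target-set size to keep (default 6).
#' @return a filtered [TargetMap-class]; a message reports the dropped count.
#' @examples
#' tm <- TargetMap(list(a = LETTERS[1:5], b = LETTERS[1:6]), "drug")
#' regulators(filterRegulators(tm))
#' @export
filterRegulators <- function(tm, minTargets = 6L) {
  stopifnot(is(tm, "TargetMap"), minTargets >= 1)
  keep <- lengths(tm@targets) >= minTargets
  if (any(!keep))
    message("filterRegulators: dropped ", sum(!keep), " regulator(s) with < ",
            minTargets, " targets")
  tm@targets <- tm@targets[keep]
  tm
}

#' Enrichment tables for every regulator of a target map
#'
#' Applies [enrich()] to each regulator's target set; results are returned in
#' the map's regulator order.
#'
#' @inheritParams enrich
#' @param tm a [TargetMap-class] (normally already passed through
#'   [filterRegulators()]).
#' @return named list of [EnrichmentTable-class] objects, one per regulator.
#' @export
enrichAll <- function(tm, pathways, universe, alpha = 0.05,
                      adjust = c("none", "BH"), ease = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(is(tm, "TargetMap"))
  out <- lapply(names(tm@targets), function(r)
    enrich(tm@targets[[r]], pathways, universe, alpha = alpha,
           adjust = adjust, ease = ease, entityName = r))
  stats::setNames(out, names(tm@targets))
}
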