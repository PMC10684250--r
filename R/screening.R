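#' @include AllClasses.R accessors.R enrichment.R
NULL

# Full-profile vectors over the pathway label universe of a table:
# raw p (NA where the pathway had no overlap) and the significance flag
# (optionally recomputed at `alpha` from adjusted/raw p per the table's
# adjustment convention).
profileVectors <- function(et, alpha = NULL) {
  ids <- et@pathwayIds
  p <- stats::setNames(rep(NA_real_, length(ids)), ids)
  sig <- stats::setNames(rep(FALSE, length(ids)), ids)
  r <- et@results
  p[r$pathway] <- r$p_raw
  if (is.null(alpha)) {
    sig[r$pathway] <- r$significant
  } else {
    if (!(length(alpha) == 1 && alpha > 0 && alpha < 1))
      stop("alpha must be in (0, 1)", call. = FALSE)
    eff <- if (et@adjust == "BH") r$p_adj else r$p_raw
    sig[r$pathway] <- eff < alpha
  }
  list(p = p, sig = sig)
}

checkSameCollection <- function(a, b) {
  if (!setequal(a@pathwayIds, b@pathwayIds))
    stop("enrichment tables were not computed on the same pathway collection",
         call. = FALSE)
}

#' Drug-disease association score on the best shared pathway
#'
#' Candidate pathways are those significant in \emph{both} tables. The score
#' pathway \eqn{k} is the candidate minimising the product
#' \eqn{P_{disease,k} \cdot P_{drug,k}} of raw enrichment p-values (ties
#' broken by lexicographically smallest pathway id) — the pathway most
#' significantly impacted by both the disease genes and the drug's targets —
#' and the score is
#' \deqn{S = -\log_{10}(P_{disease,k}) - \log_{10}(P_{drug,k}).}
#'
#' @param diseaseTable [EnrichmentTable-class] of the disease gene set.
#' @param drugTable [EnrichmentTable-class] of one drug's target set,
#'   computed on the same pathway collection.
#' @param alpha optional threshold overriding the tables' stored
#'   significance flags; must lie in (0, 1).
#' @return list with elements \code{drugId}, \code{bestPathway},
#'   \code{pDisease}, \code{pDrug} and \code{S}, or \code{NULL} when no
#'   pathway is significant in both tables (the score is undefined).
#' @export
associationScore <- function(diseaseTable, drugTable, alpha = NULL) {
  stopifnot(is(diseaseTable, "EnrichmentTable"),
            is(drugTable, "EnrichmentTable"))
  checkSameCollection(diseaseTable, drugTable)
  dis <- profileVectors(diseaseTable, alpha)
  drg <- profileVectors(drugTable, alpha)
  drg <- lapply(drg, function(v) v[names(dis$p)])  # align label order
  cand <- names(dis$p)[dis$sig & drg$sig]
  if (!length(cand)) return(NULL)
  s <- -log10(dis$p[cand]) - log10(drg$p[cand])
  best <- cand[order(-s, cand)][1]
  list(drugId = drugTable@entityId, bestPathway = best,
       pDisease = unname(dis$p[best]), pDrug = unname(drg$p[best]),
       S = unname(s[best]))
}

#' Permute a disease enrichment profile over pathway labels
#'
#' Reassigns the rows of the profile (p-values, overlap counts and
#' significance flags together) to pathway labels by a uniform random
#' permutation over the table's full pathway universe — including labels
#' that currently carry no row, which may therefore gain or lose one. The
#' multiset of p-values is preserved.
#'
#' @param diseaseTable a non-empty [EnrichmentTable-class].
#' @param perm optional integer permutation of
#'   \code{seq_along(pathwayUniverse(diseaseTable))}; the row sitting at
#'   label \code{perm[i]} moves to label \code{i}. Drawn uniformly at random
#'   from the current RNG stream when omitted.
#' @return a new [EnrichmentTable-class] with relabelled rows.
#' @export
permuteDiseaseProfile <- function(diseaseTable, perm = NULL) {
  stopifnot(is(diseaseTable, "EnrichmentTable"))
  ids <- diseaseTable@pathwayIds
  if (!nrow(diseaseTable@results)) stop("cannot permute an empty profile",
                                        call. = FALSE)
  if (is.null(perm)) perm <- sample.int(length(ids))
  stopifnot(length(perm) == length(ids), setequal(perm, seq_along(ids)))
  # old label index j appears at new position match(j, perm)
  newPos <- match(seq_along(ids), perm)
  r <- diseaseTable@results
  r$pathway <- ids[newPos[match(r$pathway, ids)]]
  r <- r[order(r$p_raw, r$pathway), , drop = FALSE]
  rownames(r) <- NULL
  out <- diseaseTable
  out@results <- r
  out
}

# Vectorised permutation null: disP/disSig are full-length profile vectors,
# drugIdx indexes the drug's candidate (significant) pathways in that label
# order, drugLogS = -log10 of the drug's raw p there. permMatrix rows are
# permutations; row i, column l says which disease label's row sits at
# label l.
nullScores <- function(disP, disSig, drugIdx, drugLogS, permMatrix) {
  if (!length(drugIdx))
    return(list(s = numeric(), nUndefined = nrow(permMatrix)))
  IDX <- permMatrix[, drugIdx, drop = FALSE]
  OK <- matrix(disSig[IDX], nrow = nrow(IDX))
  V <- matrix(-log10(disP[IDX]), nrow = nrow(IDX))
  V <- sweep(V, 2L, drugLogS, "+")
  V[!OK | is.na(V)] <- -Inf
  S <- do.call(pmax, asplit(V, 2L))
  def <- S > -Inf
  list(s = S[def], nUndefined = sum(!def))
}

#' Permutation null distribution of the association score
#'
#' Recomputes the association score of one drug against \code{nPerm}
#' uniformly permuted disease profiles (see [permuteDiseaseProfile()]).
#' Permutations under which no pathway is significant for both profiles
#' leave the score undefined; these are excluded from the null and counted.
#'
#' @inheritParams associationScore
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed making the null reproducible; if \code{NULL} the
#'   current RNG stream is used.
#' @param permMatrix optional pre-drawn permutation matrix (rows =
#'   permutations of the pathway label indices), overriding \code{nPerm} and
#'   \code{seed}; lets several drugs share one set of permutations.
#' @return list of class \code{"permutationNull"} with \code{drugId},
#'   \code{nPerm}, \code{sRandom} (defined scores only), \code{mean},
#'   \code{sd} (sample, n-1 denominator; \code{NA} when fewer than 2 defined
#'   scores), \code{nUndefined} and \code{seed}.
#' @export
permutationNull <- function(diseaseTable, drugTable, nPerm = 10000L,
                            alpha = NULL, seed = NULL, permMatrix = NULL) {
  stopifnot(is(diseaseTable, "EnrichmentTable"),
            is(drugTable, "EnrichmentTable"))
  checkSameCollection(diseaseTable, drugTable)
  P <- length(diseaseTable@pathwayIds)
  if (is.null(permMatrix)) {
    stopifnot(nPerm >= 1)
    draw <- function() matrix(unlist(lapply(seq_len(nPerm), function(i)
      sample.int(P))), nrow = nPerm, byrow = TRUE)
    permMatrix <- if (is.null(seed)) draw() else withSeed(seed, draw())
  } else nPerm <- nrow(permMatrix)
  dis <- profileVectors(diseaseTable, alpha)
  drg <- profileVectors(drugTable, alpha)
  drg <- lapply(drg, function(v) v[names(dis$p)])
  drugIdx <- which(drg$sig)
  ns <- nullScores(dis$p, dis$sig, drugIdx, -log10(drg$p[drugIdx]),
                   permMatrix)
  def <- ns$s
  structure(list(
    drugId = drugTable@entityId, nPerm = as.integer(nPerm), sRandom = def,
    mean = if (length(def)) mean(def) else NA_real_,
    sd = if (length(def) >= 2) stats::sd(def) else NA_real_,
    nUndefined = as.integer(ns$nUndefined),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "permutationNull")
}

#' @export
print.permutationNull <- function(x, ...) {
  cat(sprintf(
    "permutationNull for '%s': %d permutations, %d undefined, mean %.4g, sd %.4g\n",
    x$drugId, x$nPerm, x$nUndefined, x$mean, x$sd))
  invisible(x)
}

#' Permutation Z-score of an association score
#'
#' \deqn{Z = \frac{S - \overline{S_{random}}}{\mathrm{sd}(S_{random})}.}
#' Undefined when \code{S} is undefined or the null's standard deviation is
#' zero or undefined (a degenerate null cannot standardise the score).
#'
#' @param S observed association score (or \code{NULL}/\code{NA} when
#'   undefined).
#' @param null a \code{"permutationNull"} as returned by
#'   [permutationNull()].
#' @return the Z-score, or \code{NA} when undefined.
#' @export
zScore <- function(S, null) {
  stopifnot(inherits(null, "permutationNull"))
  if (is.null(S) || is.na(S)) return(NA_real_)
  if (is.na(null$sd) || null$sd == 0) return(NA_real_)
  (S - null$mean) / null$sd
}

#' Rank drugs and apply the Z cutoff
#'
#' Sorts drugs by descending Z (undefined Z last), breaking ties by drug id,
#' assigns ranks 1..n, and flags drugs passing the screen with a strict
#' \code{Z > cutoff} (the default 1.96 is the two-sided standard-normal
#' critical value at significance .05).
#'
#' @param scores data.frame with at least columns \code{drug_id}, \code{S}
#'   and \code{Z} (additional columns are carried through).
#' @param cutoff positive Z threshold (default 1.96).
#' @return the data.frame with added \code{passed} and \code{rank} columns,
#'   sorted by rank.
#' @export
screenDrugs <- function(scores, cutoff = 1.96) {
  stopifnot(is.data.frame(scores),
            all(c("drug_id", "S", "Z") %in% names(scores)))
  if (!(length(cutoff) == 1 && cutoff > 0)) stop("cutoff must be positive",
                                                 call. = FALSE)
  if (!nrow(scores)) {
    scores$passed <- logical(); scores$rank <- integer()
    return(scores)
  }
  ord <- order(-ifelse(is.na(scores$Z), -Inf, scores$Z), scores$drug_id)
  out <- scores[ord, , drop = FALSE]
  out$passed <- !is.na(out$Z) & out$Z > cutoff
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full drug-repurposing screen
#'
#' End-to-end screen: enrich the disease gene set and every drug's target
#' set (after the minimum-target filter) against the pathway collection,
#' compute each retained drug's association score on its best shared
#' pathway, build a permutation null per drug (all drugs share one seeded
#' set of pathway-label permutations), and rank by Z with the strict
#' \code{Z > cutoff} pass flag.
#'
#' @param study a [SynthStudy-class], or any list with elements
#'   \code{universe}, \code{pathways} ([GeneSetCollection-class]),
#'   \code{diseaseGenes} and \code{drugTargets} ([TargetMap-class]).
#' @param alpha enrichment significance threshold (default 0.05).
#' @param adjust \code{"none"} (raw p, KEGG-style) or \code{"BH"}.
#' @param minTargets minimum targets per drug (default 6).
#' @param nPerm permutations per drug (default 10000).
#' @param cutoff Z threshold (default 1.96).
#' @param seed integer seed for the permutations.
#' @param ease use the EASE-style decremented overlap in enrichment.
#' @param out optional path; when given, the report is written as a
#'   commented TSV with run metadata and the write is byte-reproducible for
#'   identical inputs and seed.
#' @return data.frame with one row per retained drug: \code{drug_id},
#'   \code{best_pathway}, \code{S}, \code{perm_mean}, \code{perm_sd},
#'   \code{n_undefined}, \code{Z}, \code{passed}, \code{rank}.
#' @examples
#' study <- generateStudy(synthConfig(seed = 7))
#' rep <- runScreen(study, nPerm = 200, seed = 7)
#' head(rep)
#' @export
runScreen <- function(study, alpha = 0.05, adjust = c("none", "BH"),
                      minTargets = 6L, nPerm = 10000L, cutoff = 1.96,
                      seed = 1L, ease = FALSE, out = NULL) {
  adjust <- match.arg(adjust)
  comp <- studyComponents(study)
  disTab <- enrich(comp$diseaseGenes, comp$pathways, comp$universe,
                   alpha = alpha, adjust = adjust, ease = ease,
                   entityName = "disease")
  drugs <- filterRegulators(comp$drugTargets, minTargets)
  drugTabs <- enrichAll(drugs, comp$pathways, comp$universe, alpha = alpha,
                        adjust = adjust, ease = ease)
  P <- length(pathwayUniverse(disTab))
  permM <- withSeed(seed, matrix(unlist(lapply(seq_len(nPerm), function(i)
    sample.int(P))), nrow = nPerm, byrow = TRUE))
  rows <- lapply(names(drugTabs), function(d) {
    sc <- associationScore(disTab, drugTabs[[d]])
    nul <- permutationNull(disTab, drugTabs[[d]], permMatrix = permM)
    data.frame(drug_id = d,
               best_pathway = if (is.null(sc)) NA_character_ else sc$bestPathway,
               S = if (is.null(sc)) NA_real_ else sc$S,
               perm_mean = nul$mean, perm_sd = nul$sd,
               n_undefined = nul$nUndefined,
               Z = zScore(if (is.null(sc)) NA else sc$S, nul),
               stringsAsFactors = FALSE)
  })
  report <- screenDrugs(do.call(rbind, rows), cutoff = cutoff)
  if (!is.null(out)) {
    meta <- c(sprintf("mdngscreen drug screen report"),
              sprintf("alpha=%g adjust=%s min_targets=%d n_perm=%d cutoff=%g seed=%d",
                      alpha, adjust, as.integer(minTargets),
                      as.integer(nPerm), cutoff, as.integer(seed)),
              sprintf("package_version=%s",
                      as.character(utils::packageVersion("mdngscreen"))))
    writeTable(report, out, comments = meta)
  }
  report
}

studyComponents <- function(study) {
  if (is(study, "SynthStudy"))
    return(list(universe = study@universe, pathways = study@pathways,
                diseaseGenes = study@diseaseGenes,
                mirnaTargets = study@mirnaTargets,
                drugTargets = study@drugTargets))
  stopifnot(is.list(study),
            all(c("universe", "pathways", "diseaseGenes", "drugTargets")
                %in% names(study)))
  study
}
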