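#' @include AllClasses.R accessors.R io.R synthetic.R enrichment.R network.R screening.R
NULL

#' Flatten enrichment tables into one data.frame
#'
#' @param tables an [EnrichmentTable-class] or a list of them.
#' @return data.frame with an \code{entity} column followed by the
#'   per-pathway enrichment columns of every table, row-bound.
#' @export
enrichmentToTable <- function(tables) {
  if (is(tables, "EnrichmentTable")) tables <- list(tables)
  rows <- lapply(tables, function(et) {
    r <- et@results
    if (!nrow(r))
      return(cbind(data.frame(entity = character()), r))
    cbind(data.frame(entity = et@entityId, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-command end-to-end run
#'
#' Simulates a synthetic study (or takes one that is already built),
#' enriches the disease genes and every retained miRNA and drug against the
#' pathway collection, builds the tripartite MDNG with its topology
#' statistics, runs the permutation Z-score drug screen, and writes all
#' artifacts plus a JSON run manifest with the record counts at each filter
#' stage.
#'
#' Artifacts written under \code{outDir}: \code{study/} (the synthetic input
#' files and their manifest), \code{disease_enrichment.tsv},
#' \code{mirna_enrichment.tsv}, \code{drug_enrichment.tsv}, \code{net.sif},
#' \code{stats.tsv}, \code{report.tsv} and \code{run_manifest.json}.
#'
#' @param config a [SynthConfig-class] (see [synthConfig()],
#'   [synthPreset()]) or an already-generated [SynthStudy-class].
#' @param outDir output directory, created if absent.
#' @inheritParams runScreen
#' @param keepPartial retain pathways with only one regulator class in the
#'   network (see [buildMdng()]).
#' @return invisibly, a list with the screen \code{report}, the
#'   \code{network} ([Mdng-class]), the \code{powerLaw} fit (or \code{NULL}
#'   when the degree distribution is degenerate) and the \code{manifest}
#'   list.
#' @examples
#' \donttest{
#' res <- runAll(synthConfig(seed = 7), tempfile("run"), nPerm = 100)
#' res$manifest$counts$drugs_passed
#' }
#' @export
runAll <- function(config, outDir, alpha = 0.05, adjust = c("none", "BH"),
                   minTargets = 6L, nPerm = 10000L, cutoff = 1.96,
                   seed = NULL, ease = FALSE, keepPartial = FALSE) {
  adjust <- match.arg(adjust)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  study <- if (is(config, "SynthStudy")) config else generateStudy(config)
  if (is.null(seed)) seed <- study@config@seed
  writeStudy(study, file.path(outDir, "study"))

  disTab <- enrich(study@diseaseGenes, study@pathways, study@universe,
                   alpha = alpha, adjust = adjust, ease = ease,
                   entityName = "disease")
  writeTable(enrichmentToTable(disTab),
             file.path(outDir, "disease_enrichment.tsv"))

  mirnas <- filterRegulators(study@mirnaTargets, minTargets)
  drugs <- filterRegulators(study@drugTargets, minTargets)
  mirTabs <- enrichAll(mirnas, study@pathways, study@universe, alpha = alpha,
                       adjust = adjust, ease = ease)
  drugTabs <- enrichAll(drugs, study@pathways, study@universe, alpha = alpha,
                        adjust = adjust, ease = ease)
  writeTable(enrichmentToTable(mirTabs),
             file.path(outDir, "mirna_enrichment.tsv"))
  writeTable(enrichmentToTable(drugTabs),
             file.path(outDir, "drug_enrichment.tsv"))

  network <- buildMdng(disTab, mirTabs, drugTabs, keepPartial = keepPartial)
  writeSif(network, file.path(outDir, "net.sif"))
  writeTable(nodeStats(network), file.path(outDir, "stats.tsv"))
  powerLaw <- NULL
  if (nodeCount(network) > 0) {
    dd <- degreeDistribution(network)
    if (length(dd) >= 2) powerLaw <- fitPowerLaw(dd)
  }

  report <- runScreen(study, alpha = alpha, adjust = adjust,
                      minTargets = minTargets, nPerm = nPerm,
                      cutoff = cutoff, seed = seed, ease = ease,
                      out = file.path(outDir, "report.tsv"))

  manifest <- list(
    config = configAsList(study@config),
    params = list(alpha = alpha, adjust = adjust,
                  min_targets = as.integer(minTargets),
                  n_perm = as.integer(nPerm), cutoff = cutoff,
                  seed = as.integer(seed), ease = ease,
                  keep_partial = keepPartial),
    counts = list(
      genes = length(study@universe),
      pathways = length(study@pathways@setIds),
      disease_genes = length(study@diseaseGenes),
      mirnas_input = length(study@mirnaTargets@targets),
      mirnas_retained = length(mirnas@targets),
      drugs_input = length(study@drugTargets@targets),
      drugs_retained = length(drugs@targets),
      disease_significant_pathways = length(significantPathways(disTab)),
      network_pathways = nodeCount(network, "pathway"),
      network_mirnas = nodeCount(network, "miRNA"),
      network_drugs = nodeCount(network, "drug"),
      network_nodes = nodeCount(network),
      network_edges = edgeCount(network),
      drugs_scored = sum(!is.na(report$Z)),
      drugs_passed = sum(report$passed)),
    power_law = if (is.null(powerLaw)) NULL else
      list(a = powerLaw@a, b = powerLaw@b, r_squared = powerLaw@rSquared,
           n_points = powerLaw@nPoints))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, network = network, powerLaw = powerLaw,
                 manifest = manifest))
}
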