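#' @include AllClasses.R accessors.R io.R
NULL

withSeed <- function(seed, expr) {
  glob <- globalenv()
  had <- exists(".Random.seed", envir = glob, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = glob, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = glob)
    else if (exists(".Random.seed", envir = glob, inherits = FALSE))
      rm(".Random.seed", envir = glob)
  })
  set.seed(seed)
  expr
}

#' Configure a synthetic study
#'
#' Builds a validated [SynthConfig-class]. The defaults define the package's
#' small "test" preset: a 200-gene universe carrying 12 overlapping pathways
#' of 10-20 genes, 3 of which are designated risk pathways; 30 disease genes
#' of which 80\% are drawn from the risk-pathway union; and 20 miRNAs plus
#' 20 drugs with 10-30 targets each, 5 of each class "responsive" (80\% of
#' their targets from risk-pathway genes) and the rest sampling the universe
#' uniformly.
#'
#' @param nGenes universe size.
#' @param nPathways number of pathways.
#' @param pathwaySizeRange inclusive (min, max) pathway size.
#' @param nRiskPathways number of planted risk pathways.
#' @param nDiseaseGenes disease risk-gene count.
#' @param diseaseSignal fraction of disease genes drawn from the risk-pathway
#'   union.
#' @param nMirnas,nDrugs regulator counts.
#' @param nResponsiveMirnas,nResponsiveDrugs responsive regulator counts.
#' @param targetsPerRegulatorRange inclusive (min, max) targets per regulator.
#' @param regulatorSignal fraction of a responsive regulator's targets drawn
#'   from risk-pathway genes.
#' @param seed integer seed; identical seeds give identical studies.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nGenes = 200, nPathways = 12,
                        pathwaySizeRange = c(10, 20), nRiskPathways = 3,
                        nDiseaseGenes = 30, diseaseSignal = 0.8,
                        nMirnas = 20, nDrugs = 20,
                        nResponsiveMirnas = 5, nResponsiveDrugs = 5,
                        targetsPerRegulatorRange = c(10, 30),
                        regulatorSignal = 0.8, seed = 1) {
  new("SynthConfig",
      nGenes = as.integer(nGenes), nPathways = as.integer(nPathways),
      pathwaySizeRange = as.integer(pathwaySizeRange),
      nRiskPathways = as.integer(nRiskPathways),
      nDiseaseGenes = as.integer(nDiseaseGenes),
      diseaseSignal = as.numeric(diseaseSignal),
      nMirnas = as.integer(nMirnas), nDrugs = as.integer(nDrugs),
      nResponsiveMirnas = as.integer(nResponsiveMirnas),
      nResponsiveDrugs = as.integer(nResponsiveDrugs),
      targetsPerRegulatorRange = as.integer(targetsPerRegulatorRange),
      regulatorSignal = as.numeric(regulatorSignal),
      seed = as.integer(seed))
}

#' Preset synthetic-study configurations
#'
#' \code{"test"} is the fast default used throughout the test suite.
#' \code{"paper-scale"} mirrors the magnitudes of a genome-wide screen
#' (thousands of genes, hundreds of pathways, 61 risk pathways, 138 miRNAs,
#' 186 drugs) for exploratory runs.
#'
#' @param preset \code{"test"} or \code{"paper-scale"}.
#' @param seed integer seed.
#' @param ... overrides passed on to [synthConfig()].
#' @return a [SynthConfig-class].
#' @export
synthPreset <- function(preset = c("test", "paper-scale"), seed = 1, ...) {
  preset <- match.arg(preset)
  if (preset == "test") return(synthConfig(seed = seed, ...))
  synthConfig(nGenes = 6000, nPathways = 300, pathwaySizeRange = c(30, 120),
              nRiskPathways = 61, nDiseaseGenes = 1102, diseaseSignal = 0.8,
              nMirnas = 138, nDrugs = 186, nResponsiveMirnas = 30,
              nResponsiveDrugs = 40,
              targetsPerRegulatorRange = c(6, 100), regulatorSignal = 0.8,
              seed = seed, ...)
}

padId <- function(prefix, i, total)
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(total))), i)

#' Generate a synthetic study with planted structure
#'
#' Samples, in a fixed order driven by a single seeded stream (pathways,
#' then disease genes, then miRNAs, then drugs):
#' \itemize{
#' \item pathways: genes drawn uniformly without replacement per pathway
#'   (pathways may overlap, as real pathway collections do);
#' \item disease genes: a \code{diseaseSignal} fraction sampled from the
#'   union of the designated risk pathways, the remainder uniform from the
#'   rest of the universe, totalling exactly \code{nDiseaseGenes};
#' \item regulators: responsive regulators draw a \code{regulatorSignal}
#'   fraction of their targets from risk-pathway genes, null regulators draw
#'   uniformly from the universe.
#' }
#' Identical configurations (including seed) reproduce the study exactly.
#'
#' @param config a [SynthConfig-class].
#' @return a [SynthStudy-class].
#' @examples
#' study <- generateStudy(synthConfig(seed = 42))
#' study
#' @export
generateStudy <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  withSeed(config@seed, {
    universe <- padId("G", seq_len(config@nGenes), config@nGenes)
    pwIds <- padId("P", seq_len(config@nPathways), config@nPathways)
    sizes <- sample(seq(config@pathwaySizeRange[1], config@pathwaySizeRange[2]),
                    config@nPathways, replace = TRUE)
    members <- lapply(sizes, function(s) sample(universe, s))
    names(members) <- pwIds
    riskIds <- sort(sample(pwIds, config@nRiskPathways))
    riskUnion <- sort(unique(unlist(members[riskIds])))

    nSig <- round(config@diseaseSignal * config@nDiseaseGenes)
    if (nSig > length(riskUnion))
      stop("infeasible config: diseaseSignal * nDiseaseGenes (", nSig,
           ") exceeds the risk-pathway union (", length(riskUnion), " genes)",
           call. = FALSE)
    disSig <- if (nSig) sample(riskUnion, nSig) else character()
    disease <- c(disSig,
                 sample(setdiff(universe, disSig), config@nDiseaseGenes - nSig))

    drawTargets <- function(responsive) {
      nt <- sample(seq(config@targetsPerRegulatorRange[1],
                       config@targetsPerRegulatorRange[2]), 1)
      if (!responsive) return(sample(universe, nt))
      ns <- round(config@regulatorSignal * nt)
      if (ns > length(riskUnion))
        stop("infeasible config: regulatorSignal * targets (", ns,
             ") exceeds the risk-pathway union (", length(riskUnion),
             " genes)", call. = FALSE)
      sig <- if (ns) sample(riskUnion, ns) else character()
      c(sig, sample(setdiff(universe, sig), nt - ns))
    }
    mirIds <- padId("hsa-mir-", seq_len(config@nMirnas), config@nMirnas)
    respMir <- sort(sample(mirIds, config@nResponsiveMirnas))
    mirTargets <- lapply(mirIds, function(m) drawTargets(m %in% respMir))
    names(mirTargets) <- mirIds
    drugIds <- padId("DB", seq_len(config@nDrugs), config@nDrugs)
    respDrug <- sort(sample(drugIds, config@nResponsiveDrugs))
    drugTargets <- lapply(drugIds, function(d) drawTargets(d %in% respDrug))
    names(drugTargets) <- drugIds

    new("SynthStudy",
        universe = universe,
        pathways = GeneSetCollection(members,
          descriptions = ifelse(pwIds %in% riskIds, "risk pathway",
                                "background pathway")),
        diseaseGenes = disease,
        mirnaTargets = TargetMap(mirTargets, "miRNA"),
        drugTargets = TargetMap(drugTargets, "drug"),
        truth = list(riskPathwayIds = riskIds,
                     responsiveMirnaIds = respMir,
                     responsiveDrugIds = respDrug),
        config = config)
  })
}

configAsList <- function(config) {
  sl <- slotNames("SynthConfig")
  stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

#' Write a synthetic study to a directory
#'
#' Emits \code{universe.txt}, \code{pathways.gmt}, \code{disease_genes.txt},
#' \code{mirna_targets.tsv}, \code{drug_targets.tsv}, \code{truth.tsv} and a
#' \code{manifest.json} recording the full configuration and seed.
#'
#' @param study a [SynthStudy-class].
#' @param outDir output directory (created if absent).
#' @return the manifest, invisibly (a list).
#' @seealso [readStudy()]
#' @export
writeStudy <- function(study, outDir) {
  stopifnot(is(study, "SynthStudy"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  writeGeneList(study@universe, p("universe.txt"))
  writeGmt(study@pathways, p("pathways.gmt"))
  writeGeneList(study@diseaseGenes, p("disease_genes.txt"))
  writeTargetMap(study@mirnaTargets, p("mirna_targets.tsv"))
  writeTargetMap(study@drugTargets, p("drug_targets.tsv"))
  tr <- study@truth
  truthTab <- data.frame(
    type = rep(c("risk_pathway", "responsive_mirna", "responsive_drug"),
               c(length(tr$riskPathwayIds), length(tr$responsiveMirnaIds),
                 length(tr$responsiveDrugIds))),
    id = c(tr$riskPathwayIds, tr$responsiveMirnaIds, tr$responsiveDrugIds),
    stringsAsFactors = FALSE)
  writeTable(truthTab, p("truth.tsv"))
  manifest <- list(config = configAsList(study@config),
                   seed = study@config@seed,
                   files = c("universe.txt", "pathways.gmt",
                             "disease_genes.txt", "mirna_targets.tsv",
                             "drug_targets.tsv", "truth.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a synthetic study back from a directory
#'
#' Reconstructs the [SynthStudy-class] written by [writeStudy()] from its
#' plain-text files and manifest.
#'
#' @param dir directory containing the study files.
#' @return a [SynthStudy-class].
#' @export
readStudy <- function(dir) {
  p <- function(f) file.path(dir, f)
  manifest <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  cfg <- do.call(synthConfig, lapply(manifest$config, unlist))
  truthTab <- readTable(p("truth.tsv"))
  new("SynthStudy",
      universe = readGeneList(p("universe.txt")),
      pathways = readGmt(p("pathways.gmt")),
      diseaseGenes = readGeneList(p("disease_genes.txt")),
      mirnaTargets = readTargetMap(p("mirna_targets.tsv"), "miRNA"),
      drugTargets = readTargetMap(p("drug_targets.tsv"), "drug"),
      truth = list(
        riskPathwayIds = truthTab$id[truthTab$type == "risk_pathway"],
        responsiveMirnaIds = truthTab$id[truthTab$type == "responsive_mirna"],
        responsiveDrugIds = truthTab$id[truthTab$type == "responsive_drug"]),
      config = cfg)
}
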