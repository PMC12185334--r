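# End-to-end orchestration: simulate -> preprocess -> pgs-prep -> fit ->
# correct -> report, driven by one config, writing every stage output and
# a count-accounting log into a run directory.

#' Build and validate a pipeline run configuration
#'
#' All stage parameters have study-calibrated defaults; a single master
#' seed fans out to named substreams per component.
#'
#' @param outDir run directory (created if absent).
#' @param seed master seed.
#' @param nFamilies,offspringPerFamily,pMz,nLoci,nProbes simulator sizes.
#' @param pMissingMother,pMissingFather,pMissingBoth parental PGS
#'   missingness (marginal, marginal, joint).
#' @param effectSpecs list of [effectSpec()] truths for causal probes.
#' @param familySd,noiseSd liability variance components.
#' @param iqrK IQR multiplier for outlier masking.
#' @param maxMissing per-probe missingness tolerance.
#' @param topQ top-variance fraction retained.
#' @param working GEE working correlation structure.
#' @param alpha family-wise significance level.
#' @param meffMethod \code{"nyholt"} or \code{"liji"}.
#' @param inputs optional named list of pre-existing input files
#'   (\code{beta}, \code{pedigree}, \code{pgs}, \code{covariates},
#'   \code{manifest}); when given, the simulate stage is skipped.
#' @return A validated \code{RunConfig} list.
#' @export
runConfig <- function(outDir, seed = 1, nFamilies = 764,
                      offspringPerFamily = 2, pMz = 0.74, nLoci = 200,
                      nProbes = 500, pMissingMother = 0.079,
                      pMissingFather = 0.189, pMissingBoth = 0.051,
                      effectSpecs = list(), familySd = 0.5, noiseSd = 0.5,
                      iqrK = 3, maxMissing = 0.05, topQ = 0.10,
                      working = "independence", alpha = 0.05,
                      meffMethod = "nyholt", inputs = NULL) {
  cfg <- list(outDir = outDir, seed = seed, nFamilies = nFamilies,
              offspringPerFamily = offspringPerFamily, pMz = pMz,
              nLoci = nLoci, nProbes = nProbes,
              pMissingMother = pMissingMother,
              pMissingFather = pMissingFather,
              pMissingBoth = pMissingBoth, effectSpecs = effectSpecs,
              familySd = familySd, noiseSd = noiseSd, iqrK = iqrK,
              maxMissing = maxMissing, topQ = topQ, working = working,
              alpha = alpha, meffMethod = meffMethod, inputs = inputs)
  class(cfg) <- "RunConfig"
  validateRunConfig(cfg)
}

#' @rdname runConfig
#' @param cfg a RunConfig (or plain list with the same fields).
#' @export
validateRunConfig <- function(cfg) {
  req <- c("outDir", "seed", "topQ", "maxMissing", "iqrK", "alpha",
           "working", "meffMethod")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config lacks field(s): ", paste(miss, collapse = ", "))
  if (cfg$topQ <= 0 || cfg$topQ > 1) stop("topQ must lie in (0, 1]")
  if (cfg$maxMissing < 0 || cfg$maxMissing > 1)
    stop("maxMissing must lie in [0, 1]")
  if (cfg$iqrK <= 0) stop("iqrK must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!cfg$working %in% c("independence", "exchangeable"))
    stop("working must be independence or exchangeable")
  if (!cfg$meffMethod %in% c("nyholt", "liji"))
    stop("meffMethod must be nyholt or liji")
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("missing input file(s): ", paste(absent, collapse = ", "))
  }
  invisible(cfg)
}

#' Read/write a RunConfig as YAML
#'
#' @param cfg a RunConfig.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "RunConfig"
  validateRunConfig(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order, writing every stage's output as TSV
#' into the run directory together with the resolved config
#' (\code{config.yaml}) and a log that records the probe/sample accounting
#' at every filter boundary. Inputs are never mutated; all outputs are new
#' files. Re-running with the same config is bit-identical.
#'
#' @param cfg a [runConfig()] object.
#' @return Invisibly, a list with the main in-memory results
#'   (\code{methyl}, \code{results}, \code{meff}, \code{hits},
#'   \code{counts}, \code{truth}).
#' @export
runPipeline <- function(cfg) {
  validateRunConfig(cfg)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(cfg$outDir, "run.log")
  logLines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    message(line)
  }
  writeRunConfig(cfg, file.path(cfg$outDir, "config.yaml"))

  if (is.null(cfg$inputs)) {
    say("stage simulate: %d families, %d loci, %d probes, seed %d",
        cfg$nFamilies, cfg$nLoci, cfg$nProbes, cfg$seed)
    fam <- simulateFamilies(cfg$nFamilies, cfg$offspringPerFamily, cfg$pMz,
                            cfg$nLoci, seed = cfg$seed)
    pedigree <- fam$pedigree
    w <- simulatePgsWeights(fam$genotypes, seed = cfg$seed)
    pgs <- computeTruePgs(fam$genotypes, pedigree, w)
    covariates <- simulateCovariates(pedigree, seed = cfg$seed)
    truth <- simulationTruth(effectSpecs = cfg$effectSpecs,
                             familySd = cfg$familySd, noiseSd = cfg$noiseSd,
                             seed = cfg$seed)
    sim <- simulateMethylation(pedigree, pgs, covariates, truth,
                               nProbes = cfg$nProbes)
    methyl <- sim$methyl
    truth <- sim$truth
    pgs <- applyParentMissingness(pgs, pedigree,
                                  cfg$pMissingMother, cfg$pMissingFather,
                                  cfg$pMissingBoth, seed = cfg$seed)
    manifest <- simulateProbeManifest(rownames(methyl), seed = cfg$seed)
    writeTable(pedigree, file.path(cfg$outDir, "pedigree.tsv"))
    writeTable(pgs, file.path(cfg$outDir, "pgs_raw.tsv"))
    writeTable(covariates, file.path(cfg$outDir, "covariates.tsv"))
    writeTable(manifest, file.path(cfg$outDir, "manifest.tsv"))
    writeBetaMatrix(methyl, file.path(cfg$outDir, "beta_raw.tsv"))
    truthOut <- truth
    truthOut$mu <- as.numeric(truthOut$mu)
    yaml::write_yaml(unclass(truthOut), file.path(cfg$outDir, "truth.yaml"))
  } else {
    say("stage load: reading supplied inputs")
    pedigree <- assertPedigree(readTable(cfg$inputs$pedigree))
    pgs <- assertPgsTable(readTable(cfg$inputs$pgs))
    covariates <- readTable(cfg$inputs$covariates)
    manifest <- readTable(cfg$inputs$manifest)
    methyl <- readBetaMatrix(cfg$inputs$beta, state = "raw")
    truth <- NULL
  }
  say("counts: %d probes x %d samples, %d families", nrow(methyl),
      ncol(methyl), length(unique(pedigree$family_id)))

  say("stage preprocess: qc filter, %gxIQR mask, impute (<=%g), residualize, top %g",
      cfg$iqrK, cfg$maxMissing, cfg$topQ)
  n0 <- nrow(methyl)
  methyl <- qcFilter(methyl, manifest)
  say("qc filter: total %d = retained %d + dropped %d",
      n0, nrow(methyl), n0 - nrow(methyl))
  methyl <- maskOutliersIqr(methyl, k = cfg$iqrK)
  say("iqr mask: %d values masked", S4Vectors::metadata(methyl)$nMasked)
  n1 <- nrow(methyl)
  methyl <- imputeMissing(methyl, maxMissing = cfg$maxMissing)
  say("imputation: total %d = retained %d + dropped %d",
      n1, nrow(methyl), n1 - nrow(methyl))
  methyl <- residualizeMethyl(methyl, covariates)
  n2 <- nrow(methyl)
  methyl <- selectTopVariance(methyl, q = cfg$topQ)
  say("top variance: total %d = retained %d + dropped %d",
      n2, nrow(methyl), n2 - nrow(methyl))
  writeBetaMatrix(methyl, file.path(cfg$outDir, "beta_residualized.tsv"))

  say("stage pgs-prep: residualize on PCs/platform, standardize, zero-impute")
  pgs <- standardizePgs(pgs, covariates)
  pgs <- imputeParentPgs(pgs)
  say("pgs: %d imputed parental entries", sum(pgs$imputed))
  writeTable(pgs, file.path(cfg$outDir, "pgs_final.tsv"))

  say("stage fit: GEE (%s working correlation)", cfg$working)
  design <- buildGeeDesign(pgs, pedigree, covariates)
  results <- fitGee(methyl, design, working = cfg$working)
  cs <- convergenceSummary(results)
  say("fit: total %d = successful %d + non-converged %d",
      cs[["total"]], cs[["successful"]], cs[["nonconverged"]])
  writeGeeResults(results, file.path(cfg$outDir, "gee_results.tsv"))

  say("stage correct: effective tests (%s)", cfg$meffMethod)
  meff <- effectiveTests(methyl, globalAlpha = cfg$alpha,
                         method = cfg$meffMethod)
  say("meff: %d probes -> %d effective tests, alpha %.4g",
      meff@mProbes, meff@mEffRounded, meff@alpha)
  writeMeffResult(meff, file.path(cfg$outDir, "meff.txt"))

  say("stage report: threshold at alpha %.4g", meff@alpha)
  hits <- classifyHits(results, adjustedAlpha(meff), manifest)
  counts <- countHits(hits)
  say("hits: %d total = direct %d + indirect %d", counts$total,
      counts$nDirect, counts$nIndirect)
  writeTable(hits, file.path(cfg$outDir, "hits.tsv"))
  writeLines(utils::capture.output(print(counts)),
             file.path(cfg$outDir, "counts.txt"))

  writeLines(logLines, logPath)
  invisible(list(methyl = methyl, results = results, meff = meff,
                 hits = hits, counts = counts, truth = truth,
                 pedigree = pedigree, pgs = pgs, design = design))
}
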