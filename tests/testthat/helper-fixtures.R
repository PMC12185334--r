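# Shared fixture builders. Everything is generated in code at test time.

# A small simulated cohort: pedigree, genotypes, PGS, covariates.
makeCohort <- function(nFamilies = 40, nLoci = 30, seed = 101, pMz = 0.5,
                       offspringPerFamily = 2) {
  fam <- simulateFamilies(nFamilies, offspringPerFamily = offspringPerFamily,
                          pMz = pMz, nLoci = nLoci, seed = seed)
  w <- simulatePgsWeights(fam$genotypes, seed = seed)
  pgs <- computeTruePgs(fam$genotypes, fam$pedigree, w)
  cov <- simulateCovariates(fam$pedigree, seed = seed)
  list(pedigree = fam$pedigree, genotypes = fam$genotypes, pgs = pgs,
       covariates = cov, weights = w)
}

# A ready-to-fit design on a small cohort.
makeDesign <- function(cohort = makeCohort()) {
  pgsF <- imputeParentPgs(standardizePgs(cohort$pgs, cohort$covariates))
  buildGeeDesign(pgsF, cohort$pedigree, cohort$covariates)
}

# Hand-build a GeeDesign from a raw matrix + cluster labels (for estimator
# oracles that need full control of X).
rawDesign <- function(X, clusters, kinds = NULL) {
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  if (is.null(kinds)) kinds <- c("intercept", rep("covariate", ncol(X) - 1))
  meta <- data.frame(column = colnames(X), kind = kinds,
                     role = NA_character_, trait = NA_character_,
                     stringsAsFactors = FALSE)
  methods::new("GeeDesign", X = X, clusters = factor(clusters),
               predictors = meta)
}

# A raw MethylExperiment from an explicit samples-x-probes matrix.
methFromSamples <- function(m, state = "raw") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("cg%06d", seq_len(ncol(m)))
  MethylExperiment(t(m), state = state)
}

invLogitMat <- function(x) 1 / (1 + exp(-x))

advanceStateTo <- function(me, to) methylNurture:::advanceState(me, to)

# Per-probe brute-force IQR mask oracle (independent of the implementation
# loop): returns a logical samples-mask per probe.
bruteIqrMask <- function(x, k = 3, type = 7) {
  obs <- !is.na(x)
  if (sum(obs) < 4) return(rep(FALSE, length(x)))
  q <- unname(quantile(x[obs], c(0.25, 0.75), type = type))
  lo <- q[1] - k * (q[2] - q[1])
  hi <- q[2] + k * (q[2] - q[1])
  obs & (x < lo | x > hi)
}
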