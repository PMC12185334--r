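# Synthetic nuclear twin families: Mendelian genotypes, polygenic scores,
# covariates, and methylation with known direct and indirect effects.

#' Simulate nuclear twin families with Mendelian genotype transmission
#'
#' Draws parental genotypes at unlinked biallelic loci in Hardy-Weinberg
#' proportions under random mating, then transmits one allele per locus per
#' parent to each offspring. MZ twin pairs duplicate the first twin's
#' genome; DZ co-twins are independent transmissions from the same parents.
#'
#' @param nFamilies number of families (>= 1).
#' @param offspringPerFamily offspring per family; the first two form the
#'   twin pair, any further offspring are singleton siblings.
#' @param pMz probability that the twin pair is monozygotic. Default 0.74,
#'   the MZ share among twins in the study population this generator
#'   emulates.
#' @param nLoci number of unlinked loci (>= 1).
#' @param seed master seed; the genotype stream is derived from it.
#' @return A list with elements \code{pedigree} (data.frame: family_id,
#'   individual_id, role, zygosity, dataset) and \code{genotypes}
#'   (\linkS4class{GenotypeSet}). Dataset labels are drawn with the cohort
#'   shares (0.06, 0.75, 0.19).
#' @examples
#' fam <- simulateFamilies(5, nLoci = 20, seed = 1)
#' table(fam$pedigree$role)
#' @export
simulateFamilies <- function(nFamilies, offspringPerFamily = 2, pMz = 0.74,
                             nLoci = 100, seed = 1) {
  if (nFamilies < 1 || nLoci < 1 || offspringPerFamily < 1)
    stop("nFamilies, nLoci and offspringPerFamily must be positive")
  if (pMz < 0 || pMz > 1) stop("pMz must lie in [0,1]")
  set.seed(childSeed(seed, "genotypes"))

  freq <- runif(nLoci, 0.05, 0.95)
  loci <- data.frame(locus_id = sprintf("rs%06d", seq_len(nLoci)),
                     freq = freq, stringsAsFactors = FALSE)

  famIds <- sprintf("fam%05d", seq_len(nFamilies))
  zyg <- ifelse(runif(nFamilies) < pMz, "MZ", "DZ")
  dataset <- sample(1:3, nFamilies, replace = TRUE,
                    prob = c(0.06, 0.75, 0.19))

  # parental haplotype pairs per locus, Bernoulli(freq) per allele
  drawParent <- function(n) {
    a1 <- matrix(rbinom(n * nLoci, 1, rep(freq, each = n)), n, nLoci)
    a2 <- matrix(rbinom(n * nLoci, 1, rep(freq, each = n)), n, nLoci)
    list(a1 = a1, a2 = a2)
  }
  mom <- drawParent(nFamilies)
  dad <- drawParent(nFamilies)

  transmit <- function(par) {
    pick <- matrix(runif(nFamilies * nLoci) < 0.5, nFamilies, nLoci)
    ifelse(pick, par$a1, par$a2)
  }

  offDos <- vector("list", offspringPerFamily)
  for (k in seq_len(offspringPerFamily)) {
    offDos[[k]] <- transmit(mom) + transmit(dad)
  }
  # MZ pairs share one genome: copy twin 1 into twin 2
  if (offspringPerFamily >= 2) {
    mz <- zyg == "MZ"
    offDos[[2]][mz, ] <- offDos[[1]][mz, ]
  }

  momDos <- mom$a1 + mom$a2
  dadDos <- dad$a1 + dad$a2
  k <- offspringPerFamily
  perFam <- k + 2L
  famCol <- rep(famIds, each = perFam)
  roleCol <- rep(c("mother", "father", rep("offspring", k)), nFamilies)
  suffix <- rep(c("_m", "_f", sprintf("_o%d", seq_len(k))), nFamilies)
  offZyg <- rep("NA", k)
  zygCol <- as.vector(vapply(zyg, function(z) {
    zz <- offZyg; if (k >= 2) zz[1:2] <- z; c("NA", "NA", zz)
  }, character(perFam)))
  pedigree <- data.frame(
    family_id = famCol,
    individual_id = paste0(famCol, suffix),
    role = roleCol,
    zygosity = zygCol,
    dataset = rep(dataset, each = perFam),
    stringsAsFactors = FALSE)
  # interleave mother/father/offspring rows family by family
  blocks <- c(list(momDos, dadDos), offDos)
  dos <- matrix(0L, nFamilies * perFam, nLoci)
  for (b in seq_len(perFam)) {
    dos[seq(b, by = perFam, length.out = nFamilies), ] <-
      as.integer(blocks[[b]])
  }
  rownames(dos) <- pedigree$individual_id
  colnames(dos) <- loci$locus_id
  assertPedigree(pedigree)
  list(pedigree = pedigree,
       genotypes = new("GenotypeSet", dosages = dos, loci = loci))
}

#' Draw random per-locus effect weights for each trait
#'
#' @param genotypes a \linkS4class{GenotypeSet} (or locus count).
#' @param traits trait names; default the six-trait panel.
#' @param seed RNG seed.
#' @return Matrix loci x traits of standard-normal weights.
#' @export
simulatePgsWeights <- function(genotypes, traits = defaultTraits(), seed = 1) {
  nLoci <- if (is(genotypes, "GenotypeSet")) nrow(lociInfo(genotypes))
           else as.integer(genotypes)
  set.seed(childSeed(seed, "weights"))
  w <- matrix(rnorm(nLoci * length(traits)), nLoci, length(traits))
  colnames(w) <- traits
  if (is(genotypes, "GenotypeSet")) rownames(w) <- lociInfo(genotypes)$locus_id
  w
}

#' Compute true polygenic scores from simulated genotypes
#'
#' PGS = weighted dosage sum per person and trait, then centred and scaled
#' within generation (offspring vs. parents) so each score has zero mean
#' and unit variance in its own generation.
#'
#' @param genotypes a \linkS4class{GenotypeSet}.
#' @param pedigree the matching pedigree data.frame.
#' @param weights loci x traits weight matrix (rownames = locus ids).
#' @return Long-format PGS table: individual_id, role, trait, value,
#'   imputed (all FALSE).
#' @export
computeTruePgs <- function(genotypes, pedigree, weights) {
  assertPedigree(pedigree)
  dos <- dosages(genotypes)
  if (is.null(rownames(weights)))
    rownames(weights) <- lociInfo(genotypes)$locus_id
  if (!identical(rownames(weights), lociInfo(genotypes)$locus_id))
    stop("weights must cover exactly the genotype loci, in order")
  raw <- dos %*% weights          # persons x traits
  role <- pedigree$role[match(rownames(raw), pedigree$individual_id)]
  if (anyNA(role)) stop("genotyped individuals missing from pedigree")
  gen <- ifelse(role == "offspring", "offspring", "parent")
  for (g in unique(gen)) {
    idx <- gen == g
    for (t in seq_len(ncol(raw))) {
      s <- sd(raw[idx, t])
      if (s == 0)
        stop("zero-variance PGS for trait '", colnames(raw)[t],
             "' in generation ", g, "; cannot standardize")
      raw[idx, t] <- (raw[idx, t] - mean(raw[idx, t])) / s
    }
  }
  out <- data.frame(
    individual_id = rep(rownames(raw), times = ncol(raw)),
    role = rep(role, times = ncol(raw)),
    trait = rep(colnames(raw), each = nrow(raw)),
    value = as.vector(raw),
    imputed = FALSE,
    stringsAsFactors = FALSE)
  assertPgsTable(out)
}

#' Simulate covariates for a pedigree
#'
#' Offspring rows carry the methylation covariates (sex, age, epithelial
#' and NK cell proportions, array row, bisulfite plate, dataset); every
#' person carries 10 genetic principal components and two genotyping
#' platform dummies. Values are filled for parents too so the table has no
#' missing entries; parental methylation covariates are simply never used.
#'
#' @param pedigree pedigree data.frame.
#' @param seed RNG seed (covariate stream derived from it).
#' @return data.frame with one row per individual.
#' @export
simulateCovariates <- function(pedigree, seed = 1) {
  assertPedigree(pedigree)
  if (!nrow(pedigree)) stop("pedigree is empty")
  set.seed(childSeed(seed, "covariates"))
  n <- nrow(pedigree)
  isOff <- pedigree$role == "offspring"

  # twins share sex and age; parents get their own
  famAge <- round(runif(length(unique(pedigree$family_id)), 5, 15), 1)
  names(famAge) <- unique(pedigree$family_id)
  famSex <- setNames(sample(c("M", "F"), length(famAge), replace = TRUE),
                     names(famAge))
  age <- ifelse(isOff, famAge[pedigree$family_id],
                famAge[pedigree$family_id] + round(runif(n, 25, 40)))
  sex <- ifelse(pedigree$role == "mother", "F",
         ifelse(pedigree$role == "father", "M", famSex[pedigree$family_id]))
  # buccal swabs are epithelial-dominated with a small immune fraction
  epi <- pmin(pmax(rnorm(n, 0.85, 0.08), 0), 1)
  nk <- pmin(pmax(rnorm(n, 0.02, 0.01), 0), 1)
  arrayRow <- sample(sprintf("R%02d", 1:8), n, replace = TRUE)
  plate <- sample(sprintf("plate%02d", 1:12), n, replace = TRUE)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  platform <- sample(1:3, n, replace = TRUE)
  out <- data.frame(
    individual_id = pedigree$individual_id,
    role = pedigree$role,
    sex = sex, age = age, epithelial = epi, nk = nk,
    array_row = arrayRow, plate = plate,
    dataset = pedigree$dataset,
    stringsAsFactors = FALSE)
  out <- cbind(out, pcs)
  out$platform2 <- as.integer(platform == 2)
  out$platform3 <- as.integer(platform == 3)
  rownames(out) <- NULL
  assertCovariates(out)
}

#' Declare direct and indirect effects of one trait on a set of probes
#'
#' @param trait trait name.
#' @param delta direct effect per SD of offspring PGS (logit scale).
#' @param alphaM maternal indirect (genetic nurture) effect.
#' @param alphaP paternal indirect effect.
#' @param causalProbes probe ids carrying these effects; all other probes
#'   have zero effect for this trait.
#' @return An effect-spec list used by [simulationTruth()].
#' @export
effectSpec <- function(trait, delta = 0, alphaM = 0, alphaP = 0,
                       causalProbes = character()) {
  list(trait = trait, delta = delta, alphaM = alphaM, alphaP = alphaP,
       causalProbes = as.character(causalProbes))
}

#' Bundle the generative truth of a methylation simulation
#'
#' @param effectSpecs list of [effectSpec()] objects (possibly empty).
#' @param mu per-probe baseline on the logit scale; scalar (recycled) or
#'   vector of length nProbes; NULL draws N(0, 1.5) baselines.
#' @param covariateEffects named numeric vector of logit-scale covariate
#'   coefficients; names among sex, age, epithelial, nk, dataset2,
#'   dataset3. NULL uses modest defaults.
#' @param familySd SD of the family-level random intercept (>= 0).
#' @param noiseSd residual SD (>= 0).
#' @param seed seed for the methylation noise stream.
#' @return SimulationTruth list, serializable with [yaml::write_yaml()].
#' @export
simulationTruth <- function(effectSpecs = list(), mu = NULL,
                            covariateEffects = NULL, familySd = 0.5,
                            noiseSd = 0.5, seed = 1) {
  if (familySd < 0 || noiseSd < 0) stop("SDs must be nonnegative")
  if (is.null(covariateEffects))
    covariateEffects <- c(sex = 0.1, age = 0.02, epithelial = 1.0,
                          nk = -0.5, dataset2 = 0.1, dataset3 = -0.1)
  structure(list(effectSpecs = effectSpecs, mu = mu,
                 covariateEffects = covariateEffects,
                 familySd = familySd, noiseSd = noiseSd, seed = seed),
            class = "SimulationTruth")
}

#' Simulate offspring methylation beta-values with known effects
#'
#' Per offspring and probe, a Gaussian liability
#' mu + sum over traits (delta PGS_off + alphaM PGS_mother +
#' alphaP PGS_father) + covariate terms + family random intercept + noise
#' is mapped through the inverse-logit to a beta-value in (0,1). Effects
#' apply only on each spec's causal probes. The liability matrix is kept as
#' a second assay so effects can be recovered on the linear scale
#' (logit(beta) equals the liability exactly).
#'
#' @param pedigree pedigree data.frame.
#' @param pgs long PGS table covering all offspring and parents.
#' @param covariates covariate table from [simulateCovariates()].
#' @param truth a [simulationTruth()] object.
#' @param nProbes number of probes to simulate.
#' @return list(methyl = \linkS4class{MethylExperiment} (state raw, assays
#'   beta and liability), truth = the truth, with resolved per-probe mu).
#' @export
simulateMethylation <- function(pedigree, pgs, covariates, truth,
                                nProbes = 100) {
  assertPedigree(pedigree); assertPgsTable(pgs); assertCovariates(covariates)
  if (nProbes < 1) stop("nProbes must be positive")
  set.seed(childSeed(truth$seed, "methylation"))
  probeIds <- sprintf("cg%08d", seq_len(nProbes))
  for (es in truth$effectSpecs) {
    unknown <- setdiff(es$causalProbes, probeIds)
    if (length(unknown))
      stop("effect spec for trait '", es$trait,
           "' names unknown probe(s): ", paste(unknown, collapse = ", "))
  }
  mu <- truth$mu
  if (is.null(mu)) mu <- rnorm(nProbes, 0, 1.5)
  mu <- rep_len(mu, nProbes)
  truth$mu <- mu

  off <- pedigree[pedigree$role == "offspring", ]
  n <- nrow(off)

  # per-offspring trait-wise PGS lookups (own, mother's, father's)
  pgsWide <- function(roleSel, ids) {
    sub <- pgs[pgs$role %in% roleSel, ]
    traits <- unique(pgs$trait)
    m <- matrix(0, length(ids), length(traits),
                dimnames = list(ids, traits))
    key <- split(sub, sub$trait)
    for (t in traits) {
      v <- key[[t]]
      m[, t] <- v$value[match(ids, v$individual_id)]
    }
    m
  }
  momId <- vapply(off$family_id, function(f)
    pedigree$individual_id[pedigree$family_id == f &
                             pedigree$role == "mother"], character(1))
  dadId <- vapply(off$family_id, function(f)
    pedigree$individual_id[pedigree$family_id == f &
                             pedigree$role == "father"], character(1))
  pgsOff <- pgsWide("offspring", off$individual_id)
  pgsMom <- pgsWide("mother", momId); rownames(pgsMom) <- off$individual_id
  pgsDad <- pgsWide("father", dadId); rownames(pgsDad) <- off$individual_id
  if (anyNA(pgsOff)) stop("PGS table does not cover all offspring")
  pgsMom[is.na(pgsMom)] <- 0  # masked parents contribute no nurture signal
  pgsDad[is.na(pgsDad)] <- 0

  cv <- covariates[match(off$individual_id, covariates$individual_id), ]
  ce <- truth$covariateEffects
  covTerm <- rep(0, n)
  if (!is.na(ce["sex"])) covTerm <- covTerm + ce[["sex"]] * (cv$sex == "M")
  if (!is.na(ce["age"])) covTerm <- covTerm + ce[["age"]] * cv$age
  if (!is.na(ce["epithelial"]))
    covTerm <- covTerm + ce[["epithelial"]] * cv$epithelial
  if (!is.na(ce["nk"])) covTerm <- covTerm + ce[["nk"]] * cv$nk
  if (!is.na(ce["dataset2"]))
    covTerm <- covTerm + ce[["dataset2"]] * (cv$dataset == 2)
  if (!is.na(ce["dataset3"]))
    covTerm <- covTerm + ce[["dataset3"]] * (cv$dataset == 3)

  # family random intercept drawn per probe: each probe has its own
  # family-level component, giving within-family correlation
  # familySd^2 / (familySd^2 + noiseSd^2) at every probe independently
  famFac <- factor(off$family_id)
  u <- matrix(rnorm(nlevels(famFac) * nProbes, 0, truth$familySd),
              nlevels(famFac), nProbes)[as.integer(famFac), , drop = FALSE]

  # genetic signal per probe: zero except on causal probes
  liab <- matrix(rep(mu, each = n), n, nProbes,
                 dimnames = list(off$individual_id, probeIds)) +
    covTerm + u
  for (es in truth$effectSpecs) {
    if (!length(es$causalProbes)) next
    sig <- es$delta * pgsOff[, es$trait] +
      es$alphaM * pgsMom[, es$trait] + es$alphaP * pgsDad[, es$trait]
    liab[, es$causalProbes] <- liab[, es$causalProbes] + sig
  }
  liab <- liab + matrix(rnorm(n * nProbes, 0, truth$noiseSd), n, nProbes)

  beta <- invLogit(liab)
  me <- MethylExperiment(t(beta), state = "raw")
  SummarizedExperiment::assay(me, "liability", withDimnames = FALSE) <- t(liab)
  list(methyl = me, truth = truth)
}

#' Mask parental polygenic scores in a subset of families
#'
#' Emulates incomplete parental genotyping: in selected families all of a
#' parent's trait scores are set missing (NA, flagged by the missing value
#' itself, not zero). Offspring scores are never masked.
#'
#' @param pgs long PGS table.
#' @param pedigree pedigree data.frame.
#' @param pMissingMother marginal probability a family's mother is missing.
#' @param pMissingFather marginal probability the father is missing.
#' @param pMissingBoth joint probability both are missing; must not exceed
#'   either marginal. Defaults reproduce 92.1% mothers present, 81.1%
#'   fathers present, 78.3% of families with both parents present.
#' @param seed RNG seed.
#' @return The PGS table with masked parental values set to NA.
#' @export
applyParentMissingness <- function(pgs, pedigree, pMissingMother = 0.079,
                                   pMissingFather = 0.189,
                                   pMissingBoth = 0.051, seed = 1) {
  assertPgsTable(pgs); assertPedigree(pedigree)
  ps <- c(pMissingMother, pMissingFather, pMissingBoth)
  if (any(ps < 0 | ps > 1)) stop("missingness probabilities must lie in [0,1]")
  if (pMissingBoth > min(pMissingMother, pMissingFather))
    stop("joint missingness cannot exceed either marginal")
  pOnlyM <- pMissingMother - pMissingBoth
  pOnlyF <- pMissingFather - pMissingBoth
  pNone <- 1 - pOnlyM - pOnlyF - pMissingBoth
  if (pNone < 0) stop("missingness probabilities sum past 1")
  set.seed(childSeed(seed, "missingness"))
  fams <- unique(pedigree$family_id)
  cat4 <- sample(c("none", "mother", "father", "both"), length(fams),
                 replace = TRUE, prob = c(pNone, pOnlyM, pOnlyF, pMissingBoth))
  names(cat4) <- fams
  famOf <- pedigree$family_id[match(pgs$individual_id, pedigree$individual_id)]
  maskMom <- pgs$role == "mother" & cat4[famOf] %in% c("mother", "both")
  maskDad <- pgs$role == "father" & cat4[famOf] %in% c("father", "both")
  pgs$value[maskMom | maskDad] <- NA_real_
  pgs
}

#' Simulate a probe manifest for synthetic probes
#'
#' Gives each probe a chromosome/position and QC fields so that manifest
#' filtering can be exercised on simulated data: a small fraction of probes
#' get exclusion flags or sub-threshold success rates.
#'
#' @param probeIds character vector of probe ids.
#' @param pFlagged probability a probe carries any exclusion flag.
#' @param pLowSuccess probability of a success rate below 0.95.
#' @param seed RNG seed.
#' @return Manifest data.frame: probe_id, chromosome, position,
#'   cross_reactive, snp_overlap, sex_chromosome, success_rate.
#' @export
simulateProbeManifest <- function(probeIds, pFlagged = 0.05,
                                  pLowSuccess = 0.02, seed = 1) {
  set.seed(childSeed(seed, "manifest"))
  n <- length(probeIds)
  flagged <- runif(n) < pFlagged
  which3 <- sample(1:3, n, replace = TRUE)
  low <- runif(n) < pLowSuccess
  data.frame(
    probe_id = probeIds,
    chromosome = sample(paste0("chr", 1:22), n, replace = TRUE),
    position = sample.int(2e8, n, replace = TRUE),
    cross_reactive = flagged & which3 == 1,
    snp_overlap = flagged & which3 == 2,
    sex_chromosome = flagged & which3 == 3,
    success_rate = ifelse(low, runif(n, 0.85, 0.949), runif(n, 0.95, 1)),
    stringsAsFactors = FALSE)
}
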