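test_that("MZ co-twins share a genome, and transmission is Mendelian", {
  fam <- simulateFamilies(1, pMz = 1, nLoci = 25, seed = 3)
  d <- dosages(fam$genotypes)
  expect_identical(d["fam00001_o1", ], d["fam00001_o2", ])

  # exhaustive parent-offspring compatibility on a small DZ instance:
  # each offspring allele count must be achievable from one maternal and
  # one paternal allele
  fam <- simulateFamilies(25, pMz = 0, nLoci = 40, seed = 7)
  ped <- fam$pedigree
  d <- dosages(fam$genotypes)
  for (f in unique(ped$family_id)) {
    m <- d[paste0(f, "_m"), ]; p <- d[paste0(f, "_f"), ]
    lo <- (m == 2) + (p == 2)
    hi <- 2 - (m == 0) - (p == 0)
    for (o in ped$individual_id[ped$family_id == f & ped$role == "offspring"]) {
      expect_true(all(d[o, ] >= lo & d[o, ] <= hi))
    }
  }
})

test_that("offspring allele frequencies track the parental generation", {
  fam <- simulateFamilies(2000, offspringPerFamily = 1, pMz = 0,
                          nLoci = 500, seed = 13)
  ped <- fam$pedigree
  d <- dosages(fam$genotypes)
  par <- d[ped$individual_id[ped$role != "offspring"], ]
  off <- d[ped$individual_id[ped$role == "offspring"], ]
  pPar <- colMeans(par) / 2
  pOff <- colMeans(off) / 2
  # each offspring contributes 2 transmitted alleles; conditional on the
  # parents the pooled offspring count is a sum of fair coin picks, so a
  # binomial SE bounds the sampling noise
  se <- sqrt(pPar * (1 - pPar) / (2 * nrow(off)))
  within <- abs(pOff - pPar) <= 3 * se
  expect_gt(mean(within), 0.98)
})

test_that("DZ co-twin dosage correlation is about one half", {
  fam <- simulateFamilies(2000, pMz = 0, nLoci = 300, seed = 17)
  d <- dosages(fam$genotypes)
  o1 <- d[grep("_o1$", rownames(d)), ]
  o2 <- d[grep("_o2$", rownames(d)), ]
  rs <- vapply(seq_len(ncol(d)), function(j) cor(o1[, j], o2[, j]),
               numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.02)
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulateFamilies(15, nLoci = 20, seed = 5)
  b <- simulateFamilies(15, nLoci = 20, seed = 5)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(dosages(a$genotypes), dosages(b$genotypes))
  expect_identical(simulateCovariates(a$pedigree, seed = 9),
                   simulateCovariates(b$pedigree, seed = 9))
})

test_that("covariates have valid ranges and the stated dataset mix", {
  fam <- simulateFamilies(5000, nLoci = 2, seed = 23)
  cov <- simulateCovariates(fam$pedigree, seed = 23)
  expect_true(all(cov$epithelial >= 0 & cov$epithelial <= 1))
  expect_true(all(cov$nk >= 0 & cov$nk <= 1))
  expect_false(anyNA(cov))
  # dataset shares (0.06, 0.75, 0.19) over 10^4 offspring, 3 SE multinomial
  off <- cov[cov$role == "offspring", ]
  expect_gte(nrow(off), 1e4)
  pr <- c(0.06, 0.75, 0.19)
  # twins share their family's dataset, so count one draw per family
  famDs <- tapply(off$dataset, sub("_o.*", "", off$individual_id), unique)
  n <- length(famDs)
  for (k in 1:3) {
    se <- sqrt(pr[k] * (1 - pr[k]) / n)
    expect_lt(abs(mean(famDs == k) - pr[k]), 3 * se)
  }
})

test_that("true PGS standardization rejects zero-variance scores", {
  co <- makeCohort(nFamilies = 5, nLoci = 10, seed = 31)
  w0 <- co$weights * 0
  expect_error(computeTruePgs(co$genotypes, co$pedigree, w0),
               "zero-variance")
  expect_error(computeTruePgs(co$genotypes, co$pedigree,
                              co$weights[-1, , drop = FALSE]),
               "loci")
})

test_that("offspring-parent PGS correlation is ~0.5, spousal ~0, MZ = 1", {
  co <- makeCohort(nFamilies = 1500, nLoci = 300, seed = 37, pMz = 0.5)
  ped <- co$pedigree
  off <- ped[ped$role == "offspring", ]
  for (tr in c("schizophrenia", "height")) {
    po <- co$pgs[co$pgs$role == "offspring" & co$pgs$trait == tr, ]
    pm <- co$pgs[co$pgs$role == "mother" & co$pgs$trait == tr, ]
    pf <- co$pgs[co$pgs$role == "father" & co$pgs$trait == tr, ]
    ov <- po$value[match(off$individual_id, po$individual_id)]
    mv <- pm$value[match(paste0(off$family_id, "_m"), pm$individual_id)]
    fv <- pf$value[match(paste0(off$family_id, "_f"), pf$individual_id)]
    expect_lt(abs(cor(ov, mv) - 0.5), 0.04)
    expect_lt(abs(cor(ov, fv) - 0.5), 0.04)
    # random mating: spousal correlation indistinguishable from 0
    fams <- unique(ped$family_id)
    sp <- cor(pm$value[match(paste0(fams, "_m"), pm$individual_id)],
              pf$value[match(paste0(fams, "_f"), pf$individual_id)])
    expect_lt(abs(sp), 3 / sqrt(length(fams)))
  }
  # MZ co-twins have identical scores
  mzFam <- unique(ped$family_id[ped$zygosity == "MZ"])
  po <- co$pgs[co$pgs$role == "offspring" & co$pgs$trait == "BMI", ]
  v1 <- po$value[match(paste0(mzFam, "_o1"), po$individual_id)]
  v2 <- po$value[match(paste0(mzFam, "_o2"), po$individual_id)]
  expect_equal(v1, v2)
})

test_that("methylation liabilities have the designed family correlation", {
  co <- makeCohort(nFamilies = 400, nLoci = 5, seed = 41)
  tr <- simulationTruth(familySd = 0.5, noiseSd = 0.5, mu = 0,
                        covariateEffects = c(sex = 0, age = 0,
                                             epithelial = 0, nk = 0,
                                             dataset2 = 0, dataset3 = 0),
                        seed = 41)
  sim <- simulateMethylation(co$pedigree, co$pgs, co$covariates, tr,
                             nProbes = 800)
  liab <- SummarizedExperiment::assay(sim$methyl, "liability")
  o1 <- grep("_o1$", colnames(liab)); o2 <- grep("_o2$", colnames(liab))
  # variance-components oracle: ICC = 0.5^2 / (0.5^2 + 0.5^2) = 0.5
  rs <- vapply(seq_len(nrow(liab)),
               function(i) cor(liab[i, o1], liab[i, o2]), numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.03)
})

test_that("methylation beta-values are inverse-logit liabilities in (0,1)", {
  co <- makeCohort(nFamilies = 10, nLoci = 5, seed = 43)
  trNull <- simulationTruth(familySd = 0, noiseSd = 0, mu = 0,
                            covariateEffects = c(sex = 0, age = 0,
                                                 epithelial = 0, nk = 0,
                                                 dataset2 = 0, dataset3 = 0),
                            seed = 43)
  sim <- simulateMethylation(co$pedigree, co$pgs, co$covariates, trNull,
                             nProbes = 6)
  expect_true(all(betaValues(sim$methyl) == 0.5))

  tr <- simulationTruth(familySd = 2, noiseSd = 3, seed = 43)
  sim <- simulateMethylation(co$pedigree, co$pgs, co$covariates, tr,
                             nProbes = 20)
  b <- betaValues(sim$methyl)
  expect_true(all(b > 0 & b < 1))
  expect_s4_class(sim$methyl, "MethylExperiment")
  expect_identical(methState(sim$methyl), "raw")

  badTruth <- simulationTruth(
    effectSpecs = list(effectSpec("BMI", delta = 1,
                                  causalProbes = "cg99999999")),
    seed = 1)
  expect_error(simulateMethylation(co$pedigree, co$pgs, co$covariates,
                                   badTruth, nProbes = 5),
               "unknown probe")
})

test_that("parental PGS masking hits the intended family fractions", {
  co <- makeCohort(nFamilies = 5000, nLoci = 2, seed = 47)
  # no masking: identity
  expect_identical(
    applyParentMissingness(co$pgs, co$pedigree, 0, 0, 0, seed = 1),
    co$pgs)
  # everything masked
  all2 <- applyParentMissingness(co$pgs, co$pedigree, 1, 1, 1, seed = 1)
  expect_true(all(is.na(all2$value[all2$role != "offspring"])))
  expect_false(anyNA(all2$value[all2$role == "offspring"]))
  # defaults reproduce ~78.3% of families with both parents present
  msk <- applyParentMissingness(co$pgs, co$pedigree, seed = 3)
  fams <- unique(co$pedigree$family_id)
  momNA <- is.na(msk$value[match(paste0(fams, "_m"), msk$individual_id)])
  dadNA <- is.na(msk$value[match(paste0(fams, "_f"), msk$individual_id)])
  bothPresent <- mean(!momNA & !dadNA)
  se <- sqrt(0.783 * 0.217 / length(fams))
  expect_lt(abs(bothPresent - 0.783), 3 * se)
  # invalid probabilities rejected
  expect_error(applyParentMissingness(co$pgs, co$pedigree, 0.5, 0.1, 0.4),
               "joint")
  expect_error(applyParentMissingness(co$pgs, co$pedigree, -0.1, 0, 0),
               "probabilities")
})
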