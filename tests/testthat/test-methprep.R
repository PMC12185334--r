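test_that("manifest QC drops flagged and low-success probes, boundary kept", {
  set.seed(1)
  m <- methFromSamples(matrix(runif(10 * 10), 10, 10))
  mf <- data.frame(probe_id = rownames(m), chromosome = "chr1",
                   position = seq_len(10) * 100,
                   cross_reactive = FALSE, snp_overlap = FALSE,
                   sex_chromosome = FALSE, success_rate = 1,
                   stringsAsFactors = FALSE)
  expect_equal(dim(qcFilter(m, mf)), dim(m))        # nothing to drop

  mf2 <- mf; mf2$cross_reactive[1:3] <- TRUE
  expect_equal(nrow(qcFilter(m, mf2)), 7)

  mf3 <- mf
  mf3$success_rate <- c(0.93, 0.94, 0.95, 0.96, 0.97, 0.98, 0.99, 1, 1, 1)
  kept <- qcFilter(m, mf3)
  # brute-force per-probe comparison: strictly below 0.95 excluded
  expect_setequal(rownames(kept),
                  mf3$probe_id[mf3$success_rate >= 0.95])
  expect_true("cg000003" %in% rownames(kept))       # boundary 0.95 kept

  expect_error(qcFilter(m, mf[-1, ]), "absent from manifest")
})

test_that("IQR masking matches a brute-force quantile oracle", {
  set.seed(2)
  # tight beta distribution so the injected extremes really are outliers
  x <- matrix(rbeta(60 * 40, 50, 50), 60, 40)
  x[5, 1] <- 0.999; x[12, c(3, 7)] <- 0.0001
  me <- methFromSamples(x)
  masked <- maskOutliersIqr(me, k = 3)
  expect_identical(methState(masked), "masked")
  oracle <- t(apply(x, 2, bruteIqrMask, k = 3))     # probes x samples
  got <- is.na(betaValues(masked))
  expect_identical(unname(got), unname(oracle))
  expect_gte(sum(oracle), 3L)                       # the injected spots
  expect_identical(S4Vectors::metadata(masked)$nMasked, sum(oracle))
})

test_that("IQR masking edge cases: constants, huge k, known single outlier", {
  cst <- methFromSamples(matrix(0.4, 6, 5))
  expect_identical(S4Vectors::metadata(maskOutliersIqr(cst))$nMasked, 0L)

  set.seed(3)
  anyd <- methFromSamples(matrix(runif(40), 8, 5))
  expect_identical(S4Vectors::metadata(maskOutliersIqr(anyd, k = 1e12))$nMasked,
                   0L)

  # eleven values 0.10..0.20 plus a 0.95: with type-7 quantiles exactly the
  # 0.95 exceeds Q3 + 3 IQR
  v <- c(seq(0.10, 0.20, length.out = 11), 0.95)
  me <- methFromSamples(matrix(v, ncol = 1))
  out <- maskOutliersIqr(me)
  expect_identical(S4Vectors::metadata(out)$nMasked, 1L)
  expect_true(is.na(betaValues(out)[1, 12]))

  thin <- methFromSamples(matrix(c(0.2, 0.3, NA, NA, NA), ncol = 1,
                                 nrow = 5))
  expect_warning(maskOutliersIqr(thin), "non-missing")
})

test_that("imputation drops high-missingness probes and mean-fills the rest", {
  set.seed(4)
  x <- matrix(runif(100 * 3), 100, 3)       # 100 samples x 3 probes
  x[1:6, 1] <- NA                            # 6% missing -> dropped
  x[1:5, 2] <- NA                            # 5% missing -> kept (boundary)
  me <- methFromSamples(x, state = "masked")
  imp <- imputeMissing(me, maxMissing = 0.05)
  expect_identical(methState(imp), "imputed")
  expect_setequal(rownames(imp), c("cg000002", "cg000003"))
  expect_false(anyNA(betaValues(imp)))
  # mean fill oracle
  expect_equal(unname(betaValues(imp)["cg000002", 1]),
               mean(x[-(1:5), 2]))

  tiny <- methFromSamples(matrix(c(0.2, 0.4, NA), nrow = 3, ncol = 1),
                          state = "masked")
  expect_equal(unname(betaValues(imputeMissing(tiny,
                                               maxMissing = 0.4))[1, 3]),
               0.3)

  # no missing values: identity
  clean <- methFromSamples(matrix(runif(20), 5, 4), state = "masked")
  expect_equal(betaValues(imputeMissing(clean)), betaValues(clean))

  allNA <- methFromSamples(matrix(NA_real_, 5, 2), state = "masked")
  expect_error(imputeMissing(allNA), "all probes")
})

test_that("low-rank refinement stays in range and fills all gaps", {
  set.seed(5)
  u <- matrix(rnorm(50 * 2), 50, 2); v <- matrix(rnorm(2 * 30), 2, 30)
  x <- invLogitMat(u %*% v)
  x[sample(length(x), 60)] <- NA
  me <- methFromSamples(x, state = "masked")
  imp <- imputeMissing(me, maxMissing = 0.2, method = "svd", rank = 2)
  b <- betaValues(imp)
  expect_false(anyNA(b))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("residualization is an orthogonal projection", {
  set.seed(6)
  co <- makeCohort(nFamilies = 25, nLoci = 10, seed = 51)
  tr <- simulationTruth(seed = 51)
  sim <- simulateMethylation(co$pedigree, co$pgs, co$covariates, tr,
                             nProbes = 10)
  me <- advanceStateTo(sim$methyl, "imputed")
  res <- residualizeMethyl(me, co$covariates)
  expect_identical(methState(res), "residualized")
  X <- stats::model.matrix(~ sex + age + epithelial + nk + array_row + plate,
    data = co$covariates[match(colnames(me),
                               co$covariates$individual_id), ])
  ip <- abs(crossprod(X, t(betaValues(res))))
  expect_lt(max(ip), 1e-8)
  # idempotence
  res2 <- residualizeMethyl(res, co$covariates)
  expect_equal(betaValues(res2), betaValues(res), tolerance = 1e-10)
})

test_that("residualization handles intercept-only, exact fits, collinearity", {
  set.seed(7)
  x <- matrix(runif(50 * 8), 50, 8)
  me <- methFromSamples(x, state = "imputed")
  cov <- data.frame(individual_id = colnames(me), stringsAsFactors = FALSE)
  ctr <- residualizeMethyl(me, cov, columns = character())
  expect_equal(unname(betaValues(ctr)), unname(betaValues(me) -
               rowMeans(betaValues(me))), tolerance = 1e-12)

  # beta a pure linear function of a covariate: residuals vanish
  covz <- data.frame(individual_id = colnames(me), z = rnorm(ncol(me)),
                     stringsAsFactors = FALSE)
  # residualized state tolerates unbounded values
  lin <- methFromSamples(outer(covz$z, 1:5) + 2, state = "residualized")
  resl <- residualizeMethyl(lin, covz, columns = "z")
  expect_lt(max(abs(betaValues(resl))), 1e-10)

  covc <- cbind(covz, z2 = 2 * covz$z)
  expect_error(residualizeMethyl(me, covc, columns = c("z", "z2")),
               "collinear.*z2")
})

test_that("top-variance selection keeps floor(q*M) probes, ties by id", {
  set.seed(8)
  # 10 probes with variances known by construction
  x <- sapply(1:10, function(k) rnorm(30, sd = sqrt(k)))
  colnames(x) <- sprintf("cg%02d", 1:10)
  me <- methFromSamples(scale(x, scale = FALSE) / 50 + 0.5)
  top2 <- selectTopVariance(me, q = 0.2)
  v <- sort(apply(x, 2, var), decreasing = TRUE)
  expect_setequal(rownames(top2), names(v)[1:2])

  all10 <- selectTopVariance(me, q = 1)
  expect_identical(rownames(all10), rownames(me))   # order preserved

  expect_error(selectTopVariance(me, q = 0.05), "zero")
  expect_error(selectTopVariance(me, q = 0), "\\(0, 1\\]")
})

test_that("the preprocessing chain only ever shrinks the probe set", {
  co <- makeCohort(nFamilies = 30, nLoci = 10, seed = 61)
  tr <- simulationTruth(seed = 61)
  sim <- simulateMethylation(co$pedigree, co$pgs, co$covariates, tr,
                             nProbes = 80)
  mf <- simulateProbeManifest(rownames(sim$methyl), seed = 61)
  s0 <- colnames(sim$methyl)
  m1 <- qcFilter(sim$methyl, mf)
  m2 <- maskOutliersIqr(m1)
  m3 <- imputeMissing(m2)
  m4 <- residualizeMethyl(m3, co$covariates)
  m5 <- selectTopVariance(m4, q = 0.5)
  probes <- lapply(list(sim$methyl, m1, m2, m3, m4, m5), rownames)
  for (i in 2:6) expect_true(all(probes[[i]] %in% probes[[i - 1]]))
  for (m in list(m1, m2, m3, m4, m5)) expect_identical(colnames(m), s0)
  expect_error(advanceStateTo(m4, "raw"), "backwards")
})
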