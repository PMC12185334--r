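# Effective number of independent tests by matrix spectral decomposition
# of the probe correlation matrix, and the resulting Bonferroni threshold.

# Nyholt's effective test count from an eigenvalue spectrum:
#   Meff = 1 + (M - 1) * (1 - Var(lambda) / M), Var with denominator M - 1.
meffNyholt <- function(lambda) {
  M <- length(lambda)
  1 + (M - 1) * (1 - var(lambda) / M)
}

# Li & Ji refinement: Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]
meffLiJi <- function(lambda) {
  lambda <- pmax(lambda, 0)
  sum(as.integer(lambda >= 1) + (lambda - floor(lambda)))
}

#' Effective number of independent tests from a correlation matrix
#'
#' @param R a probe-by-probe Pearson correlation matrix.
#' @param globalAlpha family-wise significance level, default 0.05.
#' @param method \code{"nyholt"} (default) or \code{"liji"}.
#' @return A \linkS4class{MeffResult}. The effective count is rounded up
#'   to an integer before dividing alpha (the conservative direction).
#' @examples
#' effectiveTestsFromCorrelation(matrix(c(1, .5, .5, 1), 2))  # Meff 1.75
#' @export
effectiveTestsFromCorrelation <- function(R, globalAlpha = 0.05,
                                          method = c("nyholt", "liji")) {
  method <- match.arg(method)
  if (!is.matrix(R) || nrow(R) != ncol(R) || nrow(R) < 2)
    stop("R must be a square correlation matrix with >= 2 probes")
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  makeMeffResult(lambda, globalAlpha, method)
}

makeMeffResult <- function(lambda, globalAlpha, method) {
  M <- length(lambda)
  m <- switch(method, nyholt = meffNyholt(lambda), liji = meffLiJi(lambda))
  m <- min(max(m, 1), M)
  mr <- as.integer(ceiling(m - 1e-9))
  new("MeffResult", mProbes = as.integer(M), eigenvalues = lambda,
      mEff = m, mEffRounded = mr, alpha = globalAlpha / mr, method = method)
}

#' Effective number of independent tests for a methylation matrix
#'
#' Eigen-decomposes the probe-by-probe Pearson correlation matrix. When
#' there are more probes than samples the nonzero spectrum is computed
#' from the dual sample-by-sample cross-product of the standardized data
#' (identical nonzero eigenvalues, zeros appended), which is what makes
#' genome-scale panels tractable. Requires a complete (imputed) matrix.
#'
#' @param me a \linkS4class{MethylExperiment} without missing values,
#'   >= 2 probes and >= 3 samples.
#' @param globalAlpha family-wise significance level.
#' @param method \code{"nyholt"} or \code{"liji"}.
#' @return A \linkS4class{MeffResult}.
#' @export
effectiveTests <- function(me, globalAlpha = 0.05,
                           method = c("nyholt", "liji")) {
  stopifnot(is(me, "MethylExperiment"))
  method <- match.arg(method)
  b <- betaValues(me)
  if (nrow(b) < 2 || ncol(b) < 3)
    stop("need >= 2 probes and >= 3 samples")
  if (anyNA(b))
    stop("matrix contains missing values; impute before spectral decomposition")
  sds <- sqrt(rowVars(b))
  if (any(sds == 0))
    stop("constant probe(s) with zero variance: ",
         paste(head(rownames(b)[sds == 0], 5), collapse = ", "))
  M <- nrow(b); n <- ncol(b)
  Z <- (b - rowMeans(b)) / sds          # probes x samples, standardized rows
  if (M <= n) {
    lambda <- eigen(tcrossprod(Z) / (n - 1), symmetric = TRUE,
                    only.values = TRUE)$values
  } else {
    lam <- eigen(crossprod(Z) / (n - 1), symmetric = TRUE,
                 only.values = TRUE)$values
    lambda <- c(lam, rep(0, M - n))
  }
  lambda <- pmax(lambda, 0)
  makeMeffResult(lambda, globalAlpha, method)
}

#' Bonferroni-adjusted significance level for correlated tests
#'
#' @param globalAlpha family-wise level, default 0.05.
#' @param mEff effective number of independent tests (>= 1; fractional
#'   values are rounded up before dividing).
#' @return The per-test significance level \code{globalAlpha / mEff}.
#' @examples
#' bonferroniAlpha(0.05, 1850)   # 2.7027e-05, i.e. 2.7e-5 at 2 s.f.
#' @export
bonferroniAlpha <- function(globalAlpha = 0.05, mEff) {
  if (mEff < 1) stop("mEff must be >= 1")
  if (globalAlpha <= 0 || globalAlpha >= 1)
    stop("globalAlpha must lie in (0, 1)")
  globalAlpha / ceiling(mEff - 1e-9)
}
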