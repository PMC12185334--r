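# Methylation preprocessing: manifest-flag QC, 3xIQR outlier masking,
# missingness-aware imputation, covariate residualization, and
# top-variance probe selection. Probe sets only ever shrink; the sample
# set is never touched.

#' Drop probes failing manifest QC flags or the success-rate threshold
#'
#' A probe is removed when it is flagged cross-reactive, SNP-overlapping,
#' or on a sex chromosome, or when its success rate falls strictly below
#' \code{minSuccess} (the boundary value is kept).
#'
#' @param me a \linkS4class{MethylExperiment} (state raw).
#' @param manifest probe manifest data.frame covering all probes.
#' @param minSuccess success-rate threshold, default 0.95.
#' @return The filtered MethylExperiment (state unchanged); the manifest
#'   rows of retained probes are attached as rowData.
#' @export
qcFilter <- function(me, manifest, minSuccess = 0.95) {
  stopifnot(is(me, "MethylExperiment"))
  assertManifest(manifest)
  missing <- setdiff(rownames(me), manifest$probe_id)
  if (length(missing))
    stop("probes absent from manifest: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  mf <- manifest[match(rownames(me), manifest$probe_id), ]
  keep <- !(mf$cross_reactive | mf$snp_overlap | mf$sex_chromosome) &
    mf$success_rate >= minSuccess
  out <- me[keep, ]
  SummarizedExperiment::rowData(out) <- S4Vectors::DataFrame(
    mf[keep, setdiff(names(mf), "probe_id"), drop = FALSE])
  md <- S4Vectors::metadata(out)
  md$qcDropped <- sum(!keep)
  S4Vectors::metadata(out) <- md
  out
}

#' Mask per-probe outliers beyond k times the interquartile range
#'
#' Per probe, values outside \[Q1 - k IQR, Q3 + k IQR\] are set missing.
#' Quantiles use linear interpolation between order statistics
#' (\code{type = 7}, the common default; configurable) and are computed
#' once on the original non-missing values, so masking is a single pass.
#' Probes with fewer than 4 non-missing values are left unmasked with a
#' warning.
#'
#' @param me a \linkS4class{MethylExperiment} in state raw.
#' @param k IQR multiplier, default 3.
#' @param quantileType quantile definition passed to [stats::quantile()].
#' @return MethylExperiment in state \code{masked}; the number of newly
#'   masked values is stored in \code{metadata(.)$nMasked}.
#' @export
maskOutliersIqr <- function(me, k = 3, quantileType = 7) {
  stopifnot(is(me, "MethylExperiment"))
  b <- betaValues(me)
  nMasked <- 0L
  thin <- character()
  for (i in seq_len(nrow(b))) {
    x <- b[i, ]
    obs <- !is.na(x)
    if (sum(obs) < 4L) { thin <- c(thin, rownames(b)[i]); next }
    q <- quantile(x[obs], c(0.25, 0.75), type = quantileType, names = FALSE)
    iqr <- q[2] - q[1]
    out <- obs & (x < q[1] - k * iqr | x > q[2] + k * iqr)
    if (any(out)) {
      b[i, out] <- NA_real_
      nMasked <- nMasked + sum(out)
    }
  }
  if (length(thin))
    warning(length(thin), " probe(s) with <4 non-missing values left unmasked: ",
            paste(head(thin, 5), collapse = ", "))
  SummarizedExperiment::assay(me, "beta", withDimnames = FALSE) <- b
  me <- advanceState(me, "masked")
  md <- S4Vectors::metadata(me)
  md$nMasked <- nMasked
  S4Vectors::metadata(me) <- md
  me
}

#' Impute remaining missing beta-values
#'
#' Probes whose missing fraction exceeds \code{maxMissing} (strictly) are
#' dropped; remaining missing entries are filled. The default fill is the
#' probe mean; \code{method = "svd"} additionally refines the fill by
#' iterating a truncated-SVD low-rank reconstruction of the
#' probe-centred matrix, a light-weight analogue of PCA-based imputation.
#'
#' @param me a \linkS4class{MethylExperiment} in state masked.
#' @param maxMissing maximum tolerated missing fraction per probe
#'   (default 0.05; "up to 5\%" is kept).
#' @param method \code{"mean"} (default) or \code{"svd"}.
#' @param rank number of components for \code{method = "svd"}.
#' @param maxIter,tol iteration controls for \code{method = "svd"}.
#' @return MethylExperiment in state \code{imputed}, no missing values.
#' @export
imputeMissing <- function(me, maxMissing = 0.05, method = c("mean", "svd"),
                          rank = 2, maxIter = 50, tol = 1e-6) {
  stopifnot(is(me, "MethylExperiment"))
  method <- match.arg(method)
  b <- betaValues(me)
  missFrac <- rowMeans(is.na(b))
  keep <- missFrac <= maxMissing
  if (!any(keep)) stop("all probes exceed the missingness threshold")
  me <- me[keep, ]
  b <- betaValues(me)
  nas <- is.na(b)
  if (any(nas)) {
    rm <- rowMeans(b, na.rm = TRUE)
    fill <- matrix(rm, nrow(b), ncol(b))
    b[nas] <- fill[nas]
    if (method == "svd" && ncol(b) > rank) {
      ctr <- rowMeans(b)
      for (it in seq_len(maxIter)) {
        s <- svd(b - ctr, nu = rank, nv = rank)
        rec <- s$u %*% (s$d[seq_len(rank)] * t(s$v)) + ctr
        rec <- pmin(pmax(rec, 0), 1)
        delta <- max(abs(b[nas] - rec[nas]))
        b[nas] <- rec[nas]
        if (delta < tol) break
        ctr <- rowMeans(b)
      }
    }
  }
  SummarizedExperiment::assay(me, "beta", withDimnames = FALSE) <- b
  md <- S4Vectors::metadata(me)
  md$imputeDropped <- sum(!keep)
  me <- advanceState(me, "imputed")
  S4Vectors::metadata(me) <- md
  me
}

# expand a covariate formula into a full-rank design, naming collinear
# columns on failure
buildCovariateDesign <- function(covariates, columns) {
  miss <- setdiff(columns, names(covariates))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  if (!length(columns)) {
    X <- matrix(1, nrow(covariates), 1,
                dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  f <- as.formula(paste("~", paste(columns, collapse = " + ")))
  X <- model.matrix(f, data = covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Residualize methylation on technical and biological covariates
#'
#' Per probe, ordinary least-squares residuals of the beta-values on the
#' covariate design (categorical covariates expanded to indicators against
#' a reference level). The dataset indicator is deliberately not part of
#' the default design: dataset dummies enter the association model itself.
#'
#' @param me a \linkS4class{MethylExperiment} in state imputed.
#' @param covariates covariate table with one row per sample.
#' @param columns covariate columns to adjust for; the default is the
#'   standard set sex, age, epithelial, nk, array_row, plate.
#' @return MethylExperiment in state \code{residualized}; residuals are
#'   orthogonal to every design column.
#' @export
residualizeMethyl <- function(me, covariates,
                              columns = c("sex", "age", "epithelial", "nk",
                                          "array_row", "plate")) {
  stopifnot(is(me, "MethylExperiment"))
  assertCovariates(covariates)
  ids <- colnames(me)
  idx <- match(ids, covariates$individual_id)
  if (anyNA(idx))
    stop("covariates missing for sample(s): ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  cv <- covariates[idx, , drop = FALSE]
  X <- buildCovariateDesign(cv, columns)
  qrX <- qr(X)
  resid <- t(qr.resid(qrX, t(betaValues(me))))
  dimnames(resid) <- dimnames(betaValues(me))
  SummarizedExperiment::assay(me, "beta", withDimnames = FALSE) <- resid
  advanceState(me, "residualized")
}

#' Keep the top fraction of probes by variance
#'
#' Retains the \code{floor(q * M)} probes with largest sample variance;
#' ties are broken by probe id (lexicographic) so selection is
#' deterministic.
#'
#' @param me a \linkS4class{MethylExperiment} (typically residualized).
#' @param q fraction of probes to keep, in (0, 1\].
#' @return The subsetted MethylExperiment, original probe order preserved.
#' @examples
#' # floor(0.10 * 728899) == 72889 probes would survive the default cut
#' @export
selectTopVariance <- function(me, q = 0.10) {
  stopifnot(is(me, "MethylExperiment"))
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  M <- nrow(me)
  nKeep <- floor(q * M)
  if (nKeep == 0) stop("floor(q * M) is zero; nothing would be retained")
  v <- rowVars(betaValues(me))
  ord <- order(-v, rownames(me))
  keepIds <- rownames(me)[ord[seq_len(nKeep)]]
  me[rownames(me) %in% keepIds, ]
}
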