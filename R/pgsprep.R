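# Analysis-ready polygenic scores: residualize on genotyping-platform
# dummies and 10 genetic PCs, standardize to zero mean / unit variance on
# the observed values, then zero-impute missing parental scores.

#' Residualize polygenic scores on ancestry PCs and platform dummies, then
#' standardize
#'
#' Per trait and role, the non-missing scores are regressed (OLS) on the
#' genetic principal components and genotyping-platform dummies; the
#' residuals are scaled to zero mean and unit variance. Missing entries are
#' left untouched (they are imputed afterwards, on the standardized scale).
#'
#' @param pgs long PGS table (raw scale), NA values marking missing
#'   parental scores.
#' @param covariates covariate table carrying \code{PC1..PC10} and
#'   \code{platform2}, \code{platform3} for every scored person.
#' @param pcColumns PC column names, default \code{PC1..PC10}.
#' @param platformColumns platform dummy columns.
#' @return The PGS table on the standardized-residual scale.
#' @export
standardizePgs <- function(pgs, covariates,
                           pcColumns = paste0("PC", 1:10),
                           platformColumns = c("platform2", "platform3")) {
  assertPgsTable(pgs); assertCovariates(covariates)
  covCols <- c(platformColumns, pcColumns)
  miss <- setdiff(covCols, names(covariates))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  grp <- interaction(pgs$trait, pgs$role, drop = TRUE)
  for (g in levels(grp)) {
    sel <- grp == g & !is.na(pgs$value)
    if (!any(sel)) next
    idx <- match(pgs$individual_id[sel], covariates$individual_id)
    if (anyNA(idx))
      stop("covariates missing for scored person(s): ",
           paste(head(pgs$individual_id[sel][is.na(idx)], 5), collapse = ", "))
    X <- cbind(`(Intercept)` = 1,
               as.matrix(covariates[idx, covCols, drop = FALSE]))
    if (sum(sel) <= ncol(X))
      stop("group ", g, " has too few observed scores (", sum(sel),
           ") for ", ncol(X), " regression columns")
    r <- qr.resid(qr(X), pgs$value[sel])
    s <- sd(r)
    # guard against scores that are (numerically) exact functions of the
    # covariates; the threshold is relative to the score scale
    if (!is.finite(s) || s <= 1e-10 * max(1, mean(abs(pgs$value[sel]))))
      stop("zero residual variance for group ", g)
    pgs$value[sel] <- (r - mean(r)) / s
  }
  pgs
}

#' Zero-impute missing parental polygenic scores
#'
#' On the standardized scale the score mean is zero, so mean imputation
#' sets every missing maternal or paternal entry to 0 and flags it.
#' Offspring scores must be complete.
#'
#' @param pgs standardized long PGS table.
#' @return The table with parental NAs replaced by 0 and
#'   \code{imputed = TRUE} on those rows.
#' @export
imputeParentPgs <- function(pgs) {
  assertPgsTable(pgs)
  missOff <- is.na(pgs$value) & pgs$role == "offspring"
  if (any(missOff))
    stop("offspring PGS missing for: ",
         paste(head(unique(pgs$individual_id[missOff]), 5), collapse = ", "),
         "; the design requires complete offspring scores")
  sel <- is.na(pgs$value) & pgs$role %in% c("mother", "father")
  pgs$value[sel] <- 0
  pgs$imputed[sel] <- TRUE
  pgs
}
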