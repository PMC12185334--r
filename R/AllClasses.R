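#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.methStates <- c("raw", "masked", "imputed", "residualized")

#' MethylExperiment: a methylation matrix with a processing state
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"beta"}
#' (probes in rows, offspring samples in columns) plus a processing-state
#' tag. Beta-values are methylated/total signal ratios in \[0,1\]; after
#' residualization the values are unbounded residuals. Missing entries are
#' \code{NA} in the assay. The state may only advance along
#' raw -> masked -> imputed -> residualized.
#'
#' @slot state one of \code{"raw"}, \code{"masked"}, \code{"imputed"},
#'   \code{"residualized"}.
#' @export
setClass("MethylExperiment",
  contains = "SummarizedExperiment",
  slots = c(state = "character"),
  prototype = prototype(state = "raw"))

setValidity("MethylExperiment", function(object) {
  msg <- character()
  if (length(object@state) != 1L || !object@state %in% .methStates)
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.methStates, collapse = ", ")))
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (object@state %in% c("raw", "masked", "imputed") && any(!is.na(b))) {
      rng <- range(b, na.rm = TRUE)
      if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
        msg <- c(msg, "beta-values must lie in [0,1] before residualization")
    }
    if (object@state == "imputed" && anyNA(b))
      msg <- c(msg, "imputed state must not contain missing values")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylExperiment
#'
#' @param beta numeric matrix, probes x samples, with probe ids as rownames
#'   and sample ids as colnames.
#' @param state processing state, default \code{"raw"}.
#' @param rowData optional per-probe annotation (e.g. manifest columns).
#' @param metadata optional list of run metadata.
#' @return A \linkS4class{MethylExperiment}.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:2)))
#' me <- MethylExperiment(b)
#' methState(me)
#' @export
MethylExperiment <- function(beta, state = "raw", rowData = NULL,
                             metadata = list()) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix needs probe rownames and sample colnames")
  args <- list(assays = S4Vectors::SimpleList(beta = beta),
               metadata = metadata)
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("MethylExperiment", se, state = state)
}

#' @describeIn MethylExperiment processing state accessor
#' @param x a MethylExperiment.
#' @export
methState <- function(x) {
  stopifnot(is(x, "MethylExperiment"))
  x@state
}

#' @describeIn MethylExperiment the beta/residual value matrix
#'   (probes x samples)
#' @export
betaValues <- function(x) {
  stopifnot(is(x, "MethylExperiment"))
  SummarizedExperiment::assay(x, "beta")
}

# advance the processing state, refusing to move backwards
advanceState <- function(x, to) {
  from <- match(x@state, .methStates)
  dest <- match(to, .methStates)
  if (is.na(dest)) stop("unknown state: ", to)
  if (dest < from)
    stop(sprintf("cannot move state backwards (%s -> %s)", x@state, to))
  x@state <- to
  validObject(x)
  x
}

setMethod("show", "MethylExperiment", function(object) {
  cat(sprintf("MethylExperiment: %d probes x %d samples [state: %s]\n",
              nrow(object), ncol(object), object@state))
  nm <- S4Vectors::metadata(object)$nMasked
  if (!is.null(nm)) cat(sprintf("  masked outliers: %d\n", nm))
  callNextMethod()
})

#' GenotypeSet: biallelic dosages for a simulated pedigree
#'
#' Holds per-person allele-count dosages (0/1/2) at unlinked biallelic loci
#' together with the locus table (id, population allele frequency).
#' Offspring dosages are constructed by Mendelian transmission, so parent-
#' offspring consistency holds by construction; MZ co-twins share identical
#' rows.
#'
#' @slot dosages integer-ish matrix, persons x loci, rownames are
#'   individual ids.
#' @slot loci data.frame with columns \code{locus_id}, \code{freq}.
#' @export
setClass("GenotypeSet",
  slots = c(dosages = "matrix", loci = "data.frame"))

setValidity("GenotypeSet", function(object) {
  msg <- character()
  if (!all(object@dosages %in% 0:2))
    msg <- c(msg, "dosages must be in {0,1,2}")
  if (is.null(rownames(object@dosages)))
    msg <- c(msg, "dosages need individual-id rownames")
  if (!all(c("locus_id", "freq") %in% names(object@loci)))
    msg <- c(msg, "loci needs columns locus_id, freq")
  if (ncol(object@dosages) != nrow(object@loci))
    msg <- c(msg, "dosage columns must match loci rows")
  if (any(object@loci$freq < 0.01 | object@loci$freq > 0.99))
    msg <- c(msg, "allele frequencies must lie in [0.01, 0.99]")
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeSet dosage matrix accessor
#' @param x a GenotypeSet.
#' @export
dosages <- function(x) {
  stopifnot(is(x, "GenotypeSet"))
  x@dosages
}

#' @describeIn GenotypeSet locus table accessor
#' @export
lociInfo <- function(x) {
  stopifnot(is(x, "GenotypeSet"))
  x@loci
}

setMethod("show", "GenotypeSet", function(object) {
  cat(sprintf("GenotypeSet: %d individuals x %d loci\n",
              nrow(object@dosages), nrow(object@loci)))
})

#' GeeDesign: the fixed-effect design for the per-probe GEE
#'
#' Rows are offspring samples; columns are the intercept, the offspring /
#' maternal / paternal polygenic score for each trait (in the declared
#' trait order, roles nested within trait), and dataset dummies with
#' dataset 1 as reference. Cluster labels (family ids) align with rows.
#'
#' @slot X numeric design matrix.
#' @slot clusters factor of family ids, one per row.
#' @slot predictors data.frame describing each column: \code{column},
#'   \code{kind} (\code{intercept}/\code{pgs}/\code{dataset}),
#'   \code{role}, \code{trait}.
#' @export
setClass("GeeDesign",
  slots = c(X = "matrix", clusters = "factor", predictors = "data.frame"))

setValidity("GeeDesign", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@clusters))
    msg <- c(msg, "cluster labels must cover all design rows")
  if (anyNA(object@X)) msg <- c(msg, "design matrix must not contain NA")
  if (nrow(object@predictors) != ncol(object@X))
    msg <- c(msg, "predictor metadata must describe every column")
  bad <- setdiff(unique(object@predictors$kind),
                 c("intercept", "pgs", "dataset", "covariate"))
  if (length(bad))
    msg <- c(msg, paste("unknown predictor kind(s):",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeeDesign", function(object) {
  cat(sprintf("GeeDesign: %d samples x %d columns, %d families\n",
              nrow(object@X), ncol(object@X), nlevels(object@clusters)))
  cat("  columns:", paste(head(colnames(object@X), 8), collapse = ", "),
      if (ncol(object@X) > 8) "...", "\n")
})

#' @describeIn GeeDesign design matrix accessor
#' @param x a GeeDesign.
#' @export
designMatrix <- function(x) {
  stopifnot(is(x, "GeeDesign"))
  x@X
}

#' @describeIn GeeDesign family cluster labels
#' @export
designClusters <- function(x) {
  stopifnot(is(x, "GeeDesign"))
  x@clusters
}

#' @describeIn GeeDesign per-column predictor metadata
#' @export
designPredictors <- function(x) {
  stopifnot(is(x, "GeeDesign"))
  x@predictors
}

#' GeeResults: per-probe GEE fits
#'
#' Coefficients, cluster-robust standard errors, z statistics and
#' two-sided normal-reference p-values for every probe, plus a convergence
#' flag. Inferential fields of non-converged probes are NA.
#'
#' @slot coefficients probes x predictors matrix.
#' @slot se robust standard errors, same shape.
#' @slot z robust z statistics.
#' @slot p two-sided p-values.
#' @slot converged logical per probe.
#' @slot predictors predictor metadata as in \linkS4class{GeeDesign}.
#' @slot nClusters number of families.
#' @slot working working correlation structure used.
#' @export
setClass("GeeResults",
  slots = c(coefficients = "matrix", se = "matrix", z = "matrix",
            p = "matrix", converged = "logical", predictors = "data.frame",
            nClusters = "integer", working = "character"))

setValidity("GeeResults", function(object) {
  msg <- character()
  dims <- dim(object@coefficients)
  for (s in c("se", "z", "p"))
    if (!identical(dim(slot(object, s)), dims))
      msg <- c(msg, sprintf("slot %s has mismatched dimensions", s))
  if (length(object@converged) != dims[1])
    msg <- c(msg, "converged flag must cover every probe")
  pv <- object@p[object@converged, , drop = FALSE]
  if (length(pv) && any(pv < 0 | pv > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0,1]")
  sev <- object@se[object@converged, , drop = FALSE]
  # zero SE is possible only for degenerate perfect fits (zero residuals)
  if (length(sev) && any(sev < 0, na.rm = TRUE))
    msg <- c(msg, "robust SEs of converged fits must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeeResults", function(object) {
  cs <- convergenceSummary(object)
  cat(sprintf(
    "GeeResults: %d probes x %d predictors (working: %s, %d families)\n",
    nrow(object@coefficients), ncol(object@coefficients), object@working,
    object@nClusters))
  cat(sprintf("  %d successful analyses (%d of %d probes did not converge)\n",
              cs[["successful"]], cs[["nonconverged"]], cs[["total"]]))
})

#' Convergence bookkeeping of a GeeResults object
#'
#' @param results a \linkS4class{GeeResults}.
#' @return Named integer vector \code{total}, \code{successful},
#'   \code{nonconverged}; \code{total == successful + nonconverged} always.
#' @export
convergenceSummary <- function(results) {
  stopifnot(is(results, "GeeResults"))
  total <- length(results@converged)
  ok <- sum(results@converged)
  c(total = total, successful = ok, nonconverged = total - ok)
}

#' @describeIn GeeResults coefficient matrix accessor
#' @param x a GeeResults.
#' @export
geeCoef <- function(x) { stopifnot(is(x, "GeeResults")); x@coefficients }

#' @describeIn GeeResults robust-SE matrix accessor
#' @export
geeSe <- function(x) { stopifnot(is(x, "GeeResults")); x@se }

#' @describeIn GeeResults p-value matrix accessor
#' @export
geePvalues <- function(x) { stopifnot(is(x, "GeeResults")); x@p }

#' @describeIn GeeResults per-probe convergence flags
#' @export
geeConverged <- function(x) { stopifnot(is(x, "GeeResults")); x@converged }

#' MeffResult: effective number of independent tests
#'
#' The eigenvalue spectrum of the probe correlation matrix, the effective
#' test count derived from it, and the resulting Bonferroni-adjusted
#' significance level.
#'
#' @slot mProbes number of probes.
#' @slot eigenvalues full spectrum (zeros appended when computed via the
#'   dual sample-by-sample matrix).
#' @slot mEff effective number of tests (possibly fractional).
#' @slot mEffRounded \code{ceiling(mEff)}, the divisor actually used.
#' @slot alpha adjusted significance level, global alpha / mEffRounded.
#' @slot method \code{"nyholt"} or \code{"liji"}.
#' @export
setClass("MeffResult",
  slots = c(mProbes = "integer", eigenvalues = "numeric", mEff = "numeric",
            mEffRounded = "integer", alpha = "numeric", method = "character"))

setValidity("MeffResult", function(object) {
  msg <- character()
  if (object@mEff < 1 || object@mEff > object@mProbes)
    msg <- c(msg, "mEff must lie in [1, mProbes]")
  tol <- 1e-6 * max(1, object@mProbes)
  if (any(object@eigenvalues < -tol))
    msg <- c(msg, "eigenvalues must be nonnegative up to tolerance")
  if (abs(sum(object@eigenvalues) - object@mProbes) > tol)
    msg <- c(msg, "eigenvalues must sum to the probe count")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MeffResult", function(object) {
  cat(sprintf(
    "MeffResult (%s): %d probes -> %.2f effective tests (rounded up: %d)\n",
    object@method, object@mProbes, object@mEff, object@mEffRounded))
  cat(sprintf("  adjusted alpha = %.4g\n", object@alpha))
})

#' @describeIn MeffResult effective test count
#' @param x a MeffResult.
#' @export
mEff <- function(x) { stopifnot(is(x, "MeffResult")); x@mEff }

#' @describeIn MeffResult adjusted significance level
#' @export
adjustedAlpha <- function(x) { stopifnot(is(x, "MeffResult")); x@alpha }

#' @describeIn MeffResult eigenvalue spectrum
#' @export
meffEigenvalues <- function(x) { stopifnot(is(x, "MeffResult")); x@eigenvalues }
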