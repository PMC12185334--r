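#' @importFrom methods new validObject is slot
#' @importFrom stats quantile var sd cor rnorm runif rbinom qnorm pnorm
#'   model.matrix as.formula setNames complete.cases
#' @importFrom utils head
NULL

# inverse-logit, the map from the Gaussian liability scale to beta-values
invLogit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Derive a component-specific RNG seed from a master seed
#'
#' Each simulator component (genotypes, covariates, methylation noise, ...)
#' draws from its own stream so that, e.g., adding probes does not perturb
#' the genotypes generated from the same master seed.
#'
#' @param seed master seed (integer).
#' @param tag character tag naming the component.
#' @return An integer seed in \[0, 2^31).
#' @export
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483647)
}

# row variances without matrixStats
rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The six complex traits, in the fixed declared order used for design columns.
#' Default trait names in fixed design order
#'
#' Six complex traits with polygenic scores for offspring, mother, and
#' father; the order fixes the design-matrix column order.
#'
#' @return Character vector of six trait names.
#' @export
defaultTraits <- function() {
  c("schizophrenia", "smoking", "EA", "social_deprivation", "BMI", "height")
}

# --- lightweight validators for the plain data.frame containers -------------

assertPedigree <- function(pedigree) {
  req <- c("family_id", "individual_id", "role", "zygosity", "dataset")
  miss <- setdiff(req, names(pedigree))
  if (length(miss))
    stop("pedigree lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(pedigree$individual_id))
    stop("pedigree individual_ids must be unique")
  bad <- setdiff(unique(pedigree$role), c("mother", "father", "offspring"))
  if (length(bad)) stop("unknown pedigree role(s): ", paste(bad, collapse = ", "))
  byfam <- split(pedigree$role, pedigree$family_id)
  ok <- vapply(byfam, function(r)
    sum(r == "mother") == 1L && sum(r == "father") == 1L &&
      sum(r == "offspring") >= 1L, logical(1))
  if (!all(ok))
    stop("each family needs exactly one mother, one father, >=1 offspring; bad: ",
         paste(names(byfam)[!ok], collapse = ", "))
  invisible(pedigree)
}

assertPgsTable <- function(pgs) {
  req <- c("individual_id", "role", "trait", "value", "imputed")
  miss <- setdiff(req, names(pgs))
  if (length(miss))
    stop("PGS table lacks column(s): ", paste(miss, collapse = ", "))
  invisible(pgs)
}

assertCovariates <- function(cov) {
  if (!"individual_id" %in% names(cov))
    stop("covariate table lacks an individual_id column")
  invisible(cov)
}

assertManifest <- function(manifest) {
  req <- c("probe_id", "chromosome", "position", "cross_reactive",
           "snp_overlap", "sex_chromosome", "success_rate")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop("probe manifest lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id)) stop("manifest probe_ids must be unique")
  if (any(manifest$position < 1)) stop("manifest positions must be >= 1")
  invisible(manifest)
}
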