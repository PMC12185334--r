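# Threshold GEE results into a hit table, classify significant CpGs by
# predictor role and trait, and summarize counts the way an EWAS of
# direct/indirect polygenic effects is reported.

#' Classify significant probe-predictor associations
#'
#' Emits one row per (probe, PGS predictor) with p below the threshold,
#' over converged probes only. The intercept and dataset dummies are never
#' reported as hits. Chromosome and position are joined from the manifest
#' when given.
#'
#' @param results a \linkS4class{GeeResults}.
#' @param alpha significance level in (0, 1), e.g. the Meff-adjusted
#'   level from [effectiveTests()].
#' @param manifest optional probe manifest for genomic coordinates.
#' @return Hit table data.frame: probe_id, chromosome, position,
#'   predictor_role, trait, beta, p.
#' @export
classifyHits <- function(results, alpha, manifest = NULL) {
  stopifnot(is(results, "GeeResults"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  pred <- results@predictors
  pgsCols <- which(pred$kind == "pgs")
  keep <- geeConverged(results)
  pv <- geePvalues(results)[keep, pgsCols, drop = FALSE]
  bv <- geeCoef(results)[keep, pgsCols, drop = FALSE]
  hit <- which(pv < alpha, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    out <- data.frame(probe_id = character(), chromosome = character(),
                      position = integer(), predictor_role = character(),
                      trait = character(), beta = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    probe_id = rownames(pv)[hit[, "row"]],
    chromosome = NA_character_,
    position = NA_integer_,
    predictor_role = pred$role[pgsCols][hit[, "col"]],
    trait = pred$trait[pgsCols][hit[, "col"]],
    beta = bv[hit],
    p = pv[hit],
    stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    assertManifest(manifest)
    i <- match(out$probe_id, manifest$probe_id)
    out$chromosome <- manifest$chromosome[i]
    out$position <- manifest$position[i]
  }
  out[order(out$p), , drop = FALSE]
}

#' Count significant CpGs by predictor role and trait
#'
#' Direct effects are offspring-PGS hits; indirect (genetic nurture)
#' effects are maternal plus paternal hits. Shares are computed from the
#' counted cells, e.g. the maternal share of one trait among all maternal
#' hits.
#'
#' @param hits a hit table from [classifyHits()] (columns
#'   \code{predictor_role}, \code{trait} suffice).
#' @return An object of class \code{hitCounts}: \code{byRoleTrait}
#'   (role x trait count matrix), totals \code{nDirect},
#'   \code{nIndirect}, \code{nMaternal}, \code{nPaternal},
#'   \code{nOffspring}, \code{total}.
#' @export
countHits <- function(hits) {
  roles <- c("offspring", "maternal", "paternal")
  traits <- unique(hits$trait)
  tab <- matrix(0L, length(roles), max(1L, length(traits)),
                dimnames = list(roles,
                                if (length(traits)) traits else "none"))
  if (nrow(hits)) {
    tt <- table(factor(hits$predictor_role, levels = roles),
                factor(hits$trait, levels = traits))
    tab[, colnames(tt)] <- tt
  }
  res <- list(byRoleTrait = tab,
              nOffspring = sum(tab["offspring", ]),
              nMaternal = sum(tab["maternal", ]),
              nPaternal = sum(tab["paternal", ]),
              total = sum(tab))
  res$nDirect <- res$nOffspring
  res$nIndirect <- res$nMaternal + res$nPaternal
  class(res) <- "hitCounts"
  res
}

#' @export
print.hitCounts <- function(x, ...) {
  cat("Significant CpGs by predictor role and trait:\n")
  print(x$byRoleTrait)
  cat(sprintf("direct (offspring) total: %d\n", x$nDirect))
  cat(sprintf("indirect (maternal %d + paternal %d) total: %d\n",
              x$nMaternal, x$nPaternal, x$nIndirect))
  invisible(x)
}

#' Share of one role-trait cell among all hits of that role
#'
#' @param counts a \code{hitCounts} object.
#' @param role one of offspring/maternal/paternal.
#' @param trait trait name.
#' @return Percentage (0-100) of the role's hits attributable to the
#'   trait, e.g. the maternal-schizophrenia share of all maternal
#'   genetic-nurture hits.
#' @export
roleTraitShare <- function(counts, role, trait) {
  stopifnot(inherits(counts, "hitCounts"))
  tot <- sum(counts$byRoleTrait[role, ])
  if (tot == 0) return(NA_real_)
  100 * counts$byRoleTrait[role, trait] / tot
}

#' Load the shipped table of reported significant CpG associations
#'
#' A transcription of the significant CpG-by-PGS associations reported for
#' the buccal methylation study of twin families that this package's
#' analysis reproduces in structure: probe id, genomic location (build
#' 37), predictor role, trait, and (where reported) the number of blood
#' cis-mQTLs for the CpG. Used as the reference fixture for the counting
#' logic.
#'
#' @return data.frame with columns probe_id, chromosome, position,
#'   predictor_role, trait, n_cis_mqtls (NA where not reported).
#' @export
reportedHits <- function() {
  path <- system.file("extdata", "reported_hits.tsv",
                      package = "methylNurture", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Mean number of cis-mQTLs per CpG with any reported mQTL
#'
#' @param hits a hit table carrying an \code{n_cis_mqtls} column (NA for
#'   CpGs without reported mQTLs), e.g. [reportedHits()].
#' @return Mean mQTL count over the CpGs that have one, rounded to one
#'   decimal.
#' @export
meanMqtlPerCpg <- function(hits) {
  n <- hits$n_cis_mqtls
  if (all(is.na(n))) return(NA_real_)
  round(sum(n, na.rm = TRUE) / sum(!is.na(n)), 1)
}
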