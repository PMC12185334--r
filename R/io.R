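# TSV round-trips for every container. Beta matrices travel as
# samples x probes (header row of probe ids, first column sample_id);
# everything else as plain long/wide tables with a header.

#' @importFrom data.table fread fwrite
NULL

#' Write / read a methylation matrix as TSV
#'
#' On disk the matrix is samples x probes with a \code{sample_id} first
#' column; in memory it is probes x samples. The processing state is not
#' stored in the file; supply it on read.
#'
#' @param me a \linkS4class{MethylExperiment}.
#' @param path file path.
#' @return \code{writeBetaMatrix} the path, invisibly;
#'   \code{readBetaMatrix} a MethylExperiment.
#' @export
writeBetaMatrix <- function(me, path) {
  stopifnot(is(me, "MethylExperiment"))
  b <- t(betaValues(me))
  dt <- data.table::data.table(sample_id = rownames(b))
  dt <- cbind(dt, data.table::as.data.table(b))
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname writeBetaMatrix
#' @param state processing state to assign on read.
#' @export
readBetaMatrix <- function(path, state = "raw") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- dt$sample_id
  m <- as.matrix(dt[, -1])
  rownames(m) <- ids
  MethylExperiment(t(m), state = state)
}

#' Write / read a plain table (pedigree, covariates, PGS, manifest, hits)
#'
#' @param x a data.frame.
#' @param path file path.
#' @export
writeTable <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA"))
}

#' Write / read the per-probe GEE result table
#'
#' One row per probe: the converged flag and a (beta, se, z, p) quadruple
#' per predictor column.
#'
#' @param results a \linkS4class{GeeResults}.
#' @param path file path.
#' @export
writeGeeResults <- function(results, path) {
  stopifnot(is(results, "GeeResults"))
  nm <- colnames(geeCoef(results))
  out <- data.frame(probe_id = rownames(geeCoef(results)),
                    converged = geeConverged(results))
  for (j in seq_along(nm)) {
    out[[paste0("beta.", nm[j])]] <- geeCoef(results)[, j]
    out[[paste0("se.", nm[j])]] <- geeSe(results)[, j]
    out[[paste0("z.", nm[j])]] <- results@z[, j]
    out[[paste0("p.", nm[j])]] <- geePvalues(results)[, j]
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write a MeffResult as key-value text plus its eigenvalue spectrum
#'
#' @param x a \linkS4class{MeffResult}.
#' @param path key-value file path; the spectrum goes to
#'   \code{paste0(path, ".spectrum.tsv")}.
#' @export
writeMeffResult <- function(x, path) {
  stopifnot(is(x, "MeffResult"))
  lines <- c(sprintf("m_probes\t%d", x@mProbes),
             sprintf("m_eff\t%.10g", x@mEff),
             sprintf("m_eff_rounded\t%d", x@mEffRounded),
             sprintf("alpha\t%.10g", x@alpha),
             sprintf("method\t%s", x@method))
  writeLines(lines, path)
  writeTable(data.frame(index = seq_along(x@eigenvalues),
                        eigenvalue = x@eigenvalues),
             paste0(path, ".spectrum.tsv"))
  invisible(path)
}
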