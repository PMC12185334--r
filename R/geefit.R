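# Per-probe Gaussian GEE with identity link and cluster-robust sandwich
# variance, implemented from first principles. Under the independence
# working structure the point estimates are exactly OLS and the whole
# probe panel is fitted with shared matrix factorizations; the
# exchangeable structure iterates moment updates of the common
# within-family correlation.

#' Build the fixed design for the per-probe association model
#'
#' One row per offspring: intercept; for each trait (in \code{traits}
#' order) the offspring, maternal, and paternal standardized PGS; then
#' dataset dummies with dataset 1 as reference. With six traits and three
#' datasets this is the 21-column design (1 + 18 + 2). Families are the
#' cluster labels.
#'
#' @param pgs final (standardized, parent-imputed) long PGS table.
#' @param pedigree pedigree data.frame.
#' @param covariates covariate table providing the dataset label.
#' @param traits trait order; default [defaultTraits()].
#' @return A \linkS4class{GeeDesign}.
#' @export
buildGeeDesign <- function(pgs, pedigree, covariates,
                           traits = defaultTraits()) {
  assertPgsTable(pgs); assertPedigree(pedigree); assertCovariates(covariates)
  if (anyNA(pgs$value))
    stop("PGS table still contains missing values; run imputeParentPgs() first")
  off <- pedigree[pedigree$role == "offspring", ]
  n <- nrow(off)
  momId <- pedigree$individual_id[match(paste0(off$family_id, "mother"),
            paste0(pedigree$family_id, pedigree$role))]
  dadId <- pedigree$individual_id[match(paste0(off$family_id, "father"),
            paste0(pedigree$family_id, pedigree$role))]

  lookup <- function(ids, role, trait) {
    sub <- pgs[pgs$role == role & pgs$trait == trait, ]
    v <- sub$value[match(ids, sub$individual_id)]
    v
  }
  cols <- list(`(Intercept)` = rep(1, n))
  meta <- data.frame(column = "(Intercept)", kind = "intercept",
                     role = NA_character_, trait = NA_character_,
                     stringsAsFactors = FALSE)
  for (tr in traits) {
    trio <- list(offspring = lookup(off$individual_id, "offspring", tr),
                 maternal = lookup(momId, "mother", tr),
                 paternal = lookup(dadId, "father", tr))
    for (rl in names(trio)) {
      nm <- paste(rl, tr, sep = "_")
      cols[[nm]] <- trio[[rl]]
      meta <- rbind(meta, data.frame(column = nm, kind = "pgs", role = rl,
                                     trait = tr, stringsAsFactors = FALSE))
    }
  }
  X <- do.call(cbind, cols)
  bad <- off$individual_id[!complete.cases(X)]
  if (length(bad))
    stop("offspring lacking predictors: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  ds <- covariates$dataset[match(off$individual_id, covariates$individual_id)]
  if (anyNA(ds)) stop("dataset label missing for some offspring")
  for (lev in sort(unique(ds))[-1]) {
    nm <- paste0("dataset", lev)
    X <- cbind(X, as.integer(ds == lev))
    colnames(X)[ncol(X)] <- nm
    meta <- rbind(meta, data.frame(column = nm, kind = "dataset",
                                   role = NA_character_, trait = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  rownames(X) <- off$individual_id
  new("GeeDesign", X = X, clusters = factor(off$family_id),
      predictors = meta)
}

# sandwich variance given per-row "whitened" quantities:
#   bread = sum_i X_i' V_i^-1 X_i,  meat = sum_i X_i' V_i^-1 e_i e_i' V_i^-1 X_i
# For independence V_i = I so the scores are rows of X * e.
clusterSandwich <- function(scoreRows, cluster, bread) {
  S <- rowsum(scoreRows, cluster)        # clusters x p score sums
  meat <- crossprod(S)
  bi <- solve(bread)
  bi %*% meat %*% bi
}

#' Fit the Gaussian GEE for a single probe
#'
#' Identity-link estimating equations under an independence or
#' exchangeable working correlation; variance by the cluster-robust
#' sandwich (bread = model-based information, meat = summed outer products
#' of per-family score contributions); two-sided p-values from the
#' standard-normal reference.
#'
#' @param y residualized methylation vector, aligned with the design rows.
#' @param design a \linkS4class{GeeDesign}.
#' @param working working correlation, \code{"independence"} (default) or
#'   \code{"exchangeable"}.
#' @param maxIter,tol iteration controls for the exchangeable structure.
#' @return A list: \code{coefficients}, \code{se}, \code{z}, \code{p},
#'   \code{converged}, \code{nClusters}, \code{working} (inferential
#'   entries are NA when not converged).
#' @export
fitGeeProbe <- function(y, design, working = c("independence", "exchangeable"),
                        maxIter = 25, tol = 1e-8) {
  stopifnot(is(design, "GeeDesign"))
  working <- match.arg(working)
  X <- designMatrix(design)
  cl <- designClusters(design)
  if (length(y) != nrow(X)) stop("y is not aligned with the design rows")
  if (nlevels(cl) < 2) stop("need at least 2 family clusters")
  p <- ncol(X)
  nm <- colnames(X)
  failed <- function() list(
    coefficients = setNames(rep(NA_real_, p), nm),
    se = setNames(rep(NA_real_, p), nm), z = setNames(rep(NA_real_, p), nm),
    p = setNames(rep(NA_real_, p), nm), converged = FALSE,
    nClusters = nlevels(cl), working = working)
  if (any(!is.finite(y))) return(failed())
  qrX <- qr(X)
  if (qrX$rank < p) return(failed())

  if (working == "independence") {
    beta <- qr.coef(qrX, y)
    e <- y - drop(X %*% beta)
    bread <- crossprod(X)
    vc <- clusterSandwich(X * e, cl, bread)
    converged <- TRUE
  } else {
    beta <- qr.coef(qrX, y)        # start at OLS
    idx <- split(seq_along(y), cl)
    sizes <- lengths(idx)
    converged <- FALSE
    alpha <- 0
    for (it in seq_len(maxIter)) {
      e <- y - drop(X %*% beta)
      phi <- sum(e^2) / (length(y) - p)
      num <- sum(vapply(idx, function(ii) {
        s <- sum(e[ii]); (s^2 - sum(e[ii]^2)) }, numeric(1)))
      den <- phi * (sum(sizes * (sizes - 1)) - p)
      alphaNew <- if (den > 0) num / den else 0
      if (!is.finite(alphaNew)) return(failed())
      alphaNew <- max(min(alphaNew, 0.99), -0.99)
      # GLS step under exchangeable R(alpha); V_i^-1 has closed form
      A <- matrix(0, p, p); b <- rep(0, p)
      for (ii in idx) {
        ni <- length(ii)
        Xi <- X[ii, , drop = FALSE]; yi <- y[ii]
        c1 <- 1 / (1 - alphaNew)
        c2 <- -alphaNew / ((1 - alphaNew) * (1 + (ni - 1) * alphaNew))
        XtVi <- c1 * t(Xi) + c2 * outer(colSums(Xi), rep(1, ni))
        A <- A + XtVi %*% Xi
        b <- b + XtVi %*% yi
      }
      betaNew <- tryCatch(drop(solve(A, b)), error = function(e) NULL)
      if (is.null(betaNew) || any(!is.finite(betaNew))) return(failed())
      delta <- max(abs(betaNew - beta))
      beta <- betaNew
      alpha <- alphaNew
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) return(failed())
    e <- y - drop(X %*% beta)
    bread <- matrix(0, p, p)
    score <- matrix(0, length(levels(cl)), p)
    for (g in seq_along(idx)) {
      ii <- idx[[g]]
      ni <- length(ii)
      Xi <- X[ii, , drop = FALSE]
      c1 <- 1 / (1 - alpha)
      c2 <- -alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      XtVi <- c1 * t(Xi) + c2 * outer(colSums(Xi), rep(1, ni))
      bread <- bread + XtVi %*% Xi
      score[g, ] <- XtVi %*% e[ii]
    }
    bi <- solve(bread)
    vc <- bi %*% crossprod(score) %*% bi
  }
  se <- sqrt(diag(vc))
  z <- beta / se
  pv <- 2 * pnorm(-abs(z))
  list(coefficients = setNames(drop(beta), nm), se = setNames(se, nm),
       z = setNames(z, nm), p = setNames(pv, nm), converged = converged,
       nClusters = nlevels(cl), working = working)
}

#' Fit the GEE across all probes of a methylation matrix
#'
#' One fit per probe. Under the independence working structure the
#' coefficient solve is shared across probes (a single multi-response
#' least-squares factorization) and only the per-family sandwich is
#' probe-specific, so the full panel is fast; the exchangeable structure
#' fits probe by probe. Probes with non-finite values or a rank-deficient
#' design are flagged non-converged and carry no inferential fields.
#'
#' @param me a \linkS4class{MethylExperiment}, typically residualized and
#'   variance-selected; samples must match the design rows.
#' @param design a \linkS4class{GeeDesign}.
#' @param working working correlation structure.
#' @return A \linkS4class{GeeResults}.
#' @export
fitGee <- function(me, design, working = c("independence", "exchangeable")) {
  stopifnot(is(me, "MethylExperiment"), is(design, "GeeDesign"))
  working <- match.arg(working)
  X <- designMatrix(design)
  if (!identical(colnames(me), rownames(X)))
    stop("methylation samples do not align with design rows")
  cl <- designClusters(design)
  Y <- t(betaValues(me))            # samples x probes
  P <- ncol(Y); p <- ncol(X)
  nm <- colnames(X)
  coefs <- se <- matrix(NA_real_, P, p,
                        dimnames = list(colnames(Y), nm))
  converged <- rep(FALSE, P)

  if (working == "independence") {
    qrX <- qr(X)
    ok <- qrX$rank == p
    finite <- colSums(!is.finite(Y)) == 0
    if (ok && any(finite)) {
      Yf <- Y[, finite, drop = FALSE]
      B <- qr.coef(qrX, Yf)                  # p x P coefficients
      E <- Yf - X %*% B
      bread <- crossprod(X)
      bi <- solve(bread)
      for (j in seq_len(ncol(Yf))) {
        S <- rowsum(X * E[, j], cl)
        vc <- bi %*% crossprod(S) %*% bi
        k <- which(finite)[j]
        coefs[k, ] <- B[, j]
        se[k, ] <- sqrt(diag(vc))
        converged[k] <- TRUE
      }
    }
  } else {
    for (j in seq_len(P)) {
      fit <- fitGeeProbe(Y[, j], design, working = working)
      if (fit$converged) {
        coefs[j, ] <- fit$coefficients
        se[j, ] <- fit$se
        converged[j] <- TRUE
      }
    }
  }
  z <- coefs / se
  pv <- 2 * pnorm(-abs(z))
  new("GeeResults", coefficients = coefs, se = se, z = z, p = pv,
      converged = converged, predictors = designPredictors(design),
      nClusters = nlevels(cl), working = working)
}
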