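# Per-SNP logistic association and principal components.
#
# The association fit is plain IRLS (via glm.fit, binomial/logit) with
# Wald statistics: snptest-style dosage regression, adjusted for whatever
# covariates are supplied. Score tests and mixed models are out of scope.

# fit one logistic regression and return Wald stats for the SNP column.
# Flags separation / non-convergence (NA everything, converged = FALSE).
#' @noRd
logit_wald <- function(y, x, covar = NULL) {
  X <- cbind(`(Intercept)` = 1, dosage = x, covar)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(maxit = 25L, epsilon = 1e-8)))
  if (!fit$converged) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE))
  }
  # Wald SE from the unscaled covariance of the IRLS working model;
  # glm.fit pivots columns, so locate the dosage column through the pivot
  rank <- fit$qr$rank
  piv <- fit$qr$pivot[seq_len(rank)]
  j <- which(piv == 2L)                       # dosage is column 2 of X
  if (!length(j)) {                           # aliased / dropped
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, converged = FALSE))
  }
  R <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- chol2inv(R)
  beta <- fit$coefficients[["dosage"]]
  se <- sqrt(cov[j, j])
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100) {
    # (quasi-)complete separation drives the estimate to the boundary
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, converged = FALSE))
  }
  list(beta = beta, se = se,
       p = max(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
       converged = TRUE)
}

# vectorised scan over SNP columns; monomorphic SNPs flagged with NA SE
#' @noRd
logistic_scan <- function(y, dosage, covar = NULL) {
  m <- ncol(dosage)
  beta <- se <- p <- rep(NA_real_, m)
  conv <- logical(m)
  for (j in seq_len(m)) {
    x <- dosage[, j]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) next    # monomorphic: untestable
    r <- logit_wald(y[ok], x[ok], if (is.null(covar)) NULL
                    else covar[ok, , drop = FALSE])
    beta[j] <- r$beta; se[j] <- r$se; p[j] <- r$p; conv[j] <- r$converged
  }
  list(beta = beta, se = se, p = p, converged = conv)
}

#' Per-SNP logistic-regression association scan
#'
#' Fits `status ~ dosage + sex + covariates` for every SNP by IRLS
#' (25 iterations max, tolerance 1e-8) and reports Wald estimates.
#' Samples with a missing genotype are dropped for that SNP only.
#' Non-converged or separated fits are flagged (`converged = FALSE`,
#' NA estimates) and counted in a message.
#'
#' @param hc a [hard_calls()] matrix.
#' @param samples sample table with `status` in case/control and `sex`.
#' @param covariates optional numeric matrix of extra covariates
#'   (e.g. principal components), samples in rows.
#' @param include_sex adjust for sex (default TRUE; ignored when sex is
#'   constant).
#' @return data.frame: `snp_id`, `beta`, `se`, `pvalue`, `n_used`,
#'   `converged`.
#' @export
logistic_gwas <- function(hc, samples, covariates = NULL, include_sex = TRUE) {
  y <- as.integer(samples$status == "case")
  check(length(unique(y)) == 2L, "both cases and controls are required")
  covar <- NULL
  if (include_sex && length(unique(samples$sex[samples$sex != "unknown"])) > 1L) {
    covar <- cbind(sex = as.numeric(samples$sex == "female"))
  }
  if (!is.null(covariates)) covar <- cbind(covar, as.matrix(covariates))
  fit <- logistic_scan(y, hc$dosage, covar)
  n_used <- colSums(!is.na(hc$dosage))
  bad <- sum(!fit$converged)
  if (bad > 0) msg(sprintf("logistic_gwas: %d/%d SNPs flagged (monomorphic, separated or non-converged)",
                           bad, ncol(hc$dosage)))
  data.frame(snp_id = hc$snp_meta$snp_id, beta = fit$beta, se = fit$se,
             pvalue = fit$p, n_used = n_used, converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Principal components of a dosage matrix
#'
#' Missing calls are imputed to the SNP mean, columns are standardized,
#' and PCs are extracted in decreasing order of variance explained. Sign
#' convention: the largest-magnitude loading of each component is made
#' positive, so coordinates are reproducible across runs.
#'
#' @param hc a [hard_calls()] matrix.
#' @param n_components number of components (default 2).
#' @return samples x `n_components` matrix of coordinates (columns
#'   `PC1`, `PC2`, ...).
#' @export
compute_pcs <- function(hc, n_components = 2) {
  X <- hc$dosage
  check(nrow(X) >= n_components + 1, "too few samples for requested components")
  check(ncol(X) >= 2, "at least 2 SNPs required")
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning(sprintf("%d all-missing SNP columns excluded from PCA", sum(all_missing)))
    X <- X[, !all_missing, drop = FALSE]
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[((idx - 1L) %/% nrow(X)) + 1L]
  sds <- apply(X, 2L, sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("no polymorphic SNPs: returning all-zero PC coordinates")
    return(matrix(0, nrow(X), n_components,
                  dimnames = list(NULL, paste0("PC", seq_len(n_components)))))
  }
  X <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sds[keep])
  pc <- prcomp(X, center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(k) {
    v <- pc$rotation[, k]; sign(v[which.max(abs(v))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2L, flip, `*`)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  coords
}
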