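# Discrimination analysis: Mann-Whitney AUC, DeLong confidence
# intervals, logistic predictors and extreme-tail counts.

#' Mann-Whitney AUC
#'
#' The fraction of (case, control) pairs in which the case scores higher,
#' ties counted 1/2 — computed exactly via midranks.
#'
#' @param scores_cases,scores_controls numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores_cases, scores_controls) {
  m <- length(scores_cases); n <- length(scores_controls)
  check(m > 0 && n > 0, "both classes must be non-empty")
  r <- rank(c(scores_cases, scores_controls), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' AUC with a DeLong confidence interval
#'
#' Nonparametric variance from DeLong structural components (computed by
#' midranks, so ties are handled exactly); normal-theory interval clipped
#' to \[0, 1\]. Degenerate AUC (exactly 0 or 1) collapses the interval to
#' the point with a warning.
#'
#' @param scores_cases,scores_controls numeric score vectors (>= 2 each).
#' @param level confidence level (default 0.95).
#' @return list of class `auc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`, `method = "delong"`.
#' @export
delong_ci <- function(scores_cases, scores_controls, level = 0.95) {
  m <- length(scores_cases); n <- length(scores_controls)
  check(m >= 2 && n >= 2, "need >= 2 samples per class")
  r_all <- rank(c(scores_cases, scores_controls), ties.method = "average")
  r_cases <- rank(scores_cases, ties.method = "average")
  r_ctrls <- rank(scores_controls, ties.method = "average")
  # structural components (Sun & Xu midrank formulation)
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrls) / m
  auc <- mean(v10)
  s <- var(v10) / m + var(v01) / n
  if (auc %in% c(0, 1) || s <= 0) {
    warning("degenerate AUC variance; interval collapsed to the point estimate")
    lo <- hi <- auc
  } else {
    zq <- qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - zq * sqrt(s)); hi <- min(1, auc + zq * sqrt(s))
  }
  structure(list(auc = auc, ci_low = lo, ci_high = hi, n_cases = m,
                 n_controls = n, method = "delong"),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f-%.3f] (%d cases, %d controls, %s)\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls, x$method))
  invisible(x)
}

#' Fit an in-sample logistic predictor
#'
#' Fits `status ~ predictors` by IRLS and returns the fitted
#' probabilities, used as the ROC score (in-sample, no cross-validation —
#' deliberately optimistic, matching a single-cohort design). APOE can be
#' entered as two allele-count dummies (E2 copies, E4 copies). Under
#' separation the fit is flagged and the first predictor column is
#' returned as the score with a warning.
#'
#' @param samples sample table (`status`, optionally `apoe`).
#' @param predictors numeric matrix/data.frame of predictors (e.g. a PRS
#'   column, PCs).
#' @param include_apoe add E2/E4 allele-count dummies from `samples$apoe`.
#' @return numeric vector of predicted case probabilities (attribute
#'   `converged`).
#' @export
fit_logistic_predictor <- function(samples, predictors, include_apoe = FALSE) {
  y <- as.integer(samples$status == "case")
  check(length(unique(y)) == 2L, "both classes must be present")
  X <- as.matrix(predictors)
  if (include_apoe) {
    g <- samples$apoe
    e2 <- (g %in% c("E2E3", "E2E4")) + 2 * (g == "E2E2")
    e4 <- (g %in% c("E2E4", "E3E4")) + 2 * (g == "E4E4")
    X <- cbind(X, apoe_e2 = e2, apoe_e4 = e4)
  }
  fit <- suppressWarnings(
    glm.fit(cbind(1, X), y, family = binomial(),
            control = list(maxit = 25L, epsilon = 1e-8)))
  sep <- !fit$converged || any(abs(fit$coefficients[-1]) > 15, na.rm = TRUE)
  if (sep) {
    warning("separation/non-convergence in logistic predictor; falling back to the raw first predictor")
    out <- X[, 1]
    attr(out, "converged") <- FALSE
    return(out)
  }
  out <- fit$fitted.values
  attr(out, "converged") <- TRUE
  out
}

#' Extreme-tail counts of a standardized PRS
#'
#' Counts cases and controls with score strictly below `-t` and strictly
#' above `+t` for each threshold.
#'
#' @param prs data.frame with a score column and a `status` column
#'   (case/control).
#' @param thresholds positive thresholds (default `c(1.5, 2)`).
#' @param score_col which column holds the z-standardized score
#'   (default `"adjusted_z"`).
#' @return data.frame: `threshold`, `tail` (negative/positive),
#'   `n_cases`, `n_controls`.
#' @export
tail_counts <- function(prs, thresholds = c(1.5, 2), score_col = "adjusted_z") {
  z <- prs[[score_col]]
  case <- prs$status == "case"
  out <- do.call(rbind, lapply(thresholds, function(t) {
    data.frame(threshold = t, tail = c("negative", "positive"),
               n_cases = c(sum(case & z < -t), sum(case & z > t)),
               n_controls = c(sum(!case & z < -t), sum(!case & z > t)))
  }))
  rownames(out) <- NULL
  out
}
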