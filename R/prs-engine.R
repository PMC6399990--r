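# Polygenic score construction.
#
# Scores are sums of discovery betas times effect-allele dosages over the
# retained SNP set at a p-value threshold, optionally excluding a genomic
# region (the APOE region by default elsewhere). Alleles are harmonized
# against the genotype metadata before summing; strand-ambiguous
# (palindromic) SNPs are dropped under the default policy.

#' Default APOE region (chromosome 19, GRCh37-style coordinates)
#'
#' The region removed by "APOE excluded" analyses. Bounds are inclusive.
#' @return list with `chrom`, `start_bp`, `end_bp`.
#' @export
apoe_region <- function() list(chrom = "19", start_bp = 44400000, end_bp = 46500000)

#' Scoring parameters
#'
#' @param p_threshold discovery p-value cutoff for SNP inclusion
#'   (default 0.5, the threshold that maximizes captured polygenic risk
#'   in this design).
#' @param exclude_region optional region list (`chrom`, `start_bp`,
#'   `end_bp`), e.g. [apoe_region()].
#' @param missing_policy how missing hard calls contribute:
#'   `"mean_dosage"` (default; the SNP's mean aligned dosage) or
#'   `"omit"` (contributes nothing).
#' @return list of class `score_spec`.
#' @export
score_spec <- function(p_threshold = 0.5, exclude_region = NULL,
                       missing_policy = c("mean_dosage", "omit")) {
  check(p_threshold > 0 && p_threshold <= 1, "p_threshold must lie in (0, 1]")
  if (!is.null(exclude_region)) {
    check(exclude_region$start_bp <= exclude_region$end_bp,
          "region start must not exceed end")
  }
  structure(list(p_threshold = p_threshold, exclude_region = exclude_region,
                 missing_policy = match.arg(missing_policy)),
            class = "score_spec")
}

#' The p-value threshold grid used in the threshold-profile analyses
#' @return numeric vector.
#' @export
threshold_grid <- function() c(0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Harmonize summary-statistic alleles against genotype metadata
#'
#' Determines how the effect-allele dosage relates to the stored alleleB
#' dosage: sign +1 when (effect, other) = (alleleB, alleleA), sign -1 when
#' swapped (dosage counted as `2 - dosage`). Strand-ambiguous pairs (A/T,
#' C/G) are unusable under the default policy; mismatched allele sets are
#' always unusable.
#'
#' @param effect_allele,other_allele alleles from the summary statistics.
#' @param alleleA,alleleB alleles from the genotype metadata.
#' @param drop_ambiguous drop palindromic SNPs (default TRUE).
#' @return data.frame with `sign` (+1/-1/NA) and `usable` (logical);
#'   vectorized over its arguments.
#' @export
align_alleles <- function(effect_allele, other_allele, alleleA, alleleB,
                          drop_ambiguous = TRUE) {
  direct <- effect_allele == alleleB & other_allele == alleleA
  swapped <- effect_allele == alleleA & other_allele == alleleB
  sign <- ifelse(direct, 1, ifelse(swapped, -1, NA_real_))
  usable <- !is.na(sign)
  if (drop_ambiguous) {
    usable <- usable & !is_ambiguous_pair(effect_allele, other_allele)
  }
  n_bad <- sum(!usable)
  if (n_bad > 0) msg(sprintf("align_alleles: %d SNPs unusable (allele mismatch or strand-ambiguous)", n_bad))
  data.frame(sign = sign, usable = usable)
}

#' SNP ids falling inside a genomic region
#'
#' @param snp_meta SNP metadata (`snp_id`, `chrom`, `pos`).
#' @param region list with `chrom`, `start_bp`, `end_bp`; bounds inclusive.
#' @return character vector of removed SNP ids.
#' @export
exclude_region <- function(snp_meta, region) {
  check(region$start_bp <= region$end_bp, "region start must not exceed end")
  hit <- snp_meta$chrom == as.character(region$chrom) &
    snp_meta$pos >= region$start_bp & snp_meta$pos <= region$end_bp
  snp_meta$snp_id[hit]
}

# aligned effect-allele dosage matrix for a SNP id set, missing handled
# per policy; returns list(D, betas, snp_ids, n_nonmiss per sample)
#' @noRd
aligned_dosage <- function(hc, sumstats, snp_ids, missing_policy = "mean_dosage") {
  ss <- sumstats[match(snp_ids, sumstats$SNP), , drop = FALSE]
  gi <- match(snp_ids, hc$snp_meta$snp_id)
  check(!anyNA(gi) && !anyNA(ss$SNP), "snp_ids must be present in both inputs")
  al <- align_alleles(ss$A1, ss$A2, hc$snp_meta$alleleA[gi], hc$snp_meta$alleleB[gi])
  keep <- al$usable
  ss <- ss[keep, , drop = FALSE]; gi <- gi[keep]; sgn <- al$sign[keep]
  D <- hc$dosage[, gi, drop = FALSE]
  # aligned dosage counts copies of the effect allele
  D <- sweep(D, 2L, sgn, function(d, s) ifelse(s > 0, d, 2 - d))
  nonmiss <- rowSums(!is.na(D))
  if (missing_policy == "mean_dosage") {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D))
    if (length(idx)) D[idx] <- mu[((idx - 1L) %/% nrow(D)) + 1L]
  } else {
    D[is.na(D)] <- 0
  }
  list(D = D, betas = ss$BETA, snp_ids = ss$SNP, nonmiss = nonmiss)
}

#' Compute polygenic risk scores
#'
#' Includes the retained SNPs with discovery `P <= p_threshold` that fall
#' outside any excluded region, aligns alleles, and sums
#' `beta * aligned dosage`. Scores are standardized over all scored
#' samples (`z`); when principal components are supplied, `adjusted_z` is
#' the residual of `z` on the PCs, re-standardized.
#'
#' @param hc a [hard_calls()] matrix.
#' @param sumstats discovery summary statistics.
#' @param retained SNP ids surviving LD pruning (see [greedy_prune()]);
#'   must be a subset of both inputs.
#' @param spec a [score_spec()].
#' @param pcs optional samples x k matrix of covariates to residualize on.
#' @return data.frame: `sample_id`, `n_snps_used` (non-missing included
#'   SNPs for that sample), `raw_score`, `z_score`, `adjusted_z` (equal to
#'   `z_score` when no PCs are given), with attribute `snp_ids` (the
#'   included set).
#' @export
compute_prs <- function(hc, sumstats, retained, spec = score_spec(), pcs = NULL) {
  ss <- sumstats[match(retained, sumstats$SNP), , drop = FALSE]
  check(!anyNA(ss$SNP), "retained SNPs missing from summary statistics")
  inc <- !is.na(ss$P) & ss$P <= spec$p_threshold
  if (!is.null(spec$exclude_region)) {
    gi <- match(ss$SNP, hc$snp_meta$snp_id)
    excl <- ss$SNP %in% exclude_region(hc$snp_meta[gi, , drop = FALSE],
                                       spec$exclude_region)
    inc <- inc & !excl
  }
  if (!any(inc)) {
    reg <- if (is.null(spec$exclude_region)) "none" else
      sprintf("%s:%d-%d", spec$exclude_region$chrom,
              spec$exclude_region$start_bp, spec$exclude_region$end_bp)
    stop(sprintf("no SNPs included at p <= %g (excluded region: %s)",
                 spec$p_threshold, reg), call. = FALSE)
  }
  ad <- aligned_dosage(hc, sumstats, ss$SNP[inc], spec$missing_policy)
  raw <- drop(ad$D %*% ad$betas)
  z <- as.numeric(scale(raw))
  adj <- z
  if (!is.null(pcs)) {
    fit <- lm.fit(cbind(1, as.matrix(pcs)), z)
    adj <- as.numeric(scale(fit$residuals))
  }
  out <- data.frame(sample_id = hc$sample_ids, n_snps_used = ad$nonmiss,
                    raw_score = raw, z_score = z, adjusted_z = adj,
                    stringsAsFactors = FALSE)
  attr(out, "snp_ids") <- ad$snp_ids
  out
}
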