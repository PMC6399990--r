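# Risk/alternative allele-burden comparison between APOE strata.
#
# For a SNP set at each p-value threshold, every person's risk-allele and
# alternative-allele counts are summed (risk allele = the allele with a
# positive aligned discovery beta). Two strata are compared through a
# 2x2 table of the mean (default) or total counts per stratum, with the
# cross-product odds ratio and a Pearson chi-square without continuity
# correction. Means-per-person are what threshold-profile tables usually
# print; note the chi-square on means is conservative (see the methods
# vignette), so totals are available behind `use_totals`.

#' Per-person risk and alternative allele counts
#'
#' @param hc a [hard_calls()] matrix.
#' @param sumstats discovery summary statistics (supply the betas that
#'   orient each SNP's risk allele).
#' @param snp_set SNP ids to count over (non-empty; must be present in
#'   both inputs). SNPs with `BETA = 0` count their effect allele as the
#'   risk allele.
#' @return data.frame: `sample_id`, `risk_count`, `alt_count`,
#'   `n_nonmissing`. Missing calls contribute to neither count, so
#'   `risk_count + alt_count = 2 * n_nonmissing`.
#' @export
count_alleles_per_person <- function(hc, sumstats, snp_set) {
  check(length(snp_set) > 0, "snp_set must be non-empty")
  ss <- sumstats[match(snp_set, sumstats$SNP), , drop = FALSE]
  gi <- match(snp_set, hc$snp_meta$snp_id)
  check(!anyNA(gi) && !anyNA(ss$SNP), "snp_set must be present in both inputs")
  al <- align_alleles(ss$A1, ss$A2, hc$snp_meta$alleleA[gi], hc$snp_meta$alleleB[gi])
  keep <- al$usable
  check(any(keep), "no alignable SNPs in snp_set")
  ss <- ss[keep, , drop = FALSE]; gi <- gi[keep]; sgn <- al$sign[keep]
  D <- hc$dosage[, gi, drop = FALSE]
  # effect-allele dosage, then flip SNPs with negative beta so the counted
  # allele is always the risk allele
  flip <- xor(sgn < 0, ss$BETA < 0)
  D[, flip] <- 2L - D[, flip, drop = FALSE]
  nonmiss <- rowSums(!is.na(D))
  risk <- rowSums(D, na.rm = TRUE)
  data.frame(sample_id = hc$sample_ids, risk_count = risk,
             alt_count = 2 * nonmiss - risk, n_nonmissing = nonmiss,
             stringsAsFactors = FALSE)
}

#' Compare allele burden between two strata
#'
#' Builds the 2x2 table `(risk, alternative) x (stratum A, stratum B)`
#' from mean counts per person (or totals with `use_totals = TRUE`),
#' reports the cross-product odds ratio
#' `OR = (risk_A * alt_B) / (alt_A * risk_B)` and the Pearson chi-square
#' p-value without continuity correction. A zero cell flags the OR as NA
#' and takes the p-value from Fisher's exact test on the rounded table.
#'
#' @param stratum_a_counts,stratum_b_counts outputs of
#'   [count_alleles_per_person()] subset to each stratum.
#' @param threshold the p-value threshold being summarized (echoed).
#' @param use_totals use summed rather than mean counts.
#' @return one-row data.frame: `threshold`, `mean_risk_a`, `mean_alt_a`,
#'   `mean_risk_b`, `mean_alt_b`, `odds_ratio`, `pvalue`.
#' @export
burden_contingency <- function(stratum_a_counts, stratum_b_counts,
                               threshold = NA_real_, use_totals = FALSE) {
  check(nrow(stratum_a_counts) > 0 && nrow(stratum_b_counts) > 0,
        "both strata must be non-empty")
  agg <- if (use_totals) sum else mean
  ra <- agg(stratum_a_counts$risk_count); aa <- agg(stratum_a_counts$alt_count)
  rb <- agg(stratum_b_counts$risk_count); ab <- agg(stratum_b_counts$alt_count)
  tab <- c(ra, aa, rb, ab)
  if (any(tab == 0)) {
    or <- NA_real_
    p <- stats::fisher.test(matrix(round(tab), 2, byrow = TRUE))$p.value
    warning("zero cell in burden table; OR undefined, exact p reported")
  } else {
    or <- (ra * ab) / (aa * rb)
    N <- sum(tab)
    x2 <- N * (ra * ab - aa * rb)^2 / ((ra + aa) * (rb + ab) * (ra + rb) * (aa + ab))
    p <- pchisq(x2, df = 1, lower.tail = FALSE)
  }
  data.frame(threshold = threshold, mean_risk_a = ra, mean_alt_a = aa,
             mean_risk_b = rb, mean_alt_b = ab, odds_ratio = or, pvalue = p)
}

#' Allele-burden profile over a threshold grid
#'
#' Runs the burden comparison (E3 homozygotes vs all other determinate
#' APOE genotypes by default) at every p-value threshold, separately in
#' cases and in controls, on the APOE-region-excluded SNP set.
#'
#' @param hc a [hard_calls()] matrix.
#' @param sumstats discovery summary statistics.
#' @param samples sample table with `status` and `apoe`.
#' @param retained SNP ids surviving LD pruning.
#' @param thresholds p-value grid (default [threshold_grid()]).
#' @param region region to exclude (default [apoe_region()]; NULL keeps
#'   everything).
#' @param use_totals passed to [burden_contingency()].
#' @return named list of data.frames (`cases`, `controls`), one row per
#'   threshold.
#' @export
burden_table <- function(hc, sumstats, samples, retained,
                         thresholds = threshold_grid(),
                         region = apoe_region(), use_totals = FALSE) {
  ss <- sumstats[match(retained, sumstats$SNP), , drop = FALSE]
  ss <- ss[!is.na(ss$P) & !is.na(ss$BETA), , drop = FALSE]
  if (!is.null(region)) {
    gi <- match(ss$SNP, hc$snp_meta$snp_id)
    ss <- ss[!(ss$SNP %in% exclude_region(hc$snp_meta[gi, , drop = FALSE],
                                          region)), , drop = FALSE]
  }
  e3 <- subset_stratum(samples, "E3E3")$sample_id
  other <- setdiff(samples$sample_id[!is.na(samples$apoe) &
                                       samples$apoe %in% APOE_LABELS], e3)
  per_class <- function(class) {
    ids_class <- samples$sample_id[samples$status == class]
    rows <- lapply(thresholds, function(t) {
      set <- ss$SNP[ss$P <= t]
      if (!length(set)) {
        return(data.frame(threshold = t, mean_risk_a = NA_real_,
                          mean_alt_a = NA_real_, mean_risk_b = NA_real_,
                          mean_alt_b = NA_real_, odds_ratio = NA_real_,
                          pvalue = NA_real_))
      }
      cnt <- count_alleles_per_person(hc, ss, set)
      a <- cnt[cnt$sample_id %in% intersect(e3, ids_class), , drop = FALSE]
      b <- cnt[cnt$sample_id %in% intersect(other, ids_class), , drop = FALSE]
      burden_contingency(a, b, threshold = t, use_totals = use_totals)
    })
    do.call(rbind, rows)
  }
  list(cases = per_class("case"), controls = per_class("control"))
}
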