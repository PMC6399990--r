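# APOE genotype classification and cohort strata.
#
# The three common APOE alleles are haplotypes of rs429358 and rs7412:
# (rs429358, rs7412) = (T, T) -> E2, (T, C) -> E3, (C, C) -> E4. With
# unphased dosages (copies of rs429358-C, copies of rs7412-T) the
# genotype is determined whenever at most one of the two SNPs is
# heterozygous and no (C, T) haplotype is implied; the double
# heterozygote (1, 1) is E2E4 or the rare E1/E3 and is reported as
# indeterminate rather than guessed.

#' Classify APOE genotypes from tag-SNP dosages
#'
#' @param rs429358_dosage copies of the rs429358 C allele (0/1/2);
#'   each C copy marks an E4 allele.
#' @param rs7412_dosage copies of the rs7412 T allele (0/1/2); each T
#'   copy marks an E2 allele.
#' @return character vector with values in
#'   `E2E2, E2E3, E2E4, E3E3, E3E4, E4E4` or `NA` (indeterminate:
#'   the (1,1) double heterozygote, any implied C/T haplotype, or a
#'   missing dosage).
#' @export
classify_apoe <- function(rs429358_dosage, rs7412_dosage) {
  e4 <- rs429358_dosage; e2 <- rs7412_dosage
  check(all(is.na(e4) | e4 %in% 0:2) && all(is.na(e2) | e2 %in% 0:2),
        "dosages must be 0, 1 or 2 (or NA)")
  e3 <- 2L - e4 - e2
  out <- rep(NA_character_, length(e4))
  # determinate iff at most one locus is non-homozygous-reference in a way
  # that forces the phase: any sample with both e4 > 0 and e2 > 0 requires
  # phase information (E2E4 vs a C/T haplotype), except none exists, so
  # only e4 == 0 or e2 == 0 (with e3 >= 0) is callable
  ok <- !is.na(e4) & !is.na(e2) & (e4 == 0L | e2 == 0L) & e3 >= 0L
  lab <- function(a, b) paste0(pmin(a, b), pmax(a, b))
  alleles <- cbind(ifelse(e4 >= 1, "E4", ifelse(e2 >= 1, "E2", "E3")),
                   ifelse(e4 == 2, "E4", ifelse(e2 == 2, "E2", "E3")))
  out[ok] <- lab(alleles[ok, 1], alleles[ok, 2])
  out
}

#' Subset a cohort to an APOE stratum
#'
#' Strata: `all` (identity), `non_E4` (no E4 allele), `E3E3` (E3
#' homozygotes), `E4_carriers` (at least one E4), `E4orE2_carriers`
#' (at least one E4 or E2). Samples with missing/indeterminate APOE
#' genotype are excluded from every stratum except `all`, with a message.
#'
#' @param samples sample table with an `apoe` column.
#' @param stratum one of the five labels above.
#' @return the subset sample table (row order preserved).
#' @export
subset_stratum <- function(samples,
                           stratum = c("all", "non_E4", "E3E3",
                                       "E4_carriers", "E4orE2_carriers")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") return(samples)
  g <- samples$apoe
  n_miss <- sum(is.na(g) | !(g %in% APOE_LABELS))
  if (n_miss > 0) msg(sprintf("subset_stratum: %d samples with missing/indeterminate APOE excluded", n_miss))
  has_e4 <- !is.na(g) & g %in% c("E2E4", "E3E4", "E4E4")
  has_e2 <- !is.na(g) & g %in% c("E2E2", "E2E3", "E2E4")
  valid <- !is.na(g) & g %in% APOE_LABELS
  keep <- switch(stratum,
                 non_E4 = valid & !has_e4,
                 E3E3 = valid & g == "E3E3",
                 E4_carriers = has_e4,
                 E4orE2_carriers = has_e4 | has_e2)
  out <- samples[keep, , drop = FALSE]
  msg(sprintf("subset_stratum[%s]: %d cases, %d controls", stratum,
              sum(out$status == "case"), sum(out$status == "control")))
  out
}
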