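# P-value-ordered greedy LD pruning.
#
# SNPs are visited in ascending discovery p-value (ties broken by
# chromosome, then position, then SNP id, so the result is deterministic
# and independent of input row order). A SNP is retained iff its r^2 with
# every already-retained SNP on the same chromosome within the window is
# at most r2_max. r^2 is the squared Pearson correlation of hard-call
# dosages in the test cohort itself (no external LD reference).

#' Clumping parameters
#'
#' @param r2_max maximum pairwise r-squared between retained SNPs
#'   (default 0.1).
#' @param window_bp physical window, base pairs; constraints apply to
#'   same-chromosome pairs with `|pos_i - pos_j| <= window_bp` (inclusive,
#'   default 500000).
#' @return list of class `clump_spec`.
#' @export
clump_spec <- function(r2_max = 0.1, window_bp = 500000) {
  check(r2_max >= 0 && r2_max <= 1, "r2_max must lie in [0, 1]")
  check(window_bp > 0, "window_bp must be positive")
  structure(list(r2_max = r2_max, window_bp = as.numeric(window_bp)),
            class = "clump_spec")
}

#' Pairwise r-squared between two SNPs
#'
#' Squared Pearson correlation of dosages over jointly non-missing
#' samples. A SNP with zero variance over those samples yields r² = 0
#' with a warning.
#'
#' @param hc a [hard_calls()] matrix.
#' @param snp_i,snp_j column indices or SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(hc, snp_i, snp_j) {
  i <- snp_col(hc, snp_i); j <- snp_col(hc, snp_j)
  x <- hc$dosage[, i]; y <- hc$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  check(sum(ok) >= 2, "need >= 2 jointly non-missing samples")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero dosage variance; r-squared defined as 0")
    return(0)
  }
  cor(x, y)^2
}

#' @noRd
snp_col <- function(hc, k) {
  if (is.character(k)) {
    i <- match(k, hc$snp_meta$snp_id)
    check(!is.na(i), "SNP not found: ", k)
    i
  } else as.integer(k)
}

# deterministic visiting order: p, then chrom (numeric where possible),
# then position, then id
#' @noRd
clump_order <- function(p, chrom, pos, id) {
  chrom_n <- suppressWarnings(as.numeric(chrom))
  chrom_n[is.na(chrom_n)] <- Inf
  order(p, chrom_n, chrom, pos, id)
}

#' Greedy p-value-ordered LD pruning
#'
#' @param sumstats summary-statistics data.frame (see [read_sumstats()]);
#'   supplies the ranking p-values and positions.
#' @param hc a [hard_calls()] matrix supplying LD. SNPs absent from the
#'   matrix (or with unusable statistics) are dropped before pruning, with
#'   a message.
#' @param spec a [clump_spec()].
#' @return character vector of retained SNP ids.
#' @export
greedy_prune <- function(sumstats, hc, spec = clump_spec()) {
  usable <- !is.na(sumstats$P) & !is.na(sumstats$BETA)
  ss <- sumstats[usable, , drop = FALSE]
  idx <- match(ss$SNP, hc$snp_meta$snp_id)
  dropped <- sum(is.na(idx)) + sum(!usable)
  if (dropped > 0) msg(sprintf("greedy_prune: %d SNPs dropped (absent from genotypes or untestable)", dropped))
  ss <- ss[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  check(nrow(ss) > 0, "no overlap between summary statistics and genotype matrix")

  ord <- clump_order(ss$P, ss$CHR, ss$BP, ss$SNP)
  ss <- ss[ord, , drop = FALSE]; idx <- idx[ord]
  D <- hc$dosage[, idx, drop = FALSE]
  retained <- integer(0)
  for (k in seq_len(nrow(ss))) {
    conflict <- FALSE
    if (length(retained)) {
      near <- retained[ss$CHR[retained] == ss$CHR[k] &
                         abs(ss$BP[retained] - ss$BP[k]) <= spec$window_bp]
      for (r in near) {
        x <- D[, r]; y <- D[, k]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2L) next
        if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next   # r2 defined as 0
        if (cor(x[ok], y[ok])^2 > spec$r2_max) { conflict <- TRUE; break }
      }
    }
    if (!conflict) retained <- c(retained, k)
  }
  ss$SNP[retained]
}
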