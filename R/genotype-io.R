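# Genotype containers, Oxford GEN/SAMPLE dialect, hard-calling and QC.
#
# A `gp_matrix` holds imputed genotype probabilities: a samples x snps x 3
# array of (pAA, pAB, pBB) triples plus per-SNP metadata (id, chrom, pos,
# alleleA, alleleB, info). A `hard_calls` object holds alleleB dosages in
# {0, 1, 2, NA}. Both are plain S3 lists so they stay cheap to subset.

#' Construct a genotype probability matrix
#'
#' @param probs numeric array, samples x snps x 3, of (pAA, pAB, pBB).
#' @param snp_meta data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `alleleA`, `alleleB` and optionally `info` (imputation Info score).
#' @param sample_ids character vector of sample identifiers.
#' @return an object of class `gp_matrix`.
#' @export
gp_matrix <- function(probs, snp_meta, sample_ids) {
  check(length(dim(probs)) == 3L && dim(probs)[3] == 3L,
        "probs must be a samples x snps x 3 array")
  check(nrow(snp_meta) == dim(probs)[2], "snp_meta rows must match probs columns")
  check(length(sample_ids) == dim(probs)[1], "sample_ids must match probs rows")
  need <- c("snp_id", "chrom", "pos", "alleleA", "alleleB")
  check(all(need %in% names(snp_meta)), "snp_meta missing required columns")
  if (is.null(snp_meta$info)) snp_meta$info <- NA_real_
  sums <- probs[, , 1L, drop = FALSE] + probs[, , 2L, drop = FALSE] +
    probs[, , 3L, drop = FALSE]
  check(all(probs >= -1e-9), "negative genotype probability")
  check(all(abs(sums - 1) < 1e-6), "probability triples must sum to 1 (±1e-6)")
  ok_info <- is.na(snp_meta$info) | (snp_meta$info >= 0 & snp_meta$info <= 1.05)
  check(all(ok_info), "info scores must lie in [0, 1.05]")
  structure(list(probs = probs,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids)),
            class = "gp_matrix")
}

#' @export
dim.gp_matrix <- function(x) dim(x$probs)[1:2]

#' @export
print.gp_matrix <- function(x, ...) {
  cat(sprintf("<gp_matrix> %d samples x %d SNPs\n", dim(x)[1], dim(x)[2]))
  invisible(x)
}

#' Construct a hard-call dosage matrix
#'
#' @param dosage samples x snps matrix of alleleB copy counts in
#'   `{0, 1, 2, NA}` (NA = no confident call).
#' @param snp_meta,sample_ids as in [gp_matrix()].
#' @return an object of class `hard_calls`.
#' @export
hard_calls <- function(dosage, snp_meta, sample_ids) {
  check(is.matrix(dosage), "dosage must be a matrix")
  check(nrow(snp_meta) == ncol(dosage), "snp_meta rows must match dosage columns")
  check(length(sample_ids) == nrow(dosage), "sample_ids must match dosage rows")
  vals <- dosage[!is.na(dosage)]
  check(all(vals %in% c(0, 1, 2)), "non-missing dosages must be 0, 1 or 2")
  structure(list(dosage = dosage,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids)),
            class = "hard_calls")
}

#' @export
dim.hard_calls <- function(x) dim(x$dosage)

#' @export
print.hard_calls <- function(x, ...) {
  cat(sprintf("<hard_calls> %d samples x %d SNPs (%.1f%% missing)\n",
              dim(x)[1], dim(x)[2], 100 * mean(is.na(x$dosage))))
  invisible(x)
}

# subset a gp_matrix by SNP index, keeping metadata in step
#' @noRd
gp_subset <- function(x, snp_idx) {
  gp_matrix(x$probs[, snp_idx, , drop = FALSE],
            x$snp_meta[snp_idx, , drop = FALSE],
            x$sample_ids)
}

#' Read an Oxford GEN/SAMPLE file pair
#'
#' The GEN dialect is space-delimited with one line per SNP:
#' `chrom id pos alleleA alleleB` followed by one `pAA pAB pBB` triple per
#' sample. The SAMPLE file uses the two-header-row Oxford convention
#' (`ID_1 ID_2 missing sex phenotype [apoe]` then a type row), sex coded
#' 1 = male, 2 = female, 0 = unknown and phenotype 1 = case, 0 = control.
#' Probability triples whose sum is outside 1 ± 1e-3 are renormalized with
#' a warning; sums within that band but off 1 are renormalized silently.
#'
#' @param path path to the GEN file.
#' @param sample_path path to the companion SAMPLE file.
#' @return list with `genotypes` (a [gp_matrix()]) and `samples`
#'   (a sample table: `sample_id`, `sex`, `status`, `apoe`).
#' @export
read_gen <- function(path, sample_path) {
  check(file.exists(path), "GEN file not found: ", path)
  check(file.exists(sample_path), "SAMPLE file not found: ", sample_path)
  samples <- read_sample(sample_path)
  n <- nrow(samples)

  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, " ", fixed = TRUE)
  lens <- lengths(toks)
  bad <- which(lens != 5L + 3L * n)
  if (length(bad)) {
    if (all(lens == lens[1]) && (lens[1] - 5L) %% 3L == 0L) {
      stop(sprintf("GEN file has %d samples but SAMPLE file lists %d",
                   (lens[1] - 5L) %/% 3L, n), call. = FALSE)
    }
    stop(sprintf("malformed GEN line %d: %d tokens, expected %d",
                 bad[1], lens[bad[1]], 5L + 3L * n), call. = FALSE)
  }
  m <- length(toks)
  meta <- data.frame(
    chrom   = vapply(toks, `[`, "", 1L),
    snp_id  = vapply(toks, `[`, "", 2L),
    pos     = as.integer(vapply(toks, `[`, "", 3L)),
    alleleA = vapply(toks, `[`, "", 4L),
    alleleB = vapply(toks, `[`, "", 5L),
    stringsAsFactors = FALSE
  )[, c("snp_id", "chrom", "pos", "alleleA", "alleleB")]
  num <- matrix(as.numeric(unlist(lapply(toks, `[`, -(1:5)), use.names = FALSE)),
                nrow = m, byrow = TRUE)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop("malformed GEN line ", bad, ": non-numeric probability", call. = FALSE)
  }
  probs <- array(NA_real_, c(n, m, 3L))
  probs[, , 1L] <- t(num[, seq(1L, 3L * n, by = 3L), drop = FALSE])
  probs[, , 2L] <- t(num[, seq(2L, 3L * n, by = 3L), drop = FALSE])
  probs[, , 3L] <- t(num[, seq(3L, 3L * n, by = 3L), drop = FALSE])
  sums <- probs[, , 1L] + probs[, , 2L] + probs[, , 3L]
  off <- abs(sums - 1) > 1e-3
  if (any(off)) {
    warning(sprintf("%d probability triples renormalized (sum outside 1 ± 1e-3)",
                    sum(off)))
  }
  if (any(abs(sums - 1) > 1e-9)) {
    for (k in 1:3) probs[, , k] <- probs[, , k] / sums
  }
  list(genotypes = gp_matrix(probs, meta, samples$sample_id), samples = samples)
}

#' Write an Oxford GEN file
#'
#' @param gp a [gp_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gen <- function(gp, path) {
  n <- dim(gp)[1]; m <- dim(gp)[2]
  num <- matrix(NA_real_, m, 3L * n)
  num[, seq(1L, 3L * n, by = 3L)] <- t(gp$probs[, , 1L])
  num[, seq(2L, 3L * n, by = 3L)] <- t(gp$probs[, , 2L])
  num[, seq(3L, 3L * n, by = 3L)] <- t(gp$probs[, , 3L])
  body <- apply(num, 1L, function(r) paste(fmt_num(r), collapse = " "))
  lines <- paste(gp$snp_meta$chrom, gp$snp_meta$snp_id, gp$snp_meta$pos,
                 gp$snp_meta$alleleA, gp$snp_meta$alleleB, body)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an Oxford SAMPLE file
#'
#' @param path file path.
#' @return `read_sample`: data.frame with `sample_id`, `sex`
#'   (male/female/unknown), `status` (case/control) and `apoe` (genotype
#'   label or NA).
#' @export
read_sample <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = " ", data.table = FALSE)
  check(nrow(tab) >= 1, "SAMPLE file has no data rows")
  tab <- tab[-1L, , drop = FALSE]   # drop the Oxford type row
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[as.character(tab$sex)]
  status <- ifelse(as.integer(tab$phenotype) == 1L, "case", "control")
  apoe <- if ("apoe" %in% names(tab)) {
    ifelse(tab$apoe %in% c("NA", "-", ""), NA_character_, as.character(tab$apoe))
  } else NA_character_
  data.frame(sample_id = as.character(tab$ID_1), sex = unname(sex),
             status = status, apoe = apoe, stringsAsFactors = FALSE)
}

#' @param samples a sample table (see [read_sample()]).
#' @rdname read_sample
#' @export
write_sample <- function(samples, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[samples$sex]
  pheno <- ifelse(samples$status == "case", "1", "0")
  apoe <- ifelse(is.na(samples$apoe), "NA", samples$apoe)
  lines <- c("ID_1 ID_2 missing sex phenotype apoe",
             "0 0 0 D B D",
             paste(samples$sample_id, samples$sample_id, "0", sex, pheno, apoe))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a GWAS summary-statistics table
#'
#' Tab-delimited with header `SNP CHR BP A1 A2 BETA SE P`; `A1` is the
#' effect allele (the allele `BETA` counts).
#'
#' @param path file path.
#' @return data.frame with those eight columns.
#' @export
read_sumstats <- function(path) {
  ss <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = c("SNP", "CHR", "A1", "A2")))
  validate_sumstats(ss)
}

#' @param sumstats a summary-statistics data.frame.
#' @rdname read_sumstats
#' @export
write_sumstats <- function(sumstats, path) {
  out <- sumstats[, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")]
  out$BETA <- fmt_num(out$BETA); out$SE <- fmt_num(out$SE); out$P <- fmt_num(out$P)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @noRd
validate_sumstats <- function(ss) {
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P")
  check(all(need %in% names(ss)), "summary statistics missing columns: ",
        paste(setdiff(need, names(ss)), collapse = ", "))
  ok <- !is.na(ss$SE) & !is.na(ss$P)
  check(all(ss$SE[ok] > 0), "summary statistics contain SE <= 0")
  check(all(ss$P[ok] > 0 & ss$P[ok] <= 1), "p-values must lie in (0, 1]")
  check(all(ss$A1 != ss$A2), "effect and other allele must differ")
  ss
}

#' Hard-call imputed genotype probabilities
#'
#' Converts each probability triple to the most probable genotype (alleleB
#' copy count) when that probability strictly exceeds `threshold`;
#' otherwise the call is missing. The default reproduces the common
#' "probability over 90%" rule.
#'
#' @param gp a [gp_matrix()].
#' @param threshold calling threshold in (1/3, 1]; strict inequality.
#' @return a [hard_calls()] object.
#' @export
hard_call <- function(gp, threshold = 0.9) {
  check(threshold > 1 / 3 && threshold <= 1, "threshold must lie in (1/3, 1]")
  p0 <- gp$probs[, , 1L]; p1 <- gp$probs[, , 2L]; p2 <- gp$probs[, , 3L]
  best <- pmax(p0, p1, p2)
  dos <- ifelse(best == p2, 2L, ifelse(best == p1, 1L, 0L))
  dos[best <= threshold] <- NA_integer_
  dos <- matrix(as.integer(dos), nrow = dim(gp)[1])
  hard_calls(dos, gp$snp_meta, gp$sample_ids)
}

#' Minor allele frequency from expected dosages
#'
#' MAF is the mean expected alleleB dosage over samples divided by two,
#' folded to `[0, 0.5]`. Computed on the fractional (imputed) dosages,
#' i.e. before hard-calling.
#'
#' @param gp a [gp_matrix()].
#' @param snp_index optional SNP index/indices; default all.
#' @return numeric vector of MAFs.
#' @export
compute_maf <- function(gp, snp_index = NULL) {
  check(dim(gp)[1] >= 1, "no samples")
  e <- expected_dosage(gp$probs)
  if (!is.null(snp_index)) e <- e[, snp_index, drop = FALSE]
  f <- colMeans(e) / 2
  pmin(f, 1 - f)
}

#' Apply imputation QC filters
#'
#' Retains SNPs with Info score >= `info_min` and expected-dosage MAF
#' >= `maf_min` (boundary values kept). Exclusion counts by reason are
#' reported via `message()`.
#'
#' @param gp a [gp_matrix()].
#' @param info_min minimum Info score (default 0.8).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return the filtered [gp_matrix()].
#' @export
qc_filter <- function(gp, info_min = 0.8, maf_min = 0.01) {
  check(info_min >= 0 && info_min <= 1 && maf_min >= 0 && maf_min <= 1,
        "thresholds must lie in [0, 1]")
  info <- gp$snp_meta$info
  info_ok <- is.na(info) | info >= info_min
  maf_ok <- compute_maf(gp) >= maf_min
  keep <- info_ok & maf_ok
  msg(sprintf("qc_filter: %d/%d SNPs retained (%d failed Info < %g, %d failed MAF < %g)",
              sum(keep), length(keep), sum(!info_ok), info_min, sum(!maf_ok), maf_min))
  if (!any(keep)) warning("qc_filter removed every SNP")
  gp_subset(gp, which(keep))
}
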