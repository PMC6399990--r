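# Shared fixture builders and independent brute-force oracles.

options(apoeprs.quiet = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# gp_matrix from a list of n x 3 probability matrices (one per SNP)
make_gp <- function(p, chrom = "1", pos = NULL, A = "A", B = "G", info = NULL) {
  if (is.matrix(p)) p <- list(p)
  n <- nrow(p[[1]]); m <- length(p)
  arr <- array(0, c(n, m, 3))
  for (j in seq_len(m)) arr[, j, ] <- p[[j]]
  meta <- data.frame(snp_id = paste0("snp", seq_len(m)),
                     chrom = rep(chrom, length.out = m),
                     pos = pos %||% (seq_len(m) * 1000L),
                     alleleA = rep(A, length.out = m),
                     alleleB = rep(B, length.out = m),
                     stringsAsFactors = FALSE)
  if (!is.null(info)) meta$info <- info
  gp_matrix(arr, meta, sprintf("P%03d", seq_len(n)))
}

# hard_calls from a plain dosage matrix
make_hc <- function(D, chrom = "1", pos = NULL, A = "A", B = "G", ids = NULL) {
  D <- as.matrix(D)
  meta <- data.frame(snp_id = paste0("snp", seq_len(ncol(D))),
                     chrom = rep(chrom, length.out = ncol(D)),
                     pos = pos %||% (seq_len(ncol(D)) * 1000L),
                     alleleA = rep(A, length.out = ncol(D)),
                     alleleB = rep(B, length.out = ncol(D)),
                     stringsAsFactors = FALSE)
  colnames(D) <- NULL
  hard_calls(D, meta, ids %||% sprintf("P%03d", seq_len(nrow(D))))
}

# summary statistics table
make_ss <- function(snp_id, beta, se = 0.05, p = 0.01, chrom = "1",
                    pos = NULL, A1 = "G", A2 = "A") {
  data.frame(SNP = snp_id, CHR = rep(chrom, length.out = length(snp_id)),
             BP = pos %||% (seq_along(snp_id) * 1000L),
             A1 = rep(A1, length.out = length(snp_id)),
             A2 = rep(A2, length.out = length(snp_id)),
             BETA = rep(beta, length.out = length(snp_id)),
             SE = rep(se, length.out = length(snp_id)),
             P = rep(p, length.out = length(snp_id)),
             stringsAsFactors = FALSE)
}

# brute-force Mann-Whitney AUC: explicit pair counting, ties = 1/2
auc_brute <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}

# independent greedy-prune oracle: naive loops, full r2 matrix computed
# from first principles, same ordering rule
prune_oracle <- function(ss, D, r2_max, window_bp) {
  r2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2 || var(x) == 0 || var(y) == 0) return(0)
    mx <- mean(x); my <- mean(y)
    num <- sum((x - mx) * (y - my))
    (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
  }
  cn <- suppressWarnings(as.numeric(ss$CHR)); cn[is.na(cn)] <- Inf
  ord <- order(ss$P, cn, ss$CHR, ss$BP, ss$SNP)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (ss$CHR[i] == ss$CHR[j] && abs(ss$BP[i] - ss$BP[j]) <= window_bp &&
          r2(D[, i], D[, j]) > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  ss$SNP[kept]
}

# quick null-free cohort for IO / scoring tests
tiny_cohort <- function(seed = 7, n_cases = 120, n_controls = 120,
                        n_snps = 60, n_causal = 10, discovery_n = 600, ...) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_snps = n_snps, n_causal = n_causal,
                    discovery_n = discovery_n, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  ss <- simulate_discovery_sumstats(cfg, sim$truth,
          list(samples = sim$samples, dosage = sim$true_dosage))
  list(cfg = cfg, sim = sim, ss = ss)
}
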