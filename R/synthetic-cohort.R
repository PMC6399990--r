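# Synthetic cohort generator.
#
# The generator produces (i) a test cohort of imputed-genotype-style
# probabilities with block-LD structure and an explicit APOE locus, and
# (ii) a discovery summary-statistics table from a (possibly overlapping)
# discovery sample, so the whole PRS pipeline runs without real data.
#
# Mechanism, in brief:
#  * haplotypes: Gaussian copula with AR(1) correlation `ld_rho` inside
#    blocks of `ld_block_size` SNPs, independent across blocks; alleleB is
#    carried when the latent normal falls below the MAF quantile.
#  * APOE: per-haplotype E2/E3/E4 allele drawn from `apoe_freqs`
#    (Hardy-Weinberg); encoded both as a genotype label and as two
#    biallelic SNPs (rs429358 C counts E4 alleles, rs7412 T counts E2
#    alleles) placed inside the default APOE region on chromosome 19.
#  * disease: logistic model on the log-odds scale,
#    eta = intercept + sum(beta * dosage) + APOE offset; case/control
#    quotas filled by rejection sampling from the population.
#  * imputation blur: the emitted triple mixes the true genotype's
#    indicator with a Dirichlet draw centred on the SNP's Hardy-Weinberg
#    probabilities; the mixing weight is chosen so the IMPUTE-style Info
#    score (observed / expected dosage variance) lands near a target drawn
#    from `info_range`.

APOE_LABELS <- c("E2E2", "E2E3", "E2E4", "E3E3", "E3E4", "E4E4")

#' Simulation configuration
#'
#' Defaults describe a pathological Alzheimer's-style case-control study:
#' 1011 cases and 583 controls, an APOE locus with per-allele log-odds
#' effects of +1.2 (E4) and -0.5 (E2) relative to E3, and a polygenic
#' background of small effects.
#'
#' @param n_cases,n_controls test-cohort quotas.
#' @param n_snps number of background (non-APOE) SNPs; the emitted matrix
#'   has `n_snps + 2` columns because the APOE locus adds rs429358 and
#'   rs7412.
#' @param n_causal number of background SNPs with non-zero effect.
#' @param maf_range range for alleleB frequencies, within \[0.01, 0.5\].
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho AR(1) correlation of the latent haplotype process within
#'   a block, in \[0, 1).
#' @param effect_sd standard deviation of causal log-odds effects.
#' @param apoe_freqs named frequencies of the E2/E3/E4 alleles (sum 1).
#' @param apoe_betas named per-allele log-odds effects for E2 and E4
#'   relative to E3.
#' @param info_range target range for per-SNP imputation Info scores.
#' @param discovery_n discovery-sample size for summary statistics.
#' @param overlap_fraction fraction of test samples re-used verbatim in
#'   the discovery sample, in \[0, 1\].
#' @param intercept baseline log-odds of disease (default `qlogis(0.15)`,
#'   a 15% population prevalence).
#' @param seed integer seed; mandatory.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1011, n_controls = 583, n_snps = 500,
                       n_causal = 50, maf_range = c(0.05, 0.5),
                       ld_block_size = 10, ld_rho = 0.6, effect_sd = 0.15,
                       apoe_freqs = c(E2 = 0.08, E3 = 0.77, E4 = 0.15),
                       apoe_betas = c(E2 = -0.5, E4 = 1.2),
                       info_range = c(0.85, 1), discovery_n = 4000,
                       overlap_fraction = 0, intercept = qlogis(0.15),
                       seed) {
  check(!missing(seed) && is.finite(seed), "seed is mandatory")
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
              maf_range = as.numeric(maf_range),
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              effect_sd = effect_sd,
              apoe_freqs = apoe_freqs[c("E2", "E3", "E4")],
              apoe_betas = apoe_betas[c("E2", "E4")],
              info_range = as.numeric(info_range),
              discovery_n = as.integer(discovery_n),
              overlap_fraction = overlap_fraction,
              intercept = intercept, seed = as.integer(seed))
  with(cfg, {
    check(n_cases >= 1 && n_controls >= 1 && n_snps >= 1 && ld_block_size >= 1 &&
            discovery_n >= 1, "all counts must be >= 1")
    check(n_causal >= 0 && n_causal <= n_snps, "n_causal must lie in [0, n_snps]")
    check(maf_range[1] >= 0.01 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
          "maf_range must lie within [0.01, 0.5]")
    check(ld_rho >= 0 && ld_rho < 1, "ld_rho must lie in [0, 1)")
    check(abs(sum(apoe_freqs) - 1) < 1e-9, "apoe_freqs must sum to 1")
    check(all(info_range > 0 & info_range <= 1) && info_range[1] <= info_range[2],
          "info_range must lie in (0, 1]")
    check(overlap_fraction >= 0 && overlap_fraction <= 1,
          "overlap_fraction must lie in [0, 1]")
    check(overlap_fraction * (n_cases + n_controls) <= discovery_n,
          "overlap_fraction * cohort size exceeds discovery_n")
  })
  structure(cfg, class = "sim_config")
}

# ---- fixed "world": SNP map, frequencies, true effects --------------------

# Everything downstream of the config that must agree between the test
# cohort and the discovery sample (SNP positions, allele frequencies, true
# betas) is drawn once, from a dedicated RNG stream, and carried on the
# TrueModel so simulate_discovery_sumstats() sees the same population.
#' @noRd
build_world <- function(config) {
  set.seed(config$seed)
  m <- config$n_snps
  freqs <- runif(m, config$maf_range[1], config$maf_range[2])
  n_blocks <- ceiling(m / config$ld_block_size)
  block <- rep(seq_len(n_blocks), each = config$ld_block_size)[seq_len(m)]
  # blocks round-robin over autosomes (chr 19 allowed: background positions
  # start at 1 Mb, far below the APOE region); SNPs 25 kb apart within a
  # block, blocks 1 Mb apart on the same chromosome
  chrom <- ((block - 1L) %% 22L) + 1L
  block_on_chrom <- (block - 1L) %/% 22L
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  pos <- 1000000L + block_on_chrom * 1000000L + (within - 1L) * 25000L
  snp_meta <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(chrom), pos = as.integer(pos),
    alleleA = "A", alleleB = "G", stringsAsFactors = FALSE)
  # APOE tag SNPs (GRCh37-style coordinates, inside the default region)
  apoe_meta <- data.frame(
    snp_id = c("rs429358", "rs7412"), chrom = "19",
    pos = c(45411941L, 45412079L),
    alleleA = c("T", "C"), alleleB = c("C", "T"), stringsAsFactors = FALSE)
  betas <- numeric(m)
  if (config$n_causal > 0) {
    causal <- sample.int(m, config$n_causal)
    betas[causal] <- rnorm(config$n_causal, 0, config$effect_sd)
  }
  target_info <- runif(m + 2L, config$info_range[1], config$info_range[2])
  bE2 <- config$apoe_betas[["E2"]]; bE4 <- config$apoe_betas[["E4"]]
  apoe_offsets <- c(E2E2 = 2 * bE2, E2E3 = bE2, E2E4 = bE2 + bE4,
                    E3E3 = 0, E3E4 = bE4, E4E4 = 2 * bE4)
  list(freqs = freqs, block = block, snp_meta = snp_meta,
       apoe_meta = apoe_meta, betas = betas, target_info = target_info,
       apoe_offsets = apoe_offsets)
}

# haplotype draw: n individuals x (n_snps + 2) true genotypes, plus APOE
# labels, sex, and disease status under the logistic model
#' @noRd
draw_population <- function(n, config, world) {
  m <- config$n_snps
  geno <- matrix(0L, n, m)
  thr <- qnorm(world$freqs)
  rho <- config$ld_rho; s <- sqrt(1 - rho^2)
  for (b in unique(world$block)) {
    idx <- which(world$block == b)
    z <- matrix(rnorm(2L * n * length(idx)), 2L * n, length(idx))
    if (rho > 0 && length(idx) > 1) {
      for (k in 2:length(idx)) z[, k] <- rho * z[, k - 1L] + s * z[, k]
    }
    carrier <- sweep(z, 2L, thr[idx], `<`)
    geno[, idx] <- carrier[seq_len(n), , drop = FALSE] +
      carrier[n + seq_len(n), , drop = FALSE]
  }
  # APOE: two allele draws per person
  al <- matrix(sample(c("E2", "E3", "E4"), 2L * n, replace = TRUE,
                      prob = config$apoe_freqs), n, 2L)
  apoe <- paste0(pmin(al[, 1], al[, 2]), pmax(al[, 1], al[, 2]))
  e4 <- rowSums(al == "E4"); e2 <- rowSums(al == "E2")
  geno <- cbind(geno, as.integer(e4), as.integer(e2))
  eta <- config$intercept + drop(geno[, seq_len(m), drop = FALSE] %*% world$betas) +
    unname(world$apoe_offsets[apoe])
  status <- rbinom(n, 1L, plogis(eta))
  sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "male", "female")
  list(geno = geno, apoe = apoe, sex = sex, status = status)
}

# imputation blur: true genotypes -> probability triples + realized Info
#' @noRd
blur_genotypes <- function(geno, freqs, target_info, dirichlet_conc = 50) {
  n <- nrow(geno); m <- ncol(geno)
  hwe <- rbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2) # 3 x m
  w <- rep(1 - sqrt(target_info), each = n)                     # n x m weight
  probs <- array(NA_real_, c(n, m, 3L))
  g1 <- matrix(rgamma(n * m, shape = dirichlet_conc * rep(hwe[1L, ], each = n)), n, m)
  g2 <- matrix(rgamma(n * m, shape = dirichlet_conc * rep(hwe[2L, ], each = n)), n, m)
  g3 <- matrix(rgamma(n * m, shape = dirichlet_conc * rep(hwe[3L, ], each = n)), n, m)
  tot <- g1 + g2 + g3
  probs[, , 1L] <- (1 - w) * (geno == 0L) + w * g1 / tot
  probs[, , 2L] <- (1 - w) * (geno == 1L) + w * g2 / tot
  probs[, , 3L] <- (1 - w) * (geno == 2L) + w * g3 / tot
  e <- probs[, , 2L] + 2 * probs[, , 3L]
  f <- colMeans(e) / 2
  denom <- 2 * f * (1 - f)
  ev <- (colMeans(e^2) - colMeans(e)^2) * n / (n - 1)
  info <- ifelse(denom > 0, ev / denom, 0)
  list(probs = probs, info = pmin(info, 1.05))
}

#' Simulate a case-control test cohort
#'
#' Draws individuals from the configured population model and keeps them
#' until the case and control quotas are met (rejection sampling), then
#' blurs the true genotypes into imputation-style probability triples.
#'
#' @param config a [sim_config()].
#' @return list with components:
#'   * `genotypes`: a [gp_matrix()] (`n_snps + 2` columns; the last two are
#'     the APOE tag SNPs rs429358/rs7412),
#'   * `samples`: sample table (`sample_id`, `sex`, `status`, `apoe`),
#'   * `truth`: the generating model (class `true_model`): `snp_betas`,
#'     `apoe_effect_by_genotype`, `intercept`, and the fixed world used to
#'     draw discovery samples,
#'   * `true_dosage`: the unblurred alleleB dosages (a [hard_calls()]),
#'     kept for oracle checks and for building overlapping discovery sets.
#' @export
simulate_cohort <- function(config) {
  check(inherits(config, "sim_config"), "config must come from sim_config()")
  world <- build_world(config)
  set.seed(config$seed + 1L)
  need_ca <- config$n_cases; need_co <- config$n_controls
  max_draws <- 500L * (need_ca + need_co)
  drawn <- 0L
  keep_g <- NULL; keep_apoe <- character(0); keep_sex <- character(0)
  keep_status <- integer(0)
  while (need_ca > 0L || need_co > 0L) {
    if (drawn >= max_draws) {
      stop(sprintf(paste0("could not reach %d cases / %d controls within %d ",
                          "population draws; raise the intercept or quotas"),
                   config$n_cases, config$n_controls, max_draws), call. = FALSE)
    }
    batch <- min(max(2L * (need_ca + need_co), 512L), max_draws - drawn)
    pop <- draw_population(batch, config, world)
    drawn <- drawn + batch
    want <- ifelse(pop$status == 1L, need_ca > 0L, need_co > 0L)
    # take cases/controls in draw order until each quota fills
    take <- which(want)
    if (length(take)) {
      is_case <- pop$status[take] == 1L
      take <- take[(cumsum(is_case) <= need_ca | !is_case) &
                     (cumsum(!is_case) <= need_co | is_case)]
      is_case <- pop$status[take] == 1L
      need_ca <- need_ca - sum(is_case); need_co <- need_co - sum(!is_case)
      keep_g <- rbind(keep_g, pop$geno[take, , drop = FALSE])
      keep_apoe <- c(keep_apoe, pop$apoe[take])
      keep_sex <- c(keep_sex, pop$sex[take])
      keep_status <- c(keep_status, pop$status[take])
    }
  }
  n <- nrow(keep_g)
  meta <- rbind(world$snp_meta, world$apoe_meta)
  freqs_all <- c(world$freqs,
                 config$apoe_freqs[["E4"]], config$apoe_freqs[["E2"]])
  bl <- blur_genotypes(keep_g, freqs_all, world$target_info)
  meta$info <- bl$info
  ids <- sprintf("S%05d", seq_len(n))
  samples <- data.frame(sample_id = ids, sex = keep_sex,
                        status = ifelse(keep_status == 1L, "case", "control"),
                        apoe = keep_apoe, stringsAsFactors = FALSE)
  truth <- structure(list(snp_betas = world$betas,
                          apoe_effect_by_genotype = world$apoe_offsets,
                          intercept = config$intercept, world = world),
                     class = "true_model")
  list(genotypes = gp_matrix(bl$probs, meta, ids),
       samples = samples,
       truth = truth,
       true_dosage = hard_calls(keep_g, meta[, 1:5], ids))
}

#' Simulate discovery GWAS summary statistics
#'
#' Builds a discovery sample of size `config$discovery_n` — re-using
#' `config$overlap_fraction` of the test cohort verbatim when
#' `test_cohort` is supplied — and runs a per-SNP logistic association of
#' disease status on alleleB dosage. Monomorphic SNPs get `SE = NA`,
#' `P = NA` and are excluded downstream by [qc_filter()]/[compute_prs()].
#'
#' @param config a [sim_config()].
#' @param model the `true_model` returned by [simulate_cohort()].
#' @param test_cohort optional list with `samples` and `dosage` (a
#'   [hard_calls()]) from which overlapping individuals are drawn.
#' @return a summary-statistics data.frame (`SNP CHR BP A1 A2 BETA SE P`;
#'   `A1` is alleleB, the dosage-counted allele).
#' @export
simulate_discovery_sumstats <- function(config, model, test_cohort = NULL) {
  check(inherits(model, "true_model"), "model must come from simulate_cohort()")
  world <- model$world
  set.seed(config$seed + 1000003L)
  n_overlap <- 0L
  geno <- NULL; status <- integer(0)
  if (!is.null(test_cohort) && config$overlap_fraction > 0) {
    n_test <- nrow(test_cohort$samples)
    n_overlap <- as.integer(round(config$overlap_fraction * n_test))
    pick <- sample.int(n_test, n_overlap)
    geno <- test_cohort$dosage$dosage[pick, , drop = FALSE]
    status <- as.integer(test_cohort$samples$status[pick] == "case")
  }
  n_fresh <- config$discovery_n - n_overlap
  if (n_fresh > 0) {
    pop <- draw_population(n_fresh, config, world)
    geno <- rbind(geno, pop$geno)
    status <- c(status, pop$status)
  }
  meta <- rbind(world$snp_meta, world$apoe_meta)
  fit <- logistic_scan(status, geno)
  data.frame(SNP = meta$snp_id, CHR = meta$chrom, BP = meta$pos,
             A1 = meta$alleleB, A2 = meta$alleleA,
             BETA = fit$beta, SE = fit$se, P = fit$p,
             stringsAsFactors = FALSE)
}

#' Closed-form AUC for equal-variance normal scores
#'
#' For case and control scores that are normal with common standard
#' deviation, the probability that a random case outscores a random
#' control is `pnorm((mean_case - mean_control) / (sd * sqrt(2)))`.
#'
#' @param score_mean_case,score_mean_control class means.
#' @param score_sd common within-class standard deviation (> 0).
#' @return probability in \[0, 1\].
#' @export
theoretical_auc <- function(score_mean_case, score_mean_control, score_sd) {
  check(score_sd > 0, "score_sd must be positive")
  pnorm((score_mean_case - score_mean_control) / (score_sd * sqrt(2)))
}
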