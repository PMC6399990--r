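# Synthetic cohort generator: structure, determinism, calibration.

test_that("simulate_cohort respects quotas, triple sums and determinism", {
  cfg <- sim_config(n_cases = 150, n_controls = 100, n_snps = 40,
                    n_causal = 5, discovery_n = 500, seed = 11)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$samples$status == "case"), 150)
  expect_equal(sum(sim$samples$status == "control"), 100)
  expect_equal(dim(sim$genotypes), c(250L, 42L))  # + 2 APOE tag SNPs

  sums <- sim$genotypes$probs[, , 1] + sim$genotypes$probs[, , 2] +
    sim$genotypes$probs[, , 3]
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(sim$genotypes$probs >= 0))

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$genotypes$probs, sim2$genotypes$probs)
  expect_identical(sim$samples, sim2$samples)

  # TrueModel contract
  expect_length(sim$truth$snp_betas, 40)
  expect_setequal(names(sim$truth$apoe_effect_by_genotype),
                  c("E2E2", "E2E3", "E2E4", "E3E3", "E3E4", "E4E4"))
})

test_that("config validation rejects bad worlds", {
  expect_error(sim_config(seed = 1, maf_range = c(0.001, 0.5)), "maf_range")
  expect_error(sim_config(seed = 1, apoe_freqs = c(E2 = 0.5, E3 = 0.4, E4 = 0.2)),
               "sum to 1")
  expect_error(sim_config(seed = 1, overlap_fraction = 1, discovery_n = 100),
               "discovery_n")
  expect_error(sim_config(n_cases = 100), "seed")
  # infeasible quotas: essentially nobody is a case
  cfg <- sim_config(n_cases = 500, n_controls = 10, n_snps = 10, n_causal = 0,
                    apoe_betas = c(E2 = 0, E4 = 0), intercept = qlogis(1e-5),
                    discovery_n = 100, seed = 3)
  expect_error(simulate_cohort(cfg), "population draws")
})

test_that("ld_rho = 0 gives near-zero adjacent r2; blocks carry LD otherwise", {
  cfg0 <- sim_config(n_cases = 1000, n_controls = 1000, n_snps = 60,
                     n_causal = 0, ld_rho = 0, discovery_n = 100, seed = 21)
  hc <- simulate_cohort(cfg0)$true_dosage
  r2 <- vapply(seq_len(59), function(j) {
    suppressWarnings(pairwise_r2(hc, j, j + 1))
  }, numeric(1))
  expect_lt(mean(r2), 0.02)

  cfgL <- sim_config(n_cases = 1000, n_controls = 1000, n_snps = 60,
                     n_causal = 0, ld_rho = 0.9, ld_block_size = 10,
                     discovery_n = 100, seed = 21)
  hcL <- simulate_cohort(cfgL)$true_dosage
  within <- vapply(c(1:9, 11:19), function(j) pairwise_r2(hcL, j, j + 1), numeric(1))
  expect_gt(mean(within), 0.3)   # adjacent within-block SNPs correlated
  expect_lt(pairwise_r2(hcL, 10, 11), 0.1)  # across block boundary: none
})

test_that("MAF floor and Info targets are respected at scale", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_snps = 80,
                    n_causal = 0, maf_range = c(0.01, 0.5),
                    info_range = c(0.8, 1), discovery_n = 100, seed = 5)
  sim <- simulate_cohort(cfg)
  expect_true(all(compute_maf(sim$genotypes) >= 0.009 - 0.002))
  info <- sim$genotypes$snp_meta$info
  expect_true(all(info >= 0.6 & info <= 1.05))  # loose band: blur is stochastic
})

test_that("APOE genotype frequencies follow Hardy-Weinberg", {
  cfg <- sim_config(n_cases = 2500, n_controls = 2500, n_snps = 10,
                    n_causal = 0, apoe_betas = c(E2 = 0, E4 = 0),
                    discovery_n = 100, seed = 9)
  sim <- simulate_cohort(cfg)
  f <- cfg$apoe_freqs
  exp_p <- c(E2E2 = f[["E2"]]^2, E2E3 = 2 * f[["E2"]] * f[["E3"]],
             E2E4 = 2 * f[["E2"]] * f[["E4"]], E3E3 = f[["E3"]]^2,
             E3E4 = 2 * f[["E3"]] * f[["E4"]], E4E4 = f[["E4"]]^2)
  obs <- table(factor(sim$samples$apoe, levels = names(exp_p)))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = exp_p))
  expect_gt(gof$p.value, 0.001)
})

test_that("null configuration yields chance-level discrimination", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, n_snps = 100,
                    n_causal = 0, apoe_betas = c(E2 = 0, E4 = 0),
                    discovery_n = 800, seed = 31)
  sim <- simulate_cohort(cfg)
  ss <- simulate_discovery_sumstats(cfg, sim$truth)
  hc <- hard_call(sim$genotypes)
  prs <- compute_prs(hc, ss, ss$SNP[!is.na(ss$P)], score_spec(0.5))
  case <- sim$samples$status == "case"
  auc <- auc_mann_whitney(prs$z_score[case], prs$z_score[!case])
  expect_gt(auc, 0.42); expect_lt(auc, 0.58)
})

test_that("discovery betas are consistent and null p-values uniform", {
  # strong causal SNP recovered within 3 SE at large n
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_snps = 30, n_causal = 0,
                    apoe_betas = c(E2 = 0, E4 = 0), ld_rho = 0,
                    discovery_n = 8000, seed = 13)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  truth$snp_betas[7] <- 0.5   # inject a known effect into the world
  truth$world$betas[7] <- 0.5
  ss <- simulate_discovery_sumstats(cfg, truth)
  expect_lt(abs(ss$BETA[7] - 0.5), 3 * ss$SE[7])

  # remaining null SNPs: p ~ Uniform(0,1) (independent SNPs, ld_rho = 0)
  pnull <- ss$P[-7][seq_len(29)]
  ks <- suppressWarnings(stats::ks.test(pnull, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("full-overlap discovery inflates the unadjusted AUC", {
  # paired comparison on the same worlds: discovery == test vs independent
  deltas <- vapply(1:15, function(i) {
    cfg1 <- sim_config(n_cases = 150, n_controls = 150, n_snps = 80,
                       n_causal = 0, apoe_betas = c(E2 = 0, E4 = 0),
                       discovery_n = 300, overlap_fraction = 1, seed = 100 + i)
    sim <- simulate_cohort(cfg1)
    hc <- hard_call(sim$genotypes)
    case <- sim$samples$status == "case"
    auc_of <- function(ss) {
      prs <- compute_prs(hc, ss, ss$SNP[!is.na(ss$P)], score_spec(0.5))
      auc_mann_whitney(prs$z_score[case], prs$z_score[!case])
    }
    ss_overlap <- simulate_discovery_sumstats(
      cfg1, sim$truth, list(samples = sim$samples, dosage = sim$true_dosage))
    cfg0 <- cfg1; cfg0$overlap_fraction <- 0
    ss_indep <- simulate_discovery_sumstats(cfg0, sim$truth)
    auc_of(ss_overlap) - auc_of(ss_indep)
  }, numeric(1))
  # under the null the only signal is overfitting to the test sample
  expect_gt(mean(deltas), 0.05)
})

test_that("theoretical_auc matches the closed form", {
  expect_equal(theoretical_auc(1, 1, 1), 0.5)
  expect_equal(theoretical_auc(20, 0, 1), 1.0, tolerance = 1e-9)
  expect_equal(theoretical_auc(1.19, 0, 1), 0.7999, tolerance = 5e-4)
  expect_error(theoretical_auc(1, 0, 0), "positive")
})
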