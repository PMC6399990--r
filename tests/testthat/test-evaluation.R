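# AUC, DeLong intervals, logistic predictor, tail counts.

test_that("auc_mann_whitney matches pair counting on hand cases", {
  expect_equal(auc_mann_whitney(c(2, 3), c(0, 1)), 1.0)
  expect_equal(auc_mann_whitney(c(3, 1), c(2, 0)), 0.75)
  expect_equal(auc_mann_whitney(rep(1, 5), rep(1, 7)), 0.5)
  expect_error(auc_mann_whitney(numeric(0), 1), "non-empty")
})

test_that("auc_mann_whitney equals the brute-force oracle with ties", {
  set.seed(77)
  for (i in 1:30) {
    m <- sample(2:60, 1); n <- sample(2:60, 1)
    ca <- round(rnorm(m), 1)   # rounding forces ties
    co <- round(rnorm(n), 1)
    expect_equal(auc_mann_whitney(ca, co), auc_brute(ca, co),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(5)
  ca <- rnorm(40, 1); co <- rnorm(50)
  a0 <- auc_mann_whitney(ca, co)
  expect_equal(auc_mann_whitney(exp(ca), exp(co)), a0)
  expect_equal(auc_mann_whitney(qlogis(plogis(ca)), qlogis(plogis(co))), a0,
               tolerance = 1e-12)
})

test_that("delong_ci: symmetry, degeneracy and coverage", {
  set.seed(6)
  ca <- rnorm(80, 0.8); co <- rnorm(90)
  r <- delong_ci(ca, co)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  flip <- delong_ci(co, ca)
  expect_equal(flip$auc, 1 - r$auc)
  expect_equal(flip$ci_low, 1 - r$ci_high, tolerance = 1e-12)

  expect_warning(perf <- delong_ci(c(5, 6, 7), c(1, 2, 3)), "degenerate")
  expect_equal(c(perf$auc, perf$ci_low, perf$ci_high), c(1, 1, 1))

  # null coverage: CI contains 0.5 about 95% of the time
  set.seed(8)
  n <- 400
  cover <- vapply(seq_len(500), function(i) {
    x <- rnorm(n); y <- rnorm(n)
    ci <- delong_ci(x, y)
    ci$ci_low <= 0.5 && 0.5 <= ci$ci_high
  }, logical(1))
  band <- qbinom(c(0.025, 0.975), 500, 0.95) / 500
  expect_gte(mean(cover), band[1])
  expect_lte(mean(cover), band[2])
})

test_that("DeLong interval width shrinks like 1/sqrt(n)", {
  set.seed(10)
  width <- function(n) {
    mean(vapply(1:40, function(i) {
      r <- delong_ci(rnorm(n, 0.5), rnorm(n))
      r$ci_high - r$ci_low
    }, numeric(1)))
  }
  ratio <- width(150) / width(600)
  expect_gt(ratio, 1.8); expect_lt(ratio, 2.2)
})

test_that("logistic predictor preserves single-predictor AUC and resists noise", {
  set.seed(12)
  n <- 600
  score <- rnorm(n)
  y <- rbinom(n, 1, plogis(score))
  samples <- data.frame(sample_id = seq_len(n), sex = "male",
                        status = ifelse(y == 1, "case", "control"))
  p1 <- fit_logistic_predictor(samples, cbind(prs = score))
  a_raw <- auc_mann_whitney(score[y == 1], score[y == 0])
  a_fit <- auc_mann_whitney(p1[y == 1], p1[y == 0])
  expect_equal(a_fit, a_raw, tolerance = 1e-12)

  p2 <- fit_logistic_predictor(samples, cbind(prs = score, noise = rnorm(n)))
  a2 <- auc_mann_whitney(p2[y == 1], p2[y == 0])
  expect_lt(abs(a2 - a_raw), 0.02)
})

test_that("APOE-only model recovers the enumerated mixture AUC", {
  # genotype-only score: AUC computable by enumeration over strata pairs
  set.seed(14)
  cfg <- sim_config(n_cases = 1200, n_controls = 1200, n_snps = 10,
                    n_causal = 0, discovery_n = 100, seed = 14)
  sim <- simulate_cohort(cfg)
  s <- sim$samples
  p_case <- table(s$apoe[s$status == "case"]) / sum(s$status == "case")
  p_ctrl <- table(s$apoe[s$status == "control"]) / sum(s$status == "control")
  off <- sim$truth$apoe_effect_by_genotype
  # theoretical AUC of the genotype-offset score by enumeration
  labs <- names(off)
  a_theory <- 0
  for (i in labs) for (j in labs) {
    pc <- p_case[i]; pq <- p_ctrl[j]
    if (is.na(pc) || is.na(pq)) next
    a_theory <- a_theory + pc * pq * ((off[i] > off[j]) + 0.5 * (off[i] == off[j]))
  }
  pred <- fit_logistic_predictor(s, matrix(0, nrow(s), 1), include_apoe = TRUE)
  case <- s$status == "case"
  a_emp <- auc_mann_whitney(pred[case], pred[!case])
  expect_lt(abs(a_emp - a_theory), 0.03)
})

test_that("tail_counts uses strict inequalities and is additive", {
  prs <- data.frame(adjusted_z = c(-2.5, 0, 2.5),
                    status = c("control", "control", "case"))
  tc <- tail_counts(prs, thresholds = 2)
  expect_equal(tc$n_controls[tc$tail == "negative"], 1)
  expect_equal(tc$n_cases[tc$tail == "negative"], 0)
  expect_equal(tc$n_cases[tc$tail == "positive"], 1)
  expect_equal(tc$n_controls[tc$tail == "positive"], 0)

  expect_true(all(tail_counts(prs, thresholds = 3)[, c("n_cases", "n_controls")] == 0))
  # boundary is exclusive
  prs2 <- data.frame(adjusted_z = c(-2, 2), status = c("control", "case"))
  expect_true(all(tail_counts(prs2, thresholds = 2)[, c("n_cases", "n_controls")] == 0))
  # doubling the cohort doubles counts
  tc2 <- tail_counts(rbind(prs, prs), thresholds = 2)
  expect_equal(tc2$n_cases, 2 * tc$n_cases)
  expect_equal(tc2$n_controls, 2 * tc$n_controls)
})
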