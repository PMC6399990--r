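# Allele alignment and polygenic scoring.

test_that("align_alleles handles direct, swapped and ambiguous pairs", {
  al <- suppressMessages(
    align_alleles(c("G", "A", "A", "C"), c("A", "G", "T", "T"),
                  alleleA = c("A", "A", "A", "A"),
                  alleleB = c("G", "G", "T", "G")))
  expect_equal(al$sign, c(1, -1, -1, NA))
  expect_equal(al$usable, c(TRUE, TRUE, FALSE, FALSE))  # A/T ambiguous; C/T mismatch
  al2 <- align_alleles("A", "T", alleleA = "T", alleleB = "A",
                       drop_ambiguous = FALSE)
  expect_true(al2$usable)
})

test_that("raw scores are hand-checkable sums of aligned dosages", {
  hc <- make_hc(cbind(c(0L, 1L, 2L), c(2L, 2L, 2L)),
                pos = c(1000L, 2000L))
  ss <- make_ss(c("snp1", "snp2"), beta = c(0.5, -0.3), p = 0.01,
                pos = c(1000L, 2000L))
  prs <- compute_prs(hc, ss, c("snp1", "snp2"), score_spec(0.5))
  expect_equal(prs$raw_score, c(0 - 0.6, 0.5 - 0.6, 1.0 - 0.6))
  expect_equal(prs$n_snps_used, c(2L, 2L, 2L))
  expect_equal(mean(prs$z_score), 0, tolerance = 1e-12)
  expect_equal(sd(prs$z_score), 1, tolerance = 1e-12)
})

test_that("flip invariance: swapping alleles and negating betas changes nothing", {
  co <- tiny_cohort(seed = 15)
  hc <- hard_call(co$sim$genotypes)
  kept <- greedy_prune(co$ss, hc, clump_spec(0.2, 500000))
  base <- compute_prs(hc, co$ss, kept, score_spec(0.5))
  set.seed(1); flip <- sample(nrow(co$ss), 20)
  ss2 <- co$ss
  ss2[flip, c("A1", "A2")] <- ss2[flip, c("A2", "A1")]
  ss2$BETA[flip] <- -ss2$BETA[flip]
  flipped <- compute_prs(hc, ss2, kept, score_spec(0.5))
  expect_lt(max(abs(base$z_score - flipped$z_score)), 1e-10)
})

test_that("thresholds nest and scores are additive over disjoint SNP sets", {
  co <- tiny_cohort(seed = 16)
  hc <- hard_call(co$sim$genotypes)
  kept <- greedy_prune(co$ss, hc, clump_spec(0.2, 500000))
  used <- function(t) attr(compute_prs(hc, co$ss, kept, score_spec(t)), "snp_ids")
  sets <- lapply(c(0.1, 0.3, 0.5), used)
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))

  all_set <- sets[[3]]
  half <- all_set[seq_len(floor(length(all_set) / 2))]
  rest <- setdiff(all_set, half)
  s_all <- compute_prs(hc, co$ss, all_set, score_spec(1))$raw_score
  s_a <- compute_prs(hc, co$ss, half, score_spec(1))$raw_score
  s_b <- compute_prs(hc, co$ss, rest, score_spec(1))$raw_score
  expect_equal(s_all, s_a + s_b, tolerance = 1e-10)
})

test_that("adjusted_z is orthogonal to PCs; sample order is irrelevant", {
  co <- tiny_cohort(seed = 18)
  hc <- hard_call(co$sim$genotypes)
  kept <- greedy_prune(co$ss, hc, clump_spec(0.2, 500000))
  pcs <- compute_pcs(hc, 2)
  prs <- compute_prs(hc, co$ss, kept, score_spec(0.5), pcs = pcs)
  expect_lt(abs(cor(prs$adjusted_z, pcs[, 1])), 1e-8)
  expect_lt(abs(cor(prs$adjusted_z, pcs[, 2])), 1e-8)
  expect_equal(mean(prs$adjusted_z), 0, tolerance = 1e-9)
  expect_equal(sd(prs$adjusted_z), 1, tolerance = 1e-9)

  perm <- sample(length(hc$sample_ids))
  hc_p <- hard_calls(hc$dosage[perm, ], hc$snp_meta, hc$sample_ids[perm])
  prs_p <- compute_prs(hc_p, co$ss, kept, score_spec(0.5), pcs = pcs[perm, ])
  expect_equal(prs_p$raw_score[match(prs$sample_id, prs_p$sample_id)],
               prs$raw_score, tolerance = 1e-12)
})

test_that("region exclusion is inclusive on both ends and chromosome-aware", {
  meta <- data.frame(snp_id = paste0("s", 1:4),
                     chrom = c("19", "19", "19", "1"),
                     pos = c(44400000L, 46500000L, 44399999L, 45000000L))
  removed <- exclude_region(meta, apoe_region())
  expect_setequal(removed, c("s1", "s2"))

  co <- tiny_cohort(seed = 19)
  hc <- hard_call(co$sim$genotypes)
  kept <- greedy_prune(co$ss, hc, clump_spec(0.2, 500000))
  with_apoe <- compute_prs(hc, co$ss, kept, score_spec(0.5))
  without <- compute_prs(hc, co$ss, kept, score_spec(0.5, apoe_region()))
  excluded <- setdiff(attr(with_apoe, "snp_ids"), attr(without, "snp_ids"))
  expect_true(all(excluded %in% c("rs429358", "rs7412")))
  # a region touching nothing leaves scores unchanged
  off <- score_spec(0.5, list(chrom = "19", start_bp = 1, end_bp = 2))
  expect_equal(compute_prs(hc, co$ss, kept, off)$raw_score,
               with_apoe$raw_score)
})

test_that("zero included SNPs is an explicit error naming the threshold", {
  hc <- make_hc(cbind(c(0L, 1L, 2L)))
  ss <- make_ss("snp1", beta = 0.5, p = 0.9)
  expect_error(compute_prs(hc, ss, "snp1", score_spec(0.0001)),
               "no SNPs included")
})

test_that("missing dosages follow the declared policy", {
  D <- cbind(c(0L, 1L, 2L, NA), c(1L, 1L, NA, 1L))
  hc <- make_hc(D, pos = c(1000L, 2000L))
  ss <- make_ss(c("snp1", "snp2"), beta = c(1, 1), p = 0.01, pos = c(1000L, 2000L))
  mean_d <- compute_prs(hc, ss, c("snp1", "snp2"),
                        score_spec(0.5, missing_policy = "mean_dosage"))
  expect_equal(mean_d$raw_score[4], 1 + 1)         # snp1 mean dosage = 1
  expect_equal(mean_d$n_snps_used[4], 1L)
  omit <- compute_prs(hc, ss, c("snp1", "snp2"),
                      score_spec(0.5, missing_policy = "omit"))
  expect_equal(omit$raw_score[4], 1)
})
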