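# End-to-end pipeline: simulate (optional) -> QC -> hard-call -> clump ->
# score -> stratify -> evaluate -> burden -> overlap-adjust.
#
# Driven by a single JSON-able config. All outputs are deterministic
# functions of (inputs, config, seed): no timestamps are written, so two
# runs with the same config produce byte-identical files.

#' Build a pipeline configuration
#'
#' @param simulate a [sim_config()] (the pipeline generates its own
#'   cohort), or NULL to read `gen_path`/`sample_path`/`sumstats_path`.
#' @param gen_path,sample_path,sumstats_path input files when not
#'   simulating.
#' @param out_dir output directory (created if needed); NULL returns the
#'   report without writing files.
#' @param info_min,maf_min QC thresholds.
#' @param hard_call_threshold probability needed for a genotype call.
#' @param clump a [clump_spec()].
#' @param p_thresholds the two headline scoring thresholds for the AUC
#'   grid (default `c(0.001, 0.5)`).
#' @param burden_thresholds grid for the allele-burden profile.
#' @param strata strata evaluated in the AUC grid.
#' @param region the APOE region used for exclusion analyses.
#' @param adjust_stratum stratum receiving the overlap adjustment
#'   (default "E3E3").
#' @param n_sims,noise_coefficient overlap-adjustment parameters.
#' @param tail_thresholds extreme-tail cutoffs.
#' @param n_pcs number of principal components used as covariates.
#' @param seed integer seed for every stochastic stage; mandatory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, gen_path = NULL,
                            sample_path = NULL, sumstats_path = NULL,
                            out_dir = NULL, info_min = 0.8, maf_min = 0.01,
                            hard_call_threshold = 0.9,
                            clump = clump_spec(),
                            p_thresholds = c(0.001, 0.5),
                            burden_thresholds = threshold_grid(),
                            strata = c("all", "E4_carriers",
                                       "E4orE2_carriers", "E3E3"),
                            region = apoe_region(),
                            adjust_stratum = "E3E3",
                            n_sims = 1000, noise_coefficient = 0.12,
                            tail_thresholds = c(1.5, 2),
                            n_pcs = 2, seed) {
  check(!missing(seed) && is.finite(seed), "seed is mandatory")
  if (is.null(simulate)) {
    check(!is.null(gen_path) && !is.null(sample_path) && !is.null(sumstats_path),
          "gen_path, sample_path and sumstats_path are required when not simulating")
    check(file.exists(gen_path), "genotype file not found: ", gen_path)
    check(file.exists(sample_path), "sample file not found: ", sample_path)
    check(file.exists(sumstats_path), "summary-statistics file not found: ", sumstats_path)
  } else {
    check(inherits(simulate, "sim_config"), "simulate must come from sim_config()")
  }
  structure(list(simulate = simulate, gen_path = gen_path,
                 sample_path = sample_path, sumstats_path = sumstats_path,
                 out_dir = out_dir, info_min = info_min, maf_min = maf_min,
                 hard_call_threshold = hard_call_threshold, clump = clump,
                 p_thresholds = p_thresholds,
                 burden_thresholds = burden_thresholds, strata = strata,
                 region = region, adjust_stratum = adjust_stratum,
                 n_sims = as.integer(n_sims),
                 noise_coefficient = noise_coefficient,
                 tail_thresholds = tail_thresholds, n_pcs = n_pcs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort and returns (and optionally writes)
#' a structured report: an AUC grid of strata x scoring models x APOE
#' region included/excluded, allele-burden threshold profiles for cases
#' and controls, extreme-tail counts in the adjusted stratum, and the
#' overlap-adjusted AUC. Each stage logs its input/output record counts.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with elements `auc_grid`
#'   (data.frame: stratum, p_threshold, region, auc, ci_low, ci_high,
#'   n_cases, n_controls, n_snps), `burden` (list cases/controls),
#'   `tails`, `adjusted` (an `adjusted_auc`), `counts` (per-stage record
#'   counts) and `config_digest`.
#' @export
run_pipeline <- function(config) {
  check(inherits(config, "pipeline_config"), "config must come from pipeline_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  counts <- list()

  # -- input / simulate ----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_cohort(config$simulate))
    gp <- sim$genotypes; samples <- sim$samples
    sumstats <- stage("simulate", simulate_discovery_sumstats(
      config$simulate, sim$truth,
      test_cohort = list(samples = sim$samples, dosage = sim$true_dosage)))
  } else {
    inp <- stage("read", read_gen(config$gen_path, config$sample_path))
    gp <- inp$genotypes; samples <- inp$samples
    sumstats <- stage("read", read_sumstats(config$sumstats_path))
  }
  counts$samples_in <- nrow(samples); counts$snps_in <- dim(gp)[2]
  msg(sprintf("pipeline: %d samples, %d SNPs in", counts$samples_in, counts$snps_in))

  # -- QC + hard call ------------------------------------------------------
  gp <- stage("qc", qc_filter(gp, config$info_min, config$maf_min))
  counts$snps_qc <- dim(gp)[2]
  hc <- stage("hard_call", hard_call(gp, config$hard_call_threshold))

  # -- APOE labels: fill any missing from the tag SNPs ---------------------
  tag <- match(c("rs429358", "rs7412"), hc$snp_meta$snp_id)
  if (!anyNA(tag)) {
    inferred <- classify_apoe(hc$dosage[, tag[1]], hc$dosage[, tag[2]])
    fill <- is.na(samples$apoe) | !(samples$apoe %in% APOE_LABELS)
    samples$apoe[fill] <- inferred[fill]
  }
  counts$apoe_determinate <- sum(samples$apoe %in% APOE_LABELS, na.rm = TRUE)

  # -- clump ---------------------------------------------------------------
  retained <- stage("clump", greedy_prune(sumstats, hc, config$clump))
  counts$snps_retained <- length(retained)
  msg(sprintf("pipeline: %d SNPs retained after pruning", length(retained)))

  # -- PCs on the pruned, APOE-excluded set (avoids LD/APOE-driven axes) ---
  pcs <- stage("pca", {
    pc_set <- setdiff(retained, exclude_region(hc$snp_meta, config$region))
    gi <- match(pc_set, hc$snp_meta$snp_id)
    compute_pcs(hard_calls(hc$dosage[, gi, drop = FALSE],
                           hc$snp_meta[gi, , drop = FALSE], hc$sample_ids),
                config$n_pcs)
  })

  # -- score + evaluate grid ----------------------------------------------
  auc_grid <- stage("evaluate", {
    rows <- list()
    for (pt in config$p_thresholds) {
      for (reg in c("included", "excluded")) {
        spec <- score_spec(pt, if (reg == "excluded") config$region else NULL)
        prs <- tryCatch(compute_prs(hc, sumstats, retained, spec, pcs = pcs),
                        error = function(e) NULL)
        if (is.null(prs)) {   # empty SNP set at this threshold: NA cells
          msg(sprintf("evaluate: no SNPs at p <= %g (%s); grid cells set NA", pt, reg))
          for (st in config$strata) {
            sub <- subset_stratum(samples, st)
            rows[[length(rows) + 1L]] <- data.frame(
              stratum = st, p_threshold = pt, region = reg, auc = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              n_cases = sum(sub$status == "case"),
              n_controls = sum(sub$status == "control"), n_snps = 0L,
              stringsAsFactors = FALSE)
          }
          next
        }
        prs$status <- samples$status[match(prs$sample_id, samples$sample_id)]
        prs$apoe <- samples$apoe[match(prs$sample_id, samples$sample_id)]
        for (st in config$strata) {
          sub <- subset_stratum(samples, st)
          p <- prs[prs$sample_id %in% sub$sample_id, , drop = FALSE]
          r <- delong_ci(p$adjusted_z[p$status == "case"],
                         p$adjusted_z[p$status == "control"])
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = st, p_threshold = pt, region = reg, auc = r$auc,
            ci_low = r$ci_low, ci_high = r$ci_high, n_cases = r$n_cases,
            n_controls = r$n_controls,
            n_snps = length(attr(prs, "snp_ids")),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  # -- tails in the adjustment stratum (per-stratum restandardized) --------
  tails <- stage("tails", {
    spec <- score_spec(max(config$p_thresholds))
    prs <- compute_prs(hc, sumstats, retained, spec, pcs = pcs)
    prs$status <- samples$status[match(prs$sample_id, samples$sample_id)]
    sub <- subset_stratum(samples, config$adjust_stratum)
    p <- prs[prs$sample_id %in% sub$sample_id, , drop = FALSE]
    p$adjusted_z <- as.numeric(scale(p$adjusted_z))
    tail_counts(p, config$tail_thresholds)
  })

  # -- allele burden -------------------------------------------------------
  burden <- stage("burden", burden_table(hc, sumstats, samples, retained,
                                         config$burden_thresholds,
                                         config$region))

  # -- overlap adjustment --------------------------------------------------
  adjusted <- stage("adjust", {
    sub <- subset_stratum(samples, config$adjust_stratum)
    adjusted_auc(hc, sumstats, sub, retained,
                 overlap_spec(config$n_sims, config$noise_coefficient,
                              seed = config$seed + 7L),
                 score_spec(max(config$p_thresholds)))
  })

  report <- structure(list(auc_grid = auc_grid, burden = burden,
                           tails = tails, adjusted = adjusted,
                           counts = counts,
                           config_digest = config_digest(config)),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# stable fingerprint of the analytic config (output location excluded),
# without external digest packages
#' @noRd
config_digest <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg, control = "all"), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 2147483647
}

#' @noRd
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(df, f) data.table::fwrite(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, na = "NA")
  grid <- report$auc_grid
  grid[c("auc", "ci_low", "ci_high")] <- lapply(grid[c("auc", "ci_low", "ci_high")], fmt_num)
  fw(grid, "auc_grid.tsv")
  fmt_burden <- function(df) {
    num <- setdiff(names(df), "threshold")
    df[num] <- lapply(df[num], fmt_num)
    df
  }
  fw(fmt_burden(report$burden$cases), "burden_cases.tsv")
  fw(fmt_burden(report$burden$controls), "burden_controls.tsv")
  fw(report$tails, "tail_counts.tsv")
  adj <- report$adjusted
  jsonlite::write_json(
    list(auc_unadjusted = adj$auc_unadjusted, auc_adjusted = adj$auc_adjusted,
         ci_low = adj$ci_low, ci_high = adj$ci_high, n_sims = adj$n_sims,
         noise_coefficient = adj$noise_coefficient),
    file.path(out_dir, "adjusted_auc.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(counts = report$counts, config_digest = report$config_digest),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  %d samples, %d SNPs in; %d after QC; %d retained after pruning\n",
              x$counts$samples_in, x$counts$snps_in, x$counts$snps_qc,
              x$counts$snps_retained))
  cat("  AUC grid:\n")
  print(x$auc_grid, row.names = FALSE)
  cat("  Overlap-adjusted: ")
  print(x$adjusted)
  invisible(x)
}
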