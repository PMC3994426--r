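#' Type-I error calibration of the paired genome scan
#'
#' Simulates null cohorts (no planted aberrations, only symmetric
#' tumor/normal discordance noise), runs [genome_scan()] on each, and reports
#' the empirical rejection fraction at each alpha pooled over seeds, with
#' binomial standard errors. Under the null the flip kernel keeps every SNP's
#' expected paired table symmetric, so rejection rates estimate the test's
#' actual size at these sparse discordant counts.
#'
#' @param n_snps SNPs per simulated null cohort (one chromosome).
#' @param n_patients Patients per cohort.
#' @param discordance_rate Null discordance rate.
#' @param alphas Significance levels to evaluate.
#' @param n_seeds Number of independent replicate cohorts.
#' @param base_seed Seed for replicate `i` is `base_seed + i - 1`.
#' @param maf_range Allele-frequency range of the simulated SNPs.
#' @return A list of class `calibration_report`: `scenario`, `rates` (tibble
#'   `alpha`, `n_tests`, `n_rejected`, `rate`, `se`), `seeds`.
#' @export
typeI_experiment <- function(n_snps = 10000, n_patients = 60,
                             discordance_rate = 0.05,
                             alphas = c(0.05, 0.01), n_seeds = 10,
                             base_seed = 1L, maf_range = c(0.05, 0.5)) {
  stopifnot(n_snps >= 1, n_patients >= 1, n_seeds >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_seeds) - 1L
  pvals <- vector("list", n_seeds)
  for (i in seq_along(seeds)) {
    cfg <- simulation_config(
      n_patients = n_patients, n_snps_per_chrom = n_snps,
      maf_range = maf_range, missing_rate = 0,
      discordance_rate = discordance_rate, seed = seeds[i])
    cohort <- simulate_cohort(cfg)
    pvals[[i]] <- genome_scan(cohort)$p_value
  }
  p <- unlist(pvals)
  rates <- tibble(
    alpha = alphas,
    n_tests = length(p),
    n_rejected = vapply(alphas, function(a) sum(p < a), numeric(1)),
  ) %>%
    mutate(rate = .data$n_rejected / .data$n_tests,
           se = sqrt(.data$rate * (1 - .data$rate) / .data$n_tests))
  structure(list(scenario = "null_typeI", rates = rates, seeds = seeds,
                 n_snps = n_snps, n_patients = n_patients,
                 discordance_rate = discordance_rate),
            class = "calibration_report")
}

#' Planted-truth recovery experiment
#'
#' Runs the full pipeline on independently seeded cohorts drawn from a
#' planted scenario (by default [default_scenario()]) and summarises how well
#' the planted truth is recovered: the gain-region boundary errors in SNP
#' indices, how often the unique triple-planted SNP is the top-ranked
#' candidate, and the flag rate of LOH-segment SNPs.
#'
#' @param scenario_fn A function `seed -> simulation_config` describing the
#'   scenario; default [default_scenario()].
#' @param n_seeds Number of replicate cohorts.
#' @param base_seed Seed for replicate `i` is `base_seed + i - 1`.
#' @param ... Passed to [run_pipeline()].
#' @return A list of class `calibration_report`: `per_seed` (tibble with one
#'   row per seed: boundary errors, `triple_top`, `n_candidates`),
#'   `top_rank_rate`, `seeds`.
#' @export
recovery_experiment <- function(scenario_fn = default_scenario, n_seeds = 50,
                                base_seed = 1L, ...) {
  seeds <- as.integer(base_seed) + seq_len(n_seeds) - 1L
  rows <- vector("list", n_seeds)
  for (i in seq_along(seeds)) {
    cfg <- scenario_fn(seed = seeds[i])
    cohort <- simulate_cohort(cfg)
    res <- run_pipeline(cohort, ...)
    truth <- cohort$truth

    start_err <- NA_integer_; end_err <- NA_integer_
    if (nrow(truth$cnv) > 0) {
      tc <- truth$cnv[1, ]
      hits <- res$regions[res$regions$chrom == tc$chrom &
                            res$regions$direction == tc$direction, ,
                          drop = FALSE]
      if (nrow(hits) > 0) {
        best <- which.min(abs(hits$start_idx - tc$start_idx) +
                            abs(hits$end_idx - tc$end_idx))
        start_err <- hits$start_idx[best] - tc$start_idx
        end_err <- hits$end_idx[best] - tc$end_idx
      }
    }

    triple_id <- triple_planted_snp(truth)
    triple_top <- !is.na(triple_id) && nrow(res$candidates) > 0 &&
      res$candidates$snp_id[1] == triple_id

    loh_flag_rate <- NA_real_
    if (nrow(truth$loh) > 0) {
      tl <- truth$loh[1, ]
      seg_rows <- which(cohort$annot$chrom == tl$chrom)[tl$start_idx:tl$end_idx]
      seg_ids <- cohort$annot$snp_id[seg_rows]
      loh_flag_rate <- mean(res$loh$flagged[res$loh$snp_id %in% seg_ids])
    }

    rows[[i]] <- tibble(
      seed = seeds[i], region_found = !is.na(start_err),
      start_err = start_err, end_err = end_err,
      triple_top = triple_top, n_candidates = nrow(res$candidates),
      loh_segment_flag_rate = loh_flag_rate
    )
  }
  per_seed <- bind_rows(rows)
  structure(list(scenario = "planted_recovery", per_seed = per_seed,
                 top_rank_rate = mean(per_seed$triple_top),
                 region_recovery_rate = mean(
                   per_seed$region_found &
                     abs(per_seed$start_err) <= 2 & abs(per_seed$end_err) <= 2,
                   na.rm = TRUE),
                 seeds = seeds),
            class = "calibration_report")
}

# the SNP planted in all three arms, if the scenario has exactly one
triple_planted_snp <- function(truth) {
  if (nrow(truth$assoc) == 0 || nrow(truth$cnv) == 0 || nrow(truth$loh) == 0) {
    return(NA_character_)
  }
  in_cnv <- rep(FALSE, nrow(truth$assoc))
  in_loh <- rep(FALSE, nrow(truth$assoc))
  for (i in seq_len(nrow(truth$assoc))) {
    a <- truth$assoc[i, ]
    in_cnv[i] <- any(truth$cnv$chrom == a$chrom &
                       truth$cnv$start_idx <= a$snp_idx &
                       truth$cnv$end_idx >= a$snp_idx)
    in_loh[i] <- any(truth$loh$chrom == a$chrom &
                       truth$loh$start_idx <= a$snp_idx &
                       truth$loh$end_idx >= a$snp_idx)
  }
  hit <- which(in_cnv & in_loh)
  if (length(hit) == 1) truth$assoc$snp_id[hit] else NA_character_
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report: %s> (%d seed(s): %s%s)\n", x$scenario,
              length(x$seeds), paste(head(x$seeds, 5), collapse = ", "),
              if (length(x$seeds) > 5) ", ..." else ""))
  if (!is.null(x$rates)) print(x$rates)
  if (!is.null(x$per_seed)) {
    cat(sprintf("  triple-planted SNP top-ranked in %.0f%% of seeds\n",
                100 * x$top_rank_rate))
    cat(sprintf("  planted region recovered within +/-2 SNPs in %.0f%% of seeds\n",
                100 * x$region_recovery_rate))
  }
  invisible(x)
}

#' @rdname typeI_experiment
#' @param x A `calibration_report`.
#' @param ... Unused.
#' @export
tidy.calibration_report <- function(x, ...) {
  if (!is.null(x$rates)) x$rates else x$per_seed
}
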