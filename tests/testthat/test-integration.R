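mk_regions <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(tibble::tibble(chrom = character(), start_pos = integer(),
                          end_pos = integer(), direction = character(),
                          max_support = integer()))
  }
  dplyr::bind_rows(rows)
}

mk_assoc <- function(snp_id, chrom, pos, p, alpha = 0.01) {
  tibble::tibble(snp_id = snp_id, chrom = chrom, pos = pos, p_value = p,
                 significant = p < alpha)
}

mk_loh <- function(snp_id, n_loh, flagged) {
  tibble::tibble(snp_id = snp_id, n_loh = n_loh, flagged = flagged)
}

test_that("empty arms intersect to an empty candidate list", {
  res <- intersect_arms(mk_regions(),
                        mk_assoc(character(), character(), integer(),
                                 numeric()),
                        mk_loh(character(), integer(), logical()))
  expect_equal(nrow(res), 0)
})

test_that("candidates require all three arms; any single miss excludes", {
  regions <- mk_regions(tibble::tibble(chrom = "1", start_pos = 100L,
                                       end_pos = 500L, direction = "gain",
                                       max_support = 20L))
  assoc <- mk_assoc(c("in_all", "no_cnv", "no_loh", "no_assoc"),
                    chrom = c("1", "2", "1", "1"),
                    pos = c(200L, 200L, 300L, 400L),
                    p = c(0.001, 0.002, 0.003, 0.5))
  loh <- mk_loh(c("in_all", "no_cnv", "no_loh", "no_assoc"),
                n_loh = c(12L, 13L, 2L, 15L),
                flagged = c(TRUE, TRUE, FALSE, TRUE))
  cand <- intersect_arms(regions, assoc, loh)
  expect_equal(cand$snp_id, "in_all")
  full <- intersect_arms(regions, assoc, loh, candidates_only = FALSE)
  expect_equal(nrow(full), 4)
  expect_equal(sum(full$candidate), 1)
  # a SNP with association and LOH but outside all regions is excluded
  expect_false(full$candidate[full$snp_id == "no_cnv"])
  # region membership is by inclusive bp bounds
  edge <- intersect_arms(regions,
                         mk_assoc("edge", "1", 500L, 0.001),
                         mk_loh("edge", 11L, TRUE))
  expect_equal(edge$snp_id, "edge")
})

test_that("mismatched arm annotations are an error naming the SNPs", {
  regions <- mk_regions()
  assoc <- mk_assoc("only_here", "1", 10L, 0.5)
  loh <- mk_loh("other", 0L, FALSE)
  expect_error(intersect_arms(regions, assoc, loh), "only_here")
})

test_that("the triple-planted SNP is the unique candidate on a seeded cohort", {
  cohort <- simulate_cohort(default_scenario(seed = 7))
  res <- run_pipeline(cohort)
  expect_equal(nrow(res$candidates), 1)
  truth_assoc <- cohort$truth$assoc
  triple <- truth_assoc$snp_id[truth_assoc$chrom == "1"]
  expect_equal(res$candidates$snp_id, triple)
  expect_true(res$candidates$in_recurrent_cnv)
  expect_equal(res$candidates$cnv_direction, "gain")
  expect_true(res$candidates$loh_flagged)
})

test_that("pipeline summary is consistent with its per-arm results", {
  cohort <- simulate_cohort(default_scenario(seed = 9,
                                             n_snps_per_chrom = c(2500, 2500)))
  res <- run_pipeline(cohort)
  s <- res$summary
  expect_equal(s$n_snps_retained, length(res$qc$retained))
  expect_equal(s$n_recurrent_regions, nrow(res$regions))
  expect_equal(s$n_assoc_significant, sum(res$assoc$significant))
  expect_equal(s$n_loh_flagged, sum(res$loh$flagged))
  expect_equal(s$n_candidates, nrow(res$candidates))
  # candidate set is exactly the set-theoretic intersection of arm positives
  full <- intersect_arms(res$regions, res$assoc,
                         res$loh[res$loh$snp_id %in% res$assoc$snp_id, ],
                         candidates_only = FALSE)
  manual <- with(full, snp_id[in_recurrent_cnv & assoc_significant & loh_flagged])
  expect_setequal(res$candidates$snp_id, manual)
  # thresholds for a 60-patient cohort
  expect_equal(s$cnv_support_threshold, 19L)
  expect_equal(s$loh_support_threshold, 11L)
})

test_that("pipeline reports the study-size thresholds for 61 patients", {
  cfg <- simulation_config(n_patients = 61, n_snps_per_chrom = 150, seed = 31)
  res <- run_pipeline(simulate_cohort(cfg),
                      cnv = cnv_config(min_run_snps = 10))
  expect_equal(res$summary$cnv_support_threshold, 19L)  # n > 18
  expect_equal(res$summary$loh_support_threshold, 11L)  # >= 11
})

test_that("re-running the pipeline on the same cohort is byte-identical", {
  cohort <- simulate_cohort(simulation_config(
    n_patients = 20, n_snps_per_chrom = 300, discordance_rate = 0.05,
    seed = 13))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(cohort, out_dir = d1)
  r2 <- run_pipeline(cohort, out_dir = d2)
  expect_identical(r1$summary, r2$summary)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a patient with no aberrations never adds a candidate", {
  cohort <- simulate_cohort(default_scenario(seed = 11))
  before <- run_pipeline(cohort)$candidates$snp_id
  clean <- matrix(1L, nrow(cohort$normal), 1,
                  dimnames = list(NULL, "P999"))
  clean[] <- cohort$normal[, 1]  # same genotypes in both tissues: concordant
  bigger <- paired_cohort(cbind(cohort$normal, clean),
                          cbind(cohort$tumor, clean),
                          cbind(cohort$cn, matrix(2, nrow(cohort$cn), 1,
                                                  dimnames = list(NULL, "P999"))),
                          cohort$annot)
  after <- run_pipeline(bigger)$candidates$snp_id
  expect_true(all(after %in% before))
})

test_that("cohort summary reproduces the stage bookkeeping arithmetic", {
  clin <- simulate_clinical_table(n_patients = 61, n_early = 44, seed = 2)
  s <- cohort_summary(clin)
  early <- s[s$stage_group == "I + II", ]
  expect_equal(early$n, 44)
  expect_equal(early$percent, 72)  # 44/61 = 72.13% rounded
  late <- s[s$stage_group == "III + IV", ]
  expect_equal(late$n, 17)
  expect_equal(late$percent, 28)
  expect_equal(s[s$stage_group == "Overall", ]$n, 61)
})

test_that("cohort summary handles degenerate groups and stated conventions", {
  one_group <- tibble::tibble(stage = c("I", "II", "I"), age = c(50, 60, 70))
  s <- cohort_summary(one_group)
  expect_equal(s$percent[s$stage_group == "I + II"], 100)
  expect_equal(s$age_mean[s$stage_group == "I + II"], 60)
  expect_equal(s$age_sd[s$stage_group == "I + II"], 10)  # n-1 denominator
  expect_error(cohort_summary(tibble::tibble(stage = "V", age = 60)),
               "unknown stage")
})
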