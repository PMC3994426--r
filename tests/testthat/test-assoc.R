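test_that("paired tables count complete pairs and drop missing ones", {
  diag_tab <- build_paired_table(c(0, 1, 2), c(0, 1, 2))
  expect_equal(diag(unclass(diag_tab)), c(`0` = 1L, `1` = 1L, `2` = 1L),
               ignore_attr = TRUE)
  expect_equal(sum(diag_tab), 3)

  tab <- build_paired_table(c(1, 1, NA), c(0, 2, 0))
  expect_equal(tab["1", "0"], 1L)
  expect_equal(tab["1", "2"], 1L)
  expect_equal(attr(tab, "n_missing_pairs"), 1L)

  expect_error(build_paired_table(c(0, 1), c(0, 1, 2)), "aligned")
  expect_error(build_paired_table(c(0, 3), c(0, 1)), "\\{0, 1, 2, NA\\}")
})

test_that("paired table totals equal complete-pair counts on random vectors", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    nm <- sample(c(0:2, NA), n, replace = TRUE)
    tm <- sample(c(0:2, NA), n, replace = TRUE)
    tab <- build_paired_table(nm, tm)
    n_complete <- sum(!is.na(nm) & !is.na(tm))
    expect_equal(sum(tab), n_complete)
    expect_equal(attr(tab, "n_missing_pairs"), n - n_complete)
    # recount one random cell directly
    i0 <- sample(0:2, 1); j0 <- sample(0:2, 1)
    expect_equal(tab[as.character(i0), as.character(j0)],
                 sum(nm == i0 & tm == j0, na.rm = TRUE), ignore_attr = TRUE)
  }
})

test_that("Bowker statistic matches hand-computed examples", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 6; m[2, 1] <- 2
  res <- mcnemar_bowker(m)
  expect_equal(res$statistic, (6 - 2)^2 / 8)
  expect_equal(res$df, 1L)
  expect_equal(res$p_value, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(res$p_value, 0.15730, tolerance = 1e-4)

  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- 10; m2[2, 1] <- 2
  m2[1, 3] <- 4;  m2[3, 1] <- 0
  m2[2, 3] <- 3;  m2[3, 2] <- 7
  res2 <- mcnemar_bowker(m2)
  expect_equal(res2$statistic, 64 / 12 + 16 / 4 + 16 / 10, tolerance = 1e-10)
  expect_equal(res2$df, 3L)
  expect_equal(res2$p_value,
               pchisq(64 / 12 + 16 / 4 + 16 / 10, 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res2$p_value, 0.0121, tolerance = 1e-2)
})

test_that("symmetric tables give zero statistic and p = 1", {
  m <- matrix(c(5, 3, 2, 3, 8, 4, 2, 4, 6), 3, 3)
  res <- mcnemar_bowker(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 3L)
  expect_equal(res$p_value, 1)
  # no discordant pairs at all: df 0 by reduction
  res0 <- mcnemar_bowker(diag(c(4, 5, 6)))
  expect_equal(res0$df, 0L)
  expect_equal(res0$p_value, 1)
})

test_that("Bowker statistic is invariant under transposition", {
  set.seed(40)
  for (i in 1:25) {
    m <- matrix(rpois(9, 4), 3, 3)
    a <- mcnemar_bowker(m)
    b <- mcnemar_bowker(t(m))
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$df, b$df)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("Bowker agrees with the stats::mcnemar.test oracle on populated tables", {
  set.seed(41)
  for (i in 1:25) {
    m <- matrix(rpois(9, 6) + 1, 3, 3)  # all off-diagonal pairs populated
    got <- mcnemar_bowker(m)
    want <- stats::mcnemar.test(m, correct = FALSE)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$df, unname(want$parameter), ignore_attr = TRUE)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-12)
  }
})

test_that("a pair's contribution never grows when both cells rise together", {
  for (d in c(1, 4, 9)) {
    contribs <- vapply(0:10, function(cc) {
      a <- d + cc; b <- cc
      (a - b)^2 / (a + b)
    }, numeric(1))
    expect_true(all(diff(contribs) <= 0))
  }
})

test_that("a concordant cohort scans to all-ones p-values", {
  cfg <- simulation_config(n_patients = 20, n_snps_per_chrom = 200,
                           missing_rate = 0, discordance_rate = 0, seed = 14)
  cohort <- simulate_cohort(cfg)
  scan <- genome_scan(cohort)
  expect_true(all(scan$p_value == 1))
  expect_equal(sum(scan$significant), 0)
  expect_equal(glance(scan)$n_significant, 0)
})

test_that("scanning unknown SNP ids is an error listing them", {
  cfg <- simulation_config(n_patients = 10, n_snps_per_chrom = 50, seed = 15)
  cohort <- simulate_cohort(cfg)
  expect_error(genome_scan(cohort, snp_ids = c("nope_1", "nope_2")),
               "nope_1")
})

test_that("the scan equals per-SNP Bowker tests", {
  cfg <- simulation_config(n_patients = 30, n_snps_per_chrom = 120,
                           discordance_rate = 0.2, missing_rate = 0.05,
                           seed = 16)
  cohort <- simulate_cohort(cfg)
  scan <- genome_scan(cohort)
  idx <- c(1, 17, 60, 120)
  for (i in idx) {
    tab <- build_paired_table(cohort$normal[i, ], cohort$tumor[i, ])
    res <- mcnemar_bowker(tab)
    expect_equal(scan$statistic[i], res$statistic)
    expect_equal(scan$df[i], res$df)
    expect_equal(scan$p_value[i], res$p_value)
    expect_equal(scan$n_pairs[i], sum(tab))
  }
})

test_that("null rejection never exceeds the nominal rate and nests across alphas", {
  cfg <- simulation_config(n_patients = 60, n_snps_per_chrom = 10000,
                           missing_rate = 0, discordance_rate = 0.05,
                           seed = 17)
  scan <- genome_scan(simulate_cohort(cfg))
  for (alpha in c(0.05, 0.01)) {
    frac <- mean(scan$p_value < alpha)
    se <- sqrt(alpha * (1 - alpha) / nrow(scan))
    expect_lt(frac, alpha + 3 * se)
  }
  expect_gte(mean(scan$p_value < 0.05), mean(scan$p_value < 0.01))
})

test_that("planted shifted SNPs rank among the smallest p-values", {
  hits <- 0L
  n_seeds <- 15
  for (i in seq_len(n_seeds)) {
    cfg <- simulation_config(
      n_patients = 60, n_snps_per_chrom = 10000, maf_range = c(0.3, 0.5),
      missing_rate = 0.01, discordance_rate = 0.02,
      planted_assoc = lapply(c(500, 2500, 5000, 7500, 9500),
                             function(j) planted_assoc("1", j, 0.5)),
      seed = 400 + i)
    cohort <- simulate_cohort(cfg)
    scan <- genome_scan(cohort)
    top20 <- scan$snp_id[order(scan$p_value)][1:20]
    if (all(cohort$truth$assoc$snp_id %in% top20)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("optional multiplicity adjustment adds a column without changing p", {
  cfg <- simulation_config(n_patients = 20, n_snps_per_chrom = 100,
                           discordance_rate = 0.1, seed = 18)
  cohort <- simulate_cohort(cfg)
  plain <- genome_scan(cohort)
  adj <- genome_scan(cohort, adjust = "bonferroni")
  expect_equal(adj$p_value, plain$p_value)
  expect_equal(adj$p_adjusted, pmin(plain$p_value * nrow(plain), 1))
})
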