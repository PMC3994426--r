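test_that("recurrence threshold implements the strict and non-strict rules", {
  expect_identical(recurrence_threshold(61, 0.30, strict = TRUE), 19L)
  expect_identical(recurrence_threshold(61, 0.18, strict = FALSE), 11L)
  expect_identical(recurrence_threshold(10, 1.0, strict = FALSE), 10L)
  expect_identical(recurrence_threshold(10, 0.5, strict = TRUE), 6L)
  expect_identical(recurrence_threshold(10, 0.5, strict = FALSE), 5L)
  expect_error(recurrence_threshold(10, 0), "fraction")
  expect_error(recurrence_threshold(10, 1.2), "fraction")
})

test_that("call_runs finds maximal qualifying runs and honours the length floor", {
  flat <- tibble::tibble(chrom = "1", pos = seq_len(400) * 10, cn = 2.0)
  expect_equal(nrow(call_runs(flat)), 0)

  cn <- rep(2.0, 400); cn[101:250] <- 3.0
  one <- call_runs(tibble::tibble(chrom = "1", pos = seq_len(400) * 10, cn = cn))
  expect_equal(nrow(one), 1)
  expect_equal(one$start_idx, 101L)
  expect_equal(one$end_idx, 250L)
  expect_equal(one$length_snps, 150L)
  expect_equal(one$direction, "gain")
  expect_equal(one$start_pos, 1010)
  expect_equal(one$end_pos, 2500)

  cn99 <- rep(2.0, 400); cn99[101:199] <- 3.0  # one SNP short of the floor
  expect_equal(nrow(call_runs(
    tibble::tibble(chrom = "1", pos = seq_len(400) * 10, cn = cn99))), 0)

  expect_error(call_runs(tibble::tibble(chrom = "1", pos = c(10, 5), cn = c(2, 2))),
               "strictly increasing")
  expect_error(call_runs(tibble::tibble(chrom = character(), pos = integer(),
                                        cn = numeric())), "non-empty")
})

test_that("call_runs matches the scan-loop oracle on random tracks", {
  set.seed(33)
  cfg <- cnv_config(min_run_snps = 5)
  for (i in 1:40) {
    n <- sample(50:2000, 1)
    cn <- pmax(rnorm(n, 2, sample(c(0.3, 0.6, 1.0), 1)), 0)
    track <- tibble::tibble(chrom = "1", pos = cumsum(sample(1:50, n, TRUE)),
                            cn = cn)
    got <- call_runs(track, cfg)
    want <- runs_oracle(cn, cfg$gain_threshold, cfg$loss_threshold,
                        cfg$min_run_snps)
    want <- want[order(want$start_idx), , drop = FALSE]
    expect_equal(got$start_idx, want$start_idx)
    expect_equal(got$end_idx, want$end_idx)
    expect_equal(got$direction, want$direction)
  }
})

test_that("raising the run-length floor never adds runs", {
  set.seed(91)
  cn <- pmax(rnorm(1500, 2, 0.8), 0)
  track <- tibble::tibble(chrom = "1", pos = seq_len(1500), cn = cn)
  n_prev <- Inf
  for (floor_len in c(2, 5, 10, 25, 60)) {
    n_now <- nrow(call_runs(track, cnv_config(min_run_snps = floor_len)))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("recurrent regions are maximal intervals of sufficient patient support", {
  annot <- tibble::tibble(snp_id = sprintf("s%03d", 1:400), chrom = "1",
                          pos = seq_len(400) * 100)
  runs <- tibble::tibble(
    patient = c("P001", "P002", "P003"), chrom = "1",
    start_idx = c(1L, 51L, 101L), end_idx = c(200L, 250L, 300L),
    direction = "gain")
  regions <- call_recurrent_regions(runs, annot, n_patients = 5,
                                    cnv_config(recurrence_fraction = 0.6,
                                               recurrence_strict = FALSE))
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start_idx, 101L)
  expect_equal(regions$end_idx, 200L)
  expect_equal(regions$max_support, 3L)
  expect_setequal(regions$supporting_patients[[1]], c("P001", "P002", "P003"))

  expect_equal(nrow(call_recurrent_regions(runs[0, ], annot, 5)), 0)
})

test_that("a run shared by every patient yields a region with those exact bounds", {
  annot <- tibble::tibble(snp_id = sprintf("s%03d", 1:300), chrom = "1",
                          pos = seq_len(300) * 50)
  runs <- tibble::tibble(patient = sprintf("P%03d", 1:8), chrom = "1",
                         start_idx = 40L, end_idx = 180L, direction = "loss")
  regions <- call_recurrent_regions(runs, annot, n_patients = 8, cnv_config())
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start_idx, 40L)
  expect_equal(regions$end_idx, 180L)
  expect_equal(regions$max_support, 8L)
  expect_equal(regions$direction, "loss")
})

test_that("region calling matches the brute-force counting oracle", {
  set.seed(57)
  annot <- tibble::tibble(snp_id = sprintf("s%04d", 1:250), chrom = "1",
                          pos = seq_len(250) * 10)
  for (i in 1:15) {
    runs <- random_runs(n_patients = 8, n_snp = 250, n_runs = 25)
    for (frac in c(0.25, 0.5)) {
      cfg <- cnv_config(recurrence_fraction = frac, recurrence_strict = FALSE)
      thr <- recurrence_threshold(8, frac, strict = FALSE)
      got <- call_recurrent_regions(runs, annot, 8, cfg)
      for (direction in c("gain", "loss")) {
        want <- regions_oracle(runs, 250, thr, direction)
        g <- got[got$direction == direction, , drop = FALSE]
        expect_equal(g$start_idx, want$start_idx)
        expect_equal(g$end_idx, want$end_idx)
      }
    }
  }
})

test_that("raising the recurrence fraction never widens a region", {
  set.seed(58)
  annot <- tibble::tibble(snp_id = sprintf("s%04d", 1:300), chrom = "1",
                          pos = seq_len(300) * 10)
  runs <- random_runs(n_patients = 10, n_snp = 300, n_runs = 60)
  loose <- call_recurrent_regions(runs, annot, 10,
                                  cnv_config(recurrence_fraction = 0.2,
                                             recurrence_strict = FALSE))
  tight <- call_recurrent_regions(runs, annot, 10,
                                  cnv_config(recurrence_fraction = 0.4,
                                             recurrence_strict = FALSE))
  for (i in seq_len(nrow(tight))) {
    containing <- loose$direction == tight$direction[i] &
      loose$start_idx <= tight$start_idx[i] & loose$end_idx >= tight$end_idx[i]
    expect_true(any(containing))
  }
})

test_that("delta-delta-Ct copy number is exact at the identity and doubling points", {
  expect_identical(copy_number_from_ddct(24, 23, 24, 23), 2)
  expect_equal(copy_number_from_ddct(22.585, 23, 23.585, 23), 4)
  expect_equal(copy_number_from_ddct(24.0, 23.0, 23.585, 23.0), 1.5,
               tolerance = 1e-3)
  expect_error(copy_number_from_ddct(Inf, 23, 23, 23), "finite")
})

test_that("delta-delta-Ct copy number decreases strictly in ddct", {
  ddct <- seq(-3, 3, by = 0.25)
  est <- vapply(ddct, function(d) copy_number_from_ddct(23 + d, 23, 23, 23),
                numeric(1))
  expect_true(all(diff(est) < 0))
  expect_identical(est[ddct == 0], 2)
})
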