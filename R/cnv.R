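#' Copy-number calling configuration
#'
#' Thresholds for per-patient copy-number run detection and cohort-level
#' recurrence. A SNP is a variant locus when its normal-referenced tumor
#' copy-number estimate lies beyond 2 +/- 0.5 (above `gain_threshold` for
#' gains, below `loss_threshold` for losses); a run is at least
#' `min_run_snps` consecutive variant loci of one direction, with no gap
#' tolerance; and a region is recurrent when enough patients' runs cover each
#' of its SNPs. With `recurrence_strict = TRUE` the requirement is strictly
#' more than `floor(fraction * N)` patients (for 61 patients at 30%, more than
#' 18, i.e. at least 19); with `FALSE` it is at least
#' `ceiling(fraction * N)`.
#'
#' @param gain_threshold Copy number above which a SNP counts as gained.
#' @param loss_threshold Copy number below which a SNP counts as lost.
#' @param min_run_snps Minimum number of consecutive qualifying SNPs in a run.
#' @param recurrence_fraction Fraction of the cohort required to share a
#'   region.
#' @param recurrence_strict Use the strict (`>`) patient-count convention.
#' @return A `cnv_config` list.
#' @export
cnv_config <- function(gain_threshold = 2.5, loss_threshold = 1.5,
                       min_run_snps = 100L, recurrence_fraction = 0.30,
                       recurrence_strict = TRUE) {
  if (!(loss_threshold < 2 && 2 < gain_threshold)) {
    abort("need loss_threshold < 2 < gain_threshold")
  }
  if (min_run_snps < 1) abort("min_run_snps must be >= 1")
  structure(
    list(gain_threshold = gain_threshold, loss_threshold = loss_threshold,
         min_run_snps = as.integer(min_run_snps),
         recurrence_fraction = recurrence_fraction,
         recurrence_strict = recurrence_strict),
    class = "cnv_config"
  )
}

#' Minimum patient count for a recurrent aberration
#'
#' Converts a cohort fraction into the minimum number of patients required to
#' call an aberration recurrent. The strict convention requires strictly more
#' than `floor(fraction * n_patients)` patients; the non-strict convention
#' requires at least `ceiling(fraction * n_patients)`. For a 61-patient cohort
#' these give 19 at a strict 30% (so a count of 18 is excluded) and 11 at a
#' non-strict 18%.
#'
#' @param n_patients Cohort size.
#' @param fraction Required fraction, in `(0, 1]`.
#' @param strict Logical; use the strict (`>`) convention.
#' @return Integer minimum patient count.
#' @examples
#' recurrence_threshold(61, 0.30, strict = TRUE)   # 19
#' recurrence_threshold(61, 0.18, strict = FALSE)  # 11
#' @export
recurrence_threshold <- function(n_patients, fraction, strict = TRUE) {
  stopifnot(n_patients >= 1)
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  x <- fraction * n_patients
  if (abs(x - round(x)) < 1e-9) x <- round(x)   # guard float fuzz at exact products
  if (strict) as.integer(floor(x)) + 1L else as.integer(ceiling(x))
}

#' Detect copy-number runs in one patient's track
#'
#' Scans a single patient's copy-number estimates along one chromosome and
#' returns every maximal run of consecutive SNPs that all exceed the gain
#' threshold, or all fall below the loss threshold, keeping only runs of at
#' least `min_run_snps` SNPs. A single non-qualifying SNP breaks a run.
#'
#' @param track A data frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing) and `cn` (copy-number estimates, baseline 2), all on one
#'   chromosome.
#' @param config A [cnv_config()].
#' @param patient Optional patient id carried into the output.
#' @return A tibble of runs: `patient`, `chrom`, `start_idx`, `end_idx`
#'   (1-based SNP indices within the track, inclusive), `start_pos`,
#'   `end_pos`, `direction`, `length_snps`.
#' @export
call_runs <- function(track, config = cnv_config(), patient = NA_character_) {
  track <- as_tibble(track)
  if (!all(c("chrom", "pos", "cn") %in% names(track))) {
    abort("track must have columns chrom, pos, cn")
  }
  if (nrow(track) == 0) abort("track must be non-empty")
  if (length(unique(track$chrom)) != 1) {
    abort("a track spans a single chromosome")
  }
  if (is.unsorted(track$pos, strictly = TRUE)) {
    abort("track positions must be strictly increasing")
  }
  if (any(track$cn < 0, na.rm = TRUE)) abort("copy-number estimates must be >= 0")
  gain <- runs_from_indicator(track$cn > config$gain_threshold,
                              config$min_run_snps)
  loss <- runs_from_indicator(track$cn < config$loss_threshold,
                              config$min_run_snps)
  fmt <- function(runs, direction) {
    if (nrow(runs) == 0) return(empty_runs())
    tibble(patient = patient, chrom = track$chrom[1],
           start_idx = runs$start, end_idx = runs$end,
           start_pos = track$pos[runs$start], end_pos = track$pos[runs$end],
           direction = direction, length_snps = runs$end - runs$start + 1L)
  }
  out <- bind_rows(fmt(gain, "gain"), fmt(loss, "loss"))
  arrange(out, .data$start_idx)
}

# Maximal TRUE-runs of an indicator, kept when length >= min_len.
runs_from_indicator <- function(ind, min_len) {
  ind[is.na(ind)] <- FALSE
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

empty_runs <- function() {
  tibble(patient = character(), chrom = character(), start_idx = integer(),
         end_idx = integer(), start_pos = integer(), end_pos = integer(),
         direction = character(), length_snps = integer())
}

#' Detect copy-number runs for every patient of a cohort
#'
#' Applies [call_runs()] per patient and chromosome over a cohort's
#' copy-number matrix.
#'
#' @param cohort A [paired_cohort()] with a copy-number track.
#' @param config A [cnv_config()].
#' @return A tibble of runs as in [call_runs()]; `start_idx`/`end_idx` are
#'   1-based SNP indices within the chromosome.
#' @export
call_runs_cohort <- function(cohort, config = cnv_config()) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (is.null(cohort$cn)) abort("cohort has no copy-number matrix")
  out <- list()
  for (chrom in unique(cohort$annot$chrom)) {
    rows <- chrom_rows(cohort, chrom)
    pos <- cohort$annot$pos[rows]
    for (p in seq_along(cohort$patients)) {
      track <- tibble(chrom = chrom, pos = pos, cn = cohort$cn[rows, p])
      out[[length(out) + 1]] <- call_runs(track, config,
                                          patient = cohort$patients[p])
    }
  }
  if (length(out) == 0) return(empty_runs())
  bind_rows(out)
}

#' Call recurrent copy-number regions across a cohort
#'
#' For each SNP and direction, counts the distinct patients whose qualifying
#' runs cover it; a recurrent region is a maximal interval of consecutive SNPs
#' on one chromosome whose per-SNP patient count all reach the recurrence
#' threshold. Gains and losses are called independently.
#'
#' @param runs A tibble of per-patient runs ([call_runs_cohort()]).
#' @param annot SNP annotation tibble (`snp_id`, `chrom`, `pos`).
#' @param n_patients Cohort size (the recurrence denominator).
#' @param config A [cnv_config()].
#' @return A tibble of class `cnv_regions`: `chrom`, `start_idx`, `end_idx`
#'   (1-based SNP indices within the chromosome), `start_pos`, `end_pos`,
#'   `direction`, `n_snps`, `max_support` (peak patient count) and
#'   `supporting_patients` (list column of patients whose runs overlap the
#'   region).
#' @export
call_recurrent_regions <- function(runs, annot, n_patients,
                                   config = cnv_config()) {
  annot <- as_tibble(annot)
  thr <- recurrence_threshold(n_patients, config$recurrence_fraction,
                              config$recurrence_strict)
  out <- list()
  for (chrom in unique(annot$chrom)) {
    n_snp <- sum(annot$chrom == chrom)
    pos <- annot$pos[annot$chrom == chrom]
    chrom_runs <- runs[runs$chrom == chrom, , drop = FALSE]
    for (direction in c("gain", "loss")) {
      dr <- chrom_runs[chrom_runs$direction == direction, , drop = FALSE]
      support <- integer(n_snp)
      if (nrow(dr) > 0) {
        # one patient's same-direction runs are disjoint (maximality), so
        # adding 1 per run counts distinct patients per SNP
        for (i in seq_len(nrow(dr))) {
          span <- dr$start_idx[i]:dr$end_idx[i]
          support[span] <- support[span] + 1L
        }
      }
      blocks <- runs_from_indicator(support >= thr, 1L)
      if (nrow(blocks) == 0) next
      for (b in seq_len(nrow(blocks))) {
        s <- blocks$start[b]; e <- blocks$end[b]
        overlapping <- dr$start_idx <= e & dr$end_idx >= s
        out[[length(out) + 1]] <- tibble(
          chrom = chrom, start_idx = s, end_idx = e,
          start_pos = pos[s], end_pos = pos[e],
          direction = direction, n_snps = e - s + 1L,
          max_support = max(support[s:e]),
          supporting_patients = list(sort(unique(dr$patient[overlapping])))
        )
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(chrom = character(), start_idx = integer(), end_idx = integer(),
           start_pos = integer(), end_pos = integer(), direction = character(),
           n_snps = integer(), max_support = integer(),
           supporting_patients = list())
  res <- arrange(res, .data$chrom, .data$start_idx)
  attr(res, "support_threshold") <- thr
  class(res) <- c("cnv_regions", class(res))
  res
}

#' Copy number from paired qPCR threshold cycles
#'
#' Relative quantification by the delta-delta-Ct method against a two-copy
#' reference assay: `ddct = (ct_target_tumor - ct_ref_tumor) -
#' (ct_target_normal - ct_ref_normal)` and the tumor copy-number estimate is
#' `2 * 2^(-ddct)`. Equal target/reference differences in tumor and normal
#' (`ddct = 0`) give exactly 2 copies; each cycle of earlier target
#' amplification in the tumor doubles the estimate.
#'
#' @param ct_target_tumor,ct_ref_tumor Threshold cycles of the target and
#'   reference assays in the tumor sample.
#' @param ct_target_normal,ct_ref_normal Threshold cycles in the matched
#'   normal sample.
#' @return Copy-number estimate (vectorized).
#' @examples
#' copy_number_from_ddct(24, 23, 24, 23)      # 2
#' copy_number_from_ddct(22, 23, 23, 23)      # 4: one-cycle doubling
#' @export
copy_number_from_ddct <- function(ct_target_tumor, ct_ref_tumor,
                                  ct_target_normal, ct_ref_normal) {
  cts <- c(ct_target_tumor, ct_ref_tumor, ct_target_normal, ct_ref_normal)
  if (any(!is.finite(cts))) abort("all Ct values must be finite")
  ddct <- (ct_target_tumor - ct_ref_tumor) - (ct_target_normal - ct_ref_normal)
  2 * 2^(-ddct)
}
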