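#' Simulation configuration for a synthetic paired cohort
#'
#' Describes a paired tumor/normal cohort to generate: cohort size, marker
#' density per chromosome, the allele-frequency spectrum, noise levels, and any
#' planted aberrations (recurrent copy-number segments, tumor genotype shifts,
#' LOH segments). The defaults emulate a 61-patient paired SNP-array cohort
#' with post-QC allele frequencies and low rates of missing calls and
#' tumor/normal call discordance.
#'
#' @param n_patients Number of patients (paired arrays per patient).
#' @param n_snps_per_chrom Integer vector, number of SNPs on each simulated
#'   chromosome; chromosomes are labelled `"1"`, `"2"`, ...
#' @param maf_range Length-2 numeric in `(0, 0.5]`; each SNP's minor allele
#'   frequency is drawn uniformly from this interval.
#' @param missing_rate Per-call probability of a missing genotype, applied
#'   independently to normal and tumor calls.
#' @param cn_noise_sd Standard deviation (copy-number units) of Gaussian noise
#'   around the diploid baseline 2 and around planted segment means.
#' @param discordance_rate Per-call probability that a tumor genotype is
#'   perturbed away from its normal genotype under the null. Flips use a
#'   reversible kernel with respect to the SNP's Hardy-Weinberg genotype
#'   distribution so the expected paired 3x3 table stays symmetric.
#' @param planted_cnv List of [planted_cnv()] elements.
#' @param planted_assoc List of [planted_assoc()] elements.
#' @param planted_loh List of [planted_loh()] elements.
#' @param seed Integer seed; identical configurations yield identical cohorts.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 61,
                              n_snps_per_chrom = c(2500, 2500),
                              maf_range = c(0.05, 0.5),
                              missing_rate = 0.01,
                              cn_noise_sd = 0.2,
                              discordance_rate = 0.02,
                              planted_cnv = list(),
                              planted_assoc = list(),
                              planted_loh = list(),
                              seed = 1L) {
  stopifnot(n_patients >= 1, all(n_snps_per_chrom >= 1))
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("maf_range must be (lower, upper) with 0 < lower <= upper <= 0.5")
  }
  for (p in c(missing_rate, discordance_rate)) {
    if (p < 0 || p > 1) abort("rates must lie in [0, 1]")
  }
  if (cn_noise_sd <= 0) abort("cn_noise_sd must be positive")
  chroms <- as.character(seq_along(n_snps_per_chrom))
  cfg <- structure(
    list(n_patients = as.integer(n_patients),
         n_snps_per_chrom = setNames(as.integer(n_snps_per_chrom), chroms),
         maf_range = as.numeric(maf_range),
         missing_rate = missing_rate,
         cn_noise_sd = cn_noise_sd,
         discordance_rate = discordance_rate,
         planted_cnv = planted_cnv,
         planted_assoc = planted_assoc,
         planted_loh = planted_loh,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_planted(cfg)
  cfg
}

#' Planted aberrations for the synthetic generator
#'
#' `planted_cnv()` describes a recurrent copy-number segment carried by a fixed
#' fraction of patients; `planted_assoc()` a single SNP at which heterozygous
#' normal genotypes shift to a homozygote in the tumor (the asymmetry a paired
#' symmetry test detects); `planted_loh()` a segment in which carriers lose
#' heterozygosity in the tumor.
#'
#' SNP indices are 1-based positions within the chromosome's SNP order,
#' inclusive on both ends.
#'
#' @param chrom Chromosome label (a character scalar such as `"1"`).
#' @param start_idx,end_idx 1-based inclusive SNP indices within the chromosome.
#' @param carrier_fraction Fraction of patients carrying the aberration; the
#'   generator assigns exactly `round(carrier_fraction * n_patients)` carriers
#'   chosen as the first patients of a seeded permutation.
#' @param mean_cn Mean copy number inside the segment for carriers (baseline
#'   2); gains require `mean_cn > 2.5` and losses `mean_cn < 1.5` so planted
#'   segments clear the 2 +/- 0.5 calling thresholds.
#' @param direction `"gain"` or `"loss"`.
#' @param snp_idx For `planted_assoc()`: 1-based SNP index within `chrom`.
#' @param shift_prob Probability in `(0, 1]` that a heterozygous normal call
#'   becomes homozygous in the tumor at the association SNP.
#' @param conversion_prob Probability in `(0, 1]` that a carrier's heterozygous
#'   normal call becomes homozygous in the tumor inside the LOH segment.
#'
#' @return A list describing the planted element.
#' @name planted
NULL

#' @rdname planted
#' @export
planted_cnv <- function(chrom, start_idx, end_idx, carrier_fraction,
                        mean_cn, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(start_idx >= 1, end_idx >= start_idx,
            carrier_fraction >= 0, carrier_fraction <= 1)
  if (direction == "gain" && mean_cn <= 2.5) {
    abort("planted gains need mean_cn > 2.5 to be detectable at the 2 +/- 0.5 thresholds")
  }
  if (direction == "loss" && mean_cn >= 1.5) {
    abort("planted losses need mean_cn < 1.5 to be detectable at the 2 +/- 0.5 thresholds")
  }
  list(kind = "cnv", chrom = as.character(chrom),
       start_idx = as.integer(start_idx), end_idx = as.integer(end_idx),
       carrier_fraction = carrier_fraction, mean_cn = mean_cn,
       direction = direction)
}

#' @rdname planted
#' @export
planted_assoc <- function(chrom, snp_idx, shift_prob) {
  stopifnot(snp_idx >= 1, shift_prob > 0, shift_prob <= 1)
  list(kind = "assoc", chrom = as.character(chrom),
       snp_idx = as.integer(snp_idx), shift_prob = shift_prob)
}

#' @rdname planted
#' @export
planted_loh <- function(chrom, start_idx, end_idx, carrier_fraction,
                        conversion_prob) {
  stopifnot(start_idx >= 1, end_idx >= start_idx,
            carrier_fraction >= 0, carrier_fraction <= 1,
            conversion_prob > 0, conversion_prob <= 1)
  list(kind = "loh", chrom = as.character(chrom),
       start_idx = as.integer(start_idx), end_idx = as.integer(end_idx),
       carrier_fraction = carrier_fraction, conversion_prob = conversion_prob)
}

validate_planted <- function(cfg) {
  chroms <- names(cfg$n_snps_per_chrom)
  check_interval <- function(el, what) {
    if (!el$chrom %in% chroms) {
      abort(sprintf("%s element references unknown chromosome '%s'", what, el$chrom))
    }
    n <- cfg$n_snps_per_chrom[[el$chrom]]
    hi <- if (!is.null(el$end_idx)) el$end_idx else el$snp_idx
    if (hi > n) {
      abort(sprintf("%s element on chromosome %s exceeds its %d SNPs", what, el$chrom, n))
    }
  }
  for (el in cfg$planted_cnv) check_interval(el, "planted_cnv")
  for (el in cfg$planted_assoc) check_interval(el, "planted_assoc")
  for (el in cfg$planted_loh) check_interval(el, "planted_loh")
  # reject overlapping CNV intervals of opposite direction on the same chromosome
  cnv <- cfg$planted_cnv
  if (length(cnv) > 1) {
    for (i in seq_len(length(cnv) - 1)) {
      for (j in seq(i + 1, length(cnv))) {
        a <- cnv[[i]]; b <- cnv[[j]]
        if (a$chrom == b$chrom && a$direction != b$direction &&
            a$start_idx <= b$end_idx && b$start_idx <= a$end_idx) {
          abort(sprintf(
            "planted CNV intervals [%d,%d] (%s) and [%d,%d] (%s) overlap on chromosome %s with conflicting directions",
            a$start_idx, a$end_idx, a$direction,
            b$start_idx, b$end_idx, b$direction, a$chrom))
        }
      }
    }
  }
  invisible(cfg)
}

#' Generate a synthetic paired tumor/normal cohort
#'
#' Draws normal-tissue genotypes per SNP from Hardy-Weinberg proportions at a
#' minor allele frequency sampled uniformly from `maf_range`; tumor genotypes
#' copy the normal ones apart from (i) symmetric null discordance noise,
#' (ii) planted association shifts and (iii) planted LOH conversions, in that
#' order. The tumor copy-number matrix is Gaussian noise around the diploid
#' baseline 2, except inside planted segments for their carriers, where it is
#' Gaussian around the planted mean; estimates are truncated at 0. Carriers of
#' each planted element are exactly the first
#' `round(carrier_fraction * n_patients)` patients of a seeded permutation, so
#' carrier counts are exact and recoverable.
#'
#' The null discordance kernel proposes one of the two other genotypes
#' uniformly and accepts with probability `min(1, pi_proposed / pi_current)`
#' under the SNP's Hardy-Weinberg distribution `pi`. This makes the flip
#' process reversible, so at every null SNP the expected paired 3x3 genotype
#' table is symmetric — the property a paired symmetry test's null requires.
#'
#' The same configuration (including `seed`) always yields a bit-identical
#' cohort.
#'
#' @param config A [simulation_config()].
#' @return A [paired_cohort()] whose `truth` element records every planted
#'   aberration with its carriers and SNP ids.
#' @examples
#' cfg <- simulation_config(n_patients = 20, n_snps_per_chrom = 500, seed = 7)
#' cohort <- simulate_cohort(cfg)
#' cohort
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_pat <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n_pat))
  chroms <- names(config$n_snps_per_chrom)

  annot_list <- vector("list", length(chroms))
  maf_list <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    n_snp <- config$n_snps_per_chrom[[k]]
    gaps <- sample.int(2000L, n_snp, replace = TRUE)
    pos <- cumsum(gaps)
    maf <- runif(n_snp, config$maf_range[1], config$maf_range[2])
    alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * n_snp, replace = TRUE),
                      ncol = 2)
    annot_list[[k]] <- tibble(
      snp_id = sprintf("snp_%s_%05d", chroms[k], seq_len(n_snp)),
      chrom = chroms[k],
      pos = pos,
      allele_major = alleles[, 1],
      allele_minor = alleles[, 2]
    )
    maf_list[[k]] <- maf
  }
  annot <- bind_rows(annot_list)
  maf <- unlist(maf_list, use.names = FALSE)
  n_snp_total <- nrow(annot)

  # normal genotypes: HWE draws (minor-allele dosage)
  normal <- matrix(rbinom(n_snp_total * n_pat, 2L, rep(maf, n_pat)),
                   nrow = n_snp_total, ncol = n_pat)
  tumor <- normal

  # symmetric (reversible) discordance noise
  if (config$discordance_rate > 0) {
    p0 <- (1 - maf)^2; p1 <- 2 * maf * (1 - maf); p2 <- maf^2
    pi_mat <- cbind(p0, p1, p2)                       # per-SNP HWE distribution
    attempt <- matrix(runif(n_snp_total * n_pat) < config$discordance_rate,
                      nrow = n_snp_total)
    pick <- matrix(runif(n_snp_total * n_pat), nrow = n_snp_total)
    accept_u <- matrix(runif(n_snp_total * n_pat), nrow = n_snp_total)
    idx <- which(attempt)
    if (length(idx)) {
      cur <- tumor[idx]
      # the two alternatives to each genotype, chosen uniformly
      alt1 <- c(1L, 0L, 0L)[cur + 1L]
      alt2 <- c(2L, 2L, 1L)[cur + 1L]
      prop <- ifelse(pick[idx] < 0.5, alt1, alt2)
      snp_of <- ((idx - 1L) %% n_snp_total) + 1L
      pi_cur <- pi_mat[cbind(snp_of, cur + 1L)]
      pi_prop <- pi_mat[cbind(snp_of, prop + 1L)]
      ok <- accept_u[idx] < pmin(1, pi_prop / pi_cur)
      tumor[idx[ok]] <- prop[ok]
    }
  }

  row_offset <- c(0L, cumsum(config$n_snps_per_chrom))[seq_along(chroms)]
  names(row_offset) <- chroms
  global_row <- function(chrom, idx) row_offset[[chrom]] + idx

  truth_cnv <- list(); truth_assoc <- list(); truth_loh <- list()

  pick_carriers <- function(fraction) {
    k <- round(fraction * n_pat)
    perm <- sample.int(n_pat)
    sort(perm[seq_len(k)])
  }

  # planted association shifts: het normal -> homozygote tumor
  for (el in config$planted_assoc) {
    r <- global_row(el$chrom, el$snp_idx)
    het <- which(normal[r, ] == 1L)
    shift <- het[runif(length(het)) < el$shift_prob]
    dest <- ifelse(runif(length(shift)) < 0.5, 0L, 2L)
    tumor[r, shift] <- dest
    truth_assoc[[length(truth_assoc) + 1]] <- tibble(
      chrom = el$chrom, snp_idx = el$snp_idx, snp_id = annot$snp_id[r],
      shift_prob = el$shift_prob, n_shifted = length(shift)
    )
  }

  # planted LOH conversions for carriers inside each segment
  for (el in config$planted_loh) {
    carriers <- pick_carriers(el$carrier_fraction)
    rows <- global_row(el$chrom, el$start_idx):global_row(el$chrom, el$end_idx)
    sub_n <- normal[rows, carriers, drop = FALSE]
    het <- which(sub_n == 1L)
    conv <- het[runif(length(het)) < el$conversion_prob]
    if (length(conv)) {
      keep_major <- runif(length(conv)) < 0.5
      sub_t <- tumor[rows, carriers, drop = FALSE]
      sub_t[conv] <- ifelse(keep_major, 0L, 2L)
      tumor[rows, carriers] <- sub_t
    }
    truth_loh[[length(truth_loh) + 1]] <- tibble(
      chrom = el$chrom, start_idx = el$start_idx, end_idx = el$end_idx,
      carrier_fraction = el$carrier_fraction,
      conversion_prob = el$conversion_prob,
      carriers = list(patients[carriers])
    )
  }

  # copy-number matrix: diploid baseline + planted segments, truncated at 0
  cn <- matrix(rnorm(n_snp_total * n_pat, mean = 2, sd = config$cn_noise_sd),
               nrow = n_snp_total, ncol = n_pat)
  for (el in config$planted_cnv) {
    carriers <- pick_carriers(el$carrier_fraction)
    rows <- global_row(el$chrom, el$start_idx):global_row(el$chrom, el$end_idx)
    cn[rows, carriers] <- rnorm(length(rows) * length(carriers),
                                mean = el$mean_cn, sd = config$cn_noise_sd)
    truth_cnv[[length(truth_cnv) + 1]] <- tibble(
      chrom = el$chrom, start_idx = el$start_idx, end_idx = el$end_idx,
      start_pos = annot$pos[rows[1]], end_pos = annot$pos[rows[length(rows)]],
      carrier_fraction = el$carrier_fraction, mean_cn = el$mean_cn,
      direction = el$direction, carriers = list(patients[carriers])
    )
  }
  cn <- pmax(cn, 0)

  # missingness, independent per tissue
  if (config$missing_rate > 0) {
    normal[matrix(runif(n_snp_total * n_pat) < config$missing_rate,
                  nrow = n_snp_total)] <- NA_integer_
    tumor[matrix(runif(n_snp_total * n_pat) < config$missing_rate,
                 nrow = n_snp_total)] <- NA_integer_
  }

  truth <- list(
    cnv = if (length(truth_cnv)) bind_rows(truth_cnv) else empty_truth_cnv(),
    assoc = if (length(truth_assoc)) bind_rows(truth_assoc) else empty_truth_assoc(),
    loh = if (length(truth_loh)) bind_rows(truth_loh) else empty_truth_loh(),
    maf = maf,
    config = config
  )
  colnames(normal) <- patients
  colnames(tumor) <- patients
  colnames(cn) <- patients
  paired_cohort(normal, tumor, cn, annot, truth = truth)
}

empty_truth_cnv <- function() {
  tibble(chrom = character(), start_idx = integer(), end_idx = integer(),
         start_pos = integer(), end_pos = integer(),
         carrier_fraction = numeric(), mean_cn = numeric(),
         direction = character(), carriers = list())
}
empty_truth_assoc <- function() {
  tibble(chrom = character(), snp_idx = integer(), snp_id = character(),
         shift_prob = numeric(), n_shifted = integer())
}
empty_truth_loh <- function() {
  tibble(chrom = character(), start_idx = integer(), end_idx = integer(),
         carrier_fraction = numeric(), conversion_prob = numeric(),
         carriers = list())
}

#' Default planted-recovery scenario
#'
#' A 60-patient, two-chromosome cohort with one planted recurrent gain (150
#' SNPs, 40% carriers, mean copy number 3.4), one planted LOH segment (50
#' SNPs, 30% carriers, conversion probability 0.9) overlapping the gain at
#' exactly one SNP, and five planted association SNPs (shift probability 0.6)
#' of which exactly one is that overlap SNP. Loss of heterozygosity is itself
#' a tumor/normal genotype asymmetry, so any SNP carrying both a planted LOH
#' conversion and region membership would tend to trip all three arms; the
#' single-SNP overlap makes the triple-planted SNP the unique locus with more
#' than one aberration, and hence the locus the full pipeline should recover
#' as its top candidate. Aberrations are planted on common SNPs
#' (`maf_range = c(0.3, 0.5)`), where a 60-pair design has power.
#'
#' @param seed Integer seed.
#' @param n_snps_per_chrom SNPs per chromosome (two chromosomes).
#' @return A [simulation_config()].
#' @export
default_scenario <- function(seed = 1L, n_snps_per_chrom = c(2500, 2500)) {
  simulation_config(
    n_patients = 60,
    n_snps_per_chrom = n_snps_per_chrom,
    maf_range = c(0.3, 0.5),
    missing_rate = 0.01,
    cn_noise_sd = 0.2,
    discordance_rate = 0.02,
    planted_cnv = list(planted_cnv("1", 1001, 1150, carrier_fraction = 0.4,
                                   mean_cn = 3.4, direction = "gain")),
    planted_loh = list(planted_loh("1", 1150, 1199, carrier_fraction = 0.3,
                                   conversion_prob = 0.9)),
    planted_assoc = list(
      planted_assoc("1", 1150, shift_prob = 0.6),
      planted_assoc("2", 300, shift_prob = 0.6),
      planted_assoc("2", 800, shift_prob = 0.6),
      planted_assoc("2", 1500, shift_prob = 0.6),
      planted_assoc("2", 2200, shift_prob = 0.6)
    ),
    seed = seed
  )
}

#' Synthetic clinical characteristics table
#'
#' Builds a per-patient clinical table (patient id, tumor stage, age at
#' surgery) with a fixed number of early-stage (I/II) patients, for exercising
#' cohort bookkeeping summaries.
#'
#' @param n_patients Cohort size.
#' @param n_early Number of stage I/II patients; the rest are stage III/IV.
#' @param age_mean,age_sd Normal distribution of ages (years).
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id`, `stage`, `age`.
#' @export
simulate_clinical_table <- function(n_patients = 61, n_early = 44,
                                    age_mean = 59.4, age_sd = 11, seed = 1L) {
  stopifnot(n_early >= 0, n_early <= n_patients)
  set.seed(seed)
  stage <- c(sample(c("I", "II"), n_early, replace = TRUE),
             sample(c("III", "IV"), n_patients - n_early, replace = TRUE))
  tibble(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    stage = stage,
    age = round(rnorm(n_patients, age_mean, age_sd), 1)
  )
}
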