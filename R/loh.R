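#' Loss-of-heterozygosity call for one genotype pair
#'
#' LOH is a locus heterozygous in the normal tissue and homozygous (either
#' homozygote) in the matched tumor tissue. Complete pairs that do not meet
#' the definition are `FALSE` — including homozygote-to-homozygote switches
#' (0 to 2 or 2 to 0), which are genotype discordances but not loss of
#' heterozygosity. Pairs with a missing call are undefined (`NA`).
#'
#' @param normal_gt,tumor_gt Genotype calls in `{0, 1, 2, NA}` (vectorized).
#' @return Logical vector: `TRUE` for LOH, `FALSE` otherwise, `NA` where
#'   either call is missing.
#' @examples
#' is_loh(1, 0)  # TRUE
#' is_loh(0, 2)  # FALSE: no heterozygosity to lose
#' @export
is_loh <- function(normal_gt, tumor_gt) {
  ok <- function(x) all(is.na(x) | x %in% c(0, 1, 2))
  if (!ok(normal_gt) || !ok(tumor_gt)) {
    abort("genotypes must lie in {0, 1, 2, NA}")
  }
  ifelse(is.na(normal_gt) | is.na(tumor_gt), NA,
         normal_gt == 1 & tumor_gt != 1)
}

#' Per-SNP LOH matrix of a cohort
#'
#' @param cohort A [paired_cohort()].
#' @return Logical SNP x patient matrix: `TRUE` where LOH is observed, `NA`
#'   where either tissue's call is missing.
#' @export
loh_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  m <- cohort$normal == 1L & cohort$tumor != 1L
  m[is.na(cohort$normal) | is.na(cohort$tumor)] <- NA
  m
}

#' Flag SNPs with recurrent loss of heterozygosity
#'
#' Counts, per SNP, the patients with LOH (`n_loh`) and the informative
#' patients (heterozygous normal call with both calls present,
#' `n_informative`), and flags SNPs where `n_loh` reaches the non-strict
#' recurrence threshold — at least `ceiling(fraction * N)` patients. By
#' default the denominator `N` is the full cohort (18% of 61 patients gives a
#' threshold of 11); `denominator = "informative"` instead thresholds against
#' each SNP's informative count. Homozygote-to-homozygote switches are tallied
#' separately as `n_discordant_hom` for diagnostics and never counted as LOH.
#'
#' @param cohort A [paired_cohort()].
#' @param fraction Required recurrence fraction (default 0.18).
#' @param denominator `"cohort"` (full cohort size, default) or
#'   `"informative"` (per-SNP informative patient count).
#' @return A tibble of class `loh_summary`: `snp_id`, `chrom`, `pos`,
#'   `n_loh`, `n_informative`, `n_discordant_hom`, `threshold`, `flagged`.
#'   The per-chromosome flagged counts are available via
#'   [loh_by_chromosome()].
#' @export
flag_recurrent_loh <- function(cohort, fraction = 0.18,
                               denominator = c("cohort", "informative")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  denominator <- match.arg(denominator)
  loh <- loh_matrix(cohort)
  n_loh <- rowSums(loh, na.rm = TRUE)
  informative <- cohort$normal == 1L & !is.na(cohort$tumor)
  n_informative <- rowSums(informative, na.rm = TRUE)
  disc_hom <- (cohort$normal == 0L & cohort$tumor == 2L) |
    (cohort$normal == 2L & cohort$tumor == 0L)
  n_disc_hom <- rowSums(disc_hom, na.rm = TRUE)
  if (denominator == "cohort") {
    thr <- rep(recurrence_threshold(n_patients(cohort), fraction,
                                    strict = FALSE), nrow(loh))
  } else {
    thr <- vapply(n_informative, function(n) {
      if (n == 0) NA_integer_
      else recurrence_threshold(n, fraction, strict = FALSE)
    }, integer(1))
  }
  res <- tibble(
    snp_id = cohort$annot$snp_id,
    chrom = cohort$annot$chrom,
    pos = cohort$annot$pos,
    n_loh = as.integer(n_loh),
    n_informative = as.integer(n_informative),
    n_discordant_hom = as.integer(n_disc_hom),
    threshold = as.integer(thr),
    flagged = !is.na(thr) & n_loh >= thr
  )
  attr(res, "fraction") <- fraction
  attr(res, "denominator") <- denominator
  class(res) <- c("loh_summary", class(res))
  res
}

#' Flagged-LOH counts per chromosome
#'
#' @param loh_summary A [flag_recurrent_loh()] result.
#' @return A tibble `chrom`, `n_flagged` (all chromosomes present in the
#'   summary, zero-filled).
#' @export
loh_by_chromosome <- function(loh_summary) {
  loh_summary %>%
    as_tibble() %>%
    group_by(chrom = factor(.data$chrom, levels = unique(.data$chrom))) %>%
    summarise(n_flagged = sum(.data$flagged), .groups = "drop") %>%
    mutate(chrom = as.character(.data$chrom))
}
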