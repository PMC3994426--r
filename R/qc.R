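#' Quality-control configuration
#'
#' Thresholds and ordering for the per-SNP filters applied before paired
#' association testing. Defaults follow common SNP-array practice: minor allele
#' frequency >= 1%, call rate >= 90% pooled over both tissues, exact
#' Hardy-Weinberg test on normal-tissue genotypes at alpha = 1e-4, autosomes
#' only.
#'
#' A SNP failing several filters is attributed to the FIRST failing filter in
#' `filter_order`, so the per-filter removal counts are mutually exclusive and
#' sum with the retained count to the input count. The retained SET does not
#' depend on `filter_order`; only the attribution does.
#'
#' @param maf_min Minimum minor allele frequency (a SNP is removed when its
#'   MAF is strictly below this).
#' @param call_rate_min Minimum call rate (removed when strictly below).
#' @param hwe_alpha Removal threshold for the exact Hardy-Weinberg p-value
#'   (removed when p is strictly below).
#' @param autosomes_only Drop SNPs on non-autosomal chromosomes (X, Y, MT)
#'   before all other filters.
#' @param filter_order Order in which removals are attributed; a permutation
#'   of `c("maf", "call_rate", "hwe")`.
#' @param maf_tissue Tissue whose genotypes define the allele frequency:
#'   `"normal"` (default), `"tumor"` or `"both"` (pooled).
#' @param call_rate_tissue Tissue(s) over which the call rate is pooled;
#'   default `"both"`.
#' @return A `qc_config` list.
#' @export
qc_config <- function(maf_min = 0.01, call_rate_min = 0.90, hwe_alpha = 1e-4,
                      autosomes_only = TRUE,
                      filter_order = c("maf", "call_rate", "hwe"),
                      maf_tissue = c("normal", "tumor", "both"),
                      call_rate_tissue = c("both", "normal", "tumor")) {
  for (p in c(maf_min, call_rate_min, hwe_alpha)) {
    if (p < 0 || p > 1) abort("QC thresholds must lie in [0, 1]")
  }
  if (!setequal(filter_order, c("maf", "call_rate", "hwe"))) {
    abort("filter_order must be a permutation of c('maf', 'call_rate', 'hwe')")
  }
  structure(
    list(maf_min = maf_min, call_rate_min = call_rate_min,
         hwe_alpha = hwe_alpha, autosomes_only = autosomes_only,
         filter_order = filter_order,
         maf_tissue = match.arg(maf_tissue),
         call_rate_tissue = match.arg(call_rate_tissue)),
    class = "qc_config"
  )
}

NON_AUTOSOMES <- c("X", "Y", "MT", "M", "chrX", "chrY", "chrM", "chrMT",
                   "23", "24", "25", "26")

#' Minor allele frequency from genotype counts
#'
#' Computes the frequency of the allele counted by the 0/1/2 dosage coding,
#' `(2 n2 + n1) / (2 (n0 + n1 + n2))`. When that frequency exceeds 0.5 the
#' allele labels are treated as swapped and the minor frequency
#' `min(f, 1 - f)` is returned; the swap is recorded in the `"swapped"`
#' attribute. All-missing SNPs (zero counts) return `NA`, which fails any MAF
#' threshold with its own attribution.
#'
#' @param n0,n1,n2 Vectors of genotype counts (major homozygote, heterozygote,
#'   minor homozygote), missing calls excluded.
#' @return Numeric vector of minor allele frequencies in `[0, 0.5]`, with a
#'   logical `"swapped"` attribute.
#' @examples
#' minor_allele_frequency(30, 20, 10)  # (2*10 + 20) / 120 = 1/3
#' @export
minor_allele_frequency <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  f <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  swapped <- !is.na(f) & f > 0.5
  maf <- ifelse(swapped, 1 - f, f)
  attr(maf, "swapped") <- swapped
  maf
}

#' Call rate of a SNP
#'
#' Fraction of non-missing genotype calls among all arrays considered.
#'
#' @param calls Vector (or matrix row) of genotype calls with `NA` for missing.
#' @return Fraction in `[0, 1]`.
#' @export
call_rate <- function(calls) {
  if (length(calls) == 0) abort("call_rate needs at least one array")
  mean(!is.na(calls))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' distribution over heterozygote counts `h` compatible with the minor-allele
#' count is fully enumerated with probabilities proportional to
#' `n! / (n_AA! h! n_aa!) * 2^h`, and the p-value is the total probability of
#' all configurations no more probable than the observed one. Valid at
#' arbitrarily small counts, where the chi-square approximation is not.
#'
#' @param n0,n1,n2 Genotype counts for one SNP (major homozygote,
#'   heterozygote, minor homozygote).
#' @return Exact p-value in `(0, 1]`. Monomorphic SNPs return 1 (a single
#'   configuration).
#' @examples
#' hwe_exact_test(5, 0, 5)  # 252 / choose(20, 10)
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  stopifnot(length(n0) == 1, n0 >= 0, n1 >= 0, n2 >= 0)
  n <- n0 + n1 + n2
  if (n < 1) abort("hwe_exact_test needs at least one genotyped individual")
  n_minor <- 2 * n2 + n1
  rare <- min(n_minor, 2 * n - n_minor)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logw <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - hets - (rare - hets) / 2) + hets * log(2)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  obs <- prob[hets == n1]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Per-SNP quality-control statistics
#'
#' Computes, for every SNP of a cohort, the minor allele frequency (on the
#' tissue chosen in the configuration), the call rate (pooled over the chosen
#' tissues) and the exact Hardy-Weinberg p-value on normal-tissue genotypes.
#' Hardy-Weinberg is always evaluated on the normal tissue: tumor genotypes
#' violate equilibrium by the nature of somatic aberration.
#'
#' @param cohort A [paired_cohort()].
#' @param config A [qc_config()].
#' @return A tibble with columns `snp_id`, `chrom`, `maf`, `call_rate`,
#'   `hwe_p`.
#' @export
snp_qc_stats <- function(cohort, config = qc_config()) {
  stopifnot(inherits(cohort, "paired_cohort"))
  geno_for_maf <- switch(config$maf_tissue,
    normal = cohort$normal,
    tumor = cohort$tumor,
    both = cbind(cohort$normal, cohort$tumor))
  cnt <- genotype_count_rows(geno_for_maf)
  maf <- minor_allele_frequency(cnt[, 1], cnt[, 2], cnt[, 3])
  cr_mat <- switch(config$call_rate_tissue,
    both = cbind(cohort$normal, cohort$tumor),
    normal = cohort$normal,
    tumor = cohort$tumor)
  cr <- rowMeans(!is.na(cr_mat))
  ncnt <- genotype_count_rows(cohort$normal)
  hwe_p <- vapply(seq_len(nrow(ncnt)), function(i) {
    if (sum(ncnt[i, ]) == 0) return(NA_real_)
    hwe_exact_test(ncnt[i, 1], ncnt[i, 2], ncnt[i, 3])
  }, numeric(1))
  tibble(snp_id = cohort$annot$snp_id, chrom = cohort$annot$chrom,
         maf = as.numeric(maf), call_rate = cr, hwe_p = hwe_p)
}

genotype_count_rows <- function(m) {
  cbind(n0 = rowSums(m == 0L, na.rm = TRUE),
        n1 = rowSums(m == 1L, na.rm = TRUE),
        n2 = rowSums(m == 2L, na.rm = TRUE))
}

#' Apply QC filters to a per-SNP statistics table
#'
#' Applies the thresholds of a [qc_config()] to a table of per-SNP statistics
#' and attributes each removed SNP to the first failing filter in
#' `filter_order`. An `NA` statistic counts as failing that filter. The
#' non-autosome filter, when enabled, is applied before all others.
#'
#' @param stats A data frame with columns `snp_id`, `chrom`, `maf`,
#'   `call_rate`, `hwe_p` (as from [snp_qc_stats()]).
#' @param config A [qc_config()].
#' @return An object of class `qc_result`: a list with `retained` (character
#'   vector of SNP ids, input order), `report` (tibble of removal counts per
#'   filter) and `per_snp` (the input table plus a `removed_by` column, `NA`
#'   for retained SNPs).
#' @export
qc_filter <- function(stats, config = qc_config()) {
  stats <- as_tibble(stats)
  needed <- c("snp_id", "chrom", "maf", "call_rate", "hwe_p")
  if (!all(needed %in% names(stats))) {
    abort(paste0("stats must have columns: ", paste(needed, collapse = ", ")))
  }
  n_input <- nrow(stats)
  removed_by <- rep(NA_character_, n_input)
  if (config$autosomes_only) {
    non_auto <- stats$chrom %in% NON_AUTOSOMES
    removed_by[non_auto] <- "non_autosomal"
  }
  fails <- list(
    maf = is.na(stats$maf) | stats$maf < config$maf_min,
    call_rate = is.na(stats$call_rate) | stats$call_rate < config$call_rate_min,
    hwe = is.na(stats$hwe_p) | stats$hwe_p < config$hwe_alpha
  )
  for (f in config$filter_order) {
    hit <- is.na(removed_by) & fails[[f]]
    removed_by[hit] <- f
  }
  filter_names <- c(if (config$autosomes_only) "non_autosomal",
                    config$filter_order)
  removed <- vapply(filter_names,
                    function(f) sum(removed_by == f, na.rm = TRUE), integer(1))
  report <- tibble(filter = filter_names, removed = as.integer(removed))
  res <- list(
    retained = stats$snp_id[is.na(removed_by)],
    report = report,
    n_input = n_input,
    n_retained = sum(is.na(removed_by)),
    per_snp = mutate(stats, removed_by = removed_by),
    config = config
  )
  stopifnot(res$n_input == res$n_retained + sum(report$removed))
  structure(res, class = "qc_result")
}

#' Run quality control on a paired cohort
#'
#' Convenience wrapper: computes [snp_qc_stats()] then applies [qc_filter()].
#'
#' @inheritParams snp_qc_stats
#' @return A `qc_result` (see [qc_filter()]).
#' @export
apply_qc <- function(cohort, config = qc_config()) {
  if (nrow(cohort$normal) == 0) {
    return(structure(list(
      retained = character(), report = tibble(filter = character(),
                                              removed = integer()),
      n_input = 0L, n_retained = 0L,
      per_snp = tibble(snp_id = character(), chrom = character(),
                       maf = numeric(), call_rate = numeric(),
                       hwe_p = numeric(), removed_by = character()),
      config = config), class = "qc_result"))
  }
  qc_filter(snp_qc_stats(cohort, config), config)
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  cat(sprintf("  input SNPs:    %d\n", x$n_input))
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  removed (%s): %d\n", x$report$filter[i], x$report$removed[i]))
  }
  cat(sprintf("  retained SNPs: %d\n", x$n_retained))
  invisible(x)
}

#' @rdname qc_filter
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) x$report

#' @rdname qc_filter
#' @export
glance.qc_result <- function(x, ...) {
  tibble(n_input = x$n_input, n_removed = sum(x$report$removed),
         n_retained = x$n_retained)
}
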