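#' Paired 3x3 genotype table for one SNP
#'
#' Cross-tabulates matched normal and tumor genotype calls from the same
#' patients. A patient contributes to cell `(i, j)` when the normal call is
#' `i` and the tumor call is `j`, both non-missing; patients with a missing
#' call in either tissue are counted in `n_missing_pairs` and excluded
#' (complete-pair analysis at this SNP only).
#'
#' @param normal_calls,tumor_calls Equal-length, patient-aligned genotype
#'   vectors with values in `{0, 1, 2, NA}`.
#' @return A `paired_genotype_table`: a 3x3 integer matrix (rows = normal
#'   genotype, columns = tumor genotype, dimnames `0:2`) with attribute
#'   `n_missing_pairs`.
#' @examples
#' build_paired_table(c(1, 1, NA), c(0, 2, 0))
#' @export
build_paired_table <- function(normal_calls, tumor_calls) {
  if (length(normal_calls) != length(tumor_calls)) {
    abort("normal and tumor call vectors must be patient-aligned (equal length)")
  }
  ok_vals <- function(x) all(is.na(x) | x %in% c(0, 1, 2))
  if (!ok_vals(normal_calls) || !ok_vals(tumor_calls)) {
    abort("genotype calls must lie in {0, 1, 2, NA}")
  }
  complete <- !is.na(normal_calls) & !is.na(tumor_calls)
  tab <- table(factor(normal_calls[complete], levels = 0:2),
               factor(tumor_calls[complete], levels = 0:2))
  m <- matrix(as.integer(tab), nrow = 3, dimnames = list(normal = 0:2,
                                                         tumor = 0:2))
  structure(m, n_missing_pairs = sum(!complete),
            class = c("paired_genotype_table", "matrix", "array"))
}

#' McNemar-Bowker test of symmetry for a paired 3x3 genotype table
#'
#' Tests whether tumor genotypes are distributed symmetrically around the
#' matched normal genotypes. The statistic sums, over the unordered
#' off-diagonal pairs `{i, j}` with `n[i,j] + n[j,i] > 0`,
#' `(n[i,j] - n[j,i])^2 / (n[i,j] + n[j,i])`; the degrees of freedom equal the
#' number of contributing pairs (pairs with zero discordant counts are dropped
#' rather than contributing 0/0), and the p-value is the upper tail of the
#' chi-square distribution. A table with no discordant pairs gives statistic
#' 0, df 0, p 1.
#'
#' @param table A `paired_genotype_table` or plain 3x3 count matrix.
#' @param snp_id Optional SNP id carried into the result.
#' @param alpha Significance level for the `significant` flag (raw p-value,
#'   no multiplicity correction).
#' @return An object of class `mcb_test` with elements `snp_id`, `statistic`,
#'   `df`, `p_value`, `significant`.
#' @examples
#' tab <- matrix(0, 3, 3); tab[1, 2] <- 6; tab[2, 1] <- 2
#' mcnemar_bowker(tab)  # statistic (6-2)^2/8 = 2, df 1
#' @export
mcnemar_bowker <- function(table, snp_id = NA_character_, alpha = 0.01) {
  m <- unclass(table)
  if (!is.matrix(m) || !all(dim(m) == c(3, 3))) {
    abort("table must be a 3x3 paired genotype count matrix")
  }
  if (any(m < 0)) abort("counts must be non-negative")
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  stat <- 0
  df <- 0L
  for (pr in pairs) {
    a <- m[pr[1], pr[2]]; b <- m[pr[2], pr[1]]
    s <- a + b
    if (s > 0) {
      stat <- stat + (a - b)^2 / s
      df <- df + 1L
    }
  }
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  structure(
    list(snp_id = snp_id, statistic = stat, df = df, p_value = p,
         significant = p < alpha, alpha = alpha),
    class = "mcb_test"
  )
}

#' @export
print.mcb_test <- function(x, ...) {
  cat("McNemar-Bowker symmetry test\n")
  if (!is.na(x$snp_id)) cat(sprintf("  SNP: %s\n", x$snp_id))
  cat(sprintf("  statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname mcnemar_bowker
#' @param x An `mcb_test`.
#' @param ... Unused.
#' @export
tidy.mcb_test <- function(x, ...) {
  tibble(snp_id = x$snp_id, statistic = x$statistic, df = x$df,
         p.value = x$p_value,
         method = "McNemar-Bowker symmetry test")
}

#' Genome-wide paired genotype scan
#'
#' Runs the McNemar-Bowker symmetry test at every (retained) SNP of a paired
#' cohort. Significance is judged on the raw p-value at `alpha` with no
#' multiple-testing correction: the paired design is the study's variance
#' control, and the threshold is an explicit screening criterion rather than a
#' family-wise error guarantee. An optional adjusted column can be requested.
#'
#' @param cohort A [paired_cohort()].
#' @param snp_ids SNPs to test (default: all). Ids absent from the cohort are
#'   an error.
#' @param alpha Raw-p significance threshold (default 0.01).
#' @param adjust Optional p-adjustment method passed to [stats::p.adjust()]
#'   (e.g. `"bonferroni"`, `"BH"`); `"none"` (default) adds no column.
#' @return A tibble of class `triconcord_scan`: `snp_id`, `chrom`, `pos`,
#'   `n_pairs`, `statistic`, `df`, `p_value`, `neg_log10_p`, `significant`
#'   (and `p_adjusted` when requested), one row per tested SNP in genomic
#'   order.
#' @export
genome_scan <- function(cohort, snp_ids = NULL, alpha = 0.01,
                        adjust = "none") {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (is.null(snp_ids)) {
    rows <- seq_len(nrow(cohort$normal))
  } else {
    missing_ids <- setdiff(snp_ids, cohort$annot$snp_id)
    if (length(missing_ids) > 0) {
      abort(paste0("snp_ids absent from cohort: ",
                   paste(head(missing_ids, 5), collapse = ", "),
                   if (length(missing_ids) > 5) " ..."))
    }
    rows <- match(snp_ids, cohort$annot$snp_id)
    rows <- sort(rows)
  }
  nm <- cohort$normal[rows, , drop = FALSE]
  tm <- cohort$tumor[rows, , drop = FALSE]
  complete <- !is.na(nm) & !is.na(tm)
  cell <- function(i, j) rowSums(complete & nm == i & tm == j, na.rm = TRUE)
  n01 <- cell(0L, 1L); n10 <- cell(1L, 0L)
  n02 <- cell(0L, 2L); n20 <- cell(2L, 0L)
  n12 <- cell(1L, 2L); n21 <- cell(2L, 1L)
  contrib <- function(a, b) {
    s <- a + b
    ifelse(s > 0, (a - b)^2 / s, 0)
  }
  stat <- unname(contrib(n01, n10) + contrib(n02, n20) + contrib(n12, n21))
  df <- unname((n01 + n10 > 0) + (n02 + n20 > 0) + (n12 + n21 > 0))
  p <- ifelse(df == 0, 1, pchisq(stat, df = pmax(df, 1L), lower.tail = FALSE))
  res <- tibble(
    snp_id = cohort$annot$snp_id[rows],
    chrom = cohort$annot$chrom[rows],
    pos = cohort$annot$pos[rows],
    n_pairs = unname(rowSums(complete)),
    statistic = stat,
    df = as.integer(df),
    p_value = p,
    neg_log10_p = -log10(p),
    significant = p < alpha
  )
  if (!identical(adjust, "none")) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = adjust)
  }
  attr(res, "alpha") <- alpha
  class(res) <- c("triconcord_scan", class(res))
  res
}

#' @rdname genome_scan
#' @param x A `triconcord_scan`.
#' @param ... Unused.
#' @export
glance.triconcord_scan <- function(x, ...) {
  tibble(n_snps = nrow(x), alpha = attr(x, "alpha"),
         n_significant = sum(x$significant),
         min_p = if (nrow(x)) min(x$p_value) else NA_real_)
}
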