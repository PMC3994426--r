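#' Paired tumor/normal cohort container
#'
#' Bundles the matched genotype calls, tumor copy-number estimates and SNP
#' annotation for one cohort of patients with paired tumor and adjacent-normal
#' tissue. Genotypes count copies of the minor allele (0 = major homozygote,
#' 1 = heterozygote, 2 = minor homozygote, `NA` = no call). Copy-number
#' estimates are tumor values referenced against the matched normal tissue, so
#' the diploid baseline is 2.
#'
#' @param normal,tumor Integer matrices, SNPs in rows and patients in columns,
#'   values in `{0, 1, 2, NA}`. Row names are SNP ids, column names patient ids.
#' @param cn Numeric matrix of tumor copy-number estimates with the same
#'   dimensions and dimnames as the genotype matrices, or `NULL` when no
#'   copy-number track is available.
#' @param annot A data frame of SNP annotation with columns `snp_id`, `chrom`,
#'   `pos` (1-based bp), `allele_major`, `allele_minor`, one row per genotype
#'   matrix row and in the same order.
#' @param truth Optional list describing planted aberrations (as produced by
#'   [simulate_cohort()]); `NULL` for real data.
#'
#' @return An object of class `paired_cohort`.
#' @seealso [simulate_cohort()], [read_cohort()], [write_cohort()]
#' @export
paired_cohort <- function(normal, tumor, cn = NULL, annot, truth = NULL) {
  annot <- as_tibble(annot)
  required <- c("snp_id", "chrom", "pos", "allele_major", "allele_minor")
  missing_cols <- setdiff(required, names(annot))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.matrix(normal) || !is.matrix(tumor)) {
    abort("genotype inputs must be matrices (SNPs x patients)")
  }
  if (!identical(dim(normal), dim(tumor))) {
    abort("normal and tumor genotype matrices must have identical dimensions")
  }
  if (nrow(normal) != nrow(annot)) {
    abort(sprintf("annotation has %d rows but genotype matrices have %d",
                  nrow(annot), nrow(normal)))
  }
  check_genotype_values(normal, "normal")
  check_genotype_values(tumor, "tumor")
  if (!is.null(cn)) {
    if (!is.matrix(cn) || !identical(dim(cn), dim(normal))) {
      abort("copy-number matrix must match the genotype matrix dimensions")
    }
    if (any(cn < 0, na.rm = TRUE)) abort("copy-number estimates must be >= 0")
  }
  if (anyDuplicated(annot$snp_id)) {
    abort("duplicate snp_id in annotation")
  }
  validate_annotation_order(annot)
  patients <- colnames(normal)
  if (is.null(patients)) {
    patients <- sprintf("P%03d", seq_len(ncol(normal)))
  }
  storage.mode(normal) <- "integer"
  storage.mode(tumor) <- "integer"
  dimnames(normal) <- list(annot$snp_id, patients)
  dimnames(tumor) <- list(annot$snp_id, patients)
  if (!is.null(cn)) dimnames(cn) <- list(annot$snp_id, patients)
  structure(
    list(normal = normal, tumor = tumor, cn = cn, annot = annot,
         patients = patients, truth = truth),
    class = "paired_cohort"
  )
}

check_genotype_values <- function(m, label) {
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    bad <- unique(vals[!vals %in% c(0L, 1L, 2L)])
    abort(sprintf("%s genotypes contain values outside {0,1,2,NA}: %s",
                  label, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(m)
}

validate_annotation_order <- function(annot) {
  by_chrom <- split(annot$pos, factor(annot$chrom, levels = unique(annot$chrom)))
  for (chrom in names(by_chrom)) {
    pos <- by_chrom[[chrom]]
    if (length(pos) > 1 && any(diff(pos) <= 0)) {
      i <- which(diff(pos) <= 0)[1]
      abort(sprintf(
        "positions on chromosome %s are not strictly increasing (offending pair at within-chromosome rows %d-%d)",
        chrom, i, i + 1L))
    }
  }
  invisible(annot)
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("<paired_cohort>\n")
  cat(sprintf("  %d SNPs x %d patients (paired normal/tumor genotypes)\n",
              nrow(x$normal), length(x$patients)))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$annot$chrom), collapse = ", ")))
  cat(sprintf("  copy-number track: %s\n", if (is.null(x$cn)) "absent" else "present"))
  if (!is.null(x$truth)) {
    cat(sprintf("  planted truth: %d CNV, %d association, %d LOH element(s)\n",
                nrow(x$truth$cnv), nrow(x$truth$assoc), nrow(x$truth$loh)))
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort A [paired_cohort()].
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  length(cohort$patients)
}

# Row indices of a cohort's SNPs on one chromosome, in annotation order.
chrom_rows <- function(cohort, chrom) {
  which(cohort$annot$chrom == chrom)
}
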