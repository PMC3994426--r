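#' Write a paired cohort to a directory of delimited text files
#'
#' Writes `genotypes_normal.tsv` and `genotypes_tumor.tsv` (rows = SNPs,
#' columns = patients, cells in `{0, 1, 2, NA}`), `copynumber_tumor.tsv`
#' (same shape, reals; omitted when the cohort has no copy-number track),
#' `snps.tsv` (columns `snp_id`, `chrom`, `pos_1based`, `allele_major`,
#' `allele_minor`) and, when planted truth is present, `truth.json`. Writers
#' are deterministic: the same cohort always produces byte-identical files.
#'
#' @param cohort A [paired_cohort()].
#' @param dir_path Directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_cohort <- function(cohort, dir_path) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  write_geno <- function(m, file) {
    df <- as.data.frame(m)
    df <- cbind(snp_id = cohort$annot$snp_id, df)
    readr::write_tsv(df, file.path(dir_path, file), na = "NA")
  }
  write_geno(cohort$normal, "genotypes_normal.tsv")
  write_geno(cohort$tumor, "genotypes_tumor.tsv")
  if (!is.null(cohort$cn)) write_geno(cohort$cn, "copynumber_tumor.tsv")
  write_annotation(cohort$annot, file.path(dir_path, "snps.tsv"))
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    jsonlite::write_json(
      list(cnv = truth$cnv, assoc = truth$assoc, loh = truth$loh),
      file.path(dir_path, "truth.json"), pretty = TRUE, digits = NA)
  }
  invisible(dir_path)
}

#' Read a paired cohort from a directory
#'
#' Inverse of [write_cohort()]: `read_cohort(write_cohort(x)) == x` up to the
#' planted-truth record, including missing genotype codes. Malformed
#' genotypes (anything outside `{0, 1, 2, NA}`) are a parse error naming the
#' file and line.
#'
#' @param dir_path Directory written by [write_cohort()].
#' @return A [paired_cohort()] (with `truth = NULL`; the `truth.json` file,
#'   when present, can be read separately with [jsonlite::read_json()]).
#' @export
read_cohort <- function(dir_path) {
  annot <- read_annotation(file.path(dir_path, "snps.tsv"))
  normal <- read_genotype_matrix(file.path(dir_path, "genotypes_normal.tsv"),
                                 annot$snp_id)
  tumor <- read_genotype_matrix(file.path(dir_path, "genotypes_tumor.tsv"),
                                annot$snp_id)
  cn_path <- file.path(dir_path, "copynumber_tumor.tsv")
  cn <- if (file.exists(cn_path)) read_numeric_matrix(cn_path, annot$snp_id)
        else NULL
  paired_cohort(normal, tumor, cn, annot)
}

read_genotype_matrix <- function(path, snp_ids) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), .default = readr::col_character()),
    na = character(), comment = "#", progress = FALSE)
  if (!"snp_id" %in% names(df) || ncol(df) < 1) {
    abort(paste0("malformed header in ", path, ": expected a snp_id column"))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  bad <- matrix(!(cells %in% c("0", "1", "2", "NA")), nrow = nrow(cells))
  if (any(bad)) {
    first <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "invalid genotype '%s' in %s at line %d (data row %d, column %s): genotypes must be 0, 1, 2 or NA",
      cells[first[1], first[2]], path, first[1] + 1L, first[1],
      colnames(cells)[first[2]]))
  }
  m <- matrix(suppressWarnings(as.integer(cells)), nrow = nrow(cells),
              ncol = ncol(cells), dimnames = list(df$snp_id, colnames(cells)))
  if (!identical(df$snp_id, as.character(snp_ids))) {
    abort(paste0("SNP ids in ", path, " do not match the annotation order"))
  }
  m
}

read_numeric_matrix <- function(path, snp_ids) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), .default = readr::col_double()),
    comment = "#", progress = FALSE)
  m <- matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])), nrow = nrow(df),
              ncol = ncol(df) - 1L, dimnames = list(df$snp_id, names(df)[-1]))
  if (!identical(df$snp_id, as.character(snp_ids))) {
    abort(paste0("SNP ids in ", path, " do not match the annotation order"))
  }
  m
}

#' Read or write a SNP annotation table
#'
#' The annotation TSV has columns `snp_id`, `chrom`, `pos_1based`,
#' `allele_major`, `allele_minor`. On read, duplicate SNP ids and
#' non-monotone positions within a chromosome are errors naming the offending
#' line; positions must be strictly increasing in file order within each
#' chromosome.
#'
#' @param path File path.
#' @param annot Annotation tibble with columns `snp_id`, `chrom`, `pos`,
#'   `allele_major`, `allele_minor`.
#' @return `read_annotation()` returns the annotation tibble (with the
#'   position column named `pos`); `write_annotation()` returns `path`
#'   invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        comment = "#", progress = FALSE)
  required <- c("snp_id", "chrom", "pos_1based", "allele_major", "allele_minor")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("malformed header in ", path, ": missing column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$pos_1based <- suppressWarnings(as.integer(df$pos_1based))
  if (anyNA(df$pos_1based)) {
    abort(paste0("non-integer position in ", path, " at line ",
                 which(is.na(df$pos_1based))[1] + 1L))
  }
  dup <- which(duplicated(df$snp_id))
  if (length(dup) > 0) {
    abort(sprintf("duplicate snp_id '%s' in %s at line %d",
                  df$snp_id[dup[1]], path, dup[1] + 1L))
  }
  if (any(df$pos_1based < 1, na.rm = TRUE)) {
    abort(paste0("positions must be positive 1-based integers in ", path))
  }
  for (chrom in unique(df$chrom)) {
    rows <- which(df$chrom == chrom)
    pos <- df$pos_1based[rows]
    if (length(pos) > 1 && any(diff(pos) <= 0)) {
      i <- which(diff(pos) <= 0)[1]
      abort(sprintf(
        "positions on chromosome %s are not strictly increasing in %s at line %d",
        chrom, path, rows[i + 1] + 1L))
    }
  }
  tibble(snp_id = df$snp_id, chrom = df$chrom, pos = df$pos_1based,
         allele_major = df$allele_major, allele_minor = df$allele_minor)
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annot, path) {
  annot <- as_tibble(annot)
  out <- tibble(snp_id = annot$snp_id, chrom = annot$chrom,
                pos_1based = annot$pos, allele_major = annot$allele_major,
                allele_minor = annot$allele_minor)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export one tissue's genotypes as a minimal VCF 4.2 file
#'
#' Writes CHROM, POS, ID, REF (major allele), ALT (minor allele) and a
#' GT-only FORMAT column per patient; dosages map as 0 to `0/0`, 1 to `0/1`,
#' 2 to `1/1` and missing to `./.`.
#'
#' @param cohort A [paired_cohort()].
#' @param tissue `"normal"` or `"tumor"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_vcf <- function(cohort, tissue = c("normal", "tumor"), path) {
  stopifnot(inherits(cohort, "paired_cohort"))
  tissue <- match.arg(tissue)
  m <- cohort[[tissue]]
  gt_map <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gt <- matrix(gt_map[as.character(m)], nrow = nrow(m))
  gt[is.na(m)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triconcord",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$patients), collapse = "\t")
  )
  body <- paste(cohort$annot$chrom, cohort$annot$pos, cohort$annot$snp_id,
                cohort$annot$allele_major, cohort$annot$allele_minor,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (nrow(m) == 0) body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export recurrent regions as a BED4 file
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention (`bed_start = start_pos - 1`, `bed_end = end_pos`),
#' so `bed_end - bed_start` equals the inclusive length
#' `end_pos - start_pos + 1`. The name field is `direction:support`.
#'
#' @param regions A `cnv_regions` tibble ([call_recurrent_regions()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_bed_regions()] for the inverse conversion.
#' @export
export_bed <- function(regions, path) {
  lines <- paste(regions$chrom, regions$start_pos - 1L, regions$end_pos,
                 paste0(regions$direction, ":", regions$max_support),
                 sep = "\t")
  if (nrow(regions) == 0) lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED4 file back to 1-based inclusive regions
#'
#' @param path A BED file written by [export_bed()].
#' @return A tibble `chrom`, `start_pos`, `end_pos` (1-based inclusive),
#'   `direction`, `max_support`.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_names = c("chrom", "bed_start", "bed_end",
                                            "name"),
                        col_types = "ciic", progress = FALSE)
  name_parts <- strsplit(df$name, ":", fixed = TRUE)
  tibble(
    chrom = df$chrom,
    start_pos = df$bed_start + 1L,
    end_pos = df$bed_end,
    direction = vapply(name_parts, `[`, character(1), 1),
    max_support = as.integer(vapply(name_parts, `[`, character(1), 2))
  )
}
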