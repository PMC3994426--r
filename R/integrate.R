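#' Intersect the three analysis arms into candidate biomarkers
#'
#' A candidate biomarker is a SNP that is concordantly aberrant in all three
#' arms: it lies (by bp position, inclusive bounds) inside a recurrent
#' copy-number region, its paired genotype association is significant at the
#' scan's alpha, and it is flagged as a recurrent-LOH locus. The returned
#' table carries every SNP's three arm statuses; candidates are the rows with
#' all three flags, sorted by association p-value.
#'
#' @param regions A `cnv_regions` tibble ([call_recurrent_regions()]).
#' @param assoc A `triconcord_scan` tibble ([genome_scan()]).
#' @param loh A `loh_summary` tibble ([flag_recurrent_loh()]).
#' @param candidates_only Return only the candidate rows (default `TRUE`).
#' @return A tibble of class `biomarker_candidates`: `snp_id`, `chrom`, `pos`,
#'   `in_recurrent_cnv`, `cnv_direction`, `assoc_p`, `assoc_significant`,
#'   `loh_flagged`, `n_loh`, `candidate`; candidates first, ascending p.
#' @export
intersect_arms <- function(regions, assoc, loh, candidates_only = TRUE) {
  assoc <- as_tibble(assoc)
  loh_tbl <- as_tibble(loh)
  mismatch <- setdiff(assoc$snp_id, loh_tbl$snp_id)
  if (length(mismatch) > 0) {
    abort(paste0("arms were computed over different annotations; SNPs in the ",
                 "association arm but not the LOH arm: ",
                 paste(head(mismatch, 5), collapse = ", "),
                 if (length(mismatch) > 5) " ..."))
  }
  merged <- assoc %>%
    select("snp_id", "chrom", "pos", assoc_p = "p_value",
           assoc_significant = "significant") %>%
    left_join(select(loh_tbl, "snp_id", "n_loh", loh_flagged = "flagged"),
              by = "snp_id")
  in_cnv <- rep(FALSE, nrow(merged))
  cnv_dir <- rep(NA_character_, nrow(merged))
  if (nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      hit <- merged$chrom == regions$chrom[i] &
        merged$pos >= regions$start_pos[i] & merged$pos <= regions$end_pos[i]
      in_cnv <- in_cnv | hit
      cnv_dir[hit & is.na(cnv_dir)] <- regions$direction[i]
    }
  }
  merged <- merged %>%
    mutate(in_recurrent_cnv = in_cnv, cnv_direction = cnv_dir,
           candidate = in_cnv & .data$assoc_significant & .data$loh_flagged) %>%
    select("snp_id", "chrom", "pos", "in_recurrent_cnv", "cnv_direction",
           "assoc_p", "assoc_significant", "loh_flagged", "n_loh",
           "candidate") %>%
    arrange(dplyr::desc(.data$candidate), .data$assoc_p)
  if (candidates_only) merged <- filter(merged, .data$candidate)
  class(merged) <- c("biomarker_candidates", class(merged))
  merged
}

#' Run the full triple-concordance pipeline
#'
#' Drives quality control, the copy-number arm, the paired association arm,
#' the LOH arm and their intersection over one cohort, and optionally writes
#' every arm's table plus a machine-readable JSON summary to a directory.
#' Identical inputs and configuration always produce identical outputs.
#'
#' @param cohort A [paired_cohort()], or a directory path readable by
#'   [read_cohort()].
#' @param qc A [qc_config()].
#' @param cnv A [cnv_config()].
#' @param alpha Raw-p significance threshold for the association arm.
#' @param loh_fraction Recurrence fraction for the LOH arm.
#' @param loh_denominator Denominator convention for the LOH threshold (see
#'   [flag_recurrent_loh()]).
#' @param out_dir Optional output directory.
#' @return A list of class `triconcord_pipeline`: `qc` (qc_result), `runs`,
#'   `regions`, `assoc`, `loh`, `candidates`, `summary` (one-row tibble of
#'   stage counts and the thresholds actually used).
#' @export
run_pipeline <- function(cohort, qc = qc_config(), cnv = cnv_config(),
                         alpha = 0.01, loh_fraction = 0.18,
                         loh_denominator = "cohort", out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "paired_cohort"))
  n_pat <- n_patients(cohort)

  qc_res <- apply_qc(cohort, qc)
  runs <- call_runs_cohort(cohort, cnv)
  regions <- call_recurrent_regions(runs, cohort$annot, n_pat, cnv)
  assoc <- genome_scan(cohort, snp_ids = qc_res$retained, alpha = alpha)
  loh <- flag_recurrent_loh(cohort, fraction = loh_fraction,
                            denominator = loh_denominator)
  cand <- intersect_arms(regions, assoc,
                         loh[loh$snp_id %in% assoc$snp_id, , drop = FALSE])

  cnv_thr <- recurrence_threshold(n_pat, cnv$recurrence_fraction,
                                  cnv$recurrence_strict)
  loh_thr <- recurrence_threshold(n_pat, loh_fraction, strict = FALSE)
  summary <- tibble(
    n_patients = n_pat,
    n_snps_input = qc_res$n_input,
    n_snps_retained = qc_res$n_retained,
    n_cnv_runs = nrow(runs),
    n_recurrent_regions = nrow(regions),
    cnv_support_threshold = cnv_thr,
    n_assoc_significant = sum(assoc$significant),
    alpha = alpha,
    n_loh_flagged = sum(loh$flagged),
    loh_support_threshold = if (loh_denominator == "cohort") loh_thr
      else NA_integer_,
    loh_fraction = loh_fraction,
    n_candidates = nrow(cand)
  )
  res <- structure(
    list(qc = qc_res, runs = runs, regions = regions, assoc = assoc,
         loh = loh, candidates = cand, summary = summary),
    class = "triconcord_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$qc$per_snp, file.path(out_dir, "qc_per_snp.tsv"))
  jsonlite::write_json(
    list(n_input = res$qc$n_input,
         removed_per_filter = setNames(as.list(res$qc$report$removed),
                                       res$qc$report$filter),
         n_retained = res$qc$n_retained),
    file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
  writeLines(res$qc$retained, file.path(out_dir, "retained_snps.txt"))
  readr::write_tsv(res$runs, file.path(out_dir, "cnv_runs.tsv"))
  regions_flat <- res$regions
  regions_flat$supporting_patients <-
    vapply(regions_flat$supporting_patients, paste, character(1),
           collapse = ",")
  readr::write_tsv(as_tibble(regions_flat), file.path(out_dir, "cnv_regions.tsv"))
  if (nrow(res$regions) > 0) {
    export_bed(res$regions, file.path(out_dir, "cnv_regions.bed"))
  }
  readr::write_tsv(as_tibble(res$assoc), file.path(out_dir, "assoc.tsv"))
  readr::write_tsv(as_tibble(res$loh), file.path(out_dir, "loh.tsv"))
  readr::write_tsv(loh_by_chromosome(res$loh),
                   file.path(out_dir, "loh_by_chromosome.tsv"))
  readr::write_tsv(as_tibble(res$candidates),
                   file.path(out_dir, "candidates.tsv"))
  jsonlite::write_json(as.list(res$summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' @export
print.triconcord_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<triconcord_pipeline>\n")
  cat(sprintf("  patients: %d | SNPs: %d in, %d retained after QC\n",
              s$n_patients, s$n_snps_input, s$n_snps_retained))
  cat(sprintf("  CNV: %d run(s), %d recurrent region(s) at support >= %d\n",
              s$n_cnv_runs, s$n_recurrent_regions, s$cnv_support_threshold))
  cat(sprintf("  association: %d SNP(s) with p < %g\n",
              s$n_assoc_significant, s$alpha))
  cat(sprintf("  LOH: %d flagged SNP(s) (fraction %g)\n",
              s$n_loh_flagged, s$loh_fraction))
  cat(sprintf("  candidates (triple concordant): %d\n", s$n_candidates))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `triconcord_pipeline`.
#' @param ... Unused.
#' @export
glance.triconcord_pipeline <- function(x, ...) x$summary

#' Cohort clinical bookkeeping summary
#'
#' Summarises per-patient tumor stage and age into stage groups (I + II
#' versus III + IV): patient counts, the percentage of the cohort (rounded
#' half away from zero to a whole percent), and mean and sample standard
#' deviation (n - 1 denominator) of age.
#'
#' @param clinical A data frame with columns `stage` (labels among I, II,
#'   III, IV) and `age`; see [simulate_clinical_table()].
#' @return A tibble: `stage_group`, `n`, `percent`, `age_mean`, `age_sd`,
#'   plus an `"Overall"` row.
#' @export
cohort_summary <- function(clinical) {
  clinical <- as_tibble(clinical)
  stopifnot(all(c("stage", "age") %in% names(clinical)))
  known <- c("I", "II", "III", "IV")
  bad <- setdiff(unique(clinical$stage), known)
  if (length(bad) > 0) {
    abort(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  n_total <- nrow(clinical)
  grp <- ifelse(clinical$stage %in% c("I", "II"), "I + II", "III + IV")
  per_group <- tibble(stage_group = grp, age = clinical$age) %>%
    group_by(.data$stage_group) %>%
    summarise(n = n(), age_mean = mean(.data$age), age_sd = sd(.data$age),
              .groups = "drop") %>%
    mutate(percent = round_half_up(100 * .data$n / n_total))
  overall <- tibble(stage_group = "Overall", n = n_total,
                    age_mean = mean(clinical$age), age_sd = sd(clinical$age),
                    percent = 100)
  bind_rows(per_group, overall) %>%
    select("stage_group", "n", "percent", "age_mean", "age_sd")
}

# round half away from zero (44/61 -> 72.13% -> 72; 0.5 -> 1)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
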