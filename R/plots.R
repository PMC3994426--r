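#' Manhattan plot of a paired genome scan
#'
#' Plots `-log10(p)` per SNP along the genome, coloured by chromosome, with a
#' horizontal reference line at the scan's significance threshold.
#'
#' @param scan A `triconcord_scan` tibble ([genome_scan()]).
#' @param alpha Threshold line (defaults to the scan's alpha).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, alpha = attr(scan, "alpha") %||% 0.01) {
  d <- as_tibble(scan) %>%
    mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom))) %>%
    group_by(.data$chrom) %>%
    mutate(rel = .data$pos / max(.data$pos)) %>%
    ungroup() %>%
    mutate(x = as.numeric(.data$chrom) - 1 + .data$rel)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$neg_log10_p,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_x_continuous(
      breaks = seq_along(levels(d$chrom)) - 0.5,
      labels = levels(d$chrom)) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(p))),
                  title = "Paired genotype symmetry scan") +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object A `triconcord_scan`.
#' @param ... Unused.
#' @export
autoplot.triconcord_scan <- function(object, ...) plot_manhattan(object)

#' Per-SNP copy-number support along the genome
#'
#' Plots, for one direction, the number of patients whose qualifying runs
#' cover each SNP, with a horizontal line at the recurrence support
#' threshold — the per-SNP rendering behind recurrent-region calls.
#'
#' @param runs A runs tibble ([call_runs_cohort()]).
#' @param annot SNP annotation.
#' @param n_patients Cohort size.
#' @param config A [cnv_config()].
#' @param direction `"gain"` or `"loss"`.
#' @return A ggplot object.
#' @export
plot_cnv_support <- function(runs, annot, n_patients, config = cnv_config(),
                             direction = "gain") {
  annot <- as_tibble(annot)
  thr <- recurrence_threshold(n_patients, config$recurrence_fraction,
                              config$recurrence_strict)
  support <- annot %>%
    group_by(.data$chrom) %>%
    mutate(idx = row_number()) %>%
    ungroup() %>%
    mutate(support = 0L)
  dr <- runs[runs$direction == direction, , drop = FALSE]
  for (i in seq_len(nrow(dr))) {
    hit <- support$chrom == dr$chrom[i] & support$idx >= dr$start_idx[i] &
      support$idx <= dr$end_idx[i]
    support$support[hit] <- support$support[hit] + 1L
  }
  ggplot2::ggplot(support, ggplot2::aes(x = .data$pos, y = .data$support)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "patients with qualifying run",
                  title = sprintf("Per-SNP %s support (threshold %d of %d)",
                                  direction, thr, n_patients)) +
    ggplot2::theme_minimal()
}

#' Flagged-LOH counts per chromosome
#'
#' Bar chart of the number of recurrent-LOH SNPs on each chromosome.
#'
#' @param loh_summary A [flag_recurrent_loh()] result.
#' @return A ggplot object.
#' @export
plot_loh_by_chromosome <- function(loh_summary) {
  d <- loh_by_chromosome(loh_summary) %>%
    mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom, y = .data$n_flagged)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome", y = "recurrent-LOH SNPs",
                  title = "LOH recurrence by chromosome") +
    ggplot2::theme_minimal()
}

#' @rdname plot_loh_by_chromosome
#' @param object A `loh_summary`.
#' @param ... Unused.
#' @export
autoplot.loh_summary <- function(object, ...) plot_loh_by_chromosome(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

`%||%` <- function(a, b) if (is.null(a)) b else a
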