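# Independent oracles, deliberately coded on different paths than the package.

# Exact HWE p-value by direct enumeration with exact integer weights
# (multinomial coefficients via choose(), exact in double for n <= 20).
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  n_minor <- 2 * n2 + n1
  rare <- min(n_minor, 2 * n - n_minor)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    choose(n, hom_rare) * choose(n - hom_rare, h) * 2^h
  }, numeric(1))
  obs <- w[hets == n1]
  sum(w[w <= obs]) / sum(w)
}

# Maximal threshold-runs by a plain left-to-right scan loop.
runs_oracle <- function(cn, gain, loss, min_len) {
  out <- list()
  for (direction in c("gain", "loss")) {
    qual <- if (direction == "gain") cn > gain else cn < loss
    qual[is.na(qual)] <- FALSE
    i <- 1
    while (i <= length(qual)) {
      if (qual[i]) {
        j <- i
        while (j < length(qual) && qual[j + 1]) j <- j + 1
        if (j - i + 1 >= min_len) {
          out[[length(out) + 1]] <- data.frame(
            start_idx = i, end_idx = j, direction = direction)
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      direction = character()))
  }
  do.call(rbind, out)
}

# Recurrent intervals by brute-force per-SNP patient counting.
regions_oracle <- function(runs, n_snp, threshold, direction) {
  flagged <- logical(n_snp)
  for (s in seq_len(n_snp)) {
    carriers <- character()
    for (i in seq_len(nrow(runs))) {
      if (runs$direction[i] == direction &&
          runs$start_idx[i] <= s && runs$end_idx[i] >= s) {
        carriers <- union(carriers, runs$patient[i])
      }
    }
    flagged[s] <- length(carriers) >= threshold
  }
  out <- list()
  s <- 1
  while (s <= n_snp) {
    if (flagged[s]) {
      e <- s
      while (e < n_snp && flagged[e + 1]) e <- e + 1
      out[[length(out) + 1]] <- data.frame(start_idx = s, end_idx = e)
      s <- e + 1
    } else {
      s <- s + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_idx = integer(), end_idx = integer()))
  }
  do.call(rbind, out)
}

# Random per-patient run set on a grid of n_snp SNPs. Runs of one patient and
# direction are kept disjoint, as maximal runs from a single track always are.
random_runs <- function(n_patients, n_snp, n_runs, min_len = 5, max_len = 60) {
  taken <- list()
  rows <- list()
  for (i in seq_len(n_runs)) {
    len <- sample(min_len:max_len, 1)
    start <- sample(seq_len(n_snp - len + 1), 1)
    patient <- sprintf("P%03d", sample(n_patients, 1))
    direction <- sample(c("gain", "loss"), 1)
    key <- paste(patient, direction)
    occupied <- taken[[key]]
    if (is.null(occupied)) occupied <- logical(n_snp)
    span <- start:(start + len - 1)
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    taken[[key]] <- occupied
    rows[[length(rows) + 1]] <- data.frame(
      patient = patient, chrom = "1", start_idx = start,
      end_idx = start + len - 1, direction = direction)
  }
  do.call(rbind, rows)
}

# A minimal hand-built cohort for targeted tests.
tiny_cohort <- function(normal, tumor, cn = NULL, chrom = NULL, pos = NULL) {
  s <- nrow(normal)
  if (is.null(chrom)) chrom <- rep("1", s)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(s), chrom, FUN = seq_along) * 100L
  }
  annot <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(s)), chrom = chrom, pos = as.integer(pos),
    allele_major = rep("A", s), allele_minor = rep("G", s))
  if (is.null(colnames(normal))) {
    colnames(normal) <- sprintf("P%03d", seq_len(ncol(normal)))
    colnames(tumor) <- colnames(normal)
    if (!is.null(cn)) colnames(cn) <- colnames(normal)
  }
  paired_cohort(normal, tumor, cn, annot)
}
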