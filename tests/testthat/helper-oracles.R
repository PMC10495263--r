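library(GenomicRanges)

# --- independent oracles ----------------------------------------------------

# O(n^2) repeated-pairwise-merge oracle for interval merging (0-based
# half-open data.frame in, same out). Joins any two intervals on the same
# chromosome whose gap (next.start - prev.end) is <= max_gap, until a
# fixed point is reached.
brute_merge <- function(df, max_gap) {
  repeat {
    n <- nrow(df)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i == j || merged) next
        if (df$chrom[i] != df$chrom[j]) next
        gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
        if (gap <= max_gap) {
          new_row <- data.frame(chrom = df$chrom[i],
                                start = min(df$start[i], df$start[j]),
                                end = max(df$end[i], df$end[j]))
          df <- rbind(df[-c(i, j), ], new_row)
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# direct-summation chi-square oracle
brute_chisq <- function(o) {
  n <- sum(o)
  e <- matrix(0, nrow(o), ncol(o))
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) e[i, j] <- sum(o[i, ]) * sum(o[, j]) / n
  }
  chi2 <- 0
  res <- e
  for (i in seq_len(nrow(o))) {
    for (j in seq_len(ncol(o))) {
      chi2 <- chi2 + (o[i, j] - e[i, j])^2 / e[i, j]
      res[i, j] <- (o[i, j] - e[i, j]) / sqrt(e[i, j])
    }
  }
  list(chi2 = chi2, dof = (nrow(o) - 1) * (ncol(o) - 1), residuals = res)
}

# O(n*m) pairwise sharing classification oracle
brute_sharing <- function(wt, dko) {
  lab_wt <- rep("unique_WT", nrow(wt))
  lab_dko <- rep("unique_dKO", nrow(dko))
  for (i in seq_len(nrow(wt))) {
    for (j in seq_len(nrow(dko))) {
      if (wt$chrom[i] == dko$chrom[j] &&
          wt$bait_bin[i] == dko$bait_bin[j] &&
          wt$distal_bin[i] == dko$distal_bin[j]) {
        lab_wt[i] <- "shared"
        lab_dko[j] <- "shared"
      }
    }
  }
  list(wt = lab_wt, dko = lab_dko)
}

# --- fixtures ----------------------------------------------------------------

random_interval_df <- function(n, chroms = c("chr1", "chr2"), span = 1e5,
                               max_width = 5e3) {
  start <- floor(runif(n, 0, span))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + floor(runif(n, 1, max_width)))
}

df_to_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1, df$end))
}

gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1,
                   end = end(gr))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

constant_track <- function(chrom = "chr1", start0 = 0, end0 = 1e5, value = 1) {
  GRanges(chrom, IRanges(start0 + 1, end0), score = value)
}

random_loops <- function(n, n_bins = 100, chrom = "chr1") {
  b <- sample.int(n_bins, n, replace = TRUE) - 1L
  d <- (b + sample.int(n_bins - 1, n, replace = TRUE)) %% n_bins
  dt <- data.table::data.table(chrom = chrom, bait_bin = b, distal_bin = d,
                               score = runif(n, 5, 30))
  unique(dt, by = c("chrom", "bait_bin", "distal_bin"))
}
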