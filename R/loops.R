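#' Read promoter-anchored loops from an interactBED-like TSV
#'
#' Expected tab-separated columns (with header): `chrom`, `start`, `end`
#' (bait bin span, 0-based half-open), `target_chrom`, `target_start`,
#' `target_end` (distal bin span), `score`. Anchor spans must align to the
#' bin grid. The bait is always the promoter-side anchor
#' (promoter-capture asymmetry).
#'
#' @param path File path.
#' @param condition Condition label attached to every loop (e.g. `"WT"`).
#' @param bin_size Bin width in bp (default 10000).
#' @return A `data.table` with columns `chrom`, `bait_bin`, `distal_bin`,
#'   `score`, `condition`.
#' @export
read_loops <- function(path, condition, bin_size = 10000) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  tab <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "target_chrom", "target_start",
            "target_end", "score")
  missing <- setdiff(need, names(tab))
  .assert(length(missing) == 0,
          sprintf("loop table lacks columns: %s", paste(missing, collapse = ", ")))
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$score))))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-numeric loop score '%s'",
                 path, bad[1], tab$score[bad[1]]), call. = FALSE)
  }
  .assert(all(tab$start %% bin_size == 0) && all(tab$target_start %% bin_size == 0),
          sprintf("loop anchors are not aligned to the %d bp bin grid", bin_size))
  loops <- data.table(
    chrom = as.character(tab$chrom),
    bait_bin = as.integer(tab$start %/% bin_size),
    distal_bin = as.integer(tab$target_start %/% bin_size),
    score = as.numeric(tab$score),
    condition = condition
  )
  .assert(all(tab$target_chrom == tab$chrom),
          "trans-chromosomal loops are not supported")
  .assert(all(loops$bait_bin != loops$distal_bin),
          "loop with identical bait and distal bin")
  loops
}

#' Write loops to an interactBED-like TSV
#'
#' @param loops Loop `data.table` (see [read_loops]).
#' @param path Output path.
#' @param bin_size Bin width in bp (default 10000).
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path, bin_size = 10000) {
  out <- data.table(
    chrom = loops$chrom,
    start = loops$bait_bin * bin_size,
    end = (loops$bait_bin + 1) * bin_size,
    target_chrom = loops$chrom,
    target_start = loops$distal_bin * bin_size,
    target_end = (loops$distal_bin + 1) * bin_size,
    score = .fmt_num(loops$score)
  )
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter loops on interaction score
#'
#' Retains loops with `score >= min_score` (inclusive; the CHiCAGO-style
#' significance convention). Conditions are filtered independently.
#'
#' @param loops Loop `data.table`.
#' @param min_score Minimum retained score (default 5).
#' @return The retained subset.
#' @export
filter_loops <- function(loops, min_score = 5) {
  l <- as.data.table(loops)
  .assert(is.numeric(l$score), "loop scores must be numeric")
  l[l$score >= min_score, ][]
}

#' Label loops as shared or condition-unique
#'
#' At fixed binning, "both ends overlap" reduces to exact equality of the
#' (chromosome, bait bin, distal bin) triple; a loop is `shared` when the
#' identical triple exists in the other condition, otherwise `unique_WT` /
#' `unique_dKO`. Counts satisfy `|WT| = shared_WT + unique_WT` and
#' `|dKO| = shared_dKO + unique_dKO`.
#'
#' @param wt_loops,dko_loops Filtered loop `data.table`s for each condition.
#' @return A list with `loops` (both sets row-bound, with a `sharing`
#'   column) and `counts` (named totals: `wt`, `dko`, `shared_wt`,
#'   `shared_dko`, `shared_pairs`, `unique_wt`, `unique_dko`).
#' @export
classify_sharing <- function(wt_loops, dko_loops) {
  wt <- as.data.table(wt_loops)
  dko <- as.data.table(dko_loops)
  key_wt <- paste(wt$chrom, wt$bait_bin, wt$distal_bin)
  key_dko <- paste(dko$chrom, dko$bait_bin, dko$distal_bin)
  .assert(!anyDuplicated(key_wt) && !anyDuplicated(key_dko),
          "duplicate (bait, distal) pair within a condition")
  wt$sharing <- ifelse(key_wt %in% key_dko, "shared", "unique_WT")
  dko$sharing <- ifelse(key_dko %in% key_wt, "shared", "unique_dKO")
  wt$condition <- "WT"
  dko$condition <- "dKO"
  counts <- c(
    wt = nrow(wt), dko = nrow(dko),
    shared_wt = sum(wt$sharing == "shared"),
    shared_dko = sum(dko$sharing == "shared"),
    shared_pairs = sum(wt$sharing == "shared"),
    unique_wt = sum(wt$sharing == "unique_WT"),
    unique_dko = sum(dko$sharing == "unique_dKO")
  )
  list(loops = rbind(wt, dko), counts = counts)
}

#' Fraction of unique loops explained by a one-bin distal shift
#'
#' A condition-unique loop is "shifted" when the other condition has a
#' unique loop with the same chromosome and bait bin whose distal bin
#' differs by exactly one. Partners are consumed at most once by greedy
#' matching over loops sorted by (chromosome, bait, distal); a lower
#' distal partner is preferred when both neighbours are free.
#'
#' @param labelled Output `$loops` of [classify_sharing].
#' @return A list with `fraction_wt`, `fraction_dko` (0 with
#'   `defined = FALSE` when a condition has no unique loops), `n_matched`,
#'   and the matched pair table `pairs`.
#' @export
adjacent_shift_fraction <- function(labelled) {
  l <- as.data.table(labelled)
  uw <- l[l$sharing == "unique_WT", ]
  ud <- l[l$sharing == "unique_dKO", ]
  data.table::setorder(uw, chrom, bait_bin, distal_bin)
  data.table::setorder(ud, chrom, bait_bin, distal_bin)
  used <- rep(FALSE, nrow(ud))
  ud_key <- paste(ud$chrom, ud$bait_bin, ud$distal_bin)
  match_of <- integer(0)
  wt_matched <- integer(0)
  for (i in seq_len(nrow(uw))) {
    for (delta in c(-1L, 1L)) {
      k <- paste(uw$chrom[i], uw$bait_bin[i], uw$distal_bin[i] + delta)
      j <- which(ud_key == k & !used)
      if (length(j)) {
        used[j[1]] <- TRUE
        wt_matched <- c(wt_matched, i)
        match_of <- c(match_of, j[1])
        break
      }
    }
  }
  n_matched <- length(wt_matched)
  pairs <- if (n_matched) {
    data.table(chrom = uw$chrom[wt_matched],
               bait_bin = uw$bait_bin[wt_matched],
               distal_wt = uw$distal_bin[wt_matched],
               distal_dko = ud$distal_bin[match_of])
  } else {
    data.table(chrom = character(), bait_bin = integer(),
               distal_wt = integer(), distal_dko = integer())
  }
  list(
    fraction_wt = if (nrow(uw)) n_matched / nrow(uw) else 0,
    fraction_dko = if (nrow(ud)) n_matched / nrow(ud) else 0,
    defined = nrow(uw) > 0 && nrow(ud) > 0,
    n_matched = n_matched,
    pairs = pairs
  )
}

#' Functional enrichment at distal loop ends
#'
#' Observed statistic: fraction of distal bins overlapping at least one
#' feature interval. The null redraws each loop's distal bin uniformly
#' among all bins of its chromosome `n_shuffles` times; fold enrichment is
#' observed over the null mean, with a one-sided empirical permutation p
#' (`(1 + #null >= obs) / (1 + n_shuffles)`).
#'
#' @param loops Loop `data.table`.
#' @param feature_sets Named list of `GRanges` feature sets (e.g. open
#'   chromatin, active enhancers).
#' @param n_bins Named vector: number of bins per chromosome.
#' @param bin_size Bin width in bp (default 10000).
#' @param n_shuffles Number of null redraws (default 1000; a warning is
#'   issued below 100).
#' @param seed Integer RNG seed.
#' @return A `data.frame` with one row per feature set: `observed`,
#'   `null_mean`, `fold`, `p`.
#' @export
annotate_distal_ends <- function(loops, feature_sets, n_bins,
                                 bin_size = 10000, n_shuffles = 1000,
                                 seed = 1) {
  if (n_shuffles < 100) warning("fewer than 100 shuffles: permutation p is coarse")
  l <- as.data.table(loops)
  .assert(all(l$chrom %in% names(n_bins)), "n_bins must cover every loop chromosome")
  res <- withr::with_seed(seed, {
    lapply(names(feature_sets), function(nm) {
      feats <- feature_sets[[nm]]
      hit_frac <- function(bins, chroms) {
        gr <- bins_to_granges(chroms, bins, bin_size)
        hits <- unique(queryHits(findOverlaps(gr, granges(feats),
                                              ignore.strand = TRUE)))
        length(hits) / length(gr)
      }
      obs <- hit_frac(l$distal_bin, l$chrom)
      null <- vapply(seq_len(n_shuffles), function(s) {
        rb <- floor(runif(nrow(l)) * n_bins[l$chrom])
        hit_frac(as.integer(rb), l$chrom)
      }, numeric(1))
      data.frame(feature = nm, observed = obs, null_mean = mean(null),
                 fold = if (mean(null) > 0) obs / mean(null) else NA_real_,
                 p = (1 + sum(null >= obs)) / (1 + n_shuffles))
    })
  })
  do.call(rbind, res)
}

#' Aggregate loop counts per gene over its bait bins
#'
#' Promoter-capture panels use multiple baits per gene (alternative
#' promoters); the loop count of a gene is the number of retained loops
#' over all bait bins mapped to it, per condition. A bait serving several
#' genes contributes its loops to each. Loops at baits with no gene
#' mapping are totalled in the `unassigned` bucket.
#'
#' @param loops Loop `data.table` with a `condition` column (values `"WT"`
#'   and `"dKO"`).
#' @param bait_map `data.table` with columns `chrom`, `bait_bin`,
#'   `gene_id` (many-to-many).
#' @param gene_ids Optional character vector of genes to report (zero
#'   counts for genes without loops); defaults to genes present in
#'   `bait_map`.
#' @return A list with `genes` (`data.table`: `gene_id`, `count_wt`,
#'   `count_dko`, `net_change`) and `unassigned` (named vector of loop
#'   totals at unmapped baits).
#' @export
gene_loop_counts <- function(loops, bait_map, gene_ids = NULL) {
  l <- as.data.table(loops)
  bm <- as.data.table(bait_map)
  .assert(all(c("chrom", "bait_bin", "gene_id") %in% names(bm)),
          "bait_map needs chrom, bait_bin, gene_id")
  gene_ids <- gene_ids %||% unique(bm$gene_id)
  merged <- merge(l, bm, by = c("chrom", "bait_bin"),
                  allow.cartesian = TRUE)
  counts <- merged[, list(n = .N), by = c("gene_id", "condition")]
  wide <- data.table(gene_id = gene_ids,
                     count_wt = 0L, count_dko = 0L)
  cw <- counts[counts$condition == "WT" & counts$gene_id %in% gene_ids, ]
  cd <- counts[counts$condition == "dKO" & counts$gene_id %in% gene_ids, ]
  wide$count_wt[match(cw$gene_id, wide$gene_id)] <- cw$n
  wide$count_dko[match(cd$gene_id, wide$gene_id)] <- cd$n
  wide$net_change <- wide$count_dko - wide$count_wt
  mapped_keys <- unique(paste(bm$chrom, bm$bait_bin))
  un <- l[!paste(l$chrom, l$bait_bin) %in% mapped_keys, ]
  unassigned <- c(wt = sum(un$condition == "WT"),
                  dko = sum(un$condition == "dKO"))
  list(genes = wide[], unassigned = unassigned)
}
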