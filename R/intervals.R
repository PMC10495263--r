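#' Validate a set of genomic intervals
#'
#' Checks the invariants every coordinate-carrying object in the package
#' relies on: positive widths and non-empty chromosome names. Intervals are
#' held as [GenomicRanges::GRanges] (1-based closed in memory; all on-disk
#' BED/bedGraph I/O converts from/to 0-based half-open).
#'
#' @param x A `GRanges` object.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending record.
#' @export
validate_intervals <- function(x, what = "interval") {
  .assert(methods::is(x, "GRanges"),
          sprintf("%s set must be a GRanges object", what))
  bad <- which(width(x) < 1L)
  if (length(bad)) {
    stop(sprintf("malformed %s at record %d: %s:%d-%d (end <= start)",
                 what, bad[1], as.character(seqnames(x))[bad[1]],
                 start(x)[bad[1]] - 1L, end(x)[bad[1]]), call. = FALSE)
  }
  bad <- which(as.character(seqnames(x)) == "")
  if (length(bad)) {
    stop(sprintf("malformed %s at record %d: empty chromosome name",
                 what, bad[1]), call. = FALSE)
  }
  invisible(x)
}

#' Merge intervals closer than a maximum gap
#'
#' Two intervals on the same chromosome are joined when the gap between them
#' (next start minus previous end, in bp on the 0-based half-open scale) is
#' at most `max_gap`. Touching intervals (gap 0) always merge. Strand is
#' ignored.
#'
#' @param x A `GRanges` of intervals to merge.
#' @param max_gap Maximum joinable gap in bp (`>= 0`). `max_gap = 25000` is
#'   the domain-merge distance used for macroH2A chromatin domains.
#' @return A sorted, strand-less `GRanges` of non-overlapping merged
#'   intervals.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 20001), c(100, 20100)))
#' merge_intervals(gr, max_gap = 25000)
#' @export
merge_intervals <- function(x, max_gap) {
  .assert(is.numeric(max_gap) && length(max_gap) == 1 && max_gap >= 0,
          "max_gap must be a single non-negative number")
  validate_intervals(x)
  # 0-based gap == 1-based gapwidth; reduce() merges when gapwidth < min.gapwidth
  # (and returns its result sorted)
  reduce(granges(x), min.gapwidth = max_gap + 1, ignore.strand = TRUE)
}

#' Stitch peaks with an optional TSS exclusion zone
#'
#' ROSE-style element stitching: peaks fully contained inside any
#' `[tss - exclusion_halfwidth, tss + exclusion_halfwidth)` window are
#' removed, then the survivors are merged with `max_gap = stitch_distance`.
#' Partial overlaps with the exclusion window are kept (ROSE behaviour).
#' `exclusion_halfwidth = 0` disables exclusion, the mode used when ranking
#' macroH2A domains ("no TSS exclusion").
#'
#' @param peaks A `GRanges` of peaks.
#' @param tss TSS positions: a `GRanges` (width-1 anchors; wider ranges are
#'   resolved to their strand-aware start) or a data.frame with columns
#'   `chrom` and `pos` (0-based).
#' @param stitch_distance Stitching distance in bp (default 12500).
#' @param exclusion_halfwidth Half-width of the TSS exclusion zone in bp
#'   (default 2500).
#' @return A merged `GRanges`.
#' @export
stitch_with_tss_exclusion <- function(peaks, tss = NULL,
                                      stitch_distance = 12500,
                                      exclusion_halfwidth = 2500) {
  .assert(is.numeric(stitch_distance) && stitch_distance >= 0,
          "stitch_distance must be non-negative")
  .assert(is.numeric(exclusion_halfwidth) && exclusion_halfwidth >= 0,
          "exclusion_halfwidth must be non-negative")
  validate_intervals(peaks, "peak")
  keep <- peaks
  if (exclusion_halfwidth > 0 && !is.null(tss)) {
    anchors <- tss_anchors(tss)
    if (length(anchors)) {
      # 0-based window [t - hw, t + hw)  <=>  1-based [t1 - hw, t1 + hw - 1]
      win <- GRanges(seqnames(anchors),
                     IRanges(pmax(1L, start(anchors) - as.integer(exclusion_halfwidth)),
                             start(anchors) + as.integer(exclusion_halfwidth) - 1L))
      inside <- unique(queryHits(findOverlaps(granges(keep), win,
                                              type = "within",
                                              ignore.strand = TRUE)))
      if (length(inside)) keep <- keep[-inside]
    }
  }
  merge_intervals(keep, max_gap = stitch_distance)
}

# Resolve a TSS specification to width-1 GRanges anchors (1-based).
tss_anchors <- function(tss) {
  if (is.null(tss)) return(GRanges())
  if (methods::is(tss, "GRanges")) {
    if (!length(tss)) return(GRanges())
    pos <- ifelse(as.character(strand(tss)) == "-", end(tss), start(tss))
    return(GRanges(seqnames(tss), IRanges(pos, pos)))
  }
  df <- as.data.frame(tss)
  .assert(all(c("chrom", "pos") %in% names(df)),
          "tss must be a GRanges or a data.frame with columns chrom, pos")
  if (!nrow(df)) return(GRanges())
  GRanges(df$chrom, IRanges(df$pos + 1L, df$pos + 1L))
}

#' Map intervals to fixed-size genomic bins
#'
#' Every bin `b` whose half-open span `[b * bin_size, (b + 1) * bin_size)`
#' (0-based) intersects an interval is reported. The number of bins per
#' interval equals `ceil(end / bin_size) - floor(start / bin_size)` on the
#' 0-based scale.
#'
#' @param x A `GRanges`.
#' @param bin_size Bin width in bp (`> 0`; loop analyses use 10000).
#' @return A `data.table` with columns `interval` (index into `x`), `chrom`
#'   and `bin` (0-based bin index).
#' @export
interval_to_bins <- function(x, bin_size) {
  .assert(is.numeric(bin_size) && length(bin_size) == 1 && bin_size > 0,
          "bin_size must be a single positive number")
  validate_intervals(x)
  if (!length(x)) {
    return(data.table(interval = integer(), chrom = character(), bin = integer()))
  }
  first <- (start(x) - 1L) %/% as.integer(bin_size)
  last <- (end(x) - 1L) %/% as.integer(bin_size)
  n <- last - first + 1L
  data.table(
    interval = rep(seq_along(x), n),
    chrom = rep(as.character(seqnames(x)), n),
    bin = unlist(lapply(seq_along(x), function(i) seq(first[i], last[i])),
                 use.names = FALSE)
  )
}

# 0-based position -> bin index
position_to_bin <- function(pos0, bin_size) as.integer(pos0 %/% bin_size)

# bin indices -> GRanges of bin spans
bins_to_granges <- function(chrom, bin, bin_size) {
  GRanges(chrom, IRanges(bin * bin_size + 1L, (bin + 1L) * bin_size))
}

#' Read genomic intervals or a signal track from BED/bedGraph
#'
#' Thin, validating wrapper around [rtracklayer::import]. Files are
#' pre-scanned so that malformed records (non-numeric coordinates,
#' `end <= start`, negative starts) are reported with their line number,
#' which `rtracklayer` alone does not do. Chromosome naming is not
#' validated against any assembly.
#'
#' @param path File path.
#' @param format `"bed"` (intervals; BED3/BED6) or `"bedgraph"`
#'   (a signal track: sorted non-overlapping intervals with a numeric
#'   `score`).
#' @return A `GRanges`; bedGraph input carries the track value in the
#'   `score` metadata column.
#' @export
read_regions <- function(path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  .assert(file.exists(path), sprintf("file not found: %s", path))
  tab <- fread(path, header = FALSE, sep = "\t")
  if (nrow(tab)) {
    .assert(ncol(tab) >= 3, sprintf("%s: fewer than 3 columns", path))
    s <- suppressWarnings(as.numeric(tab[[2]]))
    e <- suppressWarnings(as.numeric(tab[[3]]))
    bad <- which(is.na(s) | is.na(e) | s < 0 | e <= s)
    if (length(bad)) {
      stop(sprintf("%s line %d: invalid interval (start=%s end=%s)",
                   path, bad[1], tab[[2]][bad[1]], tab[[3]][bad[1]]),
           call. = FALSE)
    }
    if (format == "bedgraph") {
      v <- suppressWarnings(as.numeric(tab[[4]]))
      bad <- which(is.na(v))
      if (length(bad)) {
        stop(sprintf("%s line %d: non-numeric bedGraph value", path, bad[1]),
             call. = FALSE)
      }
    }
  }
  fmt <- if (format == "bedgraph") "bedGraph" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  sort(gr, ignore.strand = TRUE)
}

#' Write intervals or a signal track to BED/bedGraph
#'
#' Counterpart of [read_regions]; `write_regions(read_regions(f))` is the
#' identity on canonical records.
#'
#' @param x A `GRanges`; for bedGraph output it must carry a numeric
#'   `score` column.
#' @param path Output path.
#' @param format `"bed"` or `"bedgraph"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  validate_intervals(x)
  if (format == "bedgraph") {
    .assert(!is.null(x$score) && is.numeric(x$score),
            "bedGraph output requires a numeric score column")
    rtracklayer::export(x, path, format = "bedGraph")
  } else {
    rtracklayer::export(x, path, format = "bed")
  }
  invisible(path)
}

#' Validate a signal track
#'
#' A signal track is a `GRanges` with a non-negative numeric `score`,
#' sorted and non-overlapping within each chromosome (bedGraph semantics).
#' Uncovered bases have implicit signal 0.
#'
#' @param track A `GRanges` with `score`.
#' @return `track`, invisibly.
#' @export
validate_track <- function(track) {
  validate_intervals(track, "track interval")
  .assert(!is.null(track$score) && is.numeric(track$score),
          "signal track must carry a numeric score column")
  .assert(all(track$score >= 0), "signal track values must be non-negative")
  ch <- as.character(seqnames(track))
  o <- order(ch, start(track))
  same <- ch[o][-1] == ch[o][-length(o)]
  if (any(same & start(track)[o][-1] <= end(track)[o][-length(o)])) {
    stop("signal track intervals overlap within a chromosome", call. = FALSE)
  }
  invisible(track)
}

# Piecewise-constant coverage of a track as an RleList keyed by chromosome.
# chrom_lengths: named vector; defaults to max end per chromosome.
track_coverage <- function(track, chrom_lengths = NULL) {
  gr <- track
  if (is.null(chrom_lengths)) {
    ends <- tapply(end(gr), as.character(seqnames(gr)), max)
    chrom_lengths <- setNames(as.numeric(ends), names(ends))
  }
  gr <- GenomeInfoDb::keepSeqlevels(
    gr, intersect(seqlevels(gr), names(chrom_lengths)), pruning.mode = "coarse")
  seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
  coverage(gr, weight = gr$score)
}

# Overlap-run boundaries of queries against a SORTED, NON-OVERLAPPING
# subject (both 1-based closed, same chromosome). Query i overlaps
# subjects lo[i]..hi[i] (none when hi < lo).
.sorted_runs <- function(qs, qe, ss, se) {
  list(lo = findInterval(qs - 0.5, se) + 1L,
       hi = findInterval(qe + 0.5, ss))
}

# Total signal (value x covered bp) of `x` intervals over a signal track
# (sorted non-overlapping intervals), vectorized per chromosome.
signal_over_track <- function(x, track) {
  out <- numeric(length(x))
  if (!length(x) || !length(track)) return(out)
  xc <- as.character(seqnames(x)); tc <- as.character(seqnames(track))
  ts <- start(track); te <- end(track); sc <- track$score
  for (ch in unique(xc)) {
    qi <- which(xc == ch); si <- which(tc == ch)
    if (!length(si)) next
    o <- si[order(ts[si])]
    ss <- ts[o]; se <- te[o]; sco <- sc[o]
    cw <- c(0, cumsum((se - ss + 1) * sco))
    qs <- start(x)[qi]; qe <- end(x)[qi]
    r <- .sorted_runs(qs, qe, ss, se)
    ok <- r$hi >= r$lo
    tot <- numeric(length(qi))
    if (any(ok)) {
      l <- r$lo[ok]; h <- r$hi[ok]
      tot[ok] <- (cw[h + 1] - cw[l]) -
        pmax(0, qs[ok] - ss[l]) * sco[l] -
        pmax(0, se[h] - qe[ok]) * sco[h]
    }
    out[qi] <- tot
  }
  out
}

# TRUE for each query interval overlapping any subject interval (subject
# non-overlapping within chromosomes).
overlaps_any <- function(x, subject) {
  out <- logical(length(x))
  if (!length(x) || !length(subject)) return(out)
  xc <- as.character(seqnames(x)); sc <- as.character(seqnames(subject))
  ss_all <- start(subject); se_all <- end(subject)
  for (ch in unique(xc)) {
    qi <- which(xc == ch); si <- which(sc == ch)
    if (!length(si)) next
    o <- si[order(ss_all[si])]
    r <- .sorted_runs(start(x)[qi], end(x)[qi], ss_all[o], se_all[o])
    out[qi] <- r$hi >= r$lo
  }
  out
}

# Indices of subject intervals (non-overlapping within chromosomes) hit by
# at least one query interval.
subjects_hit <- function(x, subject) {
  if (!length(x) || !length(subject)) return(integer(0))
  xc <- as.character(seqnames(x)); sc <- as.character(seqnames(subject))
  ss_all <- start(subject); se_all <- end(subject)
  hit <- logical(length(subject))
  for (ch in unique(xc)) {
    qi <- which(xc == ch); si <- which(sc == ch)
    if (!length(si)) next
    o <- si[order(ss_all[si])]
    r <- .sorted_runs(start(x)[qi], end(x)[qi], ss_all[o], se_all[o])
    ok <- which(r$hi >= r$lo)
    if (length(ok)) {
      counts <- r$hi[ok] - r$lo[ok] + 1L
      hit[o[sequence(counts) + rep(r$lo[ok] - 1L, counts)]] <- TRUE
    }
  }
  which(hit)
}

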