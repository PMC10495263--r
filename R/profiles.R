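# Per-region binned mean signal matrix from a coverage RleList.
# starts/ends are 1-based inclusive per-bin boundaries computed by callers.
.bin_means <- function(cov, chrom, starts, ends) {
  out <- rep(0, length(starts))
  if (!chrom %in% names(cov)) return(out)
  rle <- cov[[chrom]]
  n <- length(rle)
  s <- pmax(1L, pmin(as.integer(starts), n))
  e <- pmax(1L, pmin(as.integer(ends), n))
  ok <- starts <= n & ends >= 1 & s <= e
  if (any(ok)) {
    out[ok] <- viewMeans(Views(rle, start = s[ok], end = e[ok]))
  }
  out
}

# percentile bootstrap CI of the column means of a region x bin matrix
.bootstrap_ci <- function(mat, B, seed, level = 0.95) {
  n <- nrow(mat)
  a <- (1 - level) / 2
  if (n == 1) {
    return(list(lo = mat[1, ], hi = mat[1, ]))
  }
  boot <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    t(apply(idx, 1, function(i) colMeans(mat[i, , drop = FALSE])))
  })
  list(lo = apply(boot, 2, quantile, probs = a, names = FALSE),
       hi = apply(boot, 2, quantile, probs = 1 - a, names = FALSE))
}

#' Metagene profile with bootstrap confidence band
#'
#' Each gene body is rescaled to `body_bins` bins (per-bin mean of covered
#' signal, uncovered bases counting 0), with fixed-width flanking bins of
#' `flank_bp / flank_bins` bp on both sides. Minus-strand genes are
#' reversed so that bin 1 is always the TSS side. The profile is the mean
#' over genes per bin; the confidence band is the percentile bootstrap
#' (2.5/97.5) over `bootstrap_B` gene resamples. Genes shorter than
#' `body_bins` bp are included (adjacent bins then share base pairs) and
#' flagged.
#'
#' @param track Signal track (`GRanges` with `score`).
#' @param genes `GRanges` of gene bodies with strand.
#' @param body_bins Bins across the gene body (default 100).
#' @param flank_bp Flank length in bp (default 2000).
#' @param flank_bins Bins per flank (default 20).
#' @param bootstrap_B Bootstrap resamples (default 1000).
#' @param seed Integer RNG seed for the bootstrap.
#' @return A list with `profile` (`data.frame`: `bin`, `region`, `mean`,
#'   `lo`, `hi`), `matrix` (gene x bin), `short_genes` (indices).
#' @export
metagene_profile <- function(track, genes, body_bins = 100, flank_bp = 2000,
                             flank_bins = 20, bootstrap_B = 1000, seed = 1) {
  validate_track(track)
  .assert(length(genes) >= 1, "need at least one gene")
  cov <- track_coverage(track)
  nb <- 2 * flank_bins + body_bins
  chroms <- as.character(seqnames(genes))
  mat <- matrix(0, nrow = length(genes), ncol = nb)
  flank_w <- if (flank_bins > 0) flank_bp / flank_bins else 0
  short <- which(width(genes) < body_bins)
  for (i in seq_along(genes)) {
    s <- start(genes)[i]; e <- end(genes)[i]
    # body bin boundaries (1-based inclusive)
    bs <- floor(s + (seq_len(body_bins) - 1) / body_bins * (e - s + 1))
    be <- c(bs[-1] - 1, e)
    be <- pmax(be, bs)
    if (flank_bins > 0) {
      ls <- s - flank_bp + (seq_len(flank_bins) - 1) * flank_w
      le <- ls + flank_w - 1
      rs <- e + 1 + (seq_len(flank_bins) - 1) * flank_w
      re <- rs + flank_w - 1
      starts <- c(ls, bs, rs); ends <- c(le, be, re)
    } else {
      starts <- bs; ends <- be
    }
    v <- .bin_means(cov, chroms[i], starts, ends)
    if (as.character(strand(genes))[i] == "-") v <- rev(v)
    mat[i, ] <- v
  }
  ci <- .bootstrap_ci(mat, bootstrap_B, seed)
  region <- c(rep("upstream", flank_bins), rep("body", body_bins),
              rep("downstream", flank_bins))
  list(profile = data.frame(bin = seq_len(nb), region = region,
                            mean = colMeans(mat), lo = ci$lo, hi = ci$hi),
       matrix = mat, short_genes = short)
}

#' Point-centered average signal profile
#'
#' Windows of `+-halfwidth` bp around each center position are cut into
#' fixed `bin` bp bins; the profile is the per-bin mean over regions with
#' a percentile-bootstrap confidence band, as in [metagene_profile].
#'
#' @param track Signal track.
#' @param centers `GRanges` of center points (midpoints are used for
#'   wider ranges).
#' @param halfwidth Window half-width in bp (default 5000).
#' @param bin Bin width in bp (default 50).
#' @param bootstrap_B Bootstrap resamples (default 1000).
#' @param seed Integer RNG seed.
#' @return As [metagene_profile]; `profile$pos` gives the bin center
#'   offset from the region center in bp.
#' @export
centered_profile <- function(track, centers, halfwidth = 5000, bin = 50,
                             bootstrap_B = 1000, seed = 1) {
  validate_track(track)
  .assert(length(centers) >= 1, "need at least one center")
  cov <- track_coverage(track)
  nb <- as.integer(2 * halfwidth / bin)
  .assert(nb >= 1, "halfwidth must cover at least one bin")
  mid <- (start(centers) + end(centers)) %/% 2
  chroms <- as.character(seqnames(centers))
  offs <- (seq_len(nb) - 1) * bin - halfwidth
  mat <- matrix(0, nrow = length(centers), ncol = nb)
  for (i in seq_along(centers)) {
    starts <- mid[i] + offs
    mat[i, ] <- .bin_means(cov, chroms[i], starts, starts + bin - 1)
  }
  ci <- .bootstrap_ci(mat, bootstrap_B, seed)
  list(profile = data.frame(bin = seq_len(nb), pos = offs + bin / 2,
                            mean = colMeans(mat), lo = ci$lo, hi = ci$hi),
       matrix = mat)
}

#' Genome-binned Pearson correlation between two signal tracks
#'
#' The genome is tiled at `bin_bp`; per-bin mean signal is computed for
#' both tracks and the Pearson correlation taken over bins where at least
#' one track is non-zero (all-zero bins carry no information about either
#' assay).
#'
#' @param track_a,track_b Signal tracks on the same chromosome set.
#' @param bin_bp Tile width in bp (default 1000).
#' @return Pearson correlation coefficient.
#' @export
track_correlation <- function(track_a, track_b, bin_bp = 1000) {
  validate_track(track_a); validate_track(track_b)
  chroms <- union(as.character(unique(seqnames(track_a))),
                  as.character(unique(seqnames(track_b))))
  len <- setNames(numeric(length(chroms)), chroms)
  for (tr in list(track_a, track_b)) {
    ends <- tapply(end(tr), as.character(seqnames(tr)), max)
    len[names(ends)] <- pmax(len[names(ends)], ends)
  }
  cov_a <- track_coverage(track_a, len)
  cov_b <- track_coverage(track_b, len)
  va <- vb <- numeric(0)
  for (ch in chroms) {
    nb <- ceiling(len[ch] / bin_bp)
    starts <- (seq_len(nb) - 1) * bin_bp + 1
    ends <- pmin(starts + bin_bp - 1, len[ch])
    va <- c(va, .bin_means(cov_a, ch, starts, ends))
    vb <- c(vb, .bin_means(cov_b, ch, starts, ends))
  }
  keep <- va != 0 | vb != 0
  va <- va[keep]; vb <- vb[keep]
  .assert(length(va) >= 2, "fewer than 2 informative bins")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero-variance track: correlation undefined", call. = FALSE)
  }
  cor(va, vb)
}
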