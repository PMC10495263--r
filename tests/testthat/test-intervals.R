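test_that("merge_intervals joins intervals within the gap and rejects bad input", {
  expect_length(merge_intervals(GRanges(), 25000), 0)

  gr <- df_to_gr(data.frame(chrom = "chr1", start = c(0, 20000),
                            end = c(100, 20100)))
  out <- gr_to_df(merge_intervals(gr, 25000))
  expect_equal(out$start, 0)
  expect_equal(out$end, 20100)

  far <- df_to_gr(data.frame(chrom = "chr1", start = c(0, 30000),
                             end = c(100, 30100)))
  expect_length(merge_intervals(far, 25000), 2)  # gap 29900 > 25000

  touching <- df_to_gr(data.frame(chrom = "chr1", start = c(0, 100),
                                  end = c(100, 200)))
  expect_length(merge_intervals(touching, 0), 1)

  bad <- GRanges("chr1", IRanges(10, 9))  # zero-width: end <= start in BED terms
  expect_error(merge_intervals(bad, 0), "end <= start")
  expect_error(merge_intervals(df_to_gr(random_interval_df(3)), -1),
               "non-negative")
})

test_that("merge_intervals matches the brute-force oracle and is idempotent", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      df <- random_interval_df(sample(2:25, 1))
      gap <- sample(c(0, 10, 500, 5000, 25000), 1)
      got <- gr_to_df(merge_intervals(df_to_gr(df), gap))
      want <- brute_merge(df, gap)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
      twice <- gr_to_df(merge_intervals(merge_intervals(df_to_gr(df), gap), gap))
      rownames(twice) <- NULL
      expect_equal(twice, got)
    }
  })
})

test_that("stitching removes peaks fully inside the TSS exclusion zone", {
  # peak fully inside tss +- 2500 disappears
  peak <- df_to_gr(data.frame(chrom = "chr1", start = 1000, end = 1200))
  out <- stitch_with_tss_exclusion(peak, data.frame(chrom = "chr1", pos = 1100),
                                   12500, 2500)
  expect_length(out, 0)

  # a peak merely overlapping the zone is kept (ROSE behaviour)
  wide <- df_to_gr(data.frame(chrom = "chr1", start = 1000, end = 4000))
  expect_length(stitch_with_tss_exclusion(
    wide, data.frame(chrom = "chr1", pos = 1100), 12500, 2500), 1)

  # no TSS: behaves as a plain merge
  peaks <- df_to_gr(data.frame(chrom = "chr1", start = c(0, 10000),
                               end = c(100, 10100)))
  out <- gr_to_df(stitch_with_tss_exclusion(peaks, NULL, 12500, 2500))
  expect_equal(out$end, 10100)

  # exclusion_halfwidth = 0 disables exclusion entirely
  withr::with_seed(7, df <- random_interval_df(15))
  tss <- data.frame(chrom = df$chrom, pos = df$start + 10)
  expect_equal(
    gr_to_df(stitch_with_tss_exclusion(df_to_gr(df), tss, 12500, 0)),
    gr_to_df(merge_intervals(df_to_gr(df), 12500)))
})

test_that("interval_to_bins covers exactly the touched bins", {
  one <- interval_to_bins(df_to_gr(data.frame(chrom = "chr1", start = 0,
                                              end = 10000)), 10000)
  expect_equal(one$bin, 0L)

  straddle <- interval_to_bins(df_to_gr(data.frame(chrom = "chr1", start = 9999,
                                                   end = 10001)), 10000)
  expect_equal(straddle$bin, c(0L, 1L))

  point <- interval_to_bins(df_to_gr(data.frame(chrom = "chr1", start = 25000,
                                                end = 25001)), 10000)
  expect_equal(point$bin, 2L)

  expect_error(interval_to_bins(df_to_gr(random_interval_df(2)), 0), "positive")

  # bin count identity: ceil(end/bin) - floor(start/bin)
  withr::with_seed(9, df <- random_interval_df(50, span = 5e4, max_width = 2e4))
  bins <- interval_to_bins(df_to_gr(df), 7000)
  got <- as.vector(table(factor(bins$interval, levels = seq_len(nrow(df)))))
  expect_equal(got, ceiling(df$end / 7000) - floor(df$start / 7000))
})

test_that("BED and bedGraph round-trips are lossless and errors carry line numbers", {
  withr::with_seed(11, df <- random_interval_df(100))
  df <- df[order(df$chrom, df$start), ]
  df <- df[!duplicated(df), ]
  bed <- file.path(tempdir(), "roundtrip.bed")
  write_regions(df_to_gr(df), bed, "bed")
  back <- gr_to_df(read_regions(bed, "bed"))
  rownames(back) <- rownames(df) <- NULL
  expect_equal(back, df)

  # bedGraph with values
  bg <- file.path(tempdir(), "roundtrip.bedgraph")
  track <- GRanges("chr1", IRanges(c(1, 101), c(100, 250)),
                   score = c(2.5, 0.75))
  write_regions(track, bg, "bedgraph")
  back <- read_regions(bg, "bedgraph")
  expect_equal(start(back), start(track))
  expect_equal(back$score, track$score)

  bad <- file.path(tempdir(), "bad.bed")
  writeLines(c("chr1\t0\t100", "chr1\t500\t400"), bad)
  expect_error(read_regions(bad, "bed"), "line 2")
  expect_error(write_regions(granges(track), bg, "bedgraph"), "score")
})

test_that("signal_over_track integrates value times covered bp", {
  track <- GRanges("chr1", IRanges(c(1, 501, 2001), c(500, 1000, 3000)),
                   score = c(2, 4, 1))
  x <- GRanges(c("chr1", "chr1", "chr2"),
               IRanges(c(1, 251, 1), c(1000, 2500, 100)))
  got <- macroloop:::signal_over_track(x, track)
  expect_equal(got[1], 500 * 2 + 500 * 4)
  expect_equal(got[2], 250 * 2 + 500 * 4 + 500 * 1)
  expect_equal(got[3], 0)  # chromosome absent from track
})

test_that("validate_track rejects overlapping or negative tracks", {
  ok <- GRanges("chr1", IRanges(c(1, 11), c(10, 20)), score = c(1, 2))
  expect_silent(validate_track(ok))
  bad <- GRanges("chr1", IRanges(c(1, 5), c(10, 20)), score = c(1, 2))
  expect_error(validate_track(bad), "overlap")
  neg <- GRanges("chr1", IRanges(1, 10), score = -1)
  expect_error(validate_track(neg), "non-negative")
})
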