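mk_loops <- function(bait, distal, score = 10, chrom = "chr1") {
  data.table::data.table(chrom = chrom, bait_bin = as.integer(bait),
                         distal_bin = as.integer(distal),
                         score = rep_len(score, length(bait)))
}

test_that("filter_loops keeps scores >= 5 inclusively", {
  l <- mk_loops(c(1, 2, 3), c(10, 11, 12), score = c(5.0, 4.99, 30))
  out <- filter_loops(l)
  expect_equal(out$score, c(5.0, 30))
  expect_equal(nrow(filter_loops(l[0, ])), 0)
})

test_that("classify_sharing uses exact bin equality and conserves counts", {
  wt <- mk_loops(10, 50)
  dko <- mk_loops(10, 50)
  res <- classify_sharing(wt, dko)
  expect_equal(unname(res$counts["shared_pairs"]), 1)

  res2 <- classify_sharing(mk_loops(10, 50), mk_loops(10, 51))
  expect_equal(unname(res2$counts[c("unique_wt", "unique_dko")]), c(1, 1))

  expect_error(classify_sharing(mk_loops(c(1, 1), c(5, 5)), dko), "duplicate")
})

test_that("classify_sharing equals the brute-force oracle and is symmetric", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      wt <- random_loops(100)
      dko <- random_loops(100)
      res <- classify_sharing(wt, dko)
      oracle <- brute_sharing(wt, dko)
      got <- res$loops
      expect_equal(got$sharing[got$condition == "WT"], oracle$wt)
      expect_equal(got$sharing[got$condition == "dKO"], oracle$dko)
      # conservation: |cond| = shared + unique per condition
      expect_equal(unname(res$counts["wt"]),
                   unname(res$counts["shared_wt"] + res$counts["unique_wt"]))
      expect_equal(unname(res$counts["dko"]),
                   unname(res$counts["shared_dko"] + res$counts["unique_dko"]))
      # symmetry: swapping conditions swaps the unique labels
      swapped <- classify_sharing(dko, wt)
      expect_equal(unname(swapped$counts["unique_wt"]),
                   unname(res$counts["unique_dko"]))
    }
  })
})

test_that("adjacent_shift_fraction greedily matches one-bin distal shifts", {
  lab <- function(wt, dko) classify_sharing(wt, dko)$loops

  # same bait, distal off by one: both sides fully explained
  r <- adjacent_shift_fraction(lab(mk_loops(10, 50), mk_loops(10, 51)))
  expect_equal(r$fraction_wt, 1)
  expect_equal(r$fraction_dko, 1)

  # bait differs: no match
  r2 <- adjacent_shift_fraction(lab(mk_loops(10, 50), mk_loops(12, 51)))
  expect_equal(r2$fraction_wt, 0)

  # no unique loops at all: flagged undefined, fraction 0
  r3 <- adjacent_shift_fraction(lab(mk_loops(1, 5), mk_loops(1, 5)))
  expect_false(r3$defined)
  expect_equal(r3$fraction_wt, 0)

  # one WT loop flanked by two candidate partners: exactly one is consumed
  r4 <- adjacent_shift_fraction(lab(mk_loops(10, 50),
                                    mk_loops(c(10, 10), c(49, 51))))
  expect_equal(r4$n_matched, 1)
  expect_equal(r4$fraction_dko, 0.5)

  # two WT loops, one partner: partner not double-consumed
  r5 <- adjacent_shift_fraction(lab(mk_loops(c(10, 10), c(50, 52)),
                                    mk_loops(10, 51)))
  expect_equal(r5$n_matched, 1)
})

test_that("annotate_distal_ends measures feature overlap against a permuted null", {
  loops <- mk_loops(1:20, 30 + (1:20))
  # features covering every bin: fold 1, p 1
  all_feats <- GRanges("chr1", IRanges(1, 2e6))
  res <- annotate_distal_ends(loops, list(all = all_feats),
                              n_bins = c(chr1 = 200), n_shuffles = 200,
                              seed = 1)
  expect_equal(res$observed, 1)
  expect_equal(res$fold, 1)
  expect_equal(res$p, 1)

  # features covering no distal bin but half the genome: observed 0,
  # null mean near 0.5, fold near 0
  half <- GRanges("chr1", IRanges(1, 100 * 10000))  # bins 0..99
  far_loops <- mk_loops(1:20, 100 + (1:20))
  res2 <- annotate_distal_ends(far_loops, list(half = half),
                               n_bins = c(chr1 = 200), n_shuffles = 300,
                               seed = 2)
  expect_equal(res2$observed, 0)
  expect_lt(abs(res2$null_mean - 0.5), 0.1)
  expect_warning(annotate_distal_ends(loops, list(all = all_feats),
                                      n_bins = c(chr1 = 200),
                                      n_shuffles = 10, seed = 1),
                 "shuffles")
})

test_that("gene_loop_counts sums per gene over baits and conserves totals", {
  loops <- data.table::rbindlist(list(
    cbind(mk_loops(c(1, 1, 2, 2, 2), c(10, 11, 12, 13, 14)), condition = "WT"),
    cbind(mk_loops(c(1, 9), c(10, 40)), condition = "dKO")))
  bm <- data.table::data.table(chrom = "chr1", bait_bin = c(1L, 2L),
                               gene_id = c("G", "G"))
  out <- gene_loop_counts(loops, bm)
  expect_equal(out$genes$count_wt, 5)   # baits 1 and 2 both feed gene G
  expect_equal(out$genes$count_dko, 1)
  expect_equal(out$genes$net_change, -4)
  expect_equal(unname(out$unassigned), c(0, 1))  # bait 9 unmapped

  # gene with no loops reports (0, 0, 0)
  out2 <- gene_loop_counts(loops, bm, gene_ids = c("G", "H"))
  h <- out2$genes[out2$genes$gene_id == "H", ]
  expect_equal(unlist(h[, -1], use.names = FALSE), c(0, 0, 0))

  # conservation under a single-valued map: gene totals + unassigned
  # equal retained totals per condition
  withr::with_seed(8, rl <- random_loops(200))
  rl$condition <- sample(c("WT", "dKO"), nrow(rl), TRUE)
  bm2 <- data.table::data.table(chrom = "chr1",
                                bait_bin = unique(rl$bait_bin))
  bm2$gene_id <- sprintf("G%03d", seq_len(nrow(bm2)))
  bm2 <- bm2[seq_len(nrow(bm2) - 5), ]  # leave some baits unmapped
  out3 <- gene_loop_counts(rl, bm2)
  expect_equal(sum(out3$genes$count_wt) + unname(out3$unassigned["wt"]),
               sum(rl$condition == "WT"))
  expect_equal(sum(out3$genes$count_dko) + unname(out3$unassigned["dko"]),
               sum(rl$condition == "dKO"))
})

test_that("loop TSV round-trip preserves bins and scores", {
  l <- mk_loops(c(3, 8), c(30, 2), score = c(5.5, 12.25))
  path <- file.path(tempdir(), "loops.tsv")
  write_loops(l, path)
  back <- read_loops(path, "WT")
  expect_equal(back$bait_bin, l$bait_bin)
  expect_equal(back$distal_bin, l$distal_bin)
  expect_equal(back$score, l$score)
  expect_equal(unique(back$condition), "WT")

  bad <- file.path(tempdir(), "bad_loops.tsv")
  writeLines(c("chrom\tstart\tend\ttarget_chrom\ttarget_start\ttarget_end\tscore",
               "chr1\t0\t10000\tchr1\t30000\t40000\tNA"), bad)
  expect_error(read_loops(bad, "WT"), "score")
})
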