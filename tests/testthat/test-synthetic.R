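test_that("generation is deterministic and infeasible configs are rejected", {
  b1 <- generate_dataset(synth_config_small(seed = 4))
  b2 <- generate_dataset(synth_config_small(seed = 4))
  expect_equal(b1$genes, b2$genes)
  expect_equal(b1$loops_wt, b2$loops_wt)
  expect_equal(b1$truth$targets, b2$truth$targets)
  b3 <- generate_dataset(synth_config_small(seed = 5))
  expect_false(identical(b1$loops_wt, b3$loops_wt))

  # file bundles are byte-identical under the same seed
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  generate_dataset(synth_config_small(seed = 4), dir = d1)
  generate_dataset(synth_config_small(seed = 4), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  expect_error(synth_config(n_planted_targets = 500),
               "more planted targets")
  expect_error(synth_config(genome_length = 1e6), "genome too short")
  expect_error(synth_config(gain_prob_by_mcd = c(super = 0.8, standard = 0.1,
                                                 none = 0.1),
                            loss_prob_by_mcd = c(super = 0.5, standard = 0.1,
                                                 none = 0.1)),
               "exceeds 1")
})

test_that("truth labels match re-derivation from the emitted files", {
  dir <- file.path(tempdir(), "synth_files")
  b <- generate_dataset(synth_config_small(seed = 8), dir = dir)
  expect_setequal(list.files(dir),
                  c("genes.tsv", "mcd_peaks.bed", "mcd_signal.bedgraph",
                    "h3k27ac_peaks.bed", "h3k27ac_WT_rep1.bedgraph",
                    "h3k27ac_WT_rep2.bedgraph", "h3k27ac_dKO_rep1.bedgraph",
                    "h3k27ac_dKO_rep2.bedgraph", "loops_WT.tsv",
                    "loops_dKO.tsv", "bait_map.tsv", "truth.json"))

  # run the pipeline stages from the files alone
  inputs <- list(
    genes = file.path(dir, "genes.tsv"),
    mcd_peaks = file.path(dir, "mcd_peaks.bed"),
    mcd_signal = file.path(dir, "mcd_signal.bedgraph"),
    h3k27ac_peaks = file.path(dir, "h3k27ac_peaks.bed"),
    h3k27ac_tracks = list(
      WT_rep1 = file.path(dir, "h3k27ac_WT_rep1.bedgraph"),
      WT_rep2 = file.path(dir, "h3k27ac_WT_rep2.bedgraph"),
      dKO_rep1 = file.path(dir, "h3k27ac_dKO_rep1.bedgraph"),
      dKO_rep2 = file.path(dir, "h3k27ac_dKO_rep2.bedgraph")),
    sample_conditions = list(WT_rep1 = "WT", WT_rep2 = "WT",
                             dKO_rep1 = "dKO", dKO_rep2 = "dKO"),
    loops_wt = file.path(dir, "loops_WT.tsv"),
    loops_dko = file.path(dir, "loops_dKO.tsv"),
    bait_map = file.path(dir, "bait_map.tsv"))
  bundle <- read_bundle(inputs)
  res <- analyze_bundle(bundle, list(run_profiles = FALSE))

  # domains: intervals, classes and densities
  td <- b$truth$domains
  m <- match(paste(start(res$mcds) - 1, end(res$mcds)),
             paste(td$start, td$end))
  expect_false(anyNA(m))
  expect_equal(res$mcds$klass, td$klass[m])
  expect_equal(res$mcds$density, td$density[m], tolerance = 1e-6)

  # enhancers: status and domain class
  te <- b$truth$enhancers
  m2 <- match(paste(start(res$enhancers) - 1, end(res$enhancers)),
              paste(te$start, te$end))
  expect_false(anyNA(m2))
  expect_equal(res$enhancers$status, te$status[m2])
  expect_equal(res$enhancers$mcd_klass, te$mcd_klass[m2])

  # genes: DE status and loop counts
  tg <- b$truth$genes
  m3 <- match(res$genes$gene_id, tg$gene_id)
  expect_equal(res$genes$de_status, tg$de_status[m3])
  expect_equal(res$genes$net_change, tg$net_change[m3])

  # loops: sharing labels consistent with planted origins
  sh <- res$sharing$loops
  tr <- b$truth$loops
  key <- function(d) paste(d$condition, d$bait_bin, d$distal_bin)
  mm <- match(key(sh), key(tr))
  expect_false(anyNA(mm))
  expect_equal(nrow(sh), nrow(tr))
  expected <- ifelse(tr$origin[mm] == "shared", "shared",
                     ifelse(sh$condition == "WT", "unique_WT", "unique_dKO"))
  expect_equal(sh$sharing, expected)

  # targets
  expect_setequal(res$targets$gene_id, b$truth$targets)
})

test_that("planted couplings are recoverable at the stated strength", {
  # odds ratio of receiving a unique dKO loop, gain vs static enhancers,
  # estimated from the enhancer-level table at default sizes; the receiver
  # construction makes this estimate the planted loop_coupling_or
  ors <- vapply(1:10, function(s) {
    b <- generate_dataset(synth_config(seed = s))
    mcds <- classify_mcds(score_domains(call_mcds(b$mcd_peaks), b$mcd_track))
    el <- call_enhancers(b$h3k27ac_peaks, as.data.frame(b$tss),
                         b$h3k27ac_tracks)
    enh <- enhancer_table(el, b$sample_conditions, mcds)
    sh <- classify_sharing(filter_loops(b$loops_wt),
                           filter_loops(b$loops_dko))
    rel <- enhancer_loop_relation(enh, sh$loops)
    has_udko <- !is.na(rel) & rel == "unique_dKO"
    g <- enh$status == "gain"; st <- enh$status == "static"
    (sum(has_udko & g) / sum(!has_udko & g)) /
      (sum(has_udko & st) / sum(!has_udko & st))
  }, numeric(1))
  or <- synth_config()$loop_coupling_or
  expect_gte(mean(ors), or * 0.75)
  expect_lte(mean(ors), or * 1.25)
})

test_that("adjacent-bin twins appear at the planted rate", {
  b <- generate_dataset(synth_config(seed = 33))
  sh <- classify_sharing(filter_loops(b$loops_wt), filter_loops(b$loops_dko))
  shifts <- adjacent_shift_fraction(sh$loops)
  expect_true(shifts$defined)
  # each twin event explains one pair in both conditions; with twin
  # probability rho per unique loop the matched fraction is about
  # 2*rho / (1 + rho), plus accidental adjacencies
  rho <- synth_config()$shift_prob
  expected <- 2 * rho / (1 + rho)
  expect_gt(shifts$fraction_wt, expected * 0.6)
  expect_lt(shifts$fraction_wt, expected * 1.6)
  # greedy matching never double-consumes partners
  expect_lte(shifts$n_matched,
             min(sum(sh$loops$sharing == "unique_WT"),
                 sum(sh$loops$sharing == "unique_dKO")))
})

test_that("null datasets carry no couplings", {
  cfg <- null_config(synth_config_small(seed = 1))
  expect_equal(cfg$loop_coupling_or, 1)
  expect_equal(cfg$n_planted_targets, 0)
  b <- generate_null_dataset(synth_config_small(seed = 1))
  expect_length(b$truth$targets, 0)
  # gain fraction is uniform across domain classes (within noise)
  te <- b$truth$enhancers
  frac <- tapply(te$status == "gain", te$mcd_klass, mean)
  expect_lt(max(frac, na.rm = TRUE) - min(frac, na.rm = TRUE), 0.2)
})
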