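test_that("chisq_independence matches hand-computed and oracle values", {
  t1 <- matrix(c(10, 30, 20, 40), 2)
  got <- chisq_independence(t1)
  expect_equal(got$chi2, 0.7936508, tolerance = 1e-6)
  expect_equal(got$dof, 1)
  expect_equal(got$residuals[1, 1], (10 - 12) / sqrt(12), tolerance = 1e-9)

  # O = E exactly: statistic 0, p = 1
  flat <- chisq_independence(matrix(10, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  expect_error(chisq_independence(matrix(c(1, 0, 2, 0), 2)), "collapse")
  expect_error(chisq_independence(matrix(1:3, 1)), "2x2")
})

test_that("chisq_independence agrees with the oracle and stats::chisq.test", {
  withr::with_seed(13, {
    for (rep in 1:200) {
      nr <- sample(2:4, 1); nc <- sample(2:4, 1)
      o <- matrix(rpois(nr * nc, 20) + 1, nr, nc)
      got <- chisq_independence(o)
      want <- brute_chisq(o)
      expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
      expect_equal(got$dof, want$dof)
      expect_equal(got$residuals, want$residuals, tolerance = 1e-9)
      # independent cross-check against the reference implementation
      ref <- suppressWarnings(stats::chisq.test(o, correct = FALSE))
      expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(got$p, unname(ref$p.value), tolerance = 1e-9)
    }
  })
})

test_that("adjust_pvalues implements Holm and its guarantees", {
  expect_equal(adjust_pvalues(0.01), 0.01)
  # hand computation: sorted (0.01, 0.03, 0.04) -> step-down multipliers
  # (3, 2, 1) give (0.03, 0.06, 0.04); the running maximum enforces
  # monotonicity, yielding (0.03, 0.06, 0.06)
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  withr::with_seed(2, ps <- runif(20))
  expect_true(all(adjust_pvalues(ps) >= ps))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enhancer_loop_relation applies unique_dKO > unique_WT > shared precedence", {
  enh <- df_to_gr(data.frame(chrom = "chr1",
                             start = c(100000, 200000, 300000, 400000),
                             end = c(102000, 202000, 302000, 402000)))
  loops <- data.table::data.table(
    chrom = "chr1",
    bait_bin = c(1L, 2L, 3L, 4L),
    distal_bin = c(10L, 10L, 20L, 30L),  # enh1 gets dKO-unique AND shared
    score = 10,
    condition = c("dKO", "WT", "WT", "dKO"),
    sharing = c("unique_dKO", "shared", "unique_WT", "unique_dKO"))
  rel <- enhancer_loop_relation(enh, loops)
  expect_equal(rel, c("unique_dKO", "unique_WT", "unique_dKO", NA))
})

test_that("stratified associations detect planted couplings and skip degenerate strata", {
  # construct enhancers whose loop relation is coupled to status in the
  # super stratum (odds ratio far from 1) and uncoupled elsewhere
  build <- function(n, p_gain_udko, p_static_udko, klass) {
    status <- sample(c("gain", "loss", "static"), n, TRUE, c(0.3, 0.3, 0.4))
    start <- seq(1e5, by = 2e4, length.out = n)
    gr <- GRanges("chr1", IRanges(start, start + 2000))
    gr$status <- status
    gr$mcd_klass <- klass
    p <- ifelse(status == "gain", p_gain_udko, p_static_udko)
    rel <- ifelse(runif(n) < p, "unique_dKO",
                  sample(c("unique_WT", "shared_only"), n, TRUE))
    list(gr = gr, rel = rel)
  }
  # feed the contingency builder directly through the table route
  tab_from <- function(x) {
    table(factor(x$gr$status, c("gain", "loss", "static")),
          factor(x$rel, c("unique_dKO", "unique_WT", "shared_only")))
  }
  withr::with_seed(31, {
    coupled <- build(600, 0.7, 0.2, "super")
    tst <- chisq_independence(as.matrix(unclass(tab_from(coupled))))
    expect_lt(tst$p, 0.01)
    expect_gt(tst$residuals["gain", "unique_dKO"], 0)
  })

  # all-static stratum is skipped with a note
  enh <- df_to_gr(data.frame(chrom = "chr1", start = c(1e5, 2e5),
                             end = c(1e5 + 1000, 2e5 + 1000)))
  enh$status <- "static"
  enh$mcd_klass <- "super"
  loops <- data.table::data.table(chrom = "chr1", bait_bin = c(1L, 2L),
                                  distal_bin = c(10L, 20L), score = 10,
                                  condition = "dKO", sharing = "unique_dKO")
  res <- enhancer_loop_association(enh, loops)
  expect_true(res$strata$super$skipped)
  expect_match(res$strata$super$note, "non-empty")
})

test_that("gene_loop_association couples expression with net loop change", {
  withr::with_seed(17, {
    n <- 900
    de <- sample(c("up", "down", "static"), n, TRUE, c(0.2, 0.2, 0.6))
    klass <- sample(c("super", "standard", "none"), n, TRUE)
    # planted: up genes in super domains gain loops
    p_gain <- ifelse(de == "up" & klass == "super", 0.8, 0.3)
    net <- ifelse(runif(n) < p_gain, sample(1:3, n, TRUE),
                  sample(-1:1, n, TRUE))
    g <- data.table::data.table(gene_id = as.character(seq_len(n)),
                                de_status = de, net_change = net,
                                mcd_klass = klass)
    res <- gene_loop_association(g)
    sup <- res$strata$super
    expect_false(sup$skipped)
    expect_lt(sup$p_adj, 0.01)
    expect_gt(sup$residuals["up", "gained"], 0)
  })

  # a gene with no loops counts in the unchanged column
  g0 <- data.table::data.table(
    gene_id = c("a", "b", "c", "d"),
    de_status = c("up", "down", "static", "static"),
    net_change = c(1, -1, 0, 0),
    mcd_klass = "none")
  res0 <- gene_loop_association(g0)
  expect_equal(sum(res0$strata$none$table[, "unchanged"]), 2)
})

test_that("feature_mcd_overlap_test reports residual structure and closed percentages", {
  mcds <- df_to_gr(data.frame(chrom = "chr1",
                              start = c(0, 50000), end = c(20000, 70000)))
  mcds$klass <- c("super", "standard")
  # all up features inside the super domain, statics outside
  up <- df_to_gr(data.frame(chrom = "chr1", start = seq(0, 18000, 1000),
                            end = seq(500, 18500, 1000)))
  st <- df_to_gr(data.frame(chrom = "chr1", start = seq(1e5, 1.18e5, 1000),
                            end = seq(1e5, 1.18e5, 1000) + 500))
  dn <- df_to_gr(data.frame(chrom = "chr1", start = seq(50000, 68000, 1000),
                            end = seq(50500, 68500, 1000)))
  feats <- c(up, dn, st)
  feats$status <- rep(c("up", "down", "static"), each = 19)
  res <- feature_mcd_overlap_test(feats, mcds)
  expect_gt(res$test$residuals["up", "super"], 0)
  expect_gt(res$test$residuals["down", "standard"], 0)
  expect_lt(res$test$p, 1e-6)
  expect_equal(unname(rowSums(res$percent)), rep(100, 3))
})
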