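#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the four data layers the pipeline consumes —
#' macroH2A domain peaks + signal, per-condition H3K27ac peaks + per-sample
#' signal, a differential-expression gene table, and per-condition
#' promoter-anchored loops — with planted couplings: enhancer gain/loss
#' probability depends on domain class, condition-unique loops are drawn
#' toward gain/loss enhancers at a configurable odds ratio, upregulated
#' genes are enriched in super domains and in net loop gains, and a small
#' set of planted target genes satisfies all target criteria (up,
#' looped to a gaining enhancer, net loop gain) while no other gene does.
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   output bundles.
#' @param genome_length Genome size in bp (single chromosome).
#' @param chrom Chromosome name.
#' @param bin_size Loop bin width in bp.
#' @param n_genes,n_enhancers Entity counts.
#' @param n_super_mcd,n_standard_mcd,n_low_mcd Domain counts per class
#'   (lengths 100-500 kb, 5-50 kb and 0.5-1.5 kb respectively).
#' @param frac_up,frac_down Fractions of differentially expressed genes.
#' @param de_lfc_mean,de_lfc_sd Absolute log2FC distribution of DE genes
#'   (normal, truncated above the 0.75 call threshold).
#' @param gain_prob_by_mcd,loss_prob_by_mcd Named probabilities (`super`,
#'   `standard`, `none`) that an enhancer gains/loses H3K27ac.
#' @param de_mcd_weight Named sampling weights coupling DE status to the
#'   gene's domain class.
#' @param loop_rate Mean shared loops per bait (Poisson).
#' @param loop_receiver_rate Baseline probability that an enhancer
#'   receives at least one condition-unique loop.
#' @param loop_background_rate Mean background-only (non-enhancer)
#'   condition-unique loops per bait and condition (Poisson).
#' @param loop_coupling_or Odds ratio that a gain enhancer receives a
#'   unique dKO loop, relative to non-gain enhancers (loss enhancers
#'   receive unique WT loops at the same odds ratio).
#' @param deg_loop_gain_boost Sampling-weight multiplier favouring baits
#'   of upregulated genes when unique dKO loops are placed (and baits of
#'   downregulated genes for unique WT loops), planting the
#'   expression/loop-count coupling.
#' @param shift_prob Probability that a condition-unique loop is emitted
#'   together with a +-1-bin shifted twin in the other condition.
#' @param n_planted_targets Number of planted target genes.
#' @param frac_background_distal Fraction of loop distal ends at
#'   non-enhancer bins.
#' @param frac_short_genes Fraction of genes shorter than 1 kb (exercise
#'   the matched-sampler length filter; always static).
#' @param frac_second_bait Fraction of non-upregulated genes given a
#'   second (alternative-promoter) bait bin.
#' @param junk_loop_frac Fraction of extra sub-threshold (score < 5)
#'   loops added to the raw loop files.
#' @param exclusive_targets Keep gain-enhancer loops away from
#'   upregulated non-target genes so the planted targets are exactly the
#'   genes satisfying the target criteria (disabled in null datasets).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         genome_length = 5e7,
                         chrom = "chr1",
                         bin_size = 10000,
                         n_genes = 2000,
                         n_enhancers = 3000,
                         n_super_mcd = 30,
                         n_standard_mcd = 300,
                         n_low_mcd = 100,
                         frac_up = 0.05,
                         frac_down = 0.05,
                         de_lfc_mean = 1.5,
                         de_lfc_sd = 0.3,
                         gain_prob_by_mcd = c(super = 0.4, standard = 0.15, none = 0.05),
                         loss_prob_by_mcd = c(super = 0.25, standard = 0.10, none = 0.05),
                         de_mcd_weight = c(super = 6, standard = 2, none = 1),
                         loop_rate = 3,
                         loop_receiver_rate = 0.25,
                         loop_background_rate = 0.3,
                         loop_coupling_or = 4,
                         deg_loop_gain_boost = 2.5,
                         shift_prob = 0.1,
                         n_planted_targets = 12,
                         frac_background_distal = 0.2,
                         frac_short_genes = 0.05,
                         frac_second_bait = 0.05,
                         junk_loop_frac = 0.1,
                         exclusive_targets = TRUE) {
  cfg <- as.list(environment())
  probs <- c(cfg$gain_prob_by_mcd, cfg$loss_prob_by_mcd, cfg$frac_up,
             cfg$frac_down, cfg$shift_prob, cfg$frac_background_distal,
             cfg$frac_short_genes, cfg$frac_second_bait)
  .assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  .assert(all(c("super", "standard", "none") %in% names(cfg$gain_prob_by_mcd)) &&
          all(c("super", "standard", "none") %in% names(cfg$loss_prob_by_mcd)),
          "gain/loss probabilities need super, standard and none entries")
  .assert(cfg$gain_prob_by_mcd[1] + cfg$loss_prob_by_mcd[1] <= 1 &&
          all(cfg$gain_prob_by_mcd + cfg$loss_prob_by_mcd[names(cfg$gain_prob_by_mcd)] <= 1),
          "gain + loss probability exceeds 1 in some stratum")
  .assert(cfg$n_planted_targets <= round(cfg$frac_up * cfg$n_genes),
          "more planted targets than upregulated genes")
  .assert(cfg$genome_length >= cfg$n_enhancers * 16000 + 2e5,
          "genome too short for the requested enhancer count")
  class(cfg) <- "synth_config"
  cfg
}

#' Reduced-size configuration for repeated simulation
#'
#' The default desk-scale dataset scaled down for calibration studies:
#' 500 genes, 800 enhancers on a 14 Mb chromosome, with domain counts
#' scaled to preserve genome coverage fractions.
#'
#' @param seed Integer RNG seed.
#' @param ... Overrides passed to [synth_config].
#' @return A `synth_config` list.
#' @export
synth_config_small <- function(seed = 1, ...) {
  synth_config(seed = seed, genome_length = 1.4e7, n_genes = 500,
               n_enhancers = 800, n_super_mcd = 12, n_standard_mcd = 80,
               n_low_mcd = 30, ...)
}

#' Null-coupling configuration
#'
#' All couplings removed: enhancer gain/loss probabilities uniform across
#' domain classes, loop odds ratio 1, no expression/loop boost, uniform
#' DE placement, no planted targets and no target-exclusivity
#' constraints. Used for type-I-error calibration.
#'
#' @param config A `synth_config` to neutralize.
#' @return The null `synth_config`.
#' @export
null_config <- function(config) {
  config$gain_prob_by_mcd <- c(super = 0.2, standard = 0.2, none = 0.2)
  config$loss_prob_by_mcd <- c(super = 0.2, standard = 0.2, none = 0.2)
  config$de_mcd_weight <- c(super = 1, standard = 1, none = 1)
  config$loop_coupling_or <- 1
  config$deg_loop_gain_boost <- 1
  config$n_planted_targets <- 0
  config$exclusive_targets <- FALSE
  config
}

# weighted sample without replacement returning at most k items
.swor <- function(x, k, w = NULL) {
  k <- min(k, length(x))
  if (k <= 0) return(x[0])
  if (length(x) == 1) return(x)
  sample(x, k, prob = w)
}

#' Generate a synthetic dataset with planted couplings
#'
#' See [synth_config] for the planted structure. Returns an in-memory
#' bundle (the objects the pipeline consumes) together with a ground-truth
#' record; with `dir` set, the bundle is also written as plain-text files
#' (`genes.tsv`, `mcd_peaks.bed`, `mcd_signal.bedgraph`,
#' `h3k27ac_peaks.bed`, `h3k27ac_<sample>.bedgraph`, `loops_WT.tsv`,
#' `loops_dKO.tsv`, `bait_map.tsv`, `truth.json`), byte-identical under
#' identical seeds.
#'
#' @param config A `synth_config`.
#' @param dir Optional output directory.
#' @return A list with elements `mcd_peaks`, `mcd_track`,
#'   `h3k27ac_peaks`, `h3k27ac_tracks`, `sample_conditions`, `genes`,
#'   `tss`, `loops_wt`, `loops_dko`, `bait_map`, `truth`, `config`.
#' @export
generate_dataset <- function(config = synth_config(), dir = NULL) {
  .assert(inherits(config, "synth_config"), "config must come from synth_config()")
  bundle <- withr::with_seed(config$seed, .generate_dataset_impl(config))
  if (!is.null(dir)) write_dataset(bundle, dir)
  bundle
}

#' Generate a null (uncoupled) synthetic dataset
#'
#' Convenience wrapper applying [null_config] before generation.
#'
#' @param config A `synth_config` (its couplings are neutralized).
#' @param dir Optional output directory.
#' @return As [generate_dataset].
#' @export
generate_null_dataset <- function(config = synth_config(), dir = NULL) {
  generate_dataset(null_config(config), dir)
}

.generate_dataset_impl <- function(cfg) {
  chrom <- cfg$chrom
  G <- cfg$genome_length
  B <- cfg$bin_size
  n_bins <- as.integer(G %/% B)

  ## --- enhancer lattice (0-based coordinates throughout) -----------------
  nE <- cfg$n_enhancers
  e_gap <- floor(runif(nE, 12.6e3, 13.8e3))  # > 12.5 kb: no cross-element stitching
  e_len <- floor(runif(nE, 1e3, 2.2e3))
  cs <- cumsum(e_gap + e_len)
  enh_end <- cs
  enh_start <- cs - e_len
  .assert(enh_end[nE] <= G - 1e5, "enhancer lattice exceeds genome length")

  ## --- genes in inter-enhancer gaps --------------------------------------
  nG <- cfg$n_genes
  .assert(nG <= nE, "more genes than inter-enhancer gaps")
  slot <- sort(sample(nE, nG))
  prev_end <- c(0, enh_end)[slot]          # end of previous enhancer (or 0)
  lo <- prev_end + 2800
  hi <- enh_start[slot] - 2800
  avail <- hi - lo
  n_short <- round(cfg$frac_short_genes * nG)
  short <- sample(nG, n_short)
  g_len <- floor(pmin(runif(nG, 2e3, 9e3), avail))
  g_len[short] <- floor(runif(n_short, 400, 900))
  g_start <- lo + floor(runif(nG) * (avail - g_len))
  g_end <- g_start + g_len
  g_strand <- sample(c("+", "-"), nG, replace = TRUE)
  gene_id <- sprintf("G%04d", seq_len(nG))
  tpm_wt <- round(rlnorm(nG, meanlog = 3, sdlog = 1.2), 3)

  ## --- macroH2A domains ---------------------------------------------------
  d_klass <- sample(c(rep("super", cfg$n_super_mcd),
                      rep("standard", cfg$n_standard_mcd),
                      rep("low", cfg$n_low_mcd)))
  nD <- length(d_klass)
  d_len <- numeric(nD)
  d_len[d_klass == "super"] <- floor(runif(cfg$n_super_mcd, 100e3, 500e3))
  d_len[d_klass == "standard"] <- floor(runif(cfg$n_standard_mcd, 5e3, 50e3))
  d_len[d_klass == "low"] <- floor(runif(cfg$n_low_mcd, 500, 1500))
  leftover <- G - sum(d_len) - nD * 26e3 - 1e5
  .assert(leftover > 0, "genome too short for the requested domain counts")
  raw <- runif(nD)
  d_gap <- 26e3 + floor(raw / sum(raw) * leftover)
  d_end <- cumsum(d_gap + d_len)
  d_start <- d_end - d_len
  # densities: an evenly spread super band far above the standard band, so
  # the ranked-curve elbow separates the classes unambiguously
  d_density <- numeric(nD)
  sup <- which(d_klass == "super")
  d_density[sup] <- sample(seq(12, 20, length.out = length(sup)) +
                             rnorm(length(sup), 0, 0.02))
  d_density[d_klass == "standard"] <- runif(cfg$n_standard_mcd, 2.1, 5)
  d_density[d_klass == "low"] <- runif(cfg$n_low_mcd, 1.2, 2.2)
  d_density <- round(d_density, 4)  # emitted track precision == truth precision

  ## --- overlap class of genes and enhancers -------------------------------
  # vectorized any-overlap against the (sorted, disjoint) domain intervals
  klass_of <- function(s0, e0) {
    out <- rep("none", length(s0))
    for (kl in c("standard", "super")) {
      ds <- d_start[d_klass == kl]; de <- d_end[d_klass == kl]
      if (!length(ds)) next
      lo <- findInterval(s0 + 0.5, de) + 1L  # first domain ending after s0
      hi <- findInterval(e0 - 0.5, ds)       # last domain starting before e0
      out[hi >= lo] <- kl
    }
    out
  }
  g_klass <- klass_of(g_start, g_end)
  e_klass <- klass_of(enh_start, enh_end)

  ## --- DE status with planted targets ------------------------------------
  tss0 <- ifelse(g_strand == "+", g_start, g_end - 1)
  bait_bin <- as.integer(tss0 %/% B)
  n_up <- round(cfg$frac_up * nG)
  n_down <- round(cfg$frac_down * nG)
  k <- cfg$n_planted_targets
  normal <- setdiff(seq_len(nG), short)
  de_status <- rep("static", nG)
  targets <- integer(0)
  if (k > 0) {
    cand <- normal[g_klass[normal] == "super"]
    cand <- cand[!duplicated(bait_bin[cand])]
    .assert(length(cand) >= k, "too few genes in super domains to plant targets")
    targets <- sort(.swor(cand, k))
    de_status[targets] <- "up"
  }
  w <- cfg$de_mcd_weight[g_klass]
  rest <- setdiff(normal, targets)
  ord <- sample(rest, length(rest), prob = w[rest])
  used_baits <- bait_bin[targets]
  up_extra <- integer(0)
  for (i in ord) {
    if (length(up_extra) + length(targets) >= n_up) break
    if (bait_bin[i] %in% used_baits) next
    up_extra <- c(up_extra, i)
    used_baits <- c(used_baits, bait_bin[i])
  }
  de_status[up_extra] <- "up"
  rest2 <- setdiff(rest, up_extra)
  down <- .swor(rest2, n_down, w[rest2])
  de_status[down] <- "down"
  lfc_abs <- pmax(rnorm(nG, cfg$de_lfc_mean, cfg$de_lfc_sd), 0.8)
  g_lfc <- ifelse(de_status == "up", lfc_abs,
                  ifelse(de_status == "down", -lfc_abs, runif(nG, -0.5, 0.5)))
  g_padj <- ifelse(de_status == "static", runif(nG, 0.05, 1), runif(nG, 0, 0.049))

  ## --- bait map (with alternative promoters) ------------------------------
  up_idx <- which(de_status == "up")
  non_up <- setdiff(seq_len(nG), up_idx)
  second <- non_up[runif(length(non_up)) < cfg$frac_second_bait]
  second_bin <- pmin(pmax(bait_bin[second] + sample(c(-1L, 1L), length(second),
                                                    replace = TRUE), 0L),
                     n_bins - 1L)
  bait_map <- data.table(
    chrom = chrom,
    bait_bin = c(bait_bin, second_bin),
    gene_id = c(gene_id, gene_id[second])
  )
  bait_map <- unique(bait_map)
  data.table::setorder(bait_map, bait_bin, gene_id)

  ## --- enhancer status and per-sample signal ------------------------------
  u <- runif(nE)
  pg <- cfg$gain_prob_by_mcd[e_klass]
  pl <- cfg$loss_prob_by_mcd[e_klass]
  e_status <- ifelse(u < pg, "gain", ifelse(u < pg + pl, "loss", "static"))
  e_lfc <- ifelse(e_status == "gain", pmax(rnorm(nE, 1.5, 0.3), 1.2),
                  ifelse(e_status == "loss", -pmax(rnorm(nE, 1.5, 0.3), 1.2),
                         runif(nE, -0.1, 0.1)))
  baseline <- rlnorm(nE, meanlog = log(50), sdlog = 0.4)
  samples <- c(WT_rep1 = "WT", WT_rep2 = "WT", dKO_rep1 = "dKO", dKO_rep2 = "dKO")
  depth <- runif(4, 0.7, 1.4)
  sig <- matrix(0, nE, 4, dimnames = list(NULL, names(samples)))
  for (j in 1:4) {
    eff <- if (samples[j] == "dKO") 2^e_lfc else rep(1, nE)
    sig[, j] <- baseline * eff * depth[j] * exp(rnorm(nE, 0, 0.03))
  }

  ## --- loop generation -----------------------------------------------------
  e_mid_bin <- as.integer(((enh_start + enh_end) %/% 2) %/% B)
  # every bin any enhancer interval touches, by status (for exclusion rules)
  first_bin <- as.integer(enh_start %/% B)
  last_bin <- as.integer((enh_end - 1) %/% B)
  touch_bins <- function(idx) {
    unique(unlist(lapply(idx, function(i) seq(first_bin[i], last_bin[i]))))
  }
  gain_touch <- touch_bins(which(e_status == "gain"))
  gain_mid <- e_mid_bin[e_status == "gain"]
  ord_e <- order(e_mid_bin)
  eb_sorted <- e_mid_bin[ord_e]
  estat_sorted <- e_status[ord_e]

  baits <- sort(unique(bait_map$bait_bin))
  bait_genes <- split(bait_map$gene_id, bait_map$bait_bin)
  target_ids <- gene_id[targets]
  up_ids <- gene_id[de_status == "up"]
  down_ids <- gene_id[de_status == "down"]
  is_target_bait <- vapply(bait_genes[as.character(baits)],
                           function(g) any(g %in% target_ids), logical(1))
  is_up_bait <- vapply(bait_genes[as.character(baits)],
                       function(g) any(g %in% setdiff(up_ids, target_ids)),
                       logical(1))
  is_down_bait <- vapply(bait_genes[as.character(baits)],
                         function(g) any(g %in% down_ids), logical(1))

  OR <- cfg$loop_coupling_or
  boost <- cfg$deg_loop_gain_boost
  reach <- 150L  # loops span at most 1.5 Mb
  nb_baits <- length(baits)
  used_wt <- vector("list", nb_baits)   # distal bins taken per bait/condition
  used_dko <- vector("list", nb_baits)
  excl_bait <- cfg$exclusive_targets & is_up_bait & !is_target_bait
  all_touch <- touch_bins(seq_len(nE))
  rows <- list()
  add_rows <- function(cond, bait, dist, origin) {
    if (!length(dist)) return(invisible())
    rows[[length(rows) + 1L]] <<- list(cond = rep(cond, length(dist)),
                                       bait = rep(as.integer(bait), length(dist)),
                                       dist = as.integer(dist),
                                       origin = rep(origin, length(dist)))
    invisible()
  }

  ## stage A: shared backbone and background-only unique loops, per bait
  for (bi in seq_len(nb_baits)) {
    b <- baits[bi]
    i1 <- findInterval(b - reach - 0.5, eb_sorted) + 1
    i2 <- findInterval(b + reach + 0.5, eb_sorted)
    near <- if (i2 >= i1) eb_sorted[i1:i2] else integer(0)
    nstat <- if (i2 >= i1) estat_sorted[i1:i2] else character(0)
    keep <- near != b
    near <- near[keep]; nstat <- nstat[keep]
    if (excl_bait[bi]) {
      ok <- nstat != "gain"
      near <- near[ok]; nstat <- nstat[ok]
    }
    bg_pool <- setdiff(seq(max(0L, b - reach), min(n_bins - 1L, b + reach)),
                       c(near, b, if (excl_bait[bi]) gain_touch))
    n_s <- rpois(1, cfg$loop_rate)
    n_bg <- if (n_s > 0) sum(runif(n_s) < cfg$frac_background_distal) else 0L
    sh <- c(.swor(near, n_s - n_bg), .swor(bg_pool, n_bg))
    bg_left <- setdiff(bg_pool, sh)
    bw <- .swor(bg_left, rpois(1, cfg$loop_background_rate))
    bg_left <- setdiff(bg_left, bw)
    bd <- .swor(bg_left, rpois(1, cfg$loop_background_rate))
    add_rows("WT", b, sh, "shared"); add_rows("dKO", b, sh, "shared")
    add_rows("WT", b, bw, "unique"); add_rows("dKO", b, bd, "unique")
    used_wt[[bi]] <- c(sh, bw)
    used_dko[[bi]] <- c(sh, bd)
  }

  ## stage B: per-enhancer receivers of condition-unique loops. An enhancer
  ## is a dKO receiver with probability p0, scaled to odds-ratio OR for
  ## gain enhancers (WT receivers symmetrically for losses); every receiver
  ## is guaranteed at least one condition-unique loop, so the planted
  ## odds ratio is recoverable from the enhancer-level contingency table.
  p0 <- cfg$loop_receiver_rate
  p_hi <- OR * p0 / (1 - p0 + OR * p0)
  recv_dko <- runif(nE) < ifelse(e_status == "gain", p_hi, p0)
  recv_wt <- runif(nE) < ifelse(e_status == "loss", p_hi, p0)
  place_receiver <- function(e, cond) {
    ebin <- e_mid_bin[e]
    j1 <- findInterval(ebin - reach - 0.5, baits) + 1
    j2 <- findInterval(ebin + reach + 0.5, baits)
    if (j2 < j1) return(invisible())
    cand <- j1:j2
    cand <- cand[baits[cand] != ebin]
    # gain enhancers may not receive loops (either condition) from baits of
    # non-target upregulated genes: target exactness
    if (e_status[e] == "gain") cand <- cand[!excl_bait[cand]]
    if (!length(cand)) return(invisible())
    w <- if (cond == "dKO") {
      ifelse(is_up_bait[cand] | is_target_bait[cand], boost, 1)
    } else {
      ifelse(is_down_bait[cand], boost, 1)
    }
    k <- 1L + rpois(1, 0.3)
    ordc <- if (length(cand) == 1) cand else sample(cand, length(cand), prob = w)
    placed <- 0L
    for (bi in ordc) {
      if (ebin %in% used_wt[[bi]] || ebin %in% used_dko[[bi]]) next
      add_rows(cond, baits[bi], ebin, "unique")
      if (cond == "dKO") {
        used_dko[[bi]] <<- c(used_dko[[bi]], ebin)
      } else {
        used_wt[[bi]] <<- c(used_wt[[bi]], ebin)
      }
      placed <- placed + 1L
      if (placed >= k) break
    }
    invisible()
  }
  for (e in which(recv_dko)) place_receiver(e, "dKO")
  for (e in which(recv_wt)) place_receiver(e, "WT")

  ## stage C: planted-target guarantees (a retained dKO loop onto a gain
  ## enhancer, and a strict net gain of loops)
  for (bi in which(is_target_bait)) {
    b <- baits[bi]
    if (!any(used_dko[[bi]] %in% gain_mid)) {
      fg <- setdiff(gain_mid, c(b, used_dko[[bi]], used_wt[[bi]]))
      nearfg <- fg[abs(fg - b) <= reach]
      if (length(nearfg)) fg <- nearfg
      .assert(length(fg) > 0, "no gain enhancer available for a planted target")
      d <- .swor(fg, 1)
      add_rows("dKO", b, d, "unique")
      used_dko[[bi]] <- c(used_dko[[bi]], d)
    }
    while (length(used_dko[[bi]]) <= length(used_wt[[bi]])) {
      free <- setdiff(seq(max(0L, b - reach), min(n_bins - 1L, b + reach)),
                      c(b, used_dko[[bi]], used_wt[[bi]], all_touch))
      .assert(length(free) > 0, "no free bin for a target net-gain loop")
      d <- .swor(free, 1)
      add_rows("dKO", b, d, "unique")
      used_dko[[bi]] <- c(used_dko[[bi]], d)
    }
  }

  ## stage D: +-1-bin shifted twins of unique loops (target baits skipped so
  ## the forced net loop gain is preserved)
  if (cfg$shift_prob > 0) {
    snapshot <- rows
    for (r in snapshot) {
      for (ii in which(r$origin == "unique")) {
        if (runif(1) >= cfg$shift_prob) next
        b <- r$bait[ii]
        bi <- match(b, baits)
        if (is_target_bait[bi]) next
        twin <- r$dist[ii] + sample(c(-1L, 1L), 1)
        if (twin < 0 || twin >= n_bins || twin == b) next
        # a twin colliding with either condition would change sharing labels
        if (twin %in% used_wt[[bi]] || twin %in% used_dko[[bi]]) next
        if (excl_bait[bi] && twin %in% gain_touch) next
        oc <- if (r$cond[ii] == "WT") "dKO" else "WT"
        add_rows(oc, b, twin, "twin")
        if (oc == "WT") {
          used_wt[[bi]] <- c(used_wt[[bi]], twin)
        } else {
          used_dko[[bi]] <- c(used_dko[[bi]], twin)
        }
      }
    }
  }

  loops <- data.table(
    chrom = chrom,
    bait_bin = unlist(lapply(rows, `[[`, "bait")),
    distal_bin = unlist(lapply(rows, `[[`, "dist")),
    condition = unlist(lapply(rows, `[[`, "cond")),
    origin = unlist(lapply(rows, `[[`, "origin"))
  )
  loops$score <- round(5 + rexp(nrow(loops), 1 / 5), 3)
  # sub-threshold decoys, filtered out downstream by the score >= 5 rule
  n_junk <- round(cfg$junk_loop_frac * nrow(loops))
  if (n_junk > 0) {
    jb <- sample(baits, n_junk, replace = TRUE)
    jd <- pmin(pmax(jb + sample(c(-reach:-1, 1:reach), n_junk, replace = TRUE), 0L),
               n_bins - 1L)
    junk <- data.table(chrom = chrom, bait_bin = jb, distal_bin = jd,
                       condition = sample(c("WT", "dKO"), n_junk, replace = TRUE),
                       origin = "junk",
                       score = round(runif(n_junk, 0.5, 4.9), 3))
    junk <- junk[junk$bait_bin != junk$distal_bin, ]
    key_r <- paste(loops$condition, loops$bait_bin, loops$distal_bin)
    junk <- junk[!paste(junk$condition, junk$bait_bin, junk$distal_bin) %in% key_r, ]
    junk <- junk[!duplicated(paste(junk$condition, junk$bait_bin, junk$distal_bin)), ]
    loops <- rbind(loops, junk)
  }
  data.table::setorder(loops, condition, bait_bin, distal_bin)

  ## --- assemble emitted objects -------------------------------------------
  split_interval <- function(s0, e0, min_split, gap) {
    # one or two sub-peaks tiling the edges of [s0, e0)
    n <- length(s0)
    two <- (e0 - s0) > min_split
    m <- (s0 + e0) %/% 2
    list(start = c(s0, m[two] + gap %/% 2),
         end = c(ifelse(two, m - gap %/% 2, e0), e0[two]),
         id = c(seq_len(n), which(two)))
  }
  dsp <- split_interval(d_start, d_end, 6e3, 1000L)
  o <- order(dsp$start)
  mcd_peaks <- GRanges(chrom, IRanges(dsp$start[o] + 1, dsp$end[o]))
  bg_starts <- c(0, d_end)
  bg_ends <- c(d_start, G)
  bgv <- round(runif(length(bg_starts), 0.05, 0.15), 4)
  keep_bg <- bg_ends > bg_starts
  tr <- data.table(start = c(bg_starts[keep_bg], d_start),
                   end = c(bg_ends[keep_bg], d_end),
                   value = c(bgv[keep_bg], round(d_density, 4)))
  data.table::setorder(tr, start)
  mcd_track <- GRanges(chrom, IRanges(tr$start + 1, tr$end), score = tr$value)

  esp <- split_interval(enh_start, enh_end, 2200, 400L)
  eo <- order(esp$start)
  h3_peaks <- GRanges(chrom, IRanges(esp$start[eo] + 1, esp$end[eo]))
  covered <- rowsum(esp$end - esp$start, esp$id)[, 1]  # bp per element, by id
  h3_tracks <- lapply(seq_len(4), function(j) {
    vals <- round(sig[esp$id, j] / covered[esp$id], 5)
    GRanges(chrom, IRanges(esp$start + 1, esp$end), score = as.numeric(vals))[order(esp$start)]
  })
  names(h3_tracks) <- names(samples)

  genes <- data.table(gene_id = gene_id, chrom = chrom, start = g_start,
                      end = g_end, strand = g_strand, tpm_wt = tpm_wt,
                      log2fc = round(g_lfc, 4), padj = round(g_padj, 5))
  tss <- data.table(chrom = chrom, pos = tss0)

  ## --- ground truth ---------------------------------------------------------
  retained <- loops[loops$origin != "junk", ]
  gcounts <- gene_loop_counts(retained, bait_map, gene_ids = gene_id)$genes
  truth <- list(
    params = cfg[setdiff(names(cfg), "")],
    domains = data.table(chrom = chrom, start = d_start, end = d_end,
                         klass = d_klass, density = d_density),
    enhancers = data.table(enh_id = sprintf("E%04d", seq_len(nE)),
                           chrom = chrom, start = enh_start, end = enh_end,
                           mid_bin = e_mid_bin, status = e_status,
                           mcd_klass = e_klass, log2fc = round(e_lfc, 4)),
    genes = data.table(gene_id = gene_id, de_status = de_status,
                       mcd_klass = g_klass, bait_bin = bait_bin,
                       count_wt = gcounts$count_wt[match(gene_id, gcounts$gene_id)],
                       count_dko = gcounts$count_dko[match(gene_id, gcounts$gene_id)],
                       net_change = gcounts$net_change[match(gene_id, gcounts$gene_id)]),
    loops = retained,
    targets = target_ids
  )

  list(mcd_peaks = mcd_peaks, mcd_track = mcd_track,
       h3k27ac_peaks = h3_peaks, h3k27ac_tracks = h3_tracks,
       sample_conditions = samples,
       genes = genes, tss = tss,
       loops_wt = loops[loops$condition == "WT",
                        c("chrom", "bait_bin", "distal_bin", "score", "condition")],
       loops_dko = loops[loops$condition == "dKO",
                         c("chrom", "bait_bin", "distal_bin", "score", "condition")],
       bait_map = bait_map, truth = truth, config = cfg)
}

#' Write a generated bundle to plain-text files
#'
#' @param bundle Output of [generate_dataset].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  B <- bundle$config$bin_size
  fwrite(bundle$genes, file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE)
  write_regions(bundle$mcd_peaks, file.path(dir, "mcd_peaks.bed"), "bed")
  write_regions(bundle$mcd_track, file.path(dir, "mcd_signal.bedgraph"), "bedgraph")
  write_regions(bundle$h3k27ac_peaks, file.path(dir, "h3k27ac_peaks.bed"), "bed")
  for (nm in names(bundle$h3k27ac_tracks)) {
    write_regions(bundle$h3k27ac_tracks[[nm]],
                  file.path(dir, sprintf("h3k27ac_%s.bedgraph", nm)), "bedgraph")
  }
  write_loops(bundle$loops_wt, file.path(dir, "loops_WT.tsv"), B)
  write_loops(bundle$loops_dko, file.path(dir, "loops_dKO.tsv"), B)
  fwrite(bundle$bait_map, file.path(dir, "bait_map.tsv"), sep = "\t", quote = FALSE)
  truth <- bundle$truth
  truth$params$gain_prob_by_mcd <- as.list(truth$params$gain_prob_by_mcd)
  truth$params$loss_prob_by_mcd <- as.list(truth$params$loss_prob_by_mcd)
  truth$params$de_mcd_weight <- as.list(truth$params$de_mcd_weight)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
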