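#' Default pipeline parameters
#'
#' Defaults: 25 kb domain merge,
#' 12.5 kb stitch with a 2.5 kb TSS exclusion for enhancers (none for
#' domains), 3,780 low-domain cutoff, +-0.75 log2FC thresholds, padj <
#' 0.05 for genes, loop score >= 5 at 10 kb bins, 25% TPM matching
#' tolerance and a 50 kb proximity window.
#'
#' @return Named list of parameters.
#' @export
pipeline_params <- function() {
  list(merge_gap = 25000, stitch = 12500, tss_exclusion = 2500,
       low_cutoff = 3780, enh_lfc_threshold = 0.75,
       deg_padj = 0.05, deg_lfc = 0.75,
       min_score = 5, bin_size = 10000,
       proximity_window = 50000,
       matched_k = 3, matched_tolerance = 0.25, matched_min_length = 1000,
       profile_body_bins = 50, profile_flank_bp = 2000,
       profile_flank_bins = 10, bootstrap_B = 200,
       run_profiles = TRUE, seed = 1)
}

#' Read a pipeline input bundle from files
#'
#' @param inputs Named list of file paths: `genes`, `mcd_peaks` (one or
#'   more BEDs), `mcd_signal`, `h3k27ac_peaks`, `h3k27ac_tracks` (named
#'   sample -> bedGraph path), `sample_conditions` (named sample ->
#'   `"WT"`/`"dKO"`), `loops_wt`, `loops_dko`, `bait_map`, optionally
#'   `inflammatory_genes` (one gene id per line).
#' @param bin_size Loop bin width in bp.
#' @return A bundle list as produced by [generate_dataset].
#' @export
read_bundle <- function(inputs, bin_size = 10000) {
  need <- c("genes", "mcd_peaks", "mcd_signal", "h3k27ac_peaks",
            "h3k27ac_tracks", "sample_conditions", "loops_wt", "loops_dko",
            "bait_map")
  missing <- setdiff(need, names(inputs))
  .assert(length(missing) == 0,
          sprintf("config lacks input key(s): %s", paste(missing, collapse = ", ")))
  genes <- read_gene_table(inputs$genes)
  tracks <- lapply(inputs$h3k27ac_tracks, read_regions, format = "bedgraph")
  tss0 <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  list(
    mcd_peaks = lapply(as.list(inputs$mcd_peaks), read_regions, format = "bed"),
    mcd_track = read_regions(inputs$mcd_signal, "bedgraph"),
    h3k27ac_peaks = read_regions(inputs$h3k27ac_peaks, "bed"),
    h3k27ac_tracks = tracks,
    sample_conditions = unlist(inputs$sample_conditions),
    genes = genes,
    tss = data.table(chrom = genes$chrom, pos = tss0),
    loops_wt = read_loops(inputs$loops_wt, "WT", bin_size),
    loops_dko = read_loops(inputs$loops_dko, "dKO", bin_size),
    bait_map = fread(inputs$bait_map, sep = "\t", header = TRUE),
    pathway_genes = if (!is.null(inputs$inflammatory_genes)) {
      readLines(inputs$inflammatory_genes)
    } else {
      NULL
    }
  )
}

#' Run the integrative analysis on an in-memory bundle
#'
#' Sequences domain calling -> differential enhancers -> gene
#' classification -> loop comparison -> stratified association tests ->
#' target intersection (-> signal profiles), and returns every
#' intermediate table plus a JSON-ready summary.
#'
#' @param bundle Input bundle ([generate_dataset] or [read_bundle]).
#' @param params Parameter list, see [pipeline_params].
#' @param pathway_genes Optional gene-id vector flagged in the target
#'   table (defaults to `bundle$pathway_genes`).
#' @return A list of results; `$summary` is the deterministic summary.
#' @export
analyze_bundle <- function(bundle, params = pipeline_params(),
                           pathway_genes = NULL) {
  p <- utils::modifyList(pipeline_params(), params)
  pathway_genes <- pathway_genes %||% bundle$pathway_genes

  ## macroH2A chromatin domains
  mcd_raw <- call_mcds(bundle$mcd_peaks, merge_gap = p$merge_gap)
  mcds <- classify_mcds(score_domains(mcd_raw, bundle$mcd_track,
                                      stitch = p$stitch),
                        low_cutoff = p$low_cutoff)

  ## differential enhancers
  tssdf <- as.data.frame(bundle$tss)
  elements <- call_enhancers(bundle$h3k27ac_peaks, tssdf,
                             bundle$h3k27ac_tracks,
                             stitch_distance = p$stitch,
                             exclusion_halfwidth = p$tss_exclusion)
  enhancers <- enhancer_table(elements, bundle$sample_conditions, mcds,
                              threshold = p$enh_lfc_threshold)

  ## gene classification
  genes <- classify_degs(bundle$genes, padj_cutoff = p$deg_padj,
                         lfc_cutoff = p$deg_lfc)
  gene_gr <- genes_to_granges(genes)
  genes$mcd_klass <- annotate_mcd_class(gene_gr, mcds)

  ## loop comparison
  lw <- filter_loops(bundle$loops_wt, p$min_score)
  ld <- filter_loops(bundle$loops_dko, p$min_score)
  sharing <- classify_sharing(lw, ld)
  shifts <- adjacent_shift_fraction(sharing$loops)
  counts <- gene_loop_counts(sharing$loops, bundle$bait_map,
                             gene_ids = genes$gene_id)
  genes <- merge(genes, counts$genes, by = "gene_id", sort = TRUE)

  ## stratified association tests
  assoc_enh <- enhancer_loop_association(enhancers, sharing$loops, p$bin_size)
  assoc_gene <- gene_loop_association(genes)
  gene_gr2 <- genes_to_granges(genes)
  gene_gr2$status <- genes$de_status
  overlap_genes <- feature_mcd_overlap_test(gene_gr2, mcds)
  overlap_enh <- feature_mcd_overlap_test(enhancers, mcds)

  ## target integration
  targets <- find_target_genes(genes, enhancers, sharing$loops,
                               bundle$bait_map, p$bin_size, pathway_genes)
  proximity <- proximity_analysis(gene_gr2[genes$de_status == "up"],
                                  enhancers, window = p$proximity_window)

  ## matched static controls and profiles
  matched <- sample_matched_static(genes, k_per_gene = p$matched_k,
                                   tolerance = p$matched_tolerance,
                                   min_length = p$matched_min_length,
                                   seed = p$seed)
  profiles <- NULL
  if (isTRUE(p$run_profiles)) {
    sets <- list(up = genes$de_status == "up",
                 down = genes$de_status == "down",
                 matched_static = genes$gene_id %in% matched)
    profiles <- lapply(sets, function(idx) {
      if (!sum(idx)) return(NULL)
      metagene_profile(bundle$mcd_track, gene_gr2[idx],
                       body_bins = p$profile_body_bins,
                       flank_bp = p$profile_flank_bp,
                       flank_bins = p$profile_flank_bins,
                       bootstrap_B = p$bootstrap_B, seed = p$seed)$profile
    })
  }

  summary <- list(
    params = p,
    domains = list(
      n = length(mcds),
      by_class = as.list(table(mcds$klass)),
      elbow_cutoff = mcds$elbow_cutoff[1] %||% NA_real_
    ),
    enhancers = list(
      n = length(enhancers),
      by_kind = as.list(table(enhancers$kind)),
      by_status = as.list(table(enhancers$status)),
      gain_by_kind = as.list(table(enhancers$kind[enhancers$status == "gain"])),
      loss_by_kind = as.list(table(enhancers$kind[enhancers$status == "loss"]))
    ),
    genes = list(
      n = nrow(genes),
      by_status = as.list(table(genes$de_status))
    ),
    loops = c(as.list(sharing$counts),
              list(shift_fraction_wt = shifts$fraction_wt,
                   shift_fraction_dko = shifts$fraction_dko,
                   unassigned = as.list(counts$unassigned))),
    association = list(
      enhancer_loop = .summary_records(assoc_enh$summary),
      gene_loop = .summary_records(assoc_gene$summary),
      overlap_genes_p = overlap_genes$test$p,
      overlap_enhancers_p = overlap_enh$test$p
    ),
    targets = list(
      n = nrow(targets),
      n_net_gain = sum(targets$net_gain),
      n_pathway = if ("pathway" %in% names(targets)) sum(targets$pathway) else NA_integer_,
      gene_ids = targets$gene_id
    ),
    matched_static = list(n = length(matched))
  )

  list(mcds = mcds, enhancers = enhancers, genes = genes,
       sharing = sharing, shifts = shifts, gene_counts = counts,
       assoc_enh = assoc_enh, assoc_gene = assoc_gene,
       overlap_genes = overlap_genes, overlap_enh = overlap_enh,
       targets = targets, proximity = proximity, matched_static = matched,
       profiles = profiles, summary = summary)
}

.summary_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    list(stratum = r$stratum, skipped = r$skipped, chi2 = r$chi2,
         dof = r$dof, p = r$p, p_adj = r$p_adj)
  })
}

#' Run the full pipeline from a configuration
#'
#' The configuration (YAML path or list) holds an `inputs` section (see
#' [read_bundle]), an optional `params` section overriding
#' [pipeline_params], and an optional `out_dir`. The report directory
#' receives the intermediate tables as TSV, the classified domains as
#' BED, `summary.json` (byte-identical across runs with identical
#' configuration and seed) and a parameter log.
#'
#' @param config YAML file path or list.
#' @param out_dir Report directory (overrides the config entry; optional).
#' @return The [analyze_bundle] result list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    .assert(file.exists(config), sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config) && !is.null(config$inputs),
          "config must contain an inputs section")
  params <- utils::modifyList(pipeline_params(), config$params %||% list())
  bundle <- read_bundle(config$inputs, bin_size = params$bin_size)
  res <- analyze_bundle(bundle, params)
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(out_dir)) write_report(res, out_dir)
  invisible(res)
}

#' Write a pipeline report directory
#'
#' @param res Result of [analyze_bundle].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mcd_df <- data.table(
    chrom = as.character(seqnames(res$mcds)),
    start = start(res$mcds) - 1L, end = end(res$mcds),
    klass = res$mcds$klass, density = round(res$mcds$density, 6),
    total_signal = round(res$mcds$total_signal, 4), rank = res$mcds$rank)
  fwrite(mcd_df, file.path(out_dir, "mcds.tsv"), sep = "\t", quote = FALSE)
  enh <- res$enhancers
  enh_df <- data.table(
    chrom = as.character(seqnames(enh)), start = start(enh) - 1L,
    end = end(enh), kind = enh$kind, status = enh$status,
    mcd_klass = enh$mcd_klass, log2fc = round(enh$log2fc, 6),
    norm_wt = round(enh$norm_wt, 6), norm_dko = round(enh$norm_dko, 6))
  fwrite(enh_df, file.path(out_dir, "enhancers.tsv"), sep = "\t", quote = FALSE)
  fwrite(res$genes, file.path(out_dir, "genes_classified.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(res$sharing$loops, file.path(out_dir, "loops_labelled.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(res$gene_counts$genes, file.path(out_dir, "gene_loop_counts.tsv"),
         sep = "\t", quote = FALSE)
  fwrite(res$targets, file.path(out_dir, "targets.tsv"), sep = "\t",
         quote = FALSE)
  for (nm in c("assoc_enh", "assoc_gene")) {
    fwrite(res[[nm]]$summary, file.path(out_dir, paste0(nm, "_summary.tsv")),
           sep = "\t", quote = FALSE)
  }
  if (!is.null(res$profiles)) {
    for (nm in names(res$profiles)) {
      if (is.null(res$profiles[[nm]])) next
      fwrite(res$profiles[[nm]],
             file.path(out_dir, sprintf("profile_%s.tsv", nm)),
             sep = "\t", quote = FALSE)
    }
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
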