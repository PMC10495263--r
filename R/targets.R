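#' Name the genes targeted by hyperacetylated enhancers via looping
#'
#' The final intersection: a gene qualifies when (i) it is upregulated
#' (`de_status == "up"`) and (ii) at least one retained loop, in either
#' condition, from one of its bait bins has a distal bin overlapping an
#' enhancer that gained H3K27ac. The either-condition reading reflects
#' that a promoter may keep (rather than newly gain) its contact with a
#' hyperacetylated enhancer. The output flags genes with a net loop gain
#' and, optionally, membership of a user-supplied pathway gene set (e.g.
#' inflammatory genes).
#'
#' @param genes Gene table with `gene_id`, `de_status` and per-gene loop
#'   counts `count_wt`, `count_dko`, `net_change` (see
#'   [gene_loop_counts]).
#' @param enhancers `GRanges` with a `status` column.
#' @param loops Retained loop table (both conditions).
#' @param bait_map Bait-to-gene map (`chrom`, `bait_bin`, `gene_id`).
#' @param bin_size Bin width in bp (default 10000).
#' @param pathway_genes Optional character vector flagged in the output.
#' @return A `data.table` of target genes: `gene_id`, `count_wt`,
#'   `count_dko`, `net_change`, `net_gain` (logical), `n_gain_enh_loops`,
#'   `pathway` (logical, if `pathway_genes` given).
#' @export
find_target_genes <- function(genes, enhancers, loops, bait_map,
                              bin_size = 10000, pathway_genes = NULL) {
  g <- as.data.table(genes)
  .assert(all(c("gene_id", "de_status", "count_wt", "count_dko",
                "net_change") %in% names(g)),
          "genes need gene_id, de_status and loop counts")
  .assert(!is.null(enhancers$status), "enhancers must carry a status column")
  l <- as.data.table(loops)
  gain <- enhancers[enhancers$status == "gain"]
  if (length(gain) && nrow(l)) {
    distal <- bins_to_granges(l$chrom, l$distal_bin, bin_size)
    to_gain <- rep(FALSE, nrow(l))
    to_gain[unique(queryHits(findOverlaps(distal, granges(gain),
                                          ignore.strand = TRUE)))] <- TRUE
  } else {
    to_gain <- rep(FALSE, nrow(l))
  }
  bm <- as.data.table(bait_map)
  lg <- cbind(l, to_gain = to_gain)
  merged <- merge(lg[lg$to_gain, ], bm, by = c("chrom", "bait_bin"),
                  allow.cartesian = TRUE)
  n_gain_loops <- merged[, list(n_gain_enh_loops = .N), by = "gene_id"]
  out <- merge(g[g$de_status == "up", ], n_gain_loops, by = "gene_id")
  out$net_gain <- out$net_change > 0
  if (!is.null(pathway_genes)) out$pathway <- out$gene_id %in% pathway_genes
  keep <- intersect(c("gene_id", "count_wt", "count_dko", "net_change",
                      "net_gain", "n_gain_enh_loops", "pathway"),
                    names(out))
  data.table::setorder(out, gene_id)
  out[, keep, with = FALSE][]
}

#' Distance from each gene to its nearest H3K27ac-gaining enhancer
#'
#' Distance is the minimum gap in bp between the gene body and any
#' gain-status enhancer interval (0 when overlapping); genes within
#' `window` bp are flagged.
#'
#' @param genes `GRanges` of gene bodies (with `gene_id` in `mcols`).
#' @param enhancers `GRanges` with `status`.
#' @param window Flagging window in bp (default 50000).
#' @return A `data.frame` with `gene_id`, `distance` (`NA` when no gain
#'   enhancer exists on the gene's chromosome), `within_window`.
#' @export
proximity_analysis <- function(genes, enhancers, window = 50000) {
  gain <- enhancers[enhancers$status == "gain"]
  ids <- genes$gene_id %||% as.character(seq_along(genes))
  if (!length(gain)) {
    return(data.frame(gene_id = ids, distance = NA_real_,
                      within_window = FALSE))
  }
  d <- GenomicRanges::distanceToNearest(granges(genes), granges(gain),
                                        ignore.strand = TRUE)
  dist <- rep(NA_real_, length(genes))
  dist[queryHits(d)] <- mcols(d)$distance
  data.frame(gene_id = ids, distance = dist,
             within_window = !is.na(dist) & dist <= window)
}
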