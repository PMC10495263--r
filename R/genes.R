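#' Read a gene table
#'
#' Tab-separated with header; required columns: `gene_id`, `chrom`,
#' `start`, `end` (0-based half-open), `strand`, `tpm_wt`, `log2fc`,
#' `padj`.
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_gene_table <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  tab <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "tpm_wt",
            "log2fc", "padj")
  missing <- setdiff(need, names(tab))
  .assert(length(missing) == 0,
          sprintf("gene table lacks columns: %s", paste(missing, collapse = ", ")))
  tab
}

#' Classify genes as up / down / static from differential-expression results
#'
#' A gene is `up` when `padj < padj_cutoff` and `log2fc > lfc_cutoff`,
#' `down` symmetrically, otherwise `static`. Records with missing `padj`
#' (e.g. filtered out by independent hypothesis weighting upstream) are
#' treated as static with a warning.
#'
#' @param genes A `data.frame`/`data.table` with `log2fc` and `padj`.
#' @param padj_cutoff Adjusted-p threshold (default 0.05).
#' @param lfc_cutoff log2 fold-change threshold (default 0.75; strict
#'   inequality, matching the upstream differential-expression call).
#' @return `genes` with an added `de_status` column.
#' @export
classify_degs <- function(genes, padj_cutoff = 0.05, lfc_cutoff = 0.75) {
  g <- as.data.table(genes)
  .assert(all(c("log2fc", "padj") %in% names(g)),
          "gene table needs log2fc and padj columns")
  if (anyNA(g$padj)) {
    warning(sprintf("%d gene(s) with missing padj treated as static",
                    sum(is.na(g$padj))))
  }
  sig <- !is.na(g$padj) & g$padj < padj_cutoff
  g$de_status <- ifelse(sig & g$log2fc > lfc_cutoff, "up",
                        ifelse(sig & g$log2fc < -lfc_cutoff, "down", "static"))
  g[]
}

#' Gene bodies as GRanges
#'
#' @param genes Gene table with 0-based `start`/`end` coordinates.
#' @return A `GRanges` with gene metadata.
#' @export
genes_to_granges <- function(genes) {
  g <- as.data.table(genes)
  gr <- GRanges(g$chrom, IRanges(g$start + 1L, g$end), strand = g$strand)
  mcols(gr) <- g[, setdiff(names(g), c("chrom", "start", "end", "strand")),
                 with = FALSE]
  gr
}

#' Draw expression-matched static control genes
#'
#' For each differentially expressed (DE) gene, candidate controls are
#' non-DE genes whose WT expression lies within `tolerance` of the DE
#' gene's `tpm_wt` (window `[tpm * (1 - tol), tpm * (1 + tol)]`) and whose
#' gene body is at least `min_length` bp. `k_per_gene` candidates are drawn
#' uniformly without replacement (all of them if fewer qualify), the draws
#' are concatenated and duplicates removed keeping first occurrence. The
#' result is deterministic given `seed`. DE genes with no candidates are
#' skipped with a message.
#'
#' @param genes Gene table with `gene_id`, `tpm_wt`, `de_status` and
#'   0-based `start`/`end`.
#' @param k_per_gene Controls drawn per DE gene (typical choices: 10 for a
#'   small focused gene set, 3 for a genome-wide DEG set).
#' @param tolerance Relative TPM window half-width (default 0.25).
#' @param min_length Minimum gene-body length in bp (default 1000).
#' @param seed Integer RNG seed.
#' @return Character vector of control gene ids (duplicate-free).
#' @export
sample_matched_static <- function(genes, k_per_gene = 3, tolerance = 0.25,
                                  min_length = 1000, seed = 1) {
  g <- as.data.table(genes)
  .assert(all(c("gene_id", "tpm_wt", "de_status", "start", "end") %in% names(g)),
          "gene table needs gene_id, tpm_wt, de_status, start, end")
  de <- g[g$de_status != "static", ]
  pool <- g[g$de_status == "static" & (g$end - g$start) >= min_length, ]
  picked <- withr::with_seed(seed, {
    unlist(lapply(seq_len(nrow(de)), function(i) {
      tpm <- de$tpm_wt[i]
      cand <- pool$gene_id[pool$tpm_wt >= tpm * (1 - tolerance) &
                           pool$tpm_wt <= tpm * (1 + tolerance)]
      if (!length(cand)) {
        message(sprintf("no expression-matched candidates for %s (TPM %.3g); skipped",
                        de$gene_id[i], tpm))
        return(character(0))
      }
      if (length(cand) <= k_per_gene) return(cand)
      sample(cand, k_per_gene)
    }), use.names = FALSE)
  })
  unique(picked)
}

#' Sample static peaks from a differential-accessibility table
#'
#' Uniformly samples `n` peaks satisfying `padj > padj_min` and
#' `|log2fc| <= max_abs_lfc`; if fewer qualify, all are returned with a
#' warning.
#'
#' @param peaks A `data.frame`/`data.table` with `padj` and `log2fc`.
#' @param n Number of peaks to draw (default 3000).
#' @param padj_min Minimum adjusted p (exclusive; default 0.05).
#' @param max_abs_lfc Maximum absolute log2 fold change (inclusive;
#'   default 0.2).
#' @param seed Integer RNG seed.
#' @return The sampled subset of `peaks` (rows in drawn order).
#' @export
sample_static_peaks <- function(peaks, n = 3000, padj_min = 0.05,
                                max_abs_lfc = 0.2, seed = 1) {
  p <- as.data.table(peaks)
  .assert(all(c("padj", "log2fc") %in% names(p)),
          "peak table needs padj and log2fc columns")
  elig <- p[!is.na(p$padj) & p$padj > padj_min & abs(p$log2fc) <= max_abs_lfc, ]
  if (nrow(elig) <= n) {
    if (nrow(elig) < n) {
      warning(sprintf("only %d peaks qualify (requested %d); returning all",
                      nrow(elig), n))
    }
    return(elig[])
  }
  idx <- withr::with_seed(seed, sample(nrow(elig), n))
  elig[idx][]
}
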