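#' Chi-square test of independence with Pearson residuals
#'
#' Direct implementation: expected counts `E_ij = row_i * col_j / N`,
#' statistic `sum((O - E)^2 / E)` with no continuity correction,
#' `dof = (rows - 1)(cols - 1)`, p from the chi-square distribution, and
#' Pearson residuals `(O - E) / sqrt(E)` (the per-cell deviation quantity
#' visualized as heatmaps).
#'
#' @param table Matrix of non-negative counts, at least 2x2.
#' @return A list with `chi2`, `dof`, `p`, `expected`, `residuals`,
#'   `table`.
#' @export
chisq_independence <- function(table) {
  o <- as.matrix(table)
  .assert(is.numeric(o) && nrow(o) >= 2 && ncol(o) >= 2,
          "need a numeric matrix of at least 2x2")
  .assert(all(o >= 0), "counts must be non-negative")
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  if (any(e == 0)) {
    stop("expected count of 0: collapse empty rows/columns before testing",
         call. = FALSE)
  }
  chi2 <- sum((o - e)^2 / e)
  dof <- (nrow(o) - 1L) * (ncol(o) - 1L)
  list(chi2 = chi2, dof = dof,
       p = pchisq(chi2, dof, lower.tail = FALSE),
       expected = e, residuals = (o - e) / sqrt(e), table = o)
}

#' Adjust p-values for multiple comparisons
#'
#' Holm by default (valid without independence assumptions); any
#' [stats::p.adjust] method is accepted. Adjusted values are monotone and
#' never below the raw ones.
#'
#' @param ps Numeric vector of p-values in `[0, 1]`.
#' @param method Adjustment method (default `"holm"`).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(ps, method = "holm") {
  .assert(is.numeric(ps) && all(is.na(ps) | (ps >= 0 & ps <= 1)),
          "p-values must lie in [0, 1]")
  p.adjust(ps, method = method)
}

#' Loop relation of each enhancer
#'
#' For every enhancer, collects the sharing classes of retained loops
#' whose distal bin overlaps the enhancer interval and reduces them to one
#' category with precedence `unique_dKO > unique_WT > shared-only`.
#' Enhancers untouched by any loop get `NA` (they carry no loop
#' information and are excluded from the association tables).
#'
#' @param enhancers `GRanges` of enhancer elements.
#' @param labelled Loop table with `sharing` (output `$loops` of
#'   [classify_sharing]).
#' @param bin_size Bin width in bp (default 10000).
#' @return Character vector (`"unique_dKO"`, `"unique_WT"`,
#'   `"shared_only"`, or `NA`) per enhancer.
#' @export
enhancer_loop_relation <- function(enhancers, labelled, bin_size = 10000) {
  l <- as.data.table(labelled)
  rel <- rep(NA_character_, length(enhancers))
  if (!nrow(l) || !length(enhancers)) return(rel)
  # shared loops appear in both conditions; one vote is enough
  lu <- unique(l[, c("chrom", "distal_bin", "sharing")])
  for (cls in c("shared", "unique_WT", "unique_dKO")) {  # ascending precedence
    sub <- lu[lu$sharing == cls, ]
    if (!nrow(sub)) next
    gr <- bins_to_granges(sub$chrom, sub$distal_bin, bin_size)
    rel[subjects_hit(gr, enhancers)] <- if (cls == "shared") "shared_only" else cls
  }
  rel
}

# Run chi-square per stratum and Holm-adjust across tested strata.
# tables: named list of count matrices (possibly with empty rows/cols).
.stratified_tests <- function(tables) {
  results <- lapply(names(tables), function(st) {
    tab <- tables[[st]]
    keep_r <- rowSums(tab) > 0
    keep_c <- colSums(tab) > 0
    if (sum(keep_r) < 2 || sum(keep_c) < 2) {
      return(list(stratum = st, skipped = TRUE,
                  note = "fewer than 2 non-empty rows/columns",
                  table = tab))
    }
    tst <- chisq_independence(tab[keep_r, keep_c, drop = FALSE])
    c(list(stratum = st, skipped = FALSE, note = ""), tst)
  })
  names(results) <- names(tables)
  tested <- !vapply(results, `[[`, logical(1), "skipped")
  padj <- adjust_pvalues(vapply(results[tested], `[[`, numeric(1), "p"))
  j <- 1
  for (i in which(tested)) {
    results[[i]]$p_adj <- padj[j]
    j <- j + 1
  }
  results
}

# Compact summary of .stratified_tests output.
.stratified_summary <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(stratum = r$stratum, skipped = r$skipped,
               chi2 = if (r$skipped) NA_real_ else r$chi2,
               dof = if (r$skipped) NA_integer_ else r$dof,
               p = if (r$skipped) NA_real_ else r$p,
               p_adj = if (r$skipped) NA_real_ else r$p_adj,
               note = r$note)
  }))
}

#' Enhancer-status vs loop-status association, stratified by domain class
#'
#' Per macroH2A-domain stratum (`super`, `standard`, `none`), counts
#' enhancers in a 3x3 table of H3K27ac status (`gain`/`loss`/`static`)
#' against loop relation (`unique_dKO`/`unique_WT`/`shared_only`, see
#' [enhancer_loop_relation]) and tests independence; each enhancer votes
#' once. p-values are Holm-adjusted across strata. Strata with fewer than
#' two non-empty rows or columns are skipped with a note.
#'
#' @param enhancers `GRanges` with `status` and `mcd_klass` columns.
#' @param labelled Labelled loops (output `$loops` of [classify_sharing]).
#' @param bin_size Bin width in bp (default 10000).
#' @return A list with `strata` (per-stratum test objects), `summary`
#'   (data.frame) and `relation` (per-enhancer loop relation).
#' @export
enhancer_loop_association <- function(enhancers, labelled, bin_size = 10000) {
  .assert(!is.null(enhancers$status) && !is.null(enhancers$mcd_klass),
          "enhancers must carry status and mcd_klass")
  rel <- enhancer_loop_relation(enhancers, labelled, bin_size)
  rows <- c("gain", "loss", "static")
  cols <- c("unique_dKO", "unique_WT", "shared_only")
  strata <- c("super", "standard", "none")
  tables <- lapply(strata, function(st) {
    idx <- enhancers$mcd_klass == st & !is.na(rel)
    table(factor(enhancers$status[idx], levels = rows),
          factor(rel[idx], levels = cols))
  })
  names(tables) <- strata
  tables <- lapply(tables, function(t) {
    m <- as.matrix(unclass(t))
    storage.mode(m) <- "integer"
    m
  })
  res <- .stratified_tests(tables)
  list(strata = res, summary = .stratified_summary(res), relation = rel)
}

#' Gene-expression vs loop-count-change association, stratified by domain
#' class
#'
#' Rows are differential-expression status (`up`/`down`/`static`), columns
#' the sign of the net loop change per gene (`gained` for net > 0, `lost`
#' for net < 0, `unchanged` for net = 0, genes with no loops included in
#' `unchanged`), stratified by the gene's macroH2A domain class.
#'
#' @param genes `data.frame`/`data.table` with `de_status`, `net_change`
#'   and `mcd_klass`.
#' @return As [enhancer_loop_association]: list with `strata` and
#'   `summary`.
#' @export
gene_loop_association <- function(genes) {
  g <- as.data.table(genes)
  .assert(all(c("de_status", "net_change", "mcd_klass") %in% names(g)),
          "genes need de_status, net_change, mcd_klass")
  rows <- c("up", "down", "static")
  cols <- c("gained", "lost", "unchanged")
  loopcol <- ifelse(g$net_change > 0, "gained",
                    ifelse(g$net_change < 0, "lost", "unchanged"))
  tables <- lapply(c(super = "super", standard = "standard", none = "none"),
                   function(st) {
    idx <- g$mcd_klass == st
    m <- as.matrix(unclass(table(factor(g$de_status[idx], levels = rows),
                                 factor(loopcol[idx], levels = cols))))
    storage.mode(m) <- "integer"
    m
  })
  res <- .stratified_tests(tables)
  list(strata = res, summary = .stratified_summary(res))
}

#' Feature-status vs domain-class overlap test
#'
#' Single 3x3 table of feature status (`up`/`down`/`static` for genes,
#' `gain`/`loss`/`static` for enhancers) against overlapped macroH2A
#' domain class (`super`/`standard`/`none`, any-bp gene-body or element
#' overlap), with the chi-square test, Pearson residual heatmap matrix and
#' per-status percent overlap (each status row sums to 100).
#'
#' @param features `GRanges` with a `status` column.
#' @param mcds Classified domains from [classify_mcds].
#' @param status_levels Row order (default guesses gene vs enhancer
#'   labels from the data).
#' @return A list with `test` (chi-square result), `counts`, `percent`.
#' @export
feature_mcd_overlap_test <- function(features, mcds, status_levels = NULL) {
  .assert(!is.null(features$status), "features must carry a status column")
  klass <- annotate_mcd_class(features, mcds)
  if (is.null(status_levels)) {
    status_levels <- if (any(features$status %in% c("up", "down"))) {
      c("up", "down", "static")
    } else {
      c("gain", "loss", "static")
    }
  }
  counts <- as.matrix(unclass(table(
    factor(features$status, levels = status_levels),
    factor(klass, levels = c("super", "standard", "none")))))
  storage.mode(counts) <- "integer"
  percent <- counts / pmax(rowSums(counts), 1) * 100
  list(test = chisq_independence(counts), counts = counts, percent = percent)
}
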