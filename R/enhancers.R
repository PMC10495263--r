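#' Call traditional and super-enhancers from H3K27ac peaks
#'
#' Peaks from the master (all-conditions) H3K27ac peak set are stitched at
#' `stitch_distance` with a TSS exclusion zone (peaks fully inside
#' `tss +- exclusion_halfwidth` are dropped), then each element is
#' quantified against the supplied per-sample signal tracks. Elements are
#' split into super-enhancers (SE) and traditional enhancers (TE) by the
#' ranked-curve elbow ([find_elbow]) of total H3K27ac signal (not
#' size-normalized, standard ROSE).
#'
#' @param peaks `GRanges` of H3K27ac peaks (master set).
#' @param tss TSS specification, see [stitch_with_tss_exclusion].
#' @param tracks Named list of signal tracks (`GRanges` with `score`), one
#'   per sample.
#' @param stitch_distance Stitching distance in bp (default 12500).
#' @param exclusion_halfwidth TSS exclusion half-width in bp (default 2500).
#' @return A `GRanges` of elements with columns `kind` (`"SE"`/`"TE"`) and
#'   `signal` (element x sample matrix of raw total signal).
#' @export
call_enhancers <- function(peaks, tss, tracks,
                           stitch_distance = 12500,
                           exclusion_halfwidth = 2500) {
  .assert(is.list(tracks) && length(tracks) >= 1 && !is.null(names(tracks)),
          "tracks must be a named list of signal tracks")
  elements <- stitch_with_tss_exclusion(peaks, tss,
                                        stitch_distance = stitch_distance,
                                        exclusion_halfwidth = exclusion_halfwidth)
  if (!length(elements)) {
    elements$kind <- character(0)
    return(elements)
  }
  sig <- vapply(tracks, function(tr) {
    validate_track(tr)
    signal_over_track(elements, tr)
  }, numeric(length(elements)))
  sig <- matrix(sig, nrow = length(elements),
                dimnames = list(NULL, names(tracks)))
  total <- rowMeans(sig)
  cutoff <- if (length(total) >= 3 && diff(range(total)) > 0) {
    find_elbow(total)
  } else {
    Inf
  }
  mcols(elements) <- DataFrame(kind = ifelse(total > cutoff, "SE", "TE"),
                               signal = I(sig))
  elements
}

#' Normalize an element-by-sample signal matrix across samples
#'
#' Each sample's column is divided by that sample's mean signal over all
#' elements, so that post-normalization column means are all exactly 1.
#' This removes sequencing-depth differences between samples before
#' fold-change computation.
#'
#' @param signal Numeric matrix, elements x samples (>= 1 element, >= 2
#'   samples).
#' @return The normalized matrix.
#' @export
normalize_across_samples <- function(signal) {
  .assert(is.matrix(signal) && is.numeric(signal),
          "signal must be a numeric matrix")
  .assert(nrow(signal) >= 1 && ncol(signal) >= 2,
          "need at least 1 element and 2 samples")
  m <- colMeans(signal)
  if (any(m == 0)) {
    stop(sprintf("sample '%s' has zero total signal and cannot be normalized",
                 colnames(signal)[which(m == 0)[1]] %||% which(m == 0)[1]),
         call. = FALSE)
  }
  sweep(signal, 2, m, "/")
}

#' Classify differentially activated enhancers
#'
#' Per-condition normalized signals (replicates averaged after per-sample
#' normalization) are compared as
#' `log2fc = log2((dko + eps) / (wt + eps))`; elements with
#' `log2fc >= threshold` are gains, `<= -threshold` losses, the open band
#' in between is static. The pseudocount `eps` defaults to 1% of the
#' global normalized mean, guarding zero denominators on a scale-stable
#' footing.
#'
#' @param norm_wt,norm_dko Numeric vectors of normalized condition signal
#'   per element.
#' @param threshold Absolute log2 fold-change cutoff (default 0.75,
#'   inclusive at the boundary).
#' @param pseudocount Additive pseudocount; default `0.01 * mean(c(norm_wt,
#'   norm_dko))`.
#' @return A `data.frame` with `log2fc` and `status`
#'   (`"gain"`/`"loss"`/`"static"`).
#' @export
classify_daes <- function(norm_wt, norm_dko, threshold = 0.75,
                          pseudocount = NULL) {
  .assert(length(norm_wt) == length(norm_dko),
          "condition vectors must have equal length")
  eps <- pseudocount %||% (0.01 * mean(c(norm_wt, norm_dko)))
  lfc <- log2((norm_dko + eps) / (norm_wt + eps))
  status <- ifelse(lfc >= threshold, "gain",
                   ifelse(lfc <= -threshold, "loss", "static"))
  data.frame(log2fc = lfc, status = status, stringsAsFactors = FALSE)
}

#' Annotate elements with the macroH2A domain class they overlap
#'
#' Any-bp overlap with a super domain wins over standard (precedence
#' super > standard > none); low domains are excluded from annotation.
#'
#' @param elements `GRanges` of features (enhancers or genes).
#' @param mcds Classified domains from [classify_mcds].
#' @return Character vector of `"super"`, `"standard"` or `"none"` per
#'   element.
#' @export
annotate_mcd_class <- function(elements, mcds) {
  .assert(!is.null(mcds$klass), "mcds must be classified (klass column)")
  out <- rep("none", length(elements))
  if (!length(elements) || !length(mcds)) return(out)
  for (kl in c("standard", "super")) {  # super applied last: precedence
    dom <- mcds[mcds$klass == kl]
    if (!length(dom)) next
    out[overlaps_any(elements, dom)] <- kl
  }
  out
}

#' Assemble the full differential-enhancer table
#'
#' Convenience wrapper tying together [call_enhancers] output,
#' [normalize_across_samples], [classify_daes] and [annotate_mcd_class].
#'
#' @param elements Output of [call_enhancers].
#' @param sample_conditions Named character vector mapping sample name to
#'   condition (`"WT"` or `"dKO"`).
#' @param mcds Classified domains (optional; omit for no MCD annotation).
#' @param threshold Differential log2FC threshold (default 0.75).
#' @return `elements` with added columns `norm_wt`, `norm_dko`, `log2fc`,
#'   `status` and `mcd_klass`.
#' @export
enhancer_table <- function(elements, sample_conditions, mcds = NULL,
                           threshold = 0.75) {
  sig <- elements$signal
  .assert(!is.null(sig), "elements must carry a signal matrix")
  .assert(all(colnames(sig) %in% names(sample_conditions)),
          "every sample needs a condition assignment")
  norm <- normalize_across_samples(sig)
  cond <- sample_conditions[colnames(sig)]
  .assert(all(c("WT", "dKO") %in% cond), "need both WT and dKO samples")
  nw <- rowMeans(norm[, cond == "WT", drop = FALSE])
  nd <- rowMeans(norm[, cond == "dKO", drop = FALSE])
  cls <- classify_daes(nw, nd, threshold = threshold)
  mcols(elements) <- cbind(mcols(elements), DataFrame(
    norm_wt = nw, norm_dko = nd, log2fc = cls$log2fc, status = cls$status,
    mcd_klass = if (is.null(mcds)) rep("none", length(elements)) else
      annotate_mcd_class(elements, mcds)))
  elements
}
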