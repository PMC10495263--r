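#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges reduce findOverlaps coverage Views viewMeans
#' @importFrom BiocGenerics start end width strand sort
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom data.table data.table fread fwrite setDT as.data.table := .N .SD
#' @importFrom stats pchisq p.adjust rnorm runif rpois rexp rlnorm quantile cor setNames
#' @importFrom utils head write.table
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent number formatting for emitted text files (locale-proof)
.fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}
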