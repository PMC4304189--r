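#' @importFrom IRanges IRanges findOverlaps reduce
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All genomic intervals in this package are 0-based half-open [start, end),
# the native convention of BED, genePred and chain files. IRanges is 1-based
# closed; these two helpers are the only place the shift happens.
.as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

.overlap_hits <- function(qs, qe, ss, se) {
  IRanges::findOverlaps(.as_iranges(qs, qe), .as_iranges(ss, se))
}

#' Validate a set of genomic intervals
#'
#' Checks the internal coordinate invariant 0 <= start < end and a
#' recognised strand character.
#'
#' @param df data frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`.
#' @return `df`, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
validate_coords <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(df)
}

# strand-aware TSS: leftmost base for +, rightmost transcribed base for -
# (end is half-open, so the - strand TSS is at coordinate `end`).
.tss_of <- function(start, end, strand) {
  ifelse(strand == "+", start, end)
}

# parse "a,b,c," comma lists (genePred/BED12 style) into integer vectors
.split_commas <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(v) as.integer(v[nzchar(v)]))
}

.join_commas <- function(lst) {
  vapply(lst, function(v) paste0(paste(v, collapse = ","), ","), character(1))
}
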