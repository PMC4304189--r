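# TSS validation: CAGE coincidence profiles around annotated start sites,
# per-pair coordinated activation across samples, and CpG-island overlap
# statistics for bidirectional versus single-gene promoters.

#' CAGE coincidence profile around TSSs
#'
#' For each strand-oriented offset bin around the representative TSS,
#' the percentage of loci with at least one CAGE summit in that bin.
#' Offsets are oriented in the direction of transcription (a summit
#' downstream of a minus-strand TSS has a positive offset). A locus can
#' contribute to several bins, so the bins are percentages, not a
#' distribution.
#'
#' @param loci locus table from [cluster_transcripts()].
#' @param peaks CAGE table from [read_cage_peaks()].
#' The bins are centred on offsets `-window, -window + bin, ..., window`,
#' so the central bin straddles the TSS itself (offsets in
#' `[-bin/2, bin/2)`), making the profile symmetric about 0.
#'
#' @param window half-window around the TSS in bp.
#' @param bin bin width in bp; `window` must be a multiple of `bin`.
#' @return data frame `offset` (bin centre, bp relative to TSS, oriented
#'   along the direction of transcription) and `percent_supported`.
#' @export
tss_cage_profile <- function(loci, peaks, window = 500, bin = 50) {
  if (window %% bin != 0) stop("window must be a multiple of bin")
  centers <- seq(-window, window, by = bin)
  edges <- c(centers - bin / 2, centers[length(centers)] + bin / 2)
  nb <- length(centers)
  hit <- matrix(FALSE, nrow = nrow(loci), ncol = nb)
  for (i in seq_len(nrow(loci))) {
    s <- peaks$summit[peaks$chrom == loci$chrom[i]]
    if (!length(s)) next
    off <- s - loci$tss[i]
    if (loci$strand[i] == "-") off <- -off
    b <- findInterval(off, edges, rightmost.closed = FALSE)
    b <- b[b >= 1 & b <= nb]
    hit[i, unique(b)] <- TRUE
  }
  pct <- if (nrow(loci)) 100 * colMeans(hit) else rep(0, nb)
  data.frame(offset = centers, percent_supported = pct)
}

#' Is a TSS supported by a CAGE summit?
#'
#' @param tss integer TSS coordinate(s).
#' @param chrom chromosome of each TSS.
#' @param peaks CAGE table (optionally pre-filtered to one sample).
#' @param tolerance maximum |summit - TSS| in bp.
#' @return logical vector, one per TSS.
#' @export
tss_supported <- function(tss, chrom, peaks, tolerance = 100) {
  vapply(seq_along(tss), function(i) {
    s <- peaks$summit[peaks$chrom == chrom[i]]
    any(abs(s - tss[i]) <= tolerance)
  }, logical(1))
}

#' Fraction of pairs with coordinated transcriptional activation
#'
#' A pair is coordinately activated when at least one CAGE sample supports
#' both its left and right TSS (each within `tolerance`). Returns the
#' percentage of such pairs, or `NA` on an empty pair list.
#'
#' @param pairs pair table from [find_bidirectional_pairs()].
#' @param peaks CAGE table with `sample_label`.
#' @param tolerance bp tolerance passed to [tss_supported()].
#' @return list with `percent` (scalar, 0-100 or `NA`) and `coactivated`
#'   (logical per pair).
#' @export
coordinated_activation_fraction <- function(pairs, peaks, tolerance = 100) {
  if (!nrow(pairs)) return(list(percent = NA_real_, coactivated = logical()))
  co <- rep(FALSE, nrow(pairs))
  for (smp in unique(peaks$sample_label)) {
    pk <- peaks[peaks$sample_label == smp, , drop = FALSE]
    left <- tss_supported(pairs$left_tss, pairs$chrom, pk, tolerance)
    right <- tss_supported(pairs$right_tss, pairs$chrom, pk, tolerance)
    co <- co | (left & right)
  }
  list(percent = 100 * mean(co), coactivated = co)
}

#' CpG-island overlap of bidirectional and single-gene promoters
#'
#' The bidirectional promoter region is the inter-TSS interval, padded
#' symmetrically to a minimum width (200 bp by default); the single-gene
#' promoter is a `[TSS - flank, TSS + flank)` window. Each percentage is
#' the fraction of regions intersecting at least one island.
#'
#' @param pairs pair table (bidirectional promoters).
#' @param single_tss data frame `chrom`, `tss` for genes not in any pair.
#' @param islands CpG island intervals from [read_bed_intervals()].
#' @param flank single-gene promoter half-width in bp.
#' @param min_width minimum width of the bidirectional promoter region.
#' @return list with `bidirectional_pct`, `single_pct`,
#'   `bidirectional_n_hit`, `single_n_hit`.
#' @export
cpg_overlap_stats <- function(pairs, single_tss, islands, flank = 500,
                              min_width = 200) {
  widen <- function(s, e, minw) {
    w <- e - s
    pad <- pmax(0, ceiling((minw - w) / 2))
    cbind(s - pad, e + pad)
  }
  hit_any <- function(chrom, s, e) {
    if (!length(chrom)) return(logical())
    out <- logical(length(chrom))
    for (cc in unique(chrom)) {
      qi <- which(chrom == cc)
      isl <- islands[islands$chrom == cc, , drop = FALSE]
      if (!nrow(isl)) next
      hits <- .overlap_hits(s[qi], e[qi], isl$start, isl$end)
      out[qi[unique(S4Vectors::queryHits(hits))]] <- TRUE
    }
    out
  }
  bw <- widen(pairs$start, pairs$end, min_width)
  bid <- hit_any(pairs$chrom, bw[, 1], bw[, 2])
  sgl <- hit_any(single_tss$chrom, single_tss$tss - flank, single_tss$tss + flank)
  list(bidirectional_pct = if (length(bid)) 100 * mean(bid) else 0,
       single_pct = if (length(sgl)) 100 * mean(sgl) else 0,
       bidirectional_n_hit = sum(bid), single_n_hit = sum(sgl))
}
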