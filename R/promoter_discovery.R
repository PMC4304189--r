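# Bidirectional promoter discovery: transcripts -> non-overlapping gene
# loci -> divergent (head-to-head) pairs whose TSSs lie within a distance
# limit -> collapsed, confidence-scored promoter set.

#' Cluster transcripts into non-overlapping gene loci
#'
#' Transcripts on the same chromosome and strand that overlap (directly or
#' through a chain of overlaps) are condensed into one locus. The locus
#' span is the union of its members; its representative TSS is the most
#' extreme 5' TSS among members (minimum start on `+`, maximum end on `-`).
#'
#' @param tx transcript table from [read_transcripts()].
#' @return locus table: `locus_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `n_support` (member transcript count), `transcript_ids`
#'   (comma-joined), `gene_symbol` (most frequent member symbol), `source`.
#' @export
cluster_transcripts <- function(tx) {
  if (!nrow(tx)) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      tss = integer(), n_support = integer(),
                      transcript_ids = character(), gene_symbol = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  validate_coords(tx)
  out <- list()
  for (key in unique(paste(tx$chrom, tx$strand))) {
    sub <- tx[paste(tx$chrom, tx$strand) == key, , drop = FALSE]
    red <- IRanges::reduce(.as_iranges(sub$start, sub$end))
    hits <- IRanges::findOverlaps(.as_iranges(sub$start, sub$end), red)
    comp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (k in seq_along(red)) {
      mem <- sub[comp == k, , drop = FALSE]
      strand <- mem$strand[1]
      sym <- names(sort(table(mem$gene_symbol), decreasing = TRUE))[1]
      out[[length(out) + 1L]] <- data.frame(
        locus_id = NA_character_, chrom = mem$chrom[1],
        start = min(mem$start), end = max(mem$end), strand = strand,
        tss = if (strand == "+") min(mem$tss) else max(mem$tss),
        n_support = nrow(mem),
        transcript_ids = paste(sort(mem$id), collapse = ","),
        gene_symbol = if (is.null(sym)) NA_character_ else sym,
        source = mem$source[1], stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$chrom, loci$start, loci$strand), , drop = FALSE]
  loci$locus_id <- sprintf("%s_locus_%04d", substr(loci$source, 1, 2), seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci
}

#' Filter spliced-EST transcripts
#'
#' Keeps only multi-exon EST transcripts (at least one intron) and, when
#' `require_canonical_intron` is set, only those with a canonical GT..AG
#' intron. With `genome_seq` supplied (a named list or character vector of
#' chromosome sequences) the splice dinucleotides are checked directly;
#' without sequence the `canonical_intron` flag carried by the annotation is
#' trusted.
#'
#' @param tx transcript table with `source == "spliced_est"` rows.
#' @param require_canonical_intron require a GT..AG intron.
#' @param genome_seq optional named list/vector of chromosome sequences
#'   (plain character strings, 1-based indexing into the string).
#' @return filtered transcript table.
#' @export
filter_spliced <- function(tx, require_canonical_intron = TRUE, genome_seq = NULL) {
  tx <- tx[tx$source == "spliced_est" & tx$n_exons >= 2L, , drop = FALSE]
  if (!nrow(tx) || !require_canonical_intron) return(tx)
  if (is.null(genome_seq)) {
    keep <- !is.na(tx$canonical_intron) & tx$canonical_intron
    return(tx[keep, , drop = FALSE])
  }
  keep <- vapply(seq_len(nrow(tx)), function(i) {
    seqs <- genome_seq[[tx$chrom[i]]]
    if (is.null(seqs)) stop("no sequence supplied for chromosome ", tx$chrom[i])
    seqs <- as.character(seqs)
    has_canonical_intron(.split_commas(tx$exon_starts[i])[[1]],
                         .split_commas(tx$exon_ends[i])[[1]],
                         tx$strand[i], seqs)
  }, logical(1))
  tx[keep, , drop = FALSE]
}

#' Test whether any intron has canonical GT..AG splice sites
#'
#' @param exon_starts,exon_ends sorted 0-based exon block coordinates.
#' @param strand `"+"` or `"-"`.
#' @param chrom_seq chromosome sequence as one character string.
#' @return logical scalar.
#' @export
has_canonical_intron <- function(exon_starts, exon_ends, strand, chrom_seq) {
  n <- length(exon_starts)
  if (n < 2) return(FALSE)
  for (j in seq_len(n - 1)) {
    don_start <- exon_ends[j]       # first intron base, 0-based
    acc_end <- exon_starts[j + 1]   # one past last intron base
    if (acc_end - don_start < 4) next
    intron <- toupper(substr(chrom_seq, don_start + 1L, acc_end))
    left <- substr(intron, 1, 2)
    right <- substr(intron, nchar(intron) - 1L, nchar(intron))
    # on the minus strand the transcribed donor is at the right edge
    ok <- if (strand == "+") left == "GT" && right == "AG"
          else left == "CT" && right == "AC"
    if (ok) return(TRUE)
  }
  FALSE
}

#' Find bidirectional (divergent) gene pairs
#'
#' A bidirectional pair is a minus-strand locus and a plus-strand locus on
#' the same chromosome transcribed away from each other, with the minus
#' TSS at or left of the plus TSS and the two TSSs separated by at most
#' `max_tss_distance` (1,000 bp by default; `Inf` removes the limit). The
#' promoter is the inter-TSS interval. Each locus joins at most one pair:
#' candidate pairs are ranked by TSS distance (ties by smaller start
#' coordinate) and accepted greedily.
#'
#' @param loci locus table from [cluster_transcripts()].
#' @param max_tss_distance maximum TSS separation in bp, or `Inf`.
#' @return pair table: `pair_id`, `chrom`, `left_locus`, `right_locus`,
#'   `left_tss`, `right_tss`, `tss_distance`, `start`, `end` (the promoter
#'   interval), `n_support_left`, `n_support_right`, `left_symbol`,
#'   `right_symbol`, `confidence`.
#' @export
find_bidirectional_pairs <- function(loci, max_tss_distance = 1000) {
  empty <- data.frame(pair_id = character(), chrom = character(),
                      left_locus = character(), right_locus = character(),
                      left_tss = integer(), right_tss = integer(),
                      tss_distance = integer(), start = integer(), end = integer(),
                      n_support_left = integer(), n_support_right = integer(),
                      left_symbol = character(), right_symbol = character(),
                      confidence = integer(), stringsAsFactors = FALSE)
  minus <- loci[loci$strand == "-", , drop = FALSE]
  plus <- loci[loci$strand == "+", , drop = FALSE]
  if (!nrow(minus) || !nrow(plus)) return(empty)
  cand <- list()
  for (i in seq_len(nrow(minus))) {
    p <- plus[plus$chrom == minus$chrom[i] & plus$tss >= minus$tss[i], , drop = FALSE]
    p <- p[p$tss - minus$tss[i] <= max_tss_distance, , drop = FALSE]
    if (!nrow(p)) next
    cand[[length(cand) + 1L]] <- data.frame(
      mi = i, pj = match(p$locus_id, plus$locus_id),
      dist = p$tss - minus$tss[i],
      start_key = pmin(minus$start[i], p$start), stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, cand$start_key), , drop = FALSE]
  used_m <- logical(nrow(minus)); used_p <- logical(nrow(plus))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$mi[r]; j <- cand$pj[r]
    if (used_m[i] || used_p[j]) next
    used_m[i] <- TRUE; used_p[j] <- TRUE
    lt <- minus$tss[i]; rt <- plus$tss[j]
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = NA_character_, chrom = minus$chrom[i],
      left_locus = minus$locus_id[i], right_locus = plus$locus_id[j],
      left_tss = lt, right_tss = rt, tss_distance = rt - lt,
      start = lt, end = rt,
      n_support_left = minus$n_support[i], n_support_right = plus$n_support[j],
      left_symbol = minus$gene_symbol[i], right_symbol = plus$gene_symbol[j],
      confidence = NA_integer_, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(pairs$chrom, pairs$start, pairs$end), , drop = FALSE]
  pairs$pair_id <- sprintf("pair_%04d", seq_len(nrow(pairs)))
  pairs$confidence <- assign_confidence(pairs)
  rownames(pairs) <- NULL
  pairs
}

#' Collapse overlapping candidate promoters
#'
#' Candidate pairs whose promoter intervals overlap are merged into the
#' candidate with the most supporting transcripts (ties broken by smaller
#' TSS distance, then leftmost start). The surviving candidate aggregates
#' the supporter counts of everything it absorbed and its confidence is
#' recomputed from the aggregated counts, so the output promoter intervals
#' are mutually non-overlapping. Idempotent.
#'
#' @param pairs pair table from [find_bidirectional_pairs()].
#' @return collapsed pair table.
#' @export
collapse_promoters <- function(pairs) {
  if (nrow(pairs) < 2) return(pairs)
  out <- list()
  for (chrom in unique(pairs$chrom)) {
    sub <- pairs[pairs$chrom == chrom, , drop = FALSE]
    # promoter can be zero-width (shared TSS); widen by 0 is fine since
    # tss_distance >= 0; treat zero-width as a 1 bp point for overlap tests
    s <- sub$start; e <- pmax(sub$end, sub$start + 1L)
    red_r <- IRanges::reduce(.as_iranges(s, e))
    hits <- IRanges::findOverlaps(.as_iranges(s, e), red_r)
    comp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    for (k in unique(comp)) {
      mem <- sub[comp == k, , drop = FALSE]
      supp <- mem$n_support_left + mem$n_support_right
      o <- order(-supp, mem$tss_distance, mem$start)
      win <- mem[o[1], , drop = FALSE]
      win$n_support_left <- sum(mem$n_support_left)
      win$n_support_right <- sum(mem$n_support_right)
      out[[length(out) + 1L]] <- win
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  res$confidence <- assign_confidence(res)
  rownames(res) <- NULL
  res
}

#' Assign a confidence level to bidirectional pairs
#'
#' Level 3 when both loci have at least `high` supporting transcripts,
#' level 2 when both have at least `low`, level 1 otherwise; monotone
#' non-decreasing in either count.
#'
#' @param pairs pair table (uses `n_support_left`, `n_support_right`).
#' @param low,high supporter-count cutoffs for levels 2 and 3.
#' @return integer vector of confidence levels.
#' @export
assign_confidence <- function(pairs, low = 2L, high = 5L) {
  lo <- pmin(pairs$n_support_left, pairs$n_support_right)
  ifelse(lo >= high, 3L, ifelse(lo >= low, 2L, 1L))
}

#' Promoters found only by the EST annotations
#'
#' The "additional promoters" set: EST-derived pairs whose promoter
#' interval overlaps no known-gene pair's promoter interval.
#'
#' @param est_pairs,kg_pairs pair tables from the two annotation sources.
#' @return subset of `est_pairs`.
#' @export
est_only_promoters <- function(est_pairs, kg_pairs) {
  if (!nrow(est_pairs) || !nrow(kg_pairs)) return(est_pairs)
  drop <- logical(nrow(est_pairs))
  for (chrom in unique(est_pairs$chrom)) {
    ei <- which(est_pairs$chrom == chrom)
    kg <- kg_pairs[kg_pairs$chrom == chrom, , drop = FALSE]
    if (!nrow(kg)) next
    hits <- .overlap_hits(est_pairs$start[ei], pmax(est_pairs$end[ei], est_pairs$start[ei] + 1L),
                          kg$start, pmax(kg$end, kg$start + 1L))
    drop[ei[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  est_pairs[!drop, , drop = FALSE]
}
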