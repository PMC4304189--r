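# Independent brute-force oracles and random-record generators used across
# the suite. The oracles deliberately avoid the package's own interval and
# block arithmetic: per-base loops and O(n^2) graph scans only.

# -- random records ---------------------------------------------------------

random_transcripts <- function(n, chrom = "chrZ", source = "known_gene") {
  rows <- lapply(seq_len(n), function(i) {
    start <- sample(0:50000, 1)
    n_ex <- sample(1:4, 1)
    ex_s <- sort(sample(seq(start, start + 4000, by = 10), n_ex))
    # block length < 10 keeps blocks disjoint on the 10 bp start grid
    ex_e <- ex_s + sample(5:9, n_ex, replace = TRUE)
    strand <- sample(c("+", "-"), 1)
    data.frame(id = sprintf("tx%03d", i), chrom = chrom, start = ex_s[1],
               end = ex_e[n_ex], strand = strand,
               tss = if (strand == "+") ex_s[1] else ex_e[n_ex],
               exon_starts = paste0(paste(ex_s, collapse = ","), ","),
               exon_ends = paste0(paste(ex_e, collapse = ","), ","),
               n_exons = n_ex, source = source,
               canonical_intron = if (source == "spliced_est") sample(c(TRUE, FALSE), 1) else NA,
               gene_symbol = sprintf("tx%03d", i), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

random_chain <- function(id, q_strand = sample(c("+", "-"), 1)) {
  n_blocks <- sample(1:6, 1)
  sizes <- sample(50:500, n_blocks, replace = TRUE)
  dts <- c(sample(0:300, max(0, n_blocks - 1), replace = TRUE), 0L)
  dqs <- c(sample(0:300, max(0, n_blocks - 1), replace = TRUE), 0L)
  t_start <- sample(0:5000, 1)
  t_span <- sum(sizes) + sum(dts)
  q_size <- 120000L
  q_span <- sum(sizes) + sum(dqs)
  q_start <- sample(0:(q_size - q_span), 1)
  list(score = sample(1000:100000, 1), t_chrom = paste0("chrT", id),
       t_size = 100000L, t_start = t_start, t_end = t_start + t_span,
       q_chrom = paste0("chrQ", id), q_size = q_size, q_strand = q_strand,
       q_start = q_start, q_end = q_start + q_span, chain_id = id,
       blocks = data.frame(size = sizes, dt = dts, dq = dqs))
}

# loci table built directly (bypassing transcript clustering) for
# pair-finding tests
make_loci <- function(chrom, tss, strand, start = NULL, end = NULL,
                      n_support = 1L, source = "known_gene") {
  n <- length(tss)
  if (is.null(start)) start <- ifelse(strand == "+", tss, tss - 2000L)
  if (is.null(end)) end <- ifelse(strand == "+", tss + 2000L, tss)
  data.frame(locus_id = sprintf("L%04d", seq_len(n)), chrom = chrom,
             start = start, end = end, strand = strand, tss = tss,
             n_support = rep_len(n_support, n),
             transcript_ids = sprintf("L%04d.1", seq_len(n)),
             gene_symbol = sprintf("L%04d", seq_len(n)),
             source = source, stringsAsFactors = FALSE)
}

# -- oracles ----------------------------------------------------------------

# connected components of the transcript overlap graph, O(n^2)
bf_overlap_components <- function(tx) {
  n <- nrow(tx)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- tx$chrom[i] == tx$chrom[j] & tx$strand[i] == tx$strand[j] &
      tx$start[i] < tx$end[j] & tx$start[j] < tx$end[i]
  }
  comp <- rep(NA_integer_, n); k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(tx$id, comp)
}

# greedy divergent pairing over the full candidate enumeration
bf_pairs <- function(loci, maxd) {
  minus <- loci[loci$strand == "-", ]; plus <- loci[loci$strand == "+", ]
  cand <- expand.grid(i = seq_len(nrow(minus)), j = seq_len(nrow(plus)))
  keep <- minus$chrom[cand$i] == plus$chrom[cand$j] &
    plus$tss[cand$j] >= minus$tss[cand$i] &
    plus$tss[cand$j] - minus$tss[cand$i] <= maxd
  cand <- cand[keep, , drop = FALSE]
  cand$dist <- plus$tss[cand$j] - minus$tss[cand$i]
  cand$key <- pmin(minus$start[cand$i], plus$start[cand$j])
  cand <- cand[order(cand$dist, cand$key), , drop = FALSE]
  um <- logical(nrow(minus)); up <- logical(nrow(plus)); out <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (um[i] || up[j]) next
    um[i] <- TRUE; up[j] <- TRUE
    out[[length(out) + 1L]] <- c(minus$locus_id[i], plus$locus_id[j])
  }
  out
}

# per-base chain mapping: walks every block base individually
bf_map_bases <- function(chain, start, end) {
  res <- integer(0)
  tpos <- chain$t_start; qpos <- chain$q_start
  for (i in seq_len(nrow(chain$blocks))) {
    sz <- chain$blocks$size[i]
    for (b in seq.int(tpos, tpos + sz - 1L)) {
      if (b >= start && b < end) {
        qb <- qpos + (b - tpos)
        if (chain$q_strand == "-") qb <- chain$q_size - 1L - qb
        res <- c(res, qb)
      }
    }
    tpos <- tpos + sz + chain$blocks$dt[i]
    qpos <- qpos + sz + chain$blocks$dq[i]
  }
  sort(res)
}

# target-genome bases of a chain that sit inside gapless aligned blocks
bf_aligned_target_bases <- function(chain) {
  res <- integer(0)
  tpos <- chain$t_start
  for (i in seq_len(nrow(chain$blocks))) {
    res <- c(res, seq.int(tpos, tpos + chain$blocks$size[i] - 1L))
    tpos <- tpos + chain$blocks$size[i] + chain$blocks$dt[i]
  }
  sort(res)
}

pieces_to_bases <- function(pieces) {
  if (!nrow(pieces)) return(integer(0))
  sort(unlist(Map(function(s, e) seq.int(s, e - 1L), pieces$start, pieces$end)))
}

# liftOver oracle through rtracklayer on a chain written to disk
liftover_bases <- function(chains, chain, start, end) {
  f <- tempfile(fileext = ".chain")
  write_chain(chains, f)
  ch <- rtracklayer::import.chain(f)
  gr <- GenomicRanges::GRanges(chain$t_chrom,
                               IRanges::IRanges(start + 1L, end))
  res <- rtracklayer::liftOver(gr, ch)[[1]]
  res <- res[GenomicRanges::seqnames(res) == chain$q_chrom]
  out <- unlist(Map(seq.int, GenomicRanges::start(res) - 1L,
                    GenomicRanges::end(res) - 1L))
  if (is.null(out)) integer(0) else sort(as.integer(out))
}
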