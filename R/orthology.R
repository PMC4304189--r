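# Cross-genome orthology classification of bidirectional promoters.
#
# The decision procedure follows conserved synteny through chain/net
# pairwise alignments: only level-1 net fills (the longest, best-scoring
# chains, which exclude paralogous deeper levels) define orthologous
# regions. A gene of a bidirectional pair is mapped through the level-1
# chain covering its TSS and classified into one of five categories:
#   C1  ortholog present with an orthologous divergent partner within limit
#   C2  ortholog present with a non-orthologous divergent partner within limit
#   C3  ortholog present but no divergent partner within limit
#   C4  a non-orthologous gene occupies the mapped location
#   C5  no orthology recorded (outside level-1 alignment, or nothing maps)

CATEGORIES <- c("C1", "C2", "C3", "C4", "C5")

#' Level-1 orthologous regions of a net
#'
#' Keeps only level-1 fills; deeper levels mix paralogous and orthologous
#' sequence and are discarded.
#'
#' @param nets net fill table from [read_net()].
#' @return subset of `nets` with `level == 1`.
#' @export
level1_regions <- function(nets) {
  nets[nets$level == 1L, , drop = FALSE]
}

#' Map an interval through a chain alignment
#'
#' Pure block arithmetic: bases inside gapless aligned blocks map with the
#' block's offset; bases falling into target (`dt`) or query (`dq`) gaps are
#' dropped, which can split the interval. For reverse-strand query chains
#' the UCSC convention stores query coordinates on the reversed strand; the
#' mapped pieces are flipped back to forward-strand coordinates here.
#'
#' @param chain a single chain from [read_chain()].
#' @param start,end interval on the chain's target sequence, 0-based
#'   half-open.
#' @return data frame `chrom`, `start`, `end`, `strand` of mapped query
#'   pieces (forward-strand coordinates), sorted; zero rows when nothing
#'   aligns.
#' @export
map_interval <- function(chain, start, end) {
  stopifnot(start < end)
  b <- chain$blocks
  tpos <- chain$t_start
  qpos <- chain$q_start
  pieces <- list()
  for (i in seq_len(nrow(b))) {
    bs <- tpos; be <- tpos + b$size[i]
    os <- max(start, bs); oe <- min(end, be)
    if (os < oe) {
      qs <- qpos + (os - bs)
      pieces[[length(pieces) + 1L]] <- c(qs, qs + (oe - os))
    }
    tpos <- be + b$dt[i]
    qpos <- qpos + b$size[i] + b$dq[i]
    if (tpos >= end) break
  }
  if (!length(pieces))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, pieces)
  if (chain$q_strand == "-") {
    m <- cbind(chain$q_size - m[, 2], chain$q_size - m[, 1])
  }
  out <- data.frame(chrom = chain$q_chrom, start = as.integer(m[, 1]),
                    end = as.integer(m[, 2]), strand = chain$q_strand,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Map a set of intervals through a chain set keyed by chain id
#'
#' Convenience wrapper used for lifting CAGE peaks or promoter intervals;
#' unknown chain ids are an error.
#'
#' @param chains named list from [read_chain()].
#' @param intervals data frame `chrom`, `start`, `end`.
#' @param chain_id id of the chain to map through (scalar or per-interval).
#' @return list of mapped-piece data frames, one per input interval.
#' @export
map_intervals <- function(chains, intervals, chain_id) {
  chain_id <- rep_len(as.character(chain_id), nrow(intervals))
  lapply(seq_len(nrow(intervals)), function(i) {
    ch <- chains[[chain_id[i]]]
    if (is.null(ch)) stop("unknown chain id: ", chain_id[i])
    if (intervals$chrom[i] != ch$t_chrom)
      return(map_interval(ch, 0L, 1L)[0, ])
    map_interval(ch, intervals$start[i], intervals$end[i])
  })
}

#' Fraction of exonic bases in alignable (gapless-block) positions
#'
#' Intersects a gene's exon blocks with the chain's aligned blocks; a gene
#' passes the alignability requirement when the fraction is at least the
#' configured threshold (0.5 by default in [classify_gene()]).
#'
#' @param exon_starts,exon_ends 0-based exon block coordinates.
#' @param chain a single chain from [read_chain()].
#' @return fraction in \[0, 1\].
#' @export
exons_alignable <- function(exon_starts, exon_ends, chain) {
  total <- sum(exon_ends - exon_starts)
  if (total == 0) return(0)
  aligned <- 0L
  tpos <- chain$t_start
  b <- chain$blocks
  for (i in seq_len(nrow(b))) {
    bs <- tpos; be <- tpos + b$size[i]
    aligned <- aligned + sum(pmax(0L, pmin(exon_ends, be) - pmax(exon_starts, bs)))
    tpos <- be + b$dt[i]
  }
  aligned / total
}

# internal: locate the level-1 chain covering a TSS; highest score wins
# when fills abut and both cover the position.
.level1_chain_for <- function(tss, chrom, level1, chains) {
  hit <- level1[level1$target_chrom == chrom & level1$start <= tss &
                  level1$end > tss, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  cand <- chains[as.character(hit$chain_id)]
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (!length(cand)) return(NULL)
  cand[[order(-vapply(cand, `[[`, numeric(1), "score"))[1]]]
}

# internal: best target-genome locus overlapping any mapped piece
.best_hit_locus <- function(pieces, target_loci, strand = NULL) {
  if (!nrow(pieces)) return(NULL)
  cand <- target_loci[target_loci$chrom == pieces$chrom[1], , drop = FALSE]
  if (!is.null(strand)) cand <- cand[cand$strand == strand, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  ov <- numeric(nrow(cand))
  for (j in seq_len(nrow(pieces)))
    ov <- ov + pmax(0L, pmin(cand$end, pieces$end[j]) - pmax(cand$start, pieces$start[j]))
  if (max(ov) <= 0) return(NULL)
  cand[which.max(ov), , drop = FALSE]
}

.orth_match <- function(orth, source_symbol, target_symbol) {
  any(orth$source == source_symbol & orth$target == target_symbol)
}

#' Classify one gene of a bidirectional pair in the second genome
#'
#' Applies the five-category decision procedure (see the module header).
#' Identity of known genes in the mapped location is checked against the
#' ortholog table; spliced-EST loci, which carry no protein identity, are
#' accepted on position alone (conserved synteny), and their partner is
#' checked by mapping the source partner and requiring overlap with the
#' target-side divergent partner.
#'
#' @param gene,partner single-row locus tables (the assessed gene and its
#'   pair partner) from [cluster_transcripts()].
#' @param resources list with `level1` (from [level1_regions()]), `chains`
#'   (from [read_chain()]), `target_loci` (clustered loci of the second
#'   genome) and `orthologs` (from [read_orthologs()]).
#' @param max_distance maximum target-side TSS separation in bp (`Inf` for
#'   no limit).
#' @param align_threshold minimum [exons_alignable()] fraction.
#' @return list with `category` (`"C1"`..`"C5"`), `mapped` (mapped gene
#'   pieces), `target_locus` and `target_partner` ids (or `NA`).
#' @export
classify_gene <- function(gene, partner, resources, max_distance = 1000,
                          align_threshold = 0.5) {
  for (need in c("level1", "chains", "target_loci", "orthologs"))
    if (is.null(resources[[need]]))
      stop("orthology resources missing component: ", need)
  res <- list(category = "C5", mapped = NULL,
              target_locus = NA_character_, target_partner = NA_character_)
  # (a) TSS must fall in a level-1 orthologous region
  chain <- .level1_chain_for(gene$tss, gene$chrom, resources$level1, resources$chains)
  if (is.null(chain)) return(res)
  # exon alignability: without alignable exons no orthology is recorded
  ex <- .locus_exons(gene)
  if (exons_alignable(ex$starts, ex$ends, chain) < align_threshold) return(res)
  mapped <- map_interval(chain, gene$start, gene$end)
  res$mapped <- mapped
  if (!nrow(mapped)) return(res)
  # expected strand of the ortholog in the target genome
  exp_strand <- if (chain$q_strand == "+") gene$strand else setdiff(c("+", "-"), gene$strand)
  tl <- .best_hit_locus(mapped, resources$target_loci, strand = exp_strand)
  if (is.null(tl)) tl <- .best_hit_locus(mapped, resources$target_loci)
  if (is.null(tl)) return(res)   # C5: no gene recorded at the mapped location
  res$target_locus <- tl$locus_id
  # (b) identity check at the mapped location
  identity_ok <- if (gene$source == "known_gene")
    .orth_match(resources$orthologs, gene$gene_symbol, tl$gene_symbol)
  else TRUE   # EST: presence in the orthologous position is the criterion
  if (!identity_ok) { res$category <- "C4"; return(res) }
  # (c) divergent partner of the target ortholog within max_distance,
  # measured between target-side TSSs
  cand <- resources$target_loci
  cand <- cand[cand$chrom == tl$chrom & cand$strand != tl$strand, , drop = FALSE]
  if (tl$strand == "+") {
    cand <- cand[cand$tss <= tl$tss & tl$tss - cand$tss <= max_distance, , drop = FALSE]
    dist <- tl$tss - cand$tss
  } else {
    cand <- cand[cand$tss >= tl$tss & cand$tss - tl$tss <= max_distance, , drop = FALSE]
    dist <- cand$tss - tl$tss
  }
  if (!nrow(cand)) { res$category <- "C3"; return(res) }
  tp <- cand[which.min(dist), , drop = FALSE]
  res$target_partner <- tp$locus_id
  # (d)/(e) is that partner the ortholog of the source partner?
  partner_ok <- if (partner$source == "known_gene") {
    .orth_match(resources$orthologs, partner$gene_symbol, tp$gene_symbol)
  } else {
    pchain <- .level1_chain_for(partner$tss, partner$chrom, resources$level1,
                                resources$chains)
    if (is.null(pchain)) FALSE else {
      pm <- map_interval(pchain, partner$start, partner$end)
      nrow(pm) > 0 &&
        any(pm$chrom == tp$chrom & pmin(pm$end, tp$end) > pmax(pm$start, tp$start))
    }
  }
  res$category <- if (partner_ok) "C1" else "C2"
  res
}

# union of member-transcript exon blocks of a locus; falls back to the
# locus span when the transcript table is not attached
.locus_exons <- function(locus) {
  if (!is.null(locus$exon_starts) && !is.na(locus$exon_starts)) {
    list(starts = .split_commas(locus$exon_starts)[[1]],
         ends = .split_commas(locus$exon_ends)[[1]])
  } else {
    list(starts = locus$start, ends = locus$end)
  }
}

# attach the union of member exon blocks to each locus
.attach_locus_exons <- function(loci, tx) {
  loci$exon_starts <- NA_character_; loci$exon_ends <- NA_character_
  if (!nrow(tx)) return(loci)
  for (i in seq_len(nrow(loci))) {
    ids <- strsplit(loci$transcript_ids[i], ",", fixed = TRUE)[[1]]
    mem <- tx[tx$id %in% ids, , drop = FALSE]
    if (!nrow(mem)) next
    ir <- IRanges::reduce(.as_iranges(
      unlist(.split_commas(mem$exon_starts)),
      unlist(.split_commas(mem$exon_ends))))
    loci$exon_starts[i] <- .join_commas(list(IRanges::start(ir) - 1L))
    loci$exon_ends[i] <- .join_commas(list(IRanges::end(ir)))
  }
  loci
}

#' Classify both genes of every bidirectional pair
#'
#' Runs [classify_gene()] on the left and right gene of each pair, at the
#' requested distance limit. The category counts over assessed genes always
#' partition the gene set.
#'
#' @param pairs pair table from [find_bidirectional_pairs()].
#' @param loci the locus table the pairs were built from (with exon blocks
#'   attached when available).
#' @param resources see [classify_gene()].
#' @param max_distance target-side TSS distance limit (`Inf` = unlimited).
#' @param align_threshold minimum exon-alignability fraction.
#' @return data frame with one row per assessed gene: `pair_id`, `side`,
#'   `locus_id`, `chrom`, `category`, `target_locus`, `target_partner`,
#'   `limit_used`.
#' @export
classify_all <- function(pairs, loci, resources, max_distance = 1000,
                         align_threshold = 0.5) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    for (side in c("left", "right")) {
      lid <- pairs[[paste0(side, "_locus")]][i]
      oid <- pairs[[if (side == "left") "right_locus" else "left_locus"]][i]
      g <- loci[loci$locus_id == lid, , drop = FALSE]
      p <- loci[loci$locus_id == oid, , drop = FALSE]
      cl <- classify_gene(g, p, resources, max_distance, align_threshold)
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pairs$pair_id[i], side = side, locus_id = lid,
        chrom = pairs$chrom[i], category = cl$category,
        target_locus = cl$target_locus, target_partner = cl$target_partner,
        limit_used = if (is.finite(max_distance)) max_distance else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pair_id = character(), side = character(),
                      locus_id = character(), chrom = character(),
                      category = character(), target_locus = character(),
                      target_partner = character(), limit_used = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Promoter-level orthology verdict
#'
#' A promoter is confirmed orthologous when both of its genes are C1.
#'
#' @param calls gene-level call table from [classify_all()].
#' @return data frame `pair_id`, `confirmed` (logical), `left_category`,
#'   `right_category`.
#' @export
promoter_verdict <- function(calls) {
  sp <- split(calls, calls$pair_id)
  out <- lapply(sp, function(d) {
    data.frame(pair_id = d$pair_id[1],
               left_category = d$category[d$side == "left"][1],
               right_category = d$category[d$side == "right"][1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$confirmed <- res$left_category == "C1" & res$right_category == "C1"
  rownames(res) <- NULL
  res[, c("pair_id", "confirmed", "left_category", "right_category")]
}

#' Reciprocal classification between two genomes
#'
#' Runs [classify_all()] in both directions with identical parameters and
#' summarises the asymmetry in confirmation rates.
#'
#' @param pairs_a,loci_a pairs and loci of genome A; `pairs_b`, `loci_b`
#'   likewise for genome B.
#' @param resources_ab resources for A-to-B classification; `resources_ba`
#'   for the reverse direction.
#' @param max_distance,align_threshold as in [classify_all()].
#' @return list with `a2b`, `b2a` call tables and `summary` (C1 rates per
#'   direction).
#' @export
reciprocal_classify <- function(pairs_a, loci_a, pairs_b, loci_b,
                                resources_ab, resources_ba,
                                max_distance = 1000, align_threshold = 0.5) {
  if (is.null(resources_ba$chains) || !length(resources_ba$chains))
    stop("reverse-direction chain set is missing")
  a2b <- classify_all(pairs_a, loci_a, resources_ab, max_distance, align_threshold)
  b2a <- classify_all(pairs_b, loci_b, resources_ba, max_distance, align_threshold)
  rate <- function(x) if (nrow(x)) 100 * mean(x$category == "C1") else NA_real_
  list(a2b = a2b, b2a = b2a,
       summary = data.frame(direction = c("A->B", "B->A"),
                            c1_percent = c(rate(a2b), rate(b2a))))
}

#' Per-chromosome category summary
#'
#' @param calls gene-level call table from [classify_all()].
#' @return data frame with one row per chromosome: category counts, a
#'   `total` column, and row-normalised `pct_*` columns summing to 100.
#' @export
chromosome_summary <- function(calls) {
  chroms <- sort(unique(calls$chrom))
  counts <- t(vapply(chroms, function(cc) {
    tabulate(factor(calls$category[calls$chrom == cc], levels = CATEGORIES),
             nbins = length(CATEGORIES))
  }, integer(length(CATEGORIES))))
  colnames(counts) <- CATEGORIES
  total <- rowSums(counts)
  pct <- 100 * counts / ifelse(total == 0, 1, total)
  colnames(pct) <- paste0("pct_", CATEGORIES)
  data.frame(chrom = chroms, counts, total = total, pct,
             row.names = NULL, check.names = FALSE)
}

#' Category counts at gene level
#'
#' Summarises a call table into counts and percentages per category; gene
#' level doubles the pair count since both genes of every pair are
#' assessed.
#'
#' @param calls gene-level call table from [classify_all()].
#' @return data frame `category`, `n_genes`, `percent`.
#' @export
category_summary <- function(calls) {
  n <- tabulate(factor(calls$category, levels = CATEGORIES),
                nbins = length(CATEGORIES))
  data.frame(category = CATEGORIES, n_genes = n,
             percent = if (sum(n)) 100 * n / sum(n) else rep(0, length(n)))
}

#' Unroll a pair table to gene level
#'
#' Each pair contributes its two genes, so the gene-level table always has
#' exactly twice as many rows as the pair table.
#'
#' @param pairs pair table from [find_bidirectional_pairs()].
#' @return data frame with one row per gene: `pair_id`, `side`, `locus_id`,
#'   `chrom`, `tss`.
#' @export
genes_of_pairs <- function(pairs) {
  data.frame(
    pair_id = rep(pairs$pair_id, 2),
    side = rep(c("left", "right"), each = nrow(pairs)),
    locus_id = c(pairs$left_locus, pairs$right_locus),
    chrom = rep(pairs$chrom, 2),
    tss = c(pairs$left_tss, pairs$right_tss),
    stringsAsFactors = FALSE)
}
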