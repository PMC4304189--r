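test_that("overlapping same-strand transcripts condense into one locus", {
  tx <- rbind(
    data.frame(id = "a", chrom = "chr1", start = 100L, end = 500L, strand = "+",
               tss = 100L, exon_starts = "100,", exon_ends = "500,", n_exons = 1L,
               source = "known_gene", canonical_intron = NA, gene_symbol = "a"),
    data.frame(id = "b", chrom = "chr1", start = 400L, end = 900L, strand = "+",
               tss = 400L, exon_starts = "400,", exon_ends = "900,", n_exons = 1L,
               source = "known_gene", canonical_intron = NA, gene_symbol = "a"))
  loci <- cluster_transcripts(tx)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$tss, 100L)          # most-extreme 5' TSS
  expect_equal(loci$n_support, 2L)
  # identical intervals on opposite strands stay separate
  tx$strand <- c("+", "-"); tx$start <- 100L; tx$end <- 500L
  tx$tss <- c(100L, 500L)
  expect_equal(nrow(cluster_transcripts(tx)), 2L)
})

test_that("locus partition equals the overlap-graph connected components", {
  set.seed(201)
  for (rep in 1:3) {
    tx <- random_transcripts(160)
    loci <- cluster_transcripts(tx)
    got <- lapply(strsplit(loci$transcript_ids, ","), sort)
    want <- lapply(bf_overlap_components(tx), sort)
    expect_setequal(vapply(got, paste, "", collapse = "|"),
                    vapply(want, paste, "", collapse = "|"))
    # loci on one strand+chromosome never overlap each other
    for (s in c("+", "-")) {
      l <- loci[loci$strand == s, ]
      if (nrow(l) > 1) {
        l <- l[order(l$start), ]
        expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
      }
    }
  }
})

test_that("spliced filtering removes single-exon and non-canonical ESTs", {
  tx <- random_transcripts(30, source = "spliced_est")
  out <- filter_spliced(tx, require_canonical_intron = TRUE)
  expect_true(all(out$n_exons >= 2))
  expect_true(all(out$canonical_intron))
  out2 <- filter_spliced(tx, require_canonical_intron = FALSE)
  expect_true(all(out2$n_exons >= 2))
  expect_gte(nrow(out2), nrow(out))
})

test_that("splice-site scan keeps only GT..AG introns against a toy sequence", {
  # exon [0,10) + intron + exon [30,40); plant GT..AG, GC..AG and CT..AC
  seqs <- list(
    gtag = paste0(strrep("A", 10), "GT", strrep("N", 16), "AG", strrep("A", 10)),
    gcag = paste0(strrep("A", 10), "GC", strrep("N", 16), "AG", strrep("A", 10)))
  expect_true(has_canonical_intron(c(0L, 30L), c(10L, 40L), "+", seqs$gtag))
  expect_false(has_canonical_intron(c(0L, 30L), c(10L, 40L), "+", seqs$gcag))
  # minus strand: genomic CT..AC is the reverse complement of GT..AG
  mseq <- paste0(strrep("A", 10), "CT", strrep("N", 16), "AC", strrep("A", 10))
  expect_true(has_canonical_intron(c(0L, 30L), c(10L, 40L), "-", mseq))
  expect_false(has_canonical_intron(c(0L, 30L), c(10L, 40L), "-", seqs$gtag))
  tx <- data.frame(id = "e1", chrom = "c1", start = 0L, end = 40L, strand = "+",
                   tss = 0L, exon_starts = "0,30,", exon_ends = "10,40,",
                   n_exons = 2L, source = "spliced_est", canonical_intron = FALSE,
                   gene_symbol = "e1")
  expect_equal(nrow(filter_spliced(tx, TRUE, list(c1 = seqs$gtag))), 1L)
  expect_equal(nrow(filter_spliced(tx, TRUE, list(c1 = seqs$gcag))), 0L)
  expect_error(filter_spliced(tx, TRUE, list(other = seqs$gtag)), "no sequence")
})

test_that("divergent pairs respect the distance limit and its boundary", {
  loci <- make_loci("chr1", tss = c(5000L, 5800L), strand = c("-", "+"))
  p <- find_bidirectional_pairs(loci)
  expect_equal(nrow(p), 1L)
  expect_equal(p$tss_distance, 800L)
  expect_equal(c(p$start, p$end), c(5000L, 5800L))  # promoter = [left TSS, right TSS)
  loci2 <- make_loci("chr1", tss = c(5000L, 6001L), strand = c("-", "+"))
  expect_equal(nrow(find_bidirectional_pairs(loci2)), 0L)
  expect_equal(nrow(find_bidirectional_pairs(loci2, Inf)), 1L)
})

test_that("pairing matches the exhaustive greedy oracle on random loci", {
  set.seed(202)
  for (rep in 1:5) {
    n <- 40
    loci <- make_loci("chr1", tss = sample(0:40000, n),
                      strand = sample(c("+", "-"), n, replace = TRUE))
    for (maxd in c(500, 1000, Inf)) {
      got <- find_bidirectional_pairs(loci, maxd)
      want <- bf_pairs(loci, maxd)
      expect_setequal(paste(got$left_locus, got$right_locus),
                      vapply(want, paste, "", collapse = " "))
      # monotone in the distance limit
      if (is.finite(maxd)) {
        wider <- find_bidirectional_pairs(loci, maxd * 2)
        expect_true(all(paste(got$left_locus, got$right_locus) %in%
                          paste(wider$left_locus, wider$right_locus)))
      }
    }
  }
})

test_that("promoter collapse is idempotent and resolves overlaps by support", {
  loci <- make_loci("chr1", tss = c(5000L, 5400L, 5300L, 5900L),
                    strand = c("-", "+", "-", "+"),
                    n_support = c(1L, 1L, 6L, 6L))
  # force two overlapping candidate promoters [5000,5400) and [5300,5900)
  p1 <- find_bidirectional_pairs(loci[1:2, ])
  p2 <- find_bidirectional_pairs(loci[3:4, ])
  p2$pair_id <- "pair_0002"
  both <- rbind(p1, p2)
  col <- collapse_promoters(both)
  expect_equal(nrow(col), 1L)
  expect_equal(col$left_locus, "L0003")       # more supporters wins
  expect_equal(col$n_support_left, 7L)        # supporters aggregate
  expect_equal(collapse_promoters(col), col)  # idempotent
  # disjoint promoters pass through and identical candidates deduplicate
  set.seed(203)
  for (rep in 1:5) {
    n <- 30
    loci <- make_loci("chr1", tss = sample(seq(0, 60000, by = 3), n),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      n_support = sample(1:8, n, replace = TRUE))
    p <- find_bidirectional_pairs(loci)
    cc <- collapse_promoters(p)
    expect_equal(collapse_promoters(cc), cc)
    if (nrow(cc) > 1) {
      cc <- cc[order(cc$start), ]
      expect_true(all(cc$start[-1] >= pmax(cc$end, cc$start + 1L)[-nrow(cc)]))
    }
  }
})

test_that("confidence levels are correct and monotone over the count grid", {
  grid <- expand.grid(l = 1:10, r = 1:10)
  lev <- assign_confidence(data.frame(n_support_left = grid$l,
                                      n_support_right = grid$r))
  expect_equal(lev[grid$l == 1 & grid$r == 1], 1L)
  expect_equal(lev[grid$l == 5 & grid$r == 7], 3L)
  expect_equal(lev[grid$l == 2 & grid$r == 2], 2L)
  m <- matrix(lev, 10, 10)
  expect_true(all(diff(m) >= 0))      # monotone in left count
  expect_true(all(t(diff(t(m))) >= 0))  # and in right count
})

test_that("EST-only promoters are the set difference against known-gene promoters", {
  set.seed(204)
  ds <- generate_dataset(synthetic_spec(seed = 204, n_pairs_per_category = c(4, 2, 2, 2, 2),
                                        n_est_only_pairs = 5, est_canonical_rate = 1))
  kg_pairs <- find_bidirectional_pairs(cluster_transcripts(ds$tx_a_kg))
  est <- filter_spliced(ds$tx_a_est, require_canonical_intron = TRUE)
  est_pairs <- find_bidirectional_pairs(cluster_transcripts(est))
  extra <- est_only_promoters(est_pairs, kg_pairs)
  # planted: 5 EST-only cassettes plus 2 overlays of known-gene promoters
  truth_est <- ds$truth[ds$truth$kind == "est" & ds$truth$est_retained, ]
  expect_setequal(paste(extra$chrom, extra$left_tss),
                  paste(truth_est$chrom, truth_est$left_tss))
  # overlayed promoters were discovered by ESTs but are not "additional"
  expect_gt(nrow(est_pairs), nrow(extra))
})
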