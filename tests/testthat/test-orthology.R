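identity_chain <- function(id = 1L, size = 1000L) {
  list(score = 100, t_chrom = paste0("chrT", id), t_size = 100000L,
       t_start = 0L, t_end = size, q_chrom = paste0("chrQ", id),
       q_size = 120000L, q_strand = "+", q_start = 0L, q_end = size,
       chain_id = id, blocks = data.frame(size = size, dt = 0L, dq = 0L))
}

test_that("level-1 filtering drops all deeper net levels", {
  nets <- data.frame(target_chrom = "chrA", start = c(0L, 100L, 150L, 2000L),
                     end = c(1000L, 500L, 250L, 2500L), level = c(1L, 2L, 3L, 1L),
                     chain_id = 1:4, fill_class = "top", q_chrom = "chrB",
                     q_strand = "+", stringsAsFactors = FALSE)
  l1 <- level1_regions(nets)
  expect_equal(l1$chain_id, c(1L, 4L))
  expect_equal(nrow(level1_regions(nets[0, ])), 0L)
})

test_that("identity chains map intervals unchanged; gaps empty them", {
  ch <- identity_chain()
  m <- map_interval(ch, 10L, 20L)
  expect_equal(m[, c("start", "end")], data.frame(start = 10L, end = 20L))
  gap <- ch
  gap$blocks <- data.frame(size = c(100L, 100L), dt = c(800L, 0L), dq = c(0L, 0L))
  gap$q_end <- 200L
  expect_equal(nrow(map_interval(gap, 150L, 700L)), 0L)   # entirely inside dt
  # [50,950) spans the gap: [50,100) maps in place, the second block's
  # target range [900,950) lands at query [100,150)
  split <- map_interval(gap, 50L, 950L)
  expect_equal(split$start, c(50L, 100L))
  expect_equal(split$end, c(100L, 150L))
  expect_error(map_intervals(list(`1` = ch),
                             data.frame(chrom = "chrT1", start = 1L, end = 5L),
                             99), "unknown chain id")
})

test_that("block arithmetic agrees base-for-base with per-base and liftOver oracles", {
  set.seed(401)
  chains <- lapply(1:10, random_chain)
  names(chains) <- 1:10
  for (ch in chains) {
    for (k in 1:5) {
      span <- ch$t_end - ch$t_start
      s <- ch$t_start + sample(0:(span - 2), 1)
      e <- s + sample(1:(ch$t_end - s), 1)
      got <- pieces_to_bases(map_interval(ch, s, e))
      expect_equal(got, bf_map_bases(ch, s, e))
      expect_equal(got, liftover_bases(chains[as.character(ch$chain_id)], ch, s, e))
    }
  }
})

test_that("mapping through a chain and its inverse is the identity on aligned bases", {
  set.seed(402)
  for (k in 1:10) {
    ch <- random_chain(k, q_strand = "+")
    inv <- invert_chain(ch)
    fwd <- map_interval(ch, ch$t_start, ch$t_end)
    back <- sort(unlist(lapply(seq_len(nrow(fwd)), function(i)
      pieces_to_bases(map_interval(inv, fwd$start[i], fwd$end[i])))))
    expect_equal(back, bf_aligned_target_bases(ch))
  }
})

test_that("exon alignability is the per-base fraction inside gapless blocks", {
  ch <- identity_chain()
  expect_equal(exons_alignable(c(100L, 300L), c(200L, 400L), ch), 1.0)
  gap <- ch
  gap$blocks <- data.frame(size = c(100L, 100L), dt = c(800L, 0L), dq = c(0L, 0L))
  gap$q_end <- 200L
  expect_equal(exons_alignable(c(200L, 500L), c(300L, 600L), gap), 0.0)
  set.seed(403)
  for (k in 1:20) {
    ch <- random_chain(k)
    # disjoint exon blocks: starts on a 70 bp grid, lengths under 70
    grid <- seq(ch$t_start, ch$t_end - 50L, by = 70)
    n_ex <- min(sample(1:4, 1), length(grid))
    es <- sort(sample(grid, n_ex))
    ee <- es + sample(20:60, n_ex, replace = TRUE)
    want <- length(intersect(unlist(Map(seq.int, es, ee - 1L)),
                             bf_aligned_target_bases(ch))) / sum(ee - es)
    expect_equal(exons_alignable(es, ee, ch), want)
  }
})

test_that("hand-built loci classify into the expected categories", {
  # genome A: divergent pair, minus gene [1000,3000) TSS 3000,
  # plus gene [3400,5400) TSS 3400; identity chain chrT1 -> chrQ1
  ch <- identity_chain(1L, 10000L)
  lA <- make_loci("chrT1", tss = c(3000L, 3400L), strand = c("-", "+"))
  lA$gene_symbol <- c("hA", "hB"); lA$source <- "known_gene"
  lA$exon_starts <- NA_character_; lA$exon_ends <- NA_character_
  nets <- data.frame(target_chrom = "chrT1", start = 0L, end = 10000L,
                     level = 1L, chain_id = 1L, fill_class = "top",
                     q_chrom = "chrQ1", q_strand = "+", stringsAsFactors = FALSE)
  tB <- make_loci("chrQ1", tss = c(3000L, 3400L), strand = c("-", "+"))
  tB$gene_symbol <- c("mA", "mB")
  res <- list(level1 = level1_regions(nets), chains = list(`1` = ch),
              target_loci = tB,
              orthologs = data.frame(source = c("hA", "hB"),
                                     target = c("mA", "mB")))
  expect_equal(classify_gene(lA[1, ], lA[2, ], res)$category, "C1")
  # partner not orthologous -> C2
  res2 <- res; res2$orthologs <- res$orthologs[1, , drop = FALSE]
  expect_equal(classify_gene(lA[1, ], lA[2, ], res2)$category, "C2")
  # partner annotation deleted -> C3
  res3 <- res; res3$target_loci <- tB[1, , drop = FALSE]
  expect_equal(classify_gene(lA[1, ], lA[2, ], res3)$category, "C3")
  # unrelated gene at the mapped location -> C4
  res4 <- res; res4$target_loci$gene_symbol <- c("zz", "mB")
  expect_equal(classify_gene(lA[1, ], lA[2, ], res4)$category, "C4")
  # no level-1 coverage -> C5
  res5 <- res; res5$level1 <- res$level1[0, , drop = FALSE]
  expect_equal(classify_gene(lA[1, ], lA[2, ], res5)$category, "C5")
  expect_error(classify_gene(lA[1, ], lA[2, ], res[1:3]), "missing component")
  # target partner beyond 1,000 bp: C3 at the limit, C1 unlimited
  res6 <- res; res6$target_loci$tss <- c(3000L, 4500L)
  res6$target_loci$start <- c(1000L, 4500L); res6$target_loci$end <- c(3000L, 6500L)
  expect_equal(classify_gene(lA[1, ], lA[2, ], res6, 1000)$category, "C3")
  expect_equal(classify_gene(lA[1, ], lA[2, ], res6, Inf)$category, "C1")
})

test_that("EST loci are judged by conserved synteny, not the ortholog table", {
  ch <- identity_chain(1L, 10000L)
  lA <- make_loci("chrT1", tss = c(3000L, 3400L), strand = c("-", "+"),
                  source = "spliced_est")
  lA$exon_starts <- NA_character_; lA$exon_ends <- NA_character_
  nets <- data.frame(target_chrom = "chrT1", start = 0L, end = 10000L,
                     level = 1L, chain_id = 1L, fill_class = "top",
                     q_chrom = "chrQ1", q_strand = "+", stringsAsFactors = FALSE)
  tB <- make_loci("chrQ1", tss = c(3000L, 3400L), strand = c("-", "+"),
                  source = "spliced_est")
  res <- list(level1 = level1_regions(nets), chains = list(`1` = ch),
              target_loci = tB,
              orthologs = data.frame(source = character(), target = character()))
  # both positions conserved: C1 purely on synteny
  expect_equal(classify_gene(lA[1, ], lA[2, ], res)$category, "C1")
  # partner position empty in the target genome: C3
  res3 <- res; res3$target_loci <- tB[1, , drop = FALSE]
  expect_equal(classify_gene(lA[1, ], lA[2, ], res3)$category, "C3")
})

test_that("category counts always partition the assessed genes", {
  set.seed(404)
  for (rep in 1:5) {
    ds <- generate_dataset(synthetic_spec(seed = 404 + rep,
                                          n_pairs_per_category = c(3, 2, 2, 2, 2),
                                          n_single_genes = 4, n_est_only_pairs = 0))
    loci <- cluster_transcripts(ds$tx_a_kg)
    pairs <- find_bidirectional_pairs(loci)
    res <- list(level1 = level1_regions(ds$nets_ab), chains = ds$chains_ab,
                target_loci = cluster_transcripts(ds$tx_b_kg),
                orthologs = ds$orthologs)
    for (lim in c(1000, Inf)) {
      calls <- classify_all(pairs, loci, res, lim)
      expect_equal(nrow(calls), 2L * nrow(pairs))
      expect_equal(sum(category_summary(calls)$n_genes), nrow(calls))
      expect_true(all(calls$category %in% c("C1", "C2", "C3", "C4", "C5")))
    }
  }
})

test_that("relaxing the distance limit only moves genes out of C3", {
  set.seed(405)
  for (rep in 1:5) {
    ds <- generate_dataset(synthetic_spec(seed = 500 + rep,
                                          n_pairs_per_category = c(3, 1, 3, 1, 1),
                                          overlimit_fraction = 0.6,
                                          n_single_genes = 2, n_est_only_pairs = 0))
    loci <- cluster_transcripts(ds$tx_a_kg)
    pairs <- find_bidirectional_pairs(loci)
    res <- list(level1 = level1_regions(ds$nets_ab), chains = ds$chains_ab,
                target_loci = cluster_transcripts(ds$tx_b_kg),
                orthologs = ds$orthologs)
    lim <- classify_all(pairs, loci, res, 1000)
    rel <- classify_all(pairs, loci, res, Inf)
    key <- paste(lim$pair_id, lim$side)
    stopifnot(identical(key, paste(rel$pair_id, rel$side)))
    changed <- lim$category != rel$category
    expect_true(all(lim$category[changed] == "C3"))
    expect_true(all(rel$category[changed] %in% c("C1", "C2")))
    expect_gte(sum(rel$category == "C1"), sum(lim$category == "C1"))
  }
})

test_that("reciprocal classification is symmetric on symmetric genomes and
           detects planted annotation asymmetry", {
  mk_calls <- function(seed, q) {
    ds <- generate_dataset(synthetic_spec(seed = seed,
                                          n_pairs_per_category = c(12, 0, 0, 0, 0),
                                          n_single_genes = 0, n_est_only_pairs = 0,
                                          annotation_dropout_rate = q))
    lA <- cluster_transcripts(ds$tx_a_kg); pA <- find_bidirectional_pairs(lA)
    lB <- cluster_transcripts(ds$tx_b_kg); pB <- find_bidirectional_pairs(lB)
    rAB <- list(level1 = level1_regions(ds$nets_ab), chains = ds$chains_ab,
                target_loci = lB, orthologs = ds$orthologs)
    rBA <- list(level1 = level1_regions(ds$nets_ba), chains = ds$chains_ba,
                target_loci = lA, orthologs = invert_orthologs(ds$orthologs))
    reciprocal_classify(pA, lA, pB, lB, rAB, rBA)
  }
  sym <- mk_calls(406, 0)
  expect_equal(sym$summary$c1_percent, c(100, 100))
  asym <- mk_calls(407, 0.2)
  expect_lt(asym$summary$c1_percent[1], asym$summary$c1_percent[2])
  expect_error(reciprocal_classify(NULL, NULL, NULL, NULL, list(),
                                   list(chains = NULL)), "reverse-direction")
})

test_that("chromosome summary conserves counts and row-normalises percentages", {
  calls <- data.frame(pair_id = "p1", side = "left", locus_id = "l1",
                      chrom = "chr9", category = "C1", target_locus = NA,
                      target_partner = NA, limit_used = 1000L)
  cs <- chromosome_summary(calls)
  expect_equal(cs$total, 1L)
  expect_equal(cs$pct_C1, 100)
  set.seed(408)
  calls <- data.frame(pair_id = sprintf("p%d", 1:60), side = "left",
                      locus_id = sprintf("l%d", 1:60),
                      chrom = sample(paste0("chr", 1:5), 60, replace = TRUE),
                      category = sample(c("C1", "C2", "C3", "C4", "C5"), 60,
                                        replace = TRUE),
                      target_locus = NA, target_partner = NA, limit_used = 1000L)
  cs <- chromosome_summary(calls)
  expect_equal(sum(cs$total), 60L)
  expect_equal(rowSums(cs[, c("C1", "C2", "C3", "C4", "C5")]), cs$total,
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(cs[, paste0("pct_", c("C1", "C2", "C3", "C4", "C5"))])),
               rep(100, nrow(cs)))
})
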