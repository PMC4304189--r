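test_that("BED12 parsing maps fields and computes the strand-aware TSS", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t500\ttx1\t0\t-\t100\t500\t0\t2\t100,100,\t0,300,",
               "chr1\t100\t500\ttx2\t0\t+\t100\t500\t0\t1\t400,\t0,"), f)
  tx <- read_transcripts(f, "bed12")
  expect_equal(tx$tss, c(500L, 100L))
  expect_equal(tx$n_exons, c(2L, 1L))
  expect_equal(.subset2(tx, "start"), c(100L, 100L))
  # exon blocks reconstructed from blockStarts/blockSizes
  expect_equal(tx$exon_starts[1], "100,400,")
  expect_equal(tx$exon_ends[1], "200,500,")
})

test_that("malformed lines and unknown strands are handled as specified", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\tX\ttx1\t0\t+\t100\t500\t0\t1\t400,\t0,", f)
  expect_error(read_transcripts(f, "bed12"), "line 1")
  writeLines("chr1\t100\t500\ttx1\t0\t.\t100\t500\t0\t1\t400,\t0,", f)
  expect_warning(tx <- read_transcripts(f, "bed12"), "strand")
  expect_equal(nrow(tx), 0L)
})

test_that("transcript round-trips are the identity in both formats", {
  set.seed(101)
  tx <- random_transcripts(50, source = "spliced_est")
  tx$source <- "spliced_est"
  for (fmt in c("bed12", "genepred")) {
    f <- withr::local_tempfile()
    write_transcripts(tx, f, fmt)
    back <- read_transcripts(f, fmt, source = "spliced_est")
    cols <- c("id", "chrom", "start", "end", "strand", "tss",
              "exon_starts", "exon_ends", "n_exons")
    if (fmt == "bed12") cols <- c(cols, "canonical_intron")
    expect_equal(back[cols], tx[cols])
  }
})

test_that("chain reader enforces span invariants and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("chain 100 chrA 1000 + 0 100 chrB 2000 + 50 150 1", "100", ""), f)
  ch <- read_chain(f)
  expect_length(ch, 1)
  expect_equal(ch[["1"]]$blocks$size, 100L)
  # block sizes + dt must equal the target span
  writeLines(c("chain 100 chrA 1000 + 0 120 chrB 2000 + 50 150 7", "100", ""), f)
  expect_error(read_chain(f), "chain 7")
  set.seed(102)
  chains <- lapply(1:20, random_chain)
  names(chains) <- 1:20
  f2 <- withr::local_tempfile()
  write_chain(chains, f2)
  expect_equal(read_chain(f2), chains)
})

test_that("net nesting depth yields levels and bad nesting errors", {
  f <- withr::local_tempfile()
  writeLines(c("net chrA 10000",
               " fill 0 1000 chrB + 0 0 id 1 score 5 type top",
               "  gap 100 400 chrB + 0 0",
               "   fill 150 200 chrB + 0 0 id 2 score 1 type nonSyn",
               " fill 2000 500 chrB + 0 0 id 3 score 2 type top"), f)
  net <- read_net(f)
  expect_equal(net$level, c(1L, 2L, 1L))
  expect_equal(net$chain_id, c(1L, 2L, 3L))
  writeLines(c("net chrA 10000",
               " fill 0 1000 chrB + 0 0 id 1 score 5 type top",
               "  gap 100 400 chrB + 0 0",
               "   fill 150 2000 chrB + 0 0 id 2 score 1 type inv"), f)
  expect_error(read_net(f), "escapes its parent")
})

test_that("a three-level net round-trips with planted levels intact", {
  nets <- data.frame(
    target_chrom = "chrA",
    start = c(0L, 100L, 600L, 150L, 2000L), end = c(1000L, 500L, 900L, 250L, 2600L),
    level = c(1L, 2L, 2L, 3L, 1L), chain_id = 1:5,
    fill_class = c("top", "syn", "inv", "nonSyn", "top"),
    q_chrom = "chrB", q_strand = c("+", "+", "-", "+", "+"),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_net(nets, c(chrA = 10000L), f)
  back <- read_net(f)
  o <- function(d) d[order(d$start, d$level), ]
  expect_equal(o(back), o(nets), ignore_attr = TRUE)
})

test_that("BED and CAGE readers normalise to half-open intervals and round-trip", {
  f <- withr::local_tempfile()
  writeLines("chrA\t10\t20", f)
  expect_equal(read_bed_intervals(f)$start, 10L)
  writeLines(character(), f)
  expect_equal(nrow(read_bed_intervals(f)), 0L)
  set.seed(103)
  iv <- data.frame(chrom = "chrA", start = sort(sample(0:100000, 100)) * 3L)
  iv$end <- iv$start + sample(50:500, 100, replace = TRUE)
  write_bed_intervals(iv, f)
  expect_equal(read_bed_intervals(f), iv)
  # CAGE dialect: sample label, tag count, summit offset; midpoint default
  writeLines(c("chrA\t100\t200\tliver\t7\t30", "chrA\t300\t400\tbrain\t2"), f)
  pk <- read_cage_peaks(f)
  expect_equal(pk$summit, c(130L, 350L))
  f2 <- withr::local_tempfile()
  write_cage_peaks(pk, f2)
  expect_equal(read_cage_peaks(f2), pk)
})

test_that("result writer sorts deterministically and round-trips", {
  df <- data.frame(chrom = c("chr2", "chr1"), start = c(5L, 9L),
                   end = c(10L, 20L), pair_id = c("b", "a"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_results(df, f, "tsv")
  back <- read_results(f)
  expect_equal(back$chrom, c("chr1", "chr2"))
  expect_equal(back, df[order(df$chrom), ], ignore_attr = TRUE)
  write_results(df[0, ], f, "tsv")
  expect_equal(nrow(read_results(f)), 0L)  # header-only file
  write_results(df, f, "bed")
  bed <- read_bed_intervals(f)
  expect_equal(bed$start, c(9L, 5L))       # half-open coordinates verbatim
})

test_that("expression and ortholog tables round-trip with replicate labels", {
  m <- matrix(abs(rnorm(12)), 3, 4,
              dimnames = list(c("g1", "g2", "g3"),
                              c("liver", "liver", "brain", "heart")))
  f <- withr::local_tempfile()
  write_expression(m, f)
  expect_equal(read_expression(f), m)
  orth <- data.frame(source = c("a", "b"), target = c("x", "y"),
                     stringsAsFactors = FALSE)
  write_orthologs(orth, f)
  expect_equal(read_orthologs(f), orth)
})
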