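# Synthetic paired-genome generator. Lays out gene-pair "cassettes" along
# one or more chromosomes of genome A, mirrors them in genome B through a
# consistent chain/net alignment, and plants one orthology category per
# cassette:
#   C1  both genes conserved, divergent partner within the distance limit
#   C2  assessed gene conserved, partner replaced by a non-orthologous gene
#   C3  partner annotation deleted in B (or moved beyond the limit)
#   C4  an unrelated gene occupies the mapped location
#   C5  cassette falls in an alignment gap (optionally under a level-2
#       paralog fill), so no orthology is recorded
# CAGE peaks, CpG islands and tissue expression with controlled
# co-activation / correlation structure are generated from the same truth.

.CASSETTE_W <- 20000L     # cassette width, bp
.BLOCK_INSET <- 2000L     # aligned block is [c+inset, c+W-3000)
.MARGIN <- 5000L          # chromosome end margins

#' Build a synthetic-dataset specification
#'
#' Defaults are the study conditions the analysis emulates: TSS distances
#' uniform on 100-1,000 bp, CAGE summits ~ Normal(0, 30 bp) around true
#' TSSs, a 66% coordinated-activation rate, CpG islands at 90.6% of
#' bidirectional and 55.3% of single-gene promoters, 79 tissues of which
#' 21 are shared across species, and a cross-species expression
#' correlation of 0.5.
#'
#' @param seed integer seed; every stochastic draw derives from it.
#' @param n_pairs_per_category named/unnamed integer vector of planted
#'   pair counts for C1..C5.
#' @param n_chromosomes chromosomes per genome.
#' @param chrom_length optional chromosome length in bp; must be large
#'   enough for the requested content (an error otherwise). `NULL` sizes
#'   chromosomes automatically.
#' @param tss_distance_range uniform range of planted TSS distances, bp.
#' @param overlimit_fraction fraction of C3 pairs realised as a conserved
#'   partner placed 1,100-2,000 bp away (C3 at the 1,000 bp limit, C1
#'   without it) rather than deleted.
#' @param est_per_locus_lambda Poisson rate; transcripts per locus is
#'   1 + Poisson(lambda).
#' @param n_est_only_pairs divergent pairs present only in the spliced-EST
#'   annotations.
#' @param est_canonical_rate probability an EST transcript carries a
#'   canonical intron flag.
#' @param n_single_genes genes outside any pair (CpG background set).
#' @param cage_summit_sd CAGE summit jitter around the true TSS, bp.
#' @param cage_coactivation_rate probability a pair is co-activated (both
#'   TSSs tagged in the same sample).
#' @param n_cage_samples number of CAGE sample labels.
#' @param cpg_rate_bidirectional,cpg_rate_single CpG island probabilities.
#' @param n_tissues,n_shared_tissues expression tissues in A; the first
#'   `n_shared_tissues` exist in B under the same labels.
#' @param n_replicates replicate arrays per tissue.
#' @param coexpression_loading latent-factor loading shared by the two
#'   genes of a pair (their expected expression correlation is its square).
#' @param cross_species_rho planted correlation between a gene and its
#'   ortholog over the shared tissues.
#' @param replicate_sd log2-scale replicate noise.
#' @param annotation_dropout_rate probability each B-side gene annotation
#'   is missing.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed,
                           n_pairs_per_category = c(C1 = 10L, C2 = 5L, C3 = 5L,
                                                    C4 = 5L, C5 = 5L),
                           n_chromosomes = 2L,
                           chrom_length = NULL,
                           tss_distance_range = c(100L, 1000L),
                           overlimit_fraction = 0.25,
                           est_per_locus_lambda = 1.5,
                           n_est_only_pairs = 6L,
                           est_canonical_rate = 0.9,
                           n_single_genes = 30L,
                           cage_summit_sd = 30,
                           cage_coactivation_rate = 0.66,
                           n_cage_samples = 5L,
                           cpg_rate_bidirectional = 0.906,
                           cpg_rate_single = 0.553,
                           n_tissues = 79L,
                           n_shared_tissues = 21L,
                           n_replicates = 2L,
                           coexpression_loading = 0.6,
                           cross_species_rho = 0.5,
                           replicate_sd = 0.05,
                           annotation_dropout_rate = 0) {
  if (missing(seed)) stop("a seed is mandatory")
  np <- as.integer(n_pairs_per_category)
  if (length(np) != 5 || any(np < 0)) stop("need 5 non-negative category counts")
  names(np) <- CATEGORIES
  rates <- c(overlimit_fraction, est_canonical_rate, cage_coactivation_rate,
             cpg_rate_bidirectional, cpg_rate_single, annotation_dropout_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (n_shared_tissues > n_tissues) stop("n_shared_tissues cannot exceed n_tissues")
  spec <- list(seed = as.integer(seed), n_pairs_per_category = np,
               n_chromosomes = as.integer(n_chromosomes),
               chrom_length = chrom_length,
               tss_distance_range = as.integer(tss_distance_range),
               overlimit_fraction = overlimit_fraction,
               est_per_locus_lambda = est_per_locus_lambda,
               n_est_only_pairs = as.integer(n_est_only_pairs),
               est_canonical_rate = est_canonical_rate,
               n_single_genes = as.integer(n_single_genes),
               cage_summit_sd = cage_summit_sd,
               cage_coactivation_rate = cage_coactivation_rate,
               n_cage_samples = as.integer(n_cage_samples),
               cpg_rate_bidirectional = cpg_rate_bidirectional,
               cpg_rate_single = cpg_rate_single,
               n_tissues = as.integer(n_tissues),
               n_shared_tissues = as.integer(n_shared_tissues),
               n_replicates = as.integer(n_replicates),
               coexpression_loading = coexpression_loading,
               cross_species_rho = cross_species_rho,
               replicate_sd = replicate_sd,
               annotation_dropout_rate = annotation_dropout_rate)
  class(spec) <- "synthetic_spec"
  spec
}

# one transcript row (same schema as read_transcripts output)
.syn_tx <- function(id, chrom, start, end, strand, exs, exe, source, canonical, symbol) {
  data.frame(id = id, chrom = chrom, start = start, end = end, strand = strand,
             tss = .tss_of(start, end, strand),
             exon_starts = .join_commas(list(exs)), exon_ends = .join_commas(list(exe)),
             n_exons = length(exs), source = source, canonical_intron = canonical,
             gene_symbol = symbol, stringsAsFactors = FALSE)
}

# transcripts of one gene: shared strand-aware TSS, varying 3' ends
.syn_gene <- function(symbol, chrom, body_start, body_end, strand, n_tx,
                      source = "known_gene", canonical = NA) {
  rows <- lapply(seq_len(n_tx), function(k) {
    trim <- if (n_tx == 1) 0L else sample(0:400, 1)
    if (strand == "+") { s <- body_start; e <- body_end - trim }
    else { s <- body_start + trim; e <- body_end }
    exs <- c(s, s + 1000L, e - 400L)
    exe <- c(s + 300L, s + 1600L, e)
    .syn_tx(sprintf("%s.%d", symbol, k), chrom, s, e, strand, exs, exe,
            source, canonical, symbol)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic dataset
#'
#' Builds paired toy genomes in memory and optionally writes every file the
#' pipeline consumes (annotations in genePred and BED12, chains and nets in
#' both directions, CpG and CAGE BED, expression TSVs, ortholog table,
#' truth table) using the package's own writers.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; created if needed.
#' @return list with the in-memory objects (`tx_a_kg`, `tx_a_est`,
#'   `tx_b_kg`, `chains_ab`, `chains_ba`, `nets_ab`, `nets_ba`, `cpg_a`,
#'   `cage_a`, `cage_b`, `expr_a`, `expr_b`, `orthologs`, `truth`,
#'   `single_tss_a`, `chrom_sizes_a`, `chrom_sizes_b`, and `files` when
#'   `dir` was given).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  np <- spec$n_pairs_per_category
  n_kg <- sum(np)
  # cassette plan: planted KG pairs (shuffled), EST-only pairs, single genes
  plan <- data.frame(
    kind = c(rep("kg", n_kg), rep("est", spec$n_est_only_pairs),
             rep("single", spec$n_single_genes)),
    category = c(sample(rep(CATEGORIES, np)),
                 rep(NA_character_, spec$n_est_only_pairs + spec$n_single_genes)),
    stringsAsFactors = FALSE)
  n_cass <- nrow(plan)
  per_chrom <- ceiling(n_cass / spec$n_chromosomes)
  plan$chrom_idx <- rep(seq_len(spec$n_chromosomes), each = per_chrom)[seq_len(n_cass)]
  plan$slot <- stats::ave(seq_len(n_cass), plan$chrom_idx, FUN = seq_along)
  plan$offset <- .MARGIN + (plan$slot - 1L) * .CASSETTE_W
  plan$chrom_a <- paste0("chrA", plan$chrom_idx)
  plan$chrom_b <- paste0("chrB", plan$chrom_idx)
  need_len <- .MARGIN * 2L + per_chrom * .CASSETTE_W
  if (!is.null(spec$chrom_length)) {
    if (spec$chrom_length < need_len)
      stop("chrom_length ", spec$chrom_length, " too short for the requested ",
           "content; need at least ", need_len)
    need_len <- as.integer(spec$chrom_length)
  }
  chrom_sizes_a <- stats::setNames(rep(need_len, spec$n_chromosomes),
                                   paste0("chrA", seq_len(spec$n_chromosomes)))

  d_rng <- spec$tss_distance_range
  plan$d <- NA_integer_
  kg_rows <- which(plan$kind != "single")
  plan$d[kg_rows] <- sample(seq(d_rng[1], d_rng[2]), length(kg_rows), replace = TRUE)
  plan$overlimit <- FALSE
  c3 <- which(plan$kind == "kg" & plan$category == "C3")
  plan$overlimit[c3] <- stats::runif(length(c3)) < spec$overlimit_fraction

  tx_a_kg <- list(); tx_a_est <- list(); tx_b_kg <- list()
  orth <- list(); truth <- list(); single_tss <- list()
  cpg <- list()
  chains_ab <- list(); nets_ab <- list(); nets_ba <- list()
  chrom_sizes_b <- stats::setNames(integer(spec$n_chromosomes),
                                   paste0("chrB", seq_len(spec$n_chromosomes)))
  chain_id <- 0L

  n_tx_draw <- function() 1L + stats::rpois(1, spec$est_per_locus_lambda)

  for (ci in seq_len(spec$n_chromosomes)) {
    sub <- plan[plan$chrom_idx == ci, , drop = FALSE]
    chrom_a <- paste0("chrA", ci); chrom_b <- paste0("chrB", ci)
    # ---- chain skeleton over KG non-C5 cassettes -------------------------
    aligned <- which(sub$kind == "kg" & sub$category != "C5")
    sizes <- integer(); dts <- integer(); dqs <- integer()
    qoff <- 1000L * ci       # initial target->query offset on this chromosome
    sub$qoff <- NA_integer_
    t_start <- NA_integer_; prev_end <- NA_integer_; n_skipped <- 0L
    for (r in seq_len(nrow(sub))) {
      if (!(r %in% aligned)) { n_skipped <- n_skipped + 1L; next }
      bs <- sub$offset[r] + .BLOCK_INSET
      be <- sub$offset[r] + .CASSETTE_W - 3000L
      if (is.na(t_start)) {
        t_start <- bs
      } else {
        dt <- bs - prev_end
        dq <- dt - 12000L * n_skipped + sample(-1000:1000, 1)
        dts <- c(dts, dt); dqs <- c(dqs, dq)
        qoff <- qoff + (dq - dt)
      }
      sizes <- c(sizes, be - bs)
      sub$qoff[r] <- qoff
      prev_end <- be
      n_skipped <- 0L
    }
    main_chain <- NULL
    if (length(sizes)) {
      chain_id <- chain_id + 1L
      q_start <- t_start + 1000L * ci
      q_end <- q_start + sum(sizes) + sum(dqs)
      q_size <- q_end + 25000L
      main_chain <- list(score = 1e6, t_chrom = chrom_a,
                         t_size = unname(chrom_sizes_a[chrom_a]),
                         t_start = t_start, t_end = prev_end,
                         q_chrom = chrom_b, q_size = q_size, q_strand = "+",
                         q_start = q_start, q_end = q_end,
                         chain_id = chain_id,
                         blocks = data.frame(size = sizes, dt = c(dts, 0L),
                                             dq = c(dqs, 0L)))
      .check_chain_spans(main_chain)
      chains_ab[[as.character(chain_id)]] <- main_chain
      chrom_sizes_b[chrom_b] <- q_size
      nets_ab[[length(nets_ab) + 1L]] <- data.frame(
        target_chrom = chrom_a, start = t_start, end = prev_end, level = 1L,
        chain_id = chain_id, fill_class = "top", q_chrom = chrom_b,
        q_strand = "+", stringsAsFactors = FALSE)
      nets_ba[[length(nets_ba) + 1L]] <- data.frame(
        target_chrom = chrom_b, start = q_start, end = q_end, level = 1L,
        chain_id = chain_id, fill_class = "top", q_chrom = chrom_a,
        q_strand = "+", stringsAsFactors = FALSE)
    } else {
      chrom_sizes_b[chrom_b] <- need_len
    }
    # a level-2 paralog fill over the first C5 cassette, inside the main fill
    c5r <- which(sub$kind == "kg" & sub$category == "C5")
    if (length(c5r) && !is.null(main_chain)) {
      r <- c5r[1]
      cs <- sub$offset[r] + .BLOCK_INSET
      ce <- sub$offset[r] + .CASSETTE_W - 3000L
      if (cs >= main_chain$t_start && ce <= main_chain$t_end) {
        chain_id <- chain_id + 1L
        pq <- chrom_sizes_b[chrom_b] - 20000L
        par_chain <- list(score = 5e3, t_chrom = chrom_a,
                          t_size = unname(chrom_sizes_a[chrom_a]),
                          t_start = cs, t_end = ce, q_chrom = chrom_b,
                          q_size = unname(chrom_sizes_b[chrom_b]),
                          q_strand = "+", q_start = pq, q_end = pq + (ce - cs),
                          chain_id = chain_id,
                          blocks = data.frame(size = ce - cs, dt = 0L, dq = 0L))
        chains_ab[[as.character(chain_id)]] <- par_chain
        nets_ab[[length(nets_ab) + 1L]] <- data.frame(
          target_chrom = chrom_a, start = cs, end = ce, level = 2L,
          chain_id = chain_id, fill_class = "nonSyn", q_chrom = chrom_b,
          q_strand = "+", stringsAsFactors = FALSE)
      }
    }
    # ---- genes per cassette ---------------------------------------------
    for (r in seq_len(nrow(sub))) {
      o <- sub$offset[r]
      if (sub$kind[r] == "single") {
        sym <- sprintf("sglA_%d_%d", ci, r)
        tx_a_kg[[length(tx_a_kg) + 1L]] <-
          .syn_gene(sym, chrom_a, o + 8000L, o + 13000L, "+", n_tx_draw())
        single_tss[[length(single_tss) + 1L]] <-
          data.frame(chrom = chrom_a, tss = o + 8000L, symbol = sym,
                     stringsAsFactors = FALSE)
        if (stats::runif(1) < spec$cpg_rate_single)
          cpg[[length(cpg) + 1L]] <- data.frame(
            chrom = chrom_a, start = o + 7900L, end = o + 8100L,
            stringsAsFactors = FALSE)
        next
      }
      d <- sub$d[r]
      lt <- o + 9000L          # left (minus) TSS
      rt <- lt + d             # right (plus) TSS
      left_body <- c(o + 4000L, lt)
      right_body <- c(rt, o + 15000L)
      if (sub$kind[r] == "est") {
        symL <- sprintf("estA_%d_%d_L", ci, r); symR <- sprintf("estA_%d_%d_R", ci, r)
        canL <- stats::runif(1) < spec$est_canonical_rate
        canR <- stats::runif(1) < spec$est_canonical_rate
        tx_a_est[[length(tx_a_est) + 1L]] <-
          .syn_gene(symL, chrom_a, left_body[1], left_body[2], "-", n_tx_draw(),
                    "spliced_est", canL)
        tx_a_est[[length(tx_a_est) + 1L]] <-
          .syn_gene(symR, chrom_a, right_body[1], right_body[2], "+", n_tx_draw(),
                    "spliced_est", canR)
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom_a, left_tss = lt, right_tss = rt, tss_distance = d,
          left_symbol = symL, right_symbol = symR, kind = "est",
          category = NA_character_, b_partner = NA_character_,
          coactivated = NA, est_retained = canL && canR,
          stringsAsFactors = FALSE)
        next
      }
      # KG cassette
      cat5 <- sub$category[r]
      symL <- sprintf("gA_%d_%d_L", ci, r); symR <- sprintf("gA_%d_%d_R", ci, r)
      bsymL <- sub("gA", "gB", symL); bsymR <- sub("gA", "gB", symR)
      tx_a_kg[[length(tx_a_kg) + 1L]] <-
        .syn_gene(symL, chrom_a, left_body[1], left_body[2], "-", n_tx_draw())
      tx_a_kg[[length(tx_a_kg) + 1L]] <-
        .syn_gene(symR, chrom_a, right_body[1], right_body[2], "+", n_tx_draw())
      if (stats::runif(1) < spec$cpg_rate_bidirectional)
        cpg[[length(cpg) + 1L]] <- data.frame(
          chrom = chrom_a, start = lt + pmax(0L, d %/% 2L) - 100L,
          end = lt + pmax(0L, d %/% 2L) + 100L, stringsAsFactors = FALSE)
      qo <- sub$qoff[r]
      b_partner <- "none"
      if (cat5 != "C5") {
        # B-side genes at the mapped cassette position
        bl <- left_body + qo; blt <- lt + qo; brt <- rt + qo
        br <- right_body + qo
        add_b <- function(sym, body, strand)
          .syn_gene(sym, chrom_b, body[1], body[2], strand, n_tx_draw())
        if (cat5 == "C1") {
          tx_b_kg[[length(tx_b_kg) + 1L]] <- add_b(bsymL, bl, "-")
          tx_b_kg[[length(tx_b_kg) + 1L]] <- add_b(bsymR, br, "+")
          orth[[length(orth) + 1L]] <- data.frame(
            source = c(symL, symR), target = c(bsymL, bsymR),
            stringsAsFactors = FALSE)
          b_partner <- "present"
        } else if (cat5 == "C2") {
          decoy <- sprintf("decoyB_%d_%d", ci, r)
          tx_b_kg[[length(tx_b_kg) + 1L]] <- add_b(bsymL, bl, "-")
          tx_b_kg[[length(tx_b_kg) + 1L]] <- add_b(decoy, br, "+")
          orth[[length(orth) + 1L]] <- data.frame(
            source = c(symL, symR), target = c(bsymL, bsymR),
            stringsAsFactors = FALSE)
          b_partner <- "decoy"
        } else if (cat5 == "C3") {
          tx_b_kg[[length(tx_b_kg) + 1L]] <- add_b(bsymL, bl, "-")
          orth[[length(orth) + 1L]] <- data.frame(
            source = symL, target = bsymL, stringsAsFactors = FALSE)
          if (sub$overlimit[r]) {
            d_b <- sample(1100:2000, 1)
            tx_b_kg[[length(tx_b_kg) + 1L]] <-
              add_b(bsymR, c(blt + d_b, blt + d_b + 5000L), "+")
            orth[[length(orth) + 1L]] <- data.frame(
              source = symR, target = bsymR, stringsAsFactors = FALSE)
            b_partner <- "overlimit"
          } else b_partner <- "absent"
        } else if (cat5 == "C4") {
          unrel <- sprintf("unrelB_%d_%d", ci, r)
          tx_b_kg[[length(tx_b_kg) + 1L]] <- add_b(unrel, bl, "-")
          orth[[length(orth) + 1L]] <- data.frame(
            source = symL, target = bsymL, stringsAsFactors = FALSE)
          b_partner <- "unrelated"
        }
      }
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = chrom_a, left_tss = lt, right_tss = rt, tss_distance = d,
        left_symbol = symL, right_symbol = symR, kind = "kg",
        category = cat5, b_partner = b_partner,
        coactivated = stats::runif(1) < spec$cage_coactivation_rate,
        est_retained = NA, stringsAsFactors = FALSE)
    }
  }

  tx_a_kg <- do.call(rbind, tx_a_kg)
  tx_a_est <- if (length(tx_a_est)) do.call(rbind, tx_a_est) else empty_transcripts("spliced_est")
  tx_b_kg <- if (length(tx_b_kg)) do.call(rbind, tx_b_kg) else empty_transcripts()
  truth <- do.call(rbind, truth)
  orth <- if (length(orth)) do.call(rbind, orth) else
    data.frame(source = character(), target = character())
  single_tss <- if (length(single_tss)) do.call(rbind, single_tss) else
    data.frame(chrom = character(), tss = integer(), symbol = character())
  cpg <- if (length(cpg)) do.call(rbind, cpg) else
    data.frame(chrom = character(), start = integer(), end = integer())

  # EST overlay on the first two KG pairs: bidirectional promoters that the
  # EST annotations rediscover (excluded from the "EST-only" set)
  kg_truth <- truth[truth$kind == "kg", , drop = FALSE]
  for (i in seq_len(min(2L, nrow(kg_truth)))) {
    tr <- kg_truth[i, ]
    ov <- rbind(
      .syn_gene(paste0("est_", tr$left_symbol), tr$chrom, tr$left_tss - 5000L,
                tr$left_tss, "-", 2L, "spliced_est", TRUE),
      .syn_gene(paste0("est_", tr$right_symbol), tr$chrom, tr$right_tss,
                tr$right_tss + 5000L, "+", 2L, "spliced_est", TRUE))
    tx_a_est <- rbind(tx_a_est, ov)
  }
  # a few single-exon EST decoys that filter_spliced must remove
  if (nrow(tx_a_est)) {
    dec <- lapply(seq_len(3L), function(k) {
      .syn_tx(sprintf("est_single.%d", k), tx_a_est$chrom[1],
              1000L + 900L * k, 1000L + 900L * k + 800L, "+",
              1000L + 900L * k, 1000L + 900L * k + 800L,
              "spliced_est", FALSE, sprintf("est_single%d", k))
    })
    tx_a_est <- rbind(tx_a_est, do.call(rbind, dec))
  }

  # target-side annotation dropout
  if (spec$annotation_dropout_rate > 0 && nrow(tx_b_kg)) {
    syms <- unique(tx_b_kg$gene_symbol)
    dropped <- syms[stats::runif(length(syms)) < spec$annotation_dropout_rate]
    tx_b_kg <- tx_b_kg[!tx_b_kg$gene_symbol %in% dropped, , drop = FALSE]
    truth$b_dropped_own <- sub("gA", "gB", truth$left_symbol) %in% dropped
    truth$b_dropped_partner <- sub("gA", "gB", truth$right_symbol) %in% dropped
  } else {
    truth$b_dropped_own <- FALSE
    truth$b_dropped_partner <- FALSE
  }

  chains_ba <- lapply(chains_ab, invert_chain)
  nets_ab <- do.call(rbind, nets_ab)
  nets_ba <- do.call(rbind, nets_ba)

  # ---- CAGE ---------------------------------------------------------------
  cage_a <- .gen_cage(truth[truth$kind == "kg", , drop = FALSE], spec)
  b_pairs <- truth[truth$kind == "kg" & truth$category == "C1", , drop = FALSE]
  cage_b <- if (nrow(b_pairs) && nrow(tx_b_kg)) {
    bt <- b_pairs
    bsym <- sub("gA", "gB", bt$left_symbol)
    off <- vapply(seq_len(nrow(bt)), function(i) {
      m <- tx_b_kg[tx_b_kg$gene_symbol == bsym[i], , drop = FALSE]
      if (nrow(m)) max(m$tss) - bt$left_tss[i] else NA_integer_
    }, integer(1))
    bt <- bt[!is.na(off), , drop = FALSE]; off <- off[!is.na(off)]
    bt$chrom <- sub("chrA", "chrB", bt$chrom)
    bt$left_tss <- bt$left_tss + off; bt$right_tss <- bt$right_tss + off
    .gen_cage(bt, spec)
  } else .gen_cage(truth[0, ], spec)

  # ---- expression ---------------------------------------------------------
  expr <- .gen_expression(truth[truth$kind == "kg", , drop = FALSE], spec)

  out <- list(spec = spec, truth = truth, tx_a_kg = tx_a_kg,
              tx_a_est = tx_a_est, tx_b_kg = tx_b_kg,
              chains_ab = chains_ab, chains_ba = chains_ba,
              nets_ab = nets_ab, nets_ba = nets_ba,
              cpg_a = cpg, cage_a = cage_a, cage_b = cage_b,
              expr_a = expr$a, expr_b = expr$b, orthologs = orth,
              single_tss_a = single_tss,
              chrom_sizes_a = chrom_sizes_a, chrom_sizes_b = chrom_sizes_b)
  if (!is.null(dir)) out$files <- .write_dataset(out, dir)
  out
}

#' Invert a plus-strand chain (swap target and query)
#' @param ch chain from [read_chain()] with `q_strand == "+"`.
#' @return chain mapping the former query to the former target.
#' @export
invert_chain <- function(ch) {
  stopifnot(ch$q_strand == "+")
  inv <- list(score = ch$score, t_chrom = ch$q_chrom, t_size = ch$q_size,
              t_start = ch$q_start, t_end = ch$q_end, q_chrom = ch$t_chrom,
              q_size = ch$t_size, q_strand = "+", q_start = ch$t_start,
              q_end = ch$t_end, chain_id = ch$chain_id,
              blocks = data.frame(size = ch$blocks$size, dt = ch$blocks$dq,
                                  dq = ch$blocks$dt))
  .check_chain_spans(inv)
  inv
}

#' Swap the columns of an ortholog table
#' @param orth data frame `source`, `target`.
#' @return the reverse-direction table.
#' @export
invert_orthologs <- function(orth) {
  data.frame(source = orth$target, target = orth$source, stringsAsFactors = FALSE)
}

.gen_cage <- function(kg_truth, spec) {
  rows <- list()
  samples <- sprintf("sample%02d", seq_len(spec$n_cage_samples))
  peak <- function(chrom, tss, smp) {
    summit <- as.integer(round(tss + stats::rnorm(1, 0, spec$cage_summit_sd)))
    data.frame(chrom = chrom, start = summit - 25L, end = summit + 25L,
               sample_label = smp, tag_count = 1L + stats::rpois(1, 5),
               summit = summit, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(kg_truth))) {
    tr <- kg_truth[i, ]
    if (isTRUE(tr$coactivated)) {
      s <- sample(samples, 1)
      rows[[length(rows) + 1L]] <- peak(tr$chrom, tr$left_tss, s)
      rows[[length(rows) + 1L]] <- peak(tr$chrom, tr$right_tss, s)
    } else {
      s2 <- sample(samples, 2)
      rows[[length(rows) + 1L]] <- peak(tr$chrom, tr$left_tss, s2[1])
      rows[[length(rows) + 1L]] <- peak(tr$chrom, tr$right_tss, s2[2])
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      sample_label = character(), tag_count = integer(),
                      summit = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.gen_expression <- function(kg_truth, spec) {
  lam <- spec$coexpression_loading
  rho <- spec$cross_species_rho
  nt <- spec$n_tissues; ns <- spec$n_shared_tissues
  tissues <- c(sprintf("tissue%02d", seq_len(ns)),
               if (nt > ns) sprintf("tissueA%02d", seq((ns + 1L), nt)))
  genes_a <- c(kg_truth$left_symbol, kg_truth$right_symbol)
  za <- matrix(NA_real_, nrow = length(genes_a), ncol = nt,
               dimnames = list(genes_a, tissues))
  b_syms <- character(); zb_rows <- list()
  for (i in seq_len(nrow(kg_truth))) {
    f <- stats::rnorm(nt)
    zl <- 5 + lam * f + sqrt(1 - lam^2) * stats::rnorm(nt)
    zr <- 5 + lam * f + sqrt(1 - lam^2) * stats::rnorm(nt)
    za[kg_truth$left_symbol[i], ] <- zl
    za[kg_truth$right_symbol[i], ] <- zr
    if (kg_truth$category[i] == "C1") {
      for (side in c("left", "right")) {
        zs <- if (side == "left") zl[seq_len(ns)] else zr[seq_len(ns)]
        zbv <- 5 + rho * (zs - 5) + sqrt(1 - rho^2) * stats::rnorm(ns)
        b_syms <- c(b_syms, sub("gA", "gB", kg_truth[[paste0(side, "_symbol")]][i]))
        zb_rows[[length(zb_rows) + 1L]] <- zbv
      }
    }
  }
  reps <- spec$n_replicates
  to_values <- function(z, labels) {
    m <- matrix(NA_real_, nrow = nrow(z), ncol = ncol(z) * reps,
                dimnames = list(rownames(z), rep(labels, each = reps)))
    for (j in seq_len(ncol(z)))
      for (k in seq_len(reps))
        m[, (j - 1L) * reps + k] <-
          pmax(0, 2^(z[, j] + stats::rnorm(nrow(z), 0, spec$replicate_sd)) - 1)
    m
  }
  zb <- if (length(zb_rows)) {
    mm <- do.call(rbind, zb_rows)
    dimnames(mm) <- list(b_syms, tissues[seq_len(ns)])
    mm
  } else matrix(numeric(), nrow = 0, ncol = ns,
                dimnames = list(NULL, tissues[seq_len(ns)]))
  list(a = to_values(za, tissues), b = to_values(zb, tissues[seq_len(ns)]))
}

.write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  files <- c(a_known = p("a_known.genepred"), a_est = p("a_est.bed12"),
             b_known = p("b_known.genepred"),
             chain_ab = p("a2b.chain"), chain_ba = p("b2a.chain"),
             net_ab = p("a2b.net"), net_ba = p("b2a.net"),
             cpg_a = p("a_cpg.bed"), cage_a = p("a_cage.bed"),
             cage_b = p("b_cage.bed"), expr_a = p("expr_a.tsv"),
             expr_b = p("expr_b.tsv"), orthologs = p("orthologs.tsv"),
             truth = p("truth.tsv"), single_a = p("a_single_tss.tsv"))
  write_transcripts(ds$tx_a_kg, files["a_known"], "genepred")
  write_transcripts(ds$tx_a_est, files["a_est"], "bed12")
  write_transcripts(ds$tx_b_kg, files["b_known"], "genepred")
  write_chain(ds$chains_ab, files["chain_ab"])
  write_chain(ds$chains_ba, files["chain_ba"])
  write_net(ds$nets_ab, ds$chrom_sizes_a, files["net_ab"])
  write_net(ds$nets_ba, ds$chrom_sizes_b, files["net_ba"])
  write_bed_intervals(ds$cpg_a, files["cpg_a"])
  write_cage_peaks(ds$cage_a, files["cage_a"])
  write_cage_peaks(ds$cage_b, files["cage_b"])
  write_expression(ds$expr_a, files["expr_a"])
  write_expression(ds$expr_b, files["expr_b"])
  write_orthologs(ds$orthologs, files["orthologs"])
  write_results(ds$truth, files["truth"], "tsv")
  write_results(ds$single_tss_a, files["single_a"], "tsv")
  files
}

#' Compare pipeline orthology calls against planted truth
#'
#' Joins the gene-level calls for the assessed (left) gene of every planted
#' known-gene pair to the generator truth and reports a confusion matrix
#' with accuracy and per-category precision/recall.
#'
#' @param truth truth table from [generate_dataset()].
#' @param calls gene-level calls from [classify_all()] (left side used).
#' @param pairs the pair table the calls were computed from.
#' @return list with `confusion` (truth x called), `accuracy`,
#'   `per_category` (precision/recall) and `n`.
#' @export
truth_report <- function(truth, calls, pairs) {
  tr <- truth[truth$kind == "kg", , drop = FALSE]
  key_t <- paste(tr$chrom, tr$left_tss)
  left <- calls[calls$side == "left", , drop = FALSE]
  m <- match(left$pair_id, pairs$pair_id)
  if (anyNA(m)) stop("call/pair id mismatch")
  key_c <- paste(pairs$chrom[m], pairs$left_tss[m])
  idx <- match(key_t, key_c)
  if (anyNA(idx)) stop("planted pair missing from the call set")
  called <- left$category[idx]
  conf <- table(truth = factor(tr$category, CATEGORIES),
                called = factor(called, CATEGORIES))
  per <- data.frame(
    category = CATEGORIES,
    precision = vapply(CATEGORIES, function(cc) {
      d <- sum(conf[, cc]); if (d == 0) NA_real_ else conf[cc, cc] / d
    }, numeric(1)),
    recall = vapply(CATEGORIES, function(cc) {
      d <- sum(conf[cc, ]); if (d == 0) NA_real_ else conf[cc, cc] / d
    }, numeric(1)))
  list(confusion = conf, accuracy = sum(diag(conf)) / sum(conf),
       per_category = per, n = nrow(tr))
}
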