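# Readers and writers for the standard flat-file formats the pipeline
# consumes: genePred and BED12 transcript annotations, UCSC chain and net
# alignment dumps, BED intervals (CpG islands), a CAGE-peak BED dialect,
# and gene x tissue expression tables. Every reader normalises to 0-based
# half-open coordinates; every writer is the exact inverse, so that
# read(write(x)) is the identity on valid records.

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

.fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

#' Read transcript annotations
#'
#' Parses transcript models from a genePred (10-column) or BED12 file into
#' a normalised transcript table. Coordinates are kept 0-based half-open,
#' the native convention of both formats. The transcription start site is
#' computed strand-aware: the `start` coordinate on the plus strand, the
#' `end` coordinate on the minus strand.
#'
#' For spliced-EST sets the BED12 `score` column is interpreted as the
#' canonical-intron flag (1 = at least one GT..AG intron, 0 = none); in
#' genePred, which has no score column, the flag defaults to `NA`.
#'
#' @param path path to the annotation file.
#' @param format `"bed12"` or `"genepred"`.
#' @param source evidence class recorded on every transcript, one of
#'   `"known_gene"` or `"spliced_est"`.
#' @return data frame with one row per transcript: `id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, `exon_starts`, `exon_ends` (comma-joined,
#'   0-based), `n_exons`, `source`, `canonical_intron`, `gene_symbol`.
#' @export
read_transcripts <- function(path, format = c("bed12", "genepred"),
                             source = c("known_gene", "spliced_est")) {
  format <- match.arg(format)
  source <- match.arg(source)
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_transcripts(source))
  recs <- vector("list", length(lines))
  kept <- logical(length(lines))
  for (i in seq_along(lines)) {
    f <- .fields(lines[[i]])
    rec <- switch(format,
      bed12 = .parse_bed12(f, i),
      genepred = .parse_genepred(f, i))
    if (is.null(rec)) next   # rejected (bad strand) with warning
    recs[[i]] <- rec
    kept[i] <- TRUE
  }
  out <- do.call(rbind, recs[kept])
  if (is.null(out)) return(empty_transcripts(source))
  out$source <- source
  if (source == "known_gene") out$canonical_intron <- NA
  # gene symbol: the part of the id before the first '.', the usual
  # locus.transcript naming used by the synthetic generator and many dumps
  out$gene_symbol <- sub("\\..*$", "", out$id)
  validate_coords(out)
  rownames(out) <- NULL
  out
}

empty_transcripts <- function(source = "known_gene") {
  data.frame(id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), tss = integer(),
             exon_starts = character(), exon_ends = character(),
             n_exons = integer(), source = character(),
             canonical_intron = logical(), gene_symbol = character(),
             stringsAsFactors = FALSE)
}

.parse_bed12 <- function(f, lineno) {
  if (length(f) < 12) stop("malformed BED12 at line ", lineno, ": expected 12 fields, got ", length(f))
  num <- suppressWarnings(as.integer(f[c(2, 3, 7, 8, 10)]))
  if (anyNA(num)) stop("malformed BED12 at line ", lineno, ": non-numeric coordinate field")
  if (!f[6] %in% c("+", "-")) {
    warning("line ", lineno, ": unknown strand '", f[6], "', record rejected")
    return(NULL)
  }
  start <- num[1]; end <- num[2]; n <- num[5]
  sizes <- .split_commas(f[11])[[1]]
  offs  <- .split_commas(f[12])[[1]]
  if (length(sizes) != n || length(offs) != n)
    stop("malformed BED12 at line ", lineno, ": blockCount disagrees with block lists")
  ex_start <- start + offs
  ex_end <- ex_start + sizes
  .tx_row(f[4], f[1], start, end, f[6], ex_start, ex_end,
          canonical = suppressWarnings(as.integer(f[5])) >= 1L)
}

.parse_genepred <- function(f, lineno) {
  if (length(f) < 10) stop("malformed genePred at line ", lineno, ": expected 10 fields, got ", length(f))
  num <- suppressWarnings(as.integer(f[c(4, 5, 8)]))
  if (anyNA(num)) stop("malformed genePred at line ", lineno, ": non-numeric coordinate field")
  if (!f[3] %in% c("+", "-")) {
    warning("line ", lineno, ": unknown strand '", f[3], "', record rejected")
    return(NULL)
  }
  ex_start <- .split_commas(f[9])[[1]]
  ex_end <- .split_commas(f[10])[[1]]
  if (length(ex_start) != num[3] || length(ex_end) != num[3])
    stop("malformed genePred at line ", lineno, ": exonCount disagrees with exon lists")
  .tx_row(f[1], f[2], num[1], num[2], f[3], ex_start, ex_end, canonical = NA)
}

.tx_row <- function(id, chrom, start, end, strand, ex_start, ex_end, canonical) {
  o <- order(ex_start)
  ex_start <- ex_start[o]; ex_end <- ex_end[o]
  if (any(ex_start < start) || any(ex_end > end) ||
      any(ex_end <= ex_start) ||
      (length(ex_start) > 1 && any(ex_start[-1] < ex_end[-length(ex_end)])))
    stop("transcript ", id, ": exon blocks must be sorted, non-overlapping and within the transcript span")
  data.frame(id = id, chrom = chrom, start = start, end = end, strand = strand,
             tss = .tss_of(start, end, strand),
             exon_starts = .join_commas(list(ex_start)),
             exon_ends = .join_commas(list(ex_end)),
             n_exons = length(ex_start), source = NA_character_,
             canonical_intron = canonical, gene_symbol = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write transcript annotations
#'
#' Inverse of [read_transcripts()]; the BED12 score column carries the
#' canonical-intron flag (0/1, 0 when unknown).
#'
#' @param tx transcript table as returned by [read_transcripts()].
#' @param path output path.
#' @param format `"bed12"` or `"genepred"`.
#' @export
write_transcripts <- function(tx, path, format = c("bed12", "genepred")) {
  format <- match.arg(format)
  if (!nrow(tx)) { writeLines(character(), path); return(invisible(path)) }
  validate_coords(tx)
  es <- .split_commas(tx$exon_starts)
  ee <- .split_commas(tx$exon_ends)
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    if (format == "bed12") {
      offs <- es[[i]] - tx$start[i]
      sizes <- ee[[i]] - es[[i]]
      paste(tx$chrom[i], tx$start[i], tx$end[i], tx$id[i],
            as.integer(isTRUE(tx$canonical_intron[i])), tx$strand[i],
            tx$start[i], tx$end[i], "0", length(sizes),
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(offs, collapse = ","), ","), sep = "\t")
    } else {
      paste(tx$id[i], tx$chrom[i], tx$strand[i], tx$start[i], tx$end[i],
            tx$start[i], tx$end[i], length(es[[i]]),
            paste0(paste(es[[i]], collapse = ","), ","),
            paste0(paste(ee[[i]], collapse = ","), ","), sep = "\t")
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------- chains --

#' Read a UCSC chain file
#'
#' Parses pairwise-alignment chains: each chain is a header line followed by
#' gapless block triplets `size dt dq` (the final line a bare `size`). The
#' block sums are checked against the declared target and query spans; a
#' mismatch is an error naming the chain id. Reverse-strand query
#' coordinates are kept exactly as the file states them (coordinates on the
#' reversed strand); [map_interval()] performs the flip.
#'
#' @param path chain file path.
#' @return named list of chains (names are chain ids); each chain is a list
#'   with `score`, `t_chrom`, `t_size`, `t_start`, `t_end`, `q_chrom`,
#'   `q_size`, `q_strand`, `q_start`, `q_end`, `chain_id` and a `blocks`
#'   data frame (`size`, `dt`, `dq`).
#' @export
read_chain <- function(path) {
  lines <- .read_lines_checked(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    f <- .fields(line)
    if (f[1] != "chain" || length(f) < 13)
      stop("malformed chain header at line ", i)
    hdr <- list(score = as.numeric(f[2]),
                t_chrom = f[3], t_size = as.integer(f[4]),
                t_start = as.integer(f[6]), t_end = as.integer(f[7]),
                q_chrom = f[8], q_size = as.integer(f[9]), q_strand = f[10],
                q_start = as.integer(f[11]), q_end = as.integer(f[12]),
                chain_id = as.integer(f[13]))
    if (f[5] != "+") stop("chain ", hdr$chain_id, ": target strand must be '+'")
    sizes <- integer(); dts <- integer(); dqs <- integer()
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("chain ", hdr$chain_id, ": truncated block list")
      bf <- .fields(lines[[i]])
      if (length(bf) == 3) {
        sizes <- c(sizes, as.integer(bf[1]))
        dts <- c(dts, as.integer(bf[2])); dqs <- c(dqs, as.integer(bf[3]))
        i <- i + 1L
      } else if (length(bf) == 1 && nzchar(bf[1])) {
        sizes <- c(sizes, as.integer(bf[1])); dts <- c(dts, 0L); dqs <- c(dqs, 0L)
        i <- i + 1L
        break
      } else stop("chain ", hdr$chain_id, ": malformed block line at ", i)
    }
    hdr$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    .check_chain_spans(hdr)
    chains[[as.character(hdr$chain_id)]] <- hdr
    i <- i + 1L
  }
  chains
}

.check_chain_spans <- function(ch) {
  b <- ch$blocks
  if (sum(b$size) + sum(b$dt) != ch$t_end - ch$t_start)
    stop("invalid chain ", ch$chain_id, ": block sizes + target gaps do not equal the target span")
  if (sum(b$size) + sum(b$dq) != ch$q_end - ch$q_start)
    stop("invalid chain ", ch$chain_id, ": block sizes + query gaps do not equal the query span")
  invisible(ch)
}

#' Write chains in UCSC chain format
#' @param chains named list of chains as from [read_chain()].
#' @param path output path.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ch in chains) {
    .check_chain_spans(ch)
    cat(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %d\n",
                format(ch$score, scientific = FALSE), ch$t_chrom, ch$t_size,
                ch$t_start, ch$t_end, ch$q_chrom, ch$q_size, ch$q_strand,
                ch$q_start, ch$q_end, ch$chain_id), file = con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1)
      cat(sprintf("%d\t%d\t%d\n", b$size[-n], b$dt[-n], b$dq[-n]), sep = "", file = con)
    cat(sprintf("%d\n\n", b$size[n]), file = con)
  }
  invisible(path)
}

# ------------------------------------------------------------------ nets --

#' Read a UCSC net file
#'
#' Nets arrange chains hierarchically over the target genome; indentation
#' encodes nesting. `fill` lines at nesting depth 1 are level-1 (the
#' longest, best-scoring, orthology-representing chains); each further
#' fill-within-gap nesting adds one level. A child interval escaping its
#' parent is a structure error.
#'
#' @param path net file path.
#' @return data frame of fill entries: `target_chrom`, `start`, `end`,
#'   `level`, `chain_id`, `fill_class`, `q_chrom`, `q_strand`.
#' @export
read_net <- function(path) {
  lines <- .read_lines_checked(path)
  out <- list()
  chrom <- NA_character_
  # stack of enclosing intervals (fill or gap), one per indentation depth
  stack <- list()
  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    if (!nzchar(trimws(raw))) next
    indent <- nchar(raw) - nchar(sub("^ +", "", raw))
    f <- .fields(raw)
    if (f[1] == "net") { chrom <- f[2]; stack <- list(); next }
    if (!f[1] %in% c("fill", "gap")) next
    start <- as.integer(f[2]); end <- start + as.integer(f[3])
    depth <- indent
    stack <- stack[seq_len(min(depth - 1L, length(stack)))]
    if (length(stack)) {
      par <- stack[[length(stack)]]
      if (start < par[1] || end > par[2])
        stop("net structure error at line ", i,
             ": child interval [", start, ",", end, ") escapes its parent [",
             par[1], ",", par[2], ")")
    }
    stack[[depth]] <- c(start, end)
    if (f[1] == "fill") {
      kv <- f[-seq_len(7)]
      get_kv <- function(key) {
        j <- match(key, kv)
        if (is.na(j) || j == length(kv)) NA_character_ else kv[j + 1L]
      }
      out[[length(out) + 1L]] <- data.frame(
        target_chrom = chrom, start = start, end = end,
        level = (indent + 1L) %/% 2L,
        chain_id = as.integer(get_kv("id")),
        fill_class = get_kv("type"),
        q_chrom = f[4], q_strand = f[5], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(target_chrom = character(), start = integer(),
                      end = integer(), level = integer(), chain_id = integer(),
                      fill_class = character(), q_chrom = character(),
                      q_strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write net entries in UCSC net format
#'
#' The writer emits one `net` block per target chromosome; a level-k fill is
#' indented 2k-1 spaces and, when nested, is preceded by a synthetic `gap`
#' line spanning it inside its parent fill (the minimal structure that
#' round-trips through [read_net()]).
#'
#' @param nets fill table as from [read_net()].
#' @param chrom_sizes named integer vector of target chromosome sizes.
#' @param path output path.
#' @export
write_net <- function(nets, chrom_sizes, path) {
  con <- file(path, "w"); on.exit(close(con))
  emit <- function(sub, row, lv) {
    if (lv > 1L) {
      # synthetic enclosing gap line one depth up
      cat(sprintf("%sgap %d %d %s %s 0 0\n", strrep(" ", 2L * lv - 2L),
                  sub$start[row], sub$end[row] - sub$start[row],
                  sub$q_chrom[row], sub$q_strand[row]), file = con)
    }
    cat(sprintf("%sfill %d %d %s %s 0 0 id %d score 0 type %s\n",
                strrep(" ", 2L * lv - 1L), sub$start[row],
                sub$end[row] - sub$start[row], sub$q_chrom[row],
                sub$q_strand[row], sub$chain_id[row], sub$fill_class[row]),
        file = con)
    kids <- which(sub$level == lv + 1L & sub$start >= sub$start[row] &
                    sub$end <= sub$end[row])
    for (k in kids[order(sub$start[kids])]) emit(sub, k, lv + 1L)
  }
  for (chrom in unique(nets$target_chrom)) {
    cat(sprintf("net %s %d\n", chrom, chrom_sizes[[chrom]]), file = con)
    sub <- nets[nets$target_chrom == chrom, , drop = FALSE]
    for (i in which(sub$level == 1L)[order(sub$start[sub$level == 1L])])
      emit(sub, i, 1L)
  }
  invisible(path)
}

# ------------------------------------------------------- plain BED / CAGE --

#' Read plain BED intervals
#'
#' For CpG islands and similar annotation tracks. Only the first three
#' columns are used; a fourth, when present, is kept as `name`.
#'
#' @param path BED file path.
#' @return data frame `chrom`, `start`, `end`(, `name`).
#' @export
read_bed_intervals <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  fl <- lapply(seq_along(lines), function(i) {
    f <- .fields(lines[[i]])
    if (length(f) < 3) stop("malformed BED at line ", i)
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en)) stop("malformed BED at line ", i, ": non-numeric coordinates")
    data.frame(chrom = f[1], start = st, end = en,
               name = if (length(f) >= 4) f[4] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fl)
  if (all(is.na(out$name))) out$name <- NULL
  validate_coords(out)
  out
}

#' Write BED intervals
#' @param df data frame with `chrom`, `start`, `end` and optional `name`.
#' @param path output path.
#' @export
write_bed_intervals <- function(df, path) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  cols <- c("chrom", "start", "end", intersect("name", names(df)))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CAGE peaks
#'
#' BED dialect with three extra columns: sample label, tag count and summit
#' offset within the peak. When the summit column is absent the summit
#' defaults to the interval midpoint.
#'
#' @param path CAGE BED path.
#' @return data frame `chrom`, `start`, `end`, `sample_label`, `tag_count`,
#'   `summit` (absolute coordinate).
#' @export
read_cage_peaks <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      sample_label = character(), tag_count = integer(),
                      summit = integer(), stringsAsFactors = FALSE))
  fl <- lapply(seq_along(lines), function(i) {
    f <- .fields(lines[[i]])
    if (length(f) < 5) stop("malformed CAGE BED at line ", i, ": need >= 5 columns")
    st <- as.integer(f[2]); en <- as.integer(f[3])
    summit <- if (length(f) >= 6) st + as.integer(f[6]) else st + (en - st) %/% 2L
    data.frame(chrom = f[1], start = st, end = en, sample_label = f[4],
               tag_count = as.integer(f[5]), summit = summit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fl)
  validate_coords(out)
  if (any(out$tag_count < 1L)) stop("CAGE tag counts must be >= 1")
  if (any(out$summit < out$start | out$summit >= out$end))
    stop("CAGE summit outside its peak interval")
  out
}

#' Write CAGE peaks
#' @param peaks CAGE table as from [read_cage_peaks()].
#' @param path output path.
#' @export
write_cage_peaks <- function(peaks, path) {
  df <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  utils::write.table(
    data.frame(df$chrom, df$start, df$end, df$sample_label, df$tag_count,
               df$summit - df$start),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ------------------------------------------------------- tables / results --

#' Write a result table as TSV or BED
#'
#' Generic sorted, deterministic writer used for promoter tables, orthology
#' calls and reports. TSV keeps all columns with a header; BED writes
#' `chrom`/`start`/`end` plus an id column when one exists.
#'
#' @param records data frame; when it has `chrom` and `start` columns rows
#'   are sorted by (chrom, start).
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_results <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (all(c("chrom", "start") %in% names(records)) && nrow(records))
    records <- records[order(records$chrom, records$start), , drop = FALSE]
  if (format == "bed") {
    idcol <- intersect(c("pair_id", "locus_id", "id", "name"), names(records))[1]
    df <- records[, c("chrom", "start", "end"), drop = FALSE]
    if (!is.na(idcol)) df$name <- records[[idcol]]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a result TSV written by [write_results()]
#' @param path TSV path.
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a gene x tissue expression matrix
#'
#' Tab-separated, first column gene ids, remaining columns one per array;
#' replicate arrays share a tissue label (duplicate column names are
#' preserved). Values must be non-negative.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames gene ids, colnames tissue labels.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  # data-frame column subsetting uniquifies duplicate replicate labels;
  # restore the labels exactly as the header states them
  colnames(m) <- colnames(df)[-1]
  rownames(m) <- df[[1]]
  if (any(m < 0)) stop("expression values must be non-negative")
  m
}

#' Write a gene x tissue expression matrix
#' @param mat matrix as from [read_expression()].
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ortholog identity table
#'
#' @param path TSV with columns `source` and `target` gene symbols (header
#'   optional; any two-column file is accepted).
#' @return data frame `source`, `target`.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE)
  if (identical(tolower(unlist(df[1, ])), c("source", "target"))) df <- df[-1, , drop = FALSE]
  names(df) <- c("source", "target")
  rownames(df) <- NULL
  df
}

#' Write an ortholog table
#' @param orth data frame `source`, `target`.
#' @param path output path.
#' @export
write_orthologs <- function(orth, path) {
  utils::write.table(orth[, c("source", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
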