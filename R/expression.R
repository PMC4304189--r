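# Co-expression of bidirectional gene pairs within a species and of
# confirmed orthologs across species, on log2-transformed tissue profiles.

.log2p1 <- function(x) log2(x + 1)

#' Collapse replicate arrays to one column per tissue
#'
#' Replicate arrays share a tissue label (duplicate column names); each
#' output tissue column is the per-gene median over its replicates. Gene
#' order is preserved.
#'
#' @param mat gene x array matrix from [read_expression()].
#' @param method only `"median"` is implemented.
#' @return gene x tissue matrix with unique tissue columns.
#' @export
aggregate_replicates <- function(mat, method = "median") {
  method <- match.arg(method, "median")
  labels <- colnames(mat)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every array column needs a tissue label")
  tissues <- unique(labels)
  out <- vapply(tissues, function(t) {
    cols <- mat[, labels == t, drop = FALSE]
    if (!ncol(cols)) stop("tissue with zero replicate columns: ", t)
    apply(cols, 1, stats::median)
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), tissues))
  out
}

.safe_cor <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

#' Co-expression of bidirectional gene pairs
#'
#' One correlation per pair between the log2(value + 1) tissue profiles of
#' its two genes. Pairs with a constant profile on either side get `NA`
#' and are flagged; they are excluded from the histogram.
#'
#' @param mat gene x tissue matrix (replicates already aggregated); row
#'   names must contain the pair gene symbols.
#' @param pairs pair table with `left_symbol` and `right_symbol`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `records` (`pair_id`, `r`, `n_tissues`, `method`,
#'   `defined`) and `histogram` (`bin_lo`, `bin_hi`, `count`; bin width
#'   0.1 over \[-1, 1\]).
#' @export
pair_coexpression <- function(mat, pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  lm <- .log2p1(mat)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$left_symbol[i]; b <- pairs$right_symbol[i]
    if (!a %in% rownames(lm) || !b %in% rownames(lm))
      stop("pair gene missing from the expression matrix: ",
           if (a %in% rownames(lm)) b else a)
    .safe_cor(lm[a, ], lm[b, ], method)
  }, numeric(1))
  records <- data.frame(pair_id = pairs$pair_id, r = r,
                        n_tissues = ncol(mat), method = method,
                        defined = !is.na(r), stringsAsFactors = FALSE)
  list(records = records, histogram = correlation_histogram(r))
}

#' Bin correlation coefficients at width 0.1
#' @param r numeric vector of correlations (NAs dropped).
#' @return data frame `bin_lo`, `bin_hi`, `count`.
#' @export
correlation_histogram <- function(r) {
  r <- r[!is.na(r)]
  edges <- seq(-1, 1, by = 0.1)
  counts <- tabulate(pmin(findInterval(r, edges, rightmost.closed = TRUE), 20L),
                     nbins = 20L)
  data.frame(bin_lo = edges[-21], bin_hi = edges[-1], count = counts)
}

#' Expression correlation of orthologs across species
#'
#' One correlation per confirmed ortholog gene between its log2 profiles
#' in the two species over the shared tissues (matched 1:1 by label).
#'
#' @param mat_a,mat_b gene x tissue matrices for the two species
#'   (replicates aggregated).
#' @param ortholog_map data frame `source`, `target` restricted to genes of
#'   confirmed orthologous promoters.
#' @param shared_tissues tissue labels present in both matrices; at least 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `records` (`gene`, `ortholog`, `r`, `n_tissues`,
#'   `method`, `defined`), `histogram`, and `summary` (`mean_r`,
#'   `median_r`, `n_positive`, `n_negative`).
#' @export
cross_species_correlation <- function(mat_a, mat_b, ortholog_map,
                                      shared_tissues,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(shared_tissues) < 3)
    stop("need at least 3 shared tissues for a correlation")
  missing_a <- setdiff(shared_tissues, colnames(mat_a))
  missing_b <- setdiff(shared_tissues, colnames(mat_b))
  if (length(missing_a) || length(missing_b))
    stop("shared tissues absent from a matrix: ",
         paste(c(missing_a, missing_b), collapse = ", "))
  la <- .log2p1(mat_a[, shared_tissues, drop = FALSE])
  lb <- .log2p1(mat_b[, shared_tissues, drop = FALSE])
  keep <- ortholog_map$source %in% rownames(la) &
    ortholog_map$target %in% rownames(lb)
  om <- ortholog_map[keep, , drop = FALSE]
  r <- vapply(seq_len(nrow(om)), function(i)
    .safe_cor(la[om$source[i], ], lb[om$target[i], ], method), numeric(1))
  records <- data.frame(gene = om$source, ortholog = om$target, r = r,
                        n_tissues = length(shared_tissues), method = method,
                        defined = !is.na(r), stringsAsFactors = FALSE)
  ok <- r[!is.na(r)]
  list(records = records, histogram = correlation_histogram(r),
       summary = data.frame(mean_r = mean(ok), median_r = stats::median(ok),
                            n_positive = sum(ok > 0), n_negative = sum(ok < 0)))
}
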