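#' Binary pair indicator for two expression vectors
#'
#' The rank rule of the pair transform: element `i` is 1 when gene A is
#' expressed above gene B in sample `i` (`a[i] > b[i]`), else 0.  This is the
#' ratio rule "C = A/B > 1" extended to the boundary cases the ratio cannot
#' express: ties (including 0/0) give 0, and `a > 0, b = 0` gives 1.
#'
#' @param expr_a,expr_b equal-length non-negative numeric vectors.
#' @return integer 0/1 vector.
#' @export
pair_indicator <- function(expr_a, expr_b) {
  if (length(expr_a) != length(expr_b))
    stop_stage("pairing", "expression vectors differ in length (%d vs %d)",
               length(expr_a), length(expr_b))
  as.integer(expr_a > expr_b)
}

#' Build the 0-or-1 pair matrix over a gene set
#'
#' Cyclically singly pairs the genes: one row per unordered gene pair
#' `{A, B}`, named `"A|B"` with A the lexicographically smaller identifier,
#' holding [pair_indicator()] of A over B per sample.  With `n` genes the
#' result has `n*(n-1)/2` rows, in lexicographic row order.
#'
#' @param expr numeric matrix (genes x samples) restricted to the genes to be
#'   paired, typically the DEirlncRNAs.
#' @return integer 0/1 matrix, pairs x samples, with `"A|B"` rownames.
#' @seealso [filter_valid_pairs()], [pair_meta()]
#' @export
build_pair_matrix <- function(expr) {
  if (nrow(expr) < 2)
    stop_stage("pairing", "need >= 2 genes to build pairs (got %d)", nrow(expr))
  if (anyDuplicated(rownames(expr)))
    stop_stage("pairing", "duplicate gene identifiers")
  genes <- sort(rownames(expr))
  ex <- expr[genes, , drop = FALSE]
  idx <- combn(length(genes), 2L)
  pm <- (ex[idx[1L, ], , drop = FALSE] > ex[idx[2L, ], , drop = FALSE]) + 0L
  rownames(pm) <- paste(genes[idx[1L, ]], genes[idx[2L, ]], sep = "|")
  storage.mode(pm) <- "integer"
  pm
}

#' Pair metadata: constituent genes and indicator frequency
#'
#' @param pm a pair matrix from [build_pair_matrix()].
#' @return data.frame with `pair_id`, `gene_a`, `gene_b`, `one_fraction`
#'   (row mean of the indicator).
#' @export
pair_meta <- function(pm) {
  parts <- strsplit(rownames(pm), "|", fixed = TRUE)
  data.frame(pair_id = rownames(pm),
             gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             one_fraction = rowMeans(pm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep pairs with an informative indicator frequency
#'
#' A pair whose indicator is (near-)constant 0 or 1 across samples carries no
#' ranking information, so it cannot stratify patients.  The validity band
#' keeps a pair iff `low < mean(indicator) < high`, strict on both sides;
#' the defaults implement "more than 20%" symmetrically (20% < frequency
#' < 80%).
#'
#' @param pm pair matrix from [build_pair_matrix()].
#' @param low,high open validity band bounds (defaults 0.2 and 0.8).
#' @param quiet suppress the retention message.
#' @return the filtered pair matrix (possibly 0 rows), order preserved.
#' @export
filter_valid_pairs <- function(pm, low = 0.2, high = 0.8, quiet = FALSE) {
  stopifnot(low < high)
  frac <- rowMeans(pm)
  keep <- frac > low & frac < high
  if (!quiet)
    message("filter_valid_pairs: kept ", sum(keep), " of ", nrow(pm),
            " pairs in (", low, ", ", high, ")")
  pm[keep, , drop = FALSE]
}
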