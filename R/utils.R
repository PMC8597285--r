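# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

is_constant <- function(x) {
  isTRUE(max(x) == min(x))
}

#' Min-max scale a curve to the unit interval
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return `(x - min(x)) / (max(x) - min(x))`.
#' @keywords internal
minmax_scale <- function(x) {
  if (!all(is.finite(x))) {
    stop("cannot min-max scale a curve with non-finite values")
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("cannot min-max scale a constant curve")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# shared size computation: sizes[n] = number of rows with rowSums >= n,
# n = 1..ncol. `rs` are precomputed row sums.
sizes_from_rowsums <- function(rs, n_cols) {
  counts <- tabulate(rs[rs > 0], nbins = n_cols)
  rev(cumsum(rev(counts)))
}

assert_gene_set <- function(genes, what = "gene set") {
  if (!is.character(genes) || length(genes) == 0L) {
    stop(sprintf("%s must be a non-empty character vector", what))
  }
  if (anyDuplicated(genes)) {
    stop(sprintf("%s contains duplicated symbols", what))
  }
  invisible(genes)
}
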