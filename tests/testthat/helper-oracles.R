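# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately use naive elementwise / enumeration code paths,
# never the package's vectorised implementations.

random_binary_matrix <- function(n_genes, n_models, p = 0.5) {
  m <- matrix(rbinom(n_genes * n_models, 1, p), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("m%02d", seq_len(n_models))))
  m
}

random_quantitative_matrix <- function(n_genes, n_models, sd = 1) {
  matrix(rnorm(n_genes * n_models, sd = sd), nrow = n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("m%02d", seq_len(n_models))))
}

write_matrix_csv <- function(m, path = tempfile(fileext = ".csv"),
                             gene_column = "gene") {
  header <- paste(c(gene_column, colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# elementwise loop oracle for binarization (strict <, NA -> 0)
oracle_binarize <- function(qm, threshold) {
  out <- matrix(0L, nrow(qm), ncol(qm), dimnames = dimnames(qm))
  for (i in seq_len(nrow(qm))) {
    for (j in seq_len(ncol(qm))) {
      v <- qm[i, j]
      if (!is.na(v) && v < threshold) out[i, j] <- 1L
    }
  }
  out
}

# per-model sort-based midrank oracle
oracle_ranks <- function(qm) {
  out <- qm * NA_real_
  for (j in seq_len(ncol(qm))) {
    x <- qm[, j]
    for (i in which(!is.na(x))) {
      out[i, j] <- sum(x < x[i], na.rm = TRUE) + (1 + sum(x == x[i], na.rm = TRUE)) / 2
    }
  }
  out
}

oracle_sizes <- function(bm) {
  vapply(seq_len(ncol(bm)), function(n) {
    sum(apply(bm, 1, sum) >= n)
  }, numeric(1))
}

oracle_intersection <- function(bm, n) {
  rownames(bm)[apply(bm, 1, sum) >= n]
}

oracle_recall <- function(bm, reference) {
  ref <- reference[reference %in% rownames(bm)]
  vapply(seq_len(ncol(bm)), function(n) {
    length(intersect(oracle_intersection(bm, n), ref)) / length(ref)
  }, numeric(1))
}

# exact expectation of |I_n| under independent uniform column shuffles,
# by enumeration over all 2^N subsets of columns (Poisson-binomial tail):
# any fixed row carries a 1 in column j with probability colsum_j / G.
oracle_expected_exact <- function(bm) {
  G <- nrow(bm)
  N <- ncol(bm)
  p <- apply(bm, 2, sum) / G
  prob_ge <- numeric(N)
  for (subset_bits in 0:(2^N - 1)) {
    in_set <- as.logical(bitwAnd(subset_bits, 2^(0:(N - 1))))
    pr <- prod(ifelse(in_set, p, 1 - p))
    k <- sum(in_set)
    if (k >= 1) prob_ge[1:k] <- prob_ge[1:k] + pr
  }
  G * prob_ge
}

# naive re-derivation of the full adaptive threshold selection, mirroring
# the documented rules (min-max scaling, 1e-9 tie tolerance toward larger n,
# constant recall -> most stringent threshold)
oracle_adam <- function(bm, reference, expected) {
  N <- ncol(bm)
  observed <- oracle_sizes(bm)
  recall <- oracle_recall(bm, reference)
  deviance <- log10((observed + 1) / (expected + 1))
  scale01 <- function(x) (x - min(x)) / (max(x) - min(x))
  const <- function(x) max(x) == min(x)
  if (const(recall)) {
    n_star <- N
  } else if (const(deviance)) {
    stop("degenerate")
  } else {
    gap <- abs(scale01(recall) - scale01(deviance))
    n_star <- max(which(gap <= min(gap) + 1e-9))
  }
  list(observed = observed, recall = recall, deviance = deviance,
       n_star = n_star, cfgs = oracle_intersection(bm, n_star))
}

oracle_dm_curve <- function(bm, positives, negatives, exclude = character()) {
  universe <- setdiff(rownames(bm), exclude)
  p_eff <- intersect(positives, universe)
  n_eff <- intersect(negatives, universe)
  do.call(rbind, lapply(seq_len(ncol(bm)), function(n) {
    s <- setdiff(oracle_intersection(bm, n), exclude)
    data.frame(n = n, size = length(s),
               tpr = length(intersect(s, p_eff)) / length(p_eff),
               fpr = length(intersect(s, n_eff)) / length(n_eff))
  }))
}

default_screens <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- corefitness::generate_screens(corefitness::synthetic_config(seed = 1))
    }
    cache
  }
})

truth_genes <- function(screens, lab) {
  screens$truth$gene[screens$truth$label == lab]
}
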