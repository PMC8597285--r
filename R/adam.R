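# The Adaptive Daisy Model (ADaM).
#
# The daisy model predicts core-fitness genes (CFGs) as the genes essential
# in at least n* of N screened cell lines; ADaM chooses n* adaptively as the
# largest threshold providing the trade-off between (i) recall of a reference
# set of prior known CFGs, which falls with n, and (ii) the log10 deviance of
# the fuzzy-intersection size |I_n| from its expectation under random
# permutations of the dependency matrix, which rises with n. Run per tissue
# and then again on the gene-by-tissue membership matrix, the same machinery
# yields pan-cancer CFGs (two-step procedure).

#' Fuzzy intersection sizes |I_n| for every n
#'
#' `I_n` is the set of genes dependent (call = 1) in at least `n` models, so
#' `sizes[n]` counts genes with row sum >= n. Sizes are non-increasing in n.
#'
#' @param bm Binary dependency matrix.
#' @return Integer vector of length `ncol(bm)`.
#' @export
fuzzy_intersection_sizes <- function(bm) {
  validate_binary_matrix(bm)
  sizes_from_rowsums(rowSums(bm), ncol(bm))
}

#' Fuzzy intersection I_n: genes dependent in at least n models
#'
#' @param bm Binary dependency matrix.
#' @param n Minimal number of dependent models, 1 <= n <= ncol(bm).
#' @return Character vector of gene symbols.
#' @export
fuzzy_intersection <- function(bm, n) {
  validate_binary_matrix(bm)
  if (length(n) != 1L || is.na(n) || n < 1 || n > ncol(bm) || n != as.integer(n)) {
    stop(sprintf("n must be an integer in [1, %d]", ncol(bm)))
  }
  rownames(bm)[rowSums(bm) >= n]
}

#' Recall (TPR) of a reference gene set across all thresholds n
#'
#' `TPR(n) = |I_n intersect R'| / |R'|`, with `R'` the reference restricted to
#' the genes screened in the matrix. Reference genes absent from the matrix
#' are dropped from the denominator (a message reports how many).
#'
#' @param bm Binary dependency matrix.
#' @param reference Character vector of prior known core-fitness genes
#'   (positive controls).
#' @return Numeric vector of length `ncol(bm)` with values in \[0, 1\].
#' @export
recall_curve <- function(bm, reference) {
  validate_binary_matrix(bm)
  assert_gene_set(reference, "reference")
  ref <- intersect(reference, rownames(bm))
  dropped <- length(reference) - length(ref)
  if (length(ref) == 0L) {
    stop("no reference gene is present in the dependency matrix")
  }
  if (dropped > 0) {
    message(sprintf("recall_curve: %d reference gene(s) not in the matrix were dropped", dropped))
  }
  rs <- rowSums(bm[ref, , drop = FALSE])
  vapply(seq_len(ncol(bm)), function(n) sum(rs >= n) / length(ref), numeric(1))
}

# Exact expected sizes under independent uniform within-column shuffles.
# Each column j contributes a dependency call to a fixed row with probability
# p_j = colsum_j / G, independently across columns after shuffling, so the
# row sum of any gene follows the same Poisson-binomial distribution. The
# tail probabilities are computed by convolution.
exact_expected_sizes <- function(bm) {
  G <- nrow(bm)
  N <- ncol(bm)
  p <- colSums(bm) / G
  pr <- c(1, numeric(N))  # pr[k+1] = P(row sum = k)
  for (j in seq_len(N)) {
    pr <- pr * (1 - p[j]) + c(0, pr[-(N + 1)]) * p[j]
  }
  tail_ge <- rev(cumsum(rev(pr)))  # tail_ge[k+1] = P(row sum >= k)
  G * tail_ge[-1]                  # n = 1..N
}

#' Expected fuzzy-intersection sizes under the permutation null
#'
#' The null model shuffles each column of the matrix independently, keeping
#' every cell line's number of fitness genes fixed, and averages |I_n| over
#' `n_perm` permutations. `null_model = "exact"` instead returns the exact
#' expectation over all such permutations (the row sum of any gene is then
#' Poisson-binomial with per-column probabilities `colSums(bm)/nrow(bm)`),
#' which is the `n_perm -> Inf` limit and is fully deterministic.
#'
#' @param bm Binary dependency matrix.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; required for the Monte-Carlo null.
#' @param null_model `"permutation"` (Monte-Carlo, default) or `"exact"`.
#' @return Numeric vector of expected sizes per n = 1..N.
#' @export
null_expected_sizes <- function(bm, n_perm = 1000, seed = NULL,
                                null_model = c("permutation", "exact")) {
  validate_binary_matrix(bm)
  null_model <- match.arg(null_model)
  if (null_model == "exact") {
    return(exact_expected_sizes(bm))
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(seed)) stop("seed is required for the permutation null")
  set.seed(seed)
  G <- nrow(bm)
  N <- ncol(bm)
  total <- numeric(N)
  for (p in seq_len(n_perm)) {
    rs <- numeric(G)
    for (j in seq_len(N)) {
      rs <- rs + bm[sample.int(G), j]
    }
    total <- total + sizes_from_rowsums(rs, N)
  }
  total / n_perm
}

#' Log10 deviance of observed set sizes from their null expectation
#'
#' `deviance[n] = log10((observed[n] + 1) / (expected[n] + 1))`. The add-one
#' guard keeps the curve finite when intersections are empty (expected sizes
#' near n = N are routinely < 1).
#'
#' @param observed_sizes,expected_sizes Equal-length numeric vectors.
#' @return Numeric deviance vector.
#' @export
deviance_curve <- function(observed_sizes, expected_sizes) {
  if (length(observed_sizes) != length(expected_sizes)) {
    stop("observed and expected size vectors must have equal length")
  }
  log10((observed_sizes + 1) / (expected_sizes + 1))
}

#' Select the optimal threshold n* from the recall/deviance trade-off
#'
#' Both curves are min-max scaled to \[0, 1\]; n* is the n minimising the
#' absolute gap between scaled recall and scaled deviance, i.e. the crossing
#' of the falling recall curve and the rising deviance curve. Ties (within a
#' 1e-9 numerical tolerance) are broken toward the largest n. A constant
#' curve gives no trade-off and is an error.
#'
#' @param recall Recall (TPR) per n.
#' @param deviance Log10 deviance per n.
#' @return Integer n*.
#' @export
select_threshold <- function(recall, deviance) {
  if (length(recall) != length(deviance) || length(recall) < 2L) {
    stop("recall and deviance must have equal length >= 2")
  }
  if (is_constant(recall) || is_constant(deviance)) {
    stop("degenerate trade-off: constant curve")
  }
  r <- minmax_scale(recall)
  d <- minmax_scale(deviance)
  gap <- abs(r - d)
  max(which(gap <= min(gap) + 1e-9))
}

#' Adaptive Daisy Model on one cohort of screens
#'
#' Composes the fuzzy-intersection, recall, permutation-null and deviance
#' curves and the trade-off threshold selection; the predicted core-fitness
#' genes are the fuzzy intersection at the selected n*.
#'
#' When the recall curve is constant (every threshold, including the most
#' stringent, retains the same fraction of the reference) recall imposes no
#' constraint on the trade-off and the most stringent threshold n* = N is
#' selected, with a message.
#'
#' @param bm Binary dependency matrix (genes x models).
#' @param reference Reference set of prior known core-fitness genes.
#' @param n_perm Permutations for the null (default 1000).
#' @param seed Integer seed (required for the Monte-Carlo null).
#' @param null_model `"permutation"` or `"exact"` (see
#'   [null_expected_sizes()]).
#' @return An object of class `adam_result`: list with `curves` (data.frame
#'   n, observed, expected, recall, deviance, recall_scaled, deviance_scaled),
#'   `n_star`, `cfgs`, `n_perm`, `seed`, `null_model`.
#' @export
adam <- function(bm, reference, n_perm = 1000, seed = NULL,
                 null_model = c("permutation", "exact")) {
  validate_binary_matrix(bm)
  null_model <- match.arg(null_model)
  N <- ncol(bm)
  observed <- fuzzy_intersection_sizes(bm)
  recall <- recall_curve(bm, reference)
  expected <- null_expected_sizes(bm, n_perm = n_perm, seed = seed,
                                  null_model = null_model)
  deviance <- deviance_curve(observed, expected)

  if (is_constant(recall)) {
    message(sprintf(
      "adam: recall curve is constant at %.3f; selecting the most stringent threshold n* = %d",
      recall[1], N))
    n_star <- N
    # a constant curve attains its maximum at every n
    recall_scaled <- rep(1, N)
    deviance_scaled <- if (is_constant(deviance)) rep(1, N) else minmax_scale(deviance)
  } else if (is_constant(deviance)) {
    stop("degenerate trade-off: constant deviance curve")
  } else {
    n_star <- select_threshold(recall, deviance)
    recall_scaled <- minmax_scale(recall)
    deviance_scaled <- minmax_scale(deviance)
  }

  curves <- data.frame(
    n = seq_len(N),
    observed = observed,
    expected = expected,
    recall = recall,
    deviance = deviance,
    recall_scaled = recall_scaled,
    deviance_scaled = deviance_scaled
  )
  res <- list(
    curves = curves,
    n_star = n_star,
    cfgs = fuzzy_intersection(bm, n_star),
    n_perm = if (null_model == "permutation") n_perm else NA_integer_,
    seed = seed,
    null_model = null_model
  )
  class(res) <- "adam_result"
  res
}

#' @export
print.adam_result <- function(x, ...) {
  cat(sprintf("Adaptive Daisy Model result: n* = %d of %d models, %d core-fitness genes\n",
              x$n_star, nrow(x$curves), length(x$cfgs)))
  cat(sprintf("null model: %s%s\n", x$null_model,
              if (x$null_model == "permutation")
                sprintf(" (%d permutations, seed %s)", x$n_perm, format(x$seed)) else ""))
  invisible(x)
}

#' Two-step pan-cancer Adaptive Daisy Model
#'
#' Step 1 runs [adam()] on every tissue-lineage/cancer-type with at least
#' `min_models_per_tissue` models in the matrix, yielding tissue-specific
#' core-fitness genes. Step 2 assembles the binary gene-by-tissue membership
#' matrix (rows: genes that are CFGs in at least one tissue; 1 = gene is a
#' CFG for that tissue) and applies the identical threshold-selection
#' machinery to it with the same reference set, yielding the minimum number
#' t* of tissues for which a gene must be a tissue CFG to be called a
#' pan-cancer CFG.
#'
#' @param x Binary dependency matrix, or quantitative matrix (binarized at
#'   `binarize_threshold` first).
#' @param annotation Cell-line annotation (`model_id`, `tissue`).
#' @param reference Reference core-fitness gene set.
#' @param binarize_threshold Scaled-fitness threshold used when `x` is
#'   quantitative (default -0.5).
#' @param min_models_per_tissue Minimal number of screened models for a
#'   tissue to enter step 1 (default 10); smaller tissues are skipped with a
#'   warning.
#' @param n_perm,seed,null_model Null-model parameters, as in [adam()]. Each
#'   tissue i uses `seed + i - 1`; step 2 uses `seed + T`.
#' @return An object of class `pan_adam_result`: list with `tissue_results`
#'   (named list of `adam_result`), `membership` (binary gene x tissue
#'   matrix), `step2` (the step-2 `adam_result` on the membership matrix),
#'   `t_star` and `pan_cfgs`.
#' @export
pan_cancer_adam <- function(x, annotation, reference,
                            binarize_threshold = -0.5,
                            min_models_per_tissue = 10,
                            n_perm = 1000, seed = NULL,
                            null_model = c("permutation", "exact")) {
  null_model <- match.arg(null_model)
  validate_model_annotation(annotation)
  if (!all(x == 0 | x == 1, na.rm = TRUE) || anyNA(x)) {
    message(sprintf("pan_cancer_adam: binarizing quantitative input at %.3g", binarize_threshold))
    x <- binarize(x, threshold = binarize_threshold)
  }
  validate_binary_matrix(x)
  if (null_model == "permutation" && is.null(seed)) {
    stop("seed is required for the permutation null")
  }

  ann <- annotation[annotation$model_id %in% colnames(x), , drop = FALSE]
  sizes <- table(ann$tissue)
  qualifying <- names(sizes)[sizes >= min_models_per_tissue]
  skipped <- setdiff(names(sizes), qualifying)
  if (length(skipped) > 0) {
    warning(sprintf("skipping %d tissue(s) with fewer than %d models: %s",
                    length(skipped), min_models_per_tissue,
                    paste(skipped, collapse = ", ")))
  }
  if (length(qualifying) < 2L) {
    stop("pan-cancer ADaM needs at least 2 tissues passing the size filter")
  }
  qualifying <- sort(qualifying)

  tissue_results <- vector("list", length(qualifying))
  names(tissue_results) <- qualifying
  for (i in seq_along(qualifying)) {
    bm_t <- subset_by_tissue(x, ann, qualifying[i])
    tissue_results[[i]] <- adam(
      bm_t, reference, n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + i - 1L,
      null_model = null_model
    )
  }

  cfg_union <- unique(unlist(lapply(tissue_results, `[[`, "cfgs")))
  if (length(cfg_union) == 0L) stop("no gene was predicted as a tissue CFG in step 1")
  genes <- rownames(x)[rownames(x) %in% cfg_union]  # preserve matrix order
  membership <- vapply(tissue_results,
                       function(r) as.integer(genes %in% r$cfgs),
                       integer(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, qualifying))

  step2 <- adam(membership, reference, n_perm = n_perm,
                seed = if (is.null(seed)) NULL else seed + length(qualifying),
                null_model = null_model)

  res <- list(
    tissue_results = tissue_results,
    membership = membership,
    step2 = step2,
    t_star = step2$n_star,
    pan_cfgs = step2$cfgs,
    seed = seed,
    n_perm = if (null_model == "permutation") n_perm else NA_integer_,
    null_model = null_model
  )
  class(res) <- "pan_adam_result"
  res
}

#' @export
print.pan_adam_result <- function(x, ...) {
  cat(sprintf("Pan-cancer ADaM: %d tissues, t* = %d, %d pan-cancer core-fitness genes\n",
              length(x$tissue_results), x$t_star, length(x$pan_cfgs)))
  invisible(x)
}
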