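# Benchmarking machinery: baseline daisy-model (DM) reference curves,
# classification rates against independent positive/negative control genes,
# matched-TPR false-positive-rate ratios, dependent-cell-line and fitness
# effect summaries, recall and Jaccard set comparisons.

#' True/false positive rates of a candidate gene set
#'
#' Rates are computed within a gene universe (typically the screened genes):
#' `tpr = |candidate ∩ P ∩ U| / |P ∩ U|` and
#' `fpr = |candidate ∩ Ng ∩ U| / |Ng ∩ U|`.
#'
#' @param candidate Predicted gene set.
#' @param positives,negatives Independent positive/negative control gene
#'   sets.
#' @param universe Gene universe.
#' @return Named list with `tpr` and `fpr`.
#' @export
classification_rates <- function(candidate, positives, negatives, universe) {
  p_eff <- intersect(positives, universe)
  n_eff <- intersect(negatives, universe)
  if (length(p_eff) == 0L) stop("no positive control is in the universe")
  if (length(n_eff) == 0L) stop("no negative control is in the universe")
  cand <- intersect(candidate, universe)
  list(
    tpr = length(intersect(cand, p_eff)) / length(p_eff),
    fpr = length(intersect(cand, n_eff)) / length(n_eff)
  )
}

#' Baseline daisy-model reference curve
#'
#' For every minimal number of dependent cell lines n, the baseline DM
#' predicts as core-fitness genes the fuzzy intersection I_n (optionally
#' minus a training-gene exclusion list), and its TPR/FPR against the
#' supplied controls are recorded. The universe is the set of screened genes
#' minus the exclusion list.
#'
#' @param bm Binary dependency matrix.
#' @param positives,negatives Control gene sets.
#' @param exclude Genes (e.g. training-set genes) removed from both the
#'   baseline sets and the universe (default none).
#' @return An object of class `dm_curve`: data.frame with columns `n`,
#'   `size`, `tpr`, `fpr`.
#' @export
dm_reference_curve <- function(bm, positives, negatives, exclude = character()) {
  validate_binary_matrix(bm)
  universe <- setdiff(rownames(bm), exclude)
  N <- ncol(bm)
  rows <- lapply(seq_len(N), function(n) {
    set_n <- setdiff(fuzzy_intersection(bm, n), exclude)
    rates <- classification_rates(set_n, positives, negatives, universe)
    data.frame(n = n, size = length(set_n), tpr = rates$tpr, fpr = rates$fpr)
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("dm_curve", "data.frame")
  curve
}

#' Baseline FPR of the daisy model at a matched TPR
#'
#' Returns the threshold `dm_n` (the largest n whose baseline TPR is at
#' least `tpr_observed`) and the baseline FPR at exactly `tpr_observed`,
#' linearly interpolated along the (TPR, FPR) staircase of the DM curve.
#' When several n share a TPR, the most stringent (largest n, lowest FPR) is
#' used. A TPR outside the curve's range would require extrapolation and is
#' an error reporting the attainable range.
#'
#' @param curve A `dm_curve` from [dm_reference_curve()].
#' @param tpr_observed Observed TPR of the set being benchmarked.
#' @return Named list with `baseline_fpr` and `dm_n`.
#' @export
baseline_fpr_at_tpr <- function(curve, tpr_observed) {
  if (!inherits(curve, "dm_curve")) stop("curve must be a dm_curve")
  tpr <- curve$tpr
  if (tpr_observed > max(tpr) + 1e-12 || tpr_observed < min(tpr) - 1e-12) {
    stop(sprintf(
      "observed TPR %.4f is outside the baseline range [%.4f, %.4f]: extrapolation required",
      tpr_observed, min(tpr), max(tpr)))
  }
  dm_n <- max(curve$n[tpr >= tpr_observed - 1e-12])
  # one point per distinct TPR, keeping the largest n (lowest FPR) at ties
  keep <- !duplicated(tpr, fromLast = TRUE)
  xs <- tpr[keep]
  ys <- curve$fpr[keep]
  o <- order(xs)
  baseline_fpr <- stats::approx(xs[o], ys[o], xout = tpr_observed,
                                rule = 1, ties = "ordered")$y
  list(baseline_fpr = baseline_fpr, dm_n = dm_n)
}

#' Median percentage of dependent cell lines for a gene set
#'
#' Per gene, the fraction of models with a dependency call; the median over
#' the set is reported as a percentage.
#'
#' @param bm Binary dependency matrix.
#' @param set Gene set (genes absent from the matrix are ignored).
#' @return Median percentage in \[0, 100\].
#' @export
dependent_fraction_summary <- function(bm, set) {
  validate_binary_matrix(bm)
  genes <- intersect(set, rownames(bm))
  if (length(genes) == 0L) stop("no gene of the set is in the matrix")
  100 * stats::median(rowMeans(bm[genes, , drop = FALSE]))
}

#' Grand median scaled fitness effect of a gene set
#'
#' Per gene, the median scaled fitness score across models (missing scores
#' ignored); the median over the set is returned.
#'
#' @param qm Quantitative dependency matrix.
#' @param set Gene set.
#' @return Grand median scaled fitness effect.
#' @export
fitness_effect_summary <- function(qm, set) {
  validate_quantitative_matrix(qm)
  genes <- intersect(set, rownames(qm))
  if (length(genes) == 0L) stop("no gene of the set is in the matrix")
  per_gene <- apply(qm[genes, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  stats::median(per_gene)
}

#' Recall of a target gene set by a candidate set
#'
#' @param candidate,target Gene sets; `target` must be non-empty.
#' @return `|candidate ∩ target| / |target|`.
#' @export
set_recall <- function(candidate, target) {
  target <- unique(target)
  if (length(target) == 0L) stop("target set is empty")
  length(intersect(candidate, target)) / length(target)
}

#' Pairwise Jaccard similarity of gene sets
#'
#' `J(a, b) = |a ∩ b| / |a ∪ b|`; comparing two empty sets is undefined and
#' raises an error.
#'
#' @param sets Named list of at least two gene sets.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) stop("need at least 2 gene sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  k <- length(sets)
  J <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      a <- unique(sets[[i]])
      b <- unique(sets[[j]])
      u <- length(union(a, b))
      if (u == 0L) stop(sprintf("Jaccard of '%s' and '%s' undefined: both sets empty",
                                names(sets)[i], names(sets)[j]))
      J[i, j] <- J[j, i] <- length(intersect(a, b)) / u
    }
  }
  J
}

#' Benchmark report for a collection of predicted gene sets
#'
#' Evaluates each set against independent controls and the baseline daisy
#' model: TPR, FPR, the baseline FPR at the matched TPR, their ratio (the
#' size-adjusted headline metric), the DM threshold attaining the TPR, and
#' the dependent-cell-line / fitness-effect summaries.
#'
#' @param sets Named list of predicted gene sets.
#' @param bm Binary dependency matrix (defines the universe and the DM).
#' @param positives,negatives Independent control gene sets.
#' @param qm Optional quantitative matrix for the fitness-effect summary.
#' @param exclude Training genes to exclude from baseline sets and universe.
#' @return Data.frame with one row per set: `set`, `size`, `tpr`, `fpr`,
#'   `baseline_fpr_at_tpr`, `fpr_ratio`, `dm_n_at_tpr`,
#'   `median_dependent_fraction`, `median_fitness_effect`.
#' @export
benchmark_sets <- function(sets, bm, positives, negatives, qm = NULL,
                           exclude = character()) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list of gene sets")
  }
  curve <- dm_reference_curve(bm, positives, negatives, exclude = exclude)
  universe <- setdiff(rownames(bm), exclude)
  rows <- lapply(names(sets), function(nm) {
    s <- setdiff(sets[[nm]], exclude)
    rates <- classification_rates(s, positives, negatives, universe)
    base <- baseline_fpr_at_tpr(curve, rates$tpr)
    data.frame(
      set = nm,
      size = length(intersect(s, universe)),
      tpr = rates$tpr,
      fpr = rates$fpr,
      baseline_fpr_at_tpr = base$baseline_fpr,
      fpr_ratio = if (base$baseline_fpr > 0) rates$fpr / base$baseline_fpr else NA_real_,
      dm_n_at_tpr = base$dm_n,
      median_dependent_fraction = dependent_fraction_summary(bm, s),
      median_fitness_effect = if (is.null(qm)) NA_real_ else fitness_effect_summary(qm, s),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
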