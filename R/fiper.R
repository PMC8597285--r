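# The Fitness Percentile (FiPer) method.
#
# FiPer classifies common-essential genes (CEGs) from a pooled, unsupervised
# analysis of quantitative dependency matrices. For each gene, cell lines are
# sorted by decreasing dependency on the gene, and the gene's fitness-rank
# within each line (1 = most essential gene of that line) is traced along
# that ordering: the fitness-rank versus dependency-percentile curve. Genes
# that are essential everywhere stay top-ranked even in their least dependent
# lines, giving a flat low curve. Four scores summarise the curve (Fixed,
# Average, Slope, AUC); a kernel-density estimate of the typically bimodal
# score distribution supplies the discriminative threshold.

FIPER_VARIANTS <- c("auc", "average", "slope", "fixed")

#' Per-model fitness ranks of all genes
#'
#' Within each model, genes are ranked by ascending scaled fitness score
#' (rank 1 = most negative = most essential), with midranks for ties.
#' Missing scores are excluded from that model's ranking and stay `NA`.
#'
#' @param qm Quantitative dependency matrix.
#' @return Numeric matrix of ranks, same dimensions and dimnames as `qm`.
#' @export
gene_ranks_per_model <- function(qm) {
  validate_quantitative_matrix(qm)
  n_ok <- colSums(!is.na(qm))
  if (any(n_ok < 2)) {
    stop(sprintf("model(s) with fewer than 2 non-missing scores: %s",
                 paste(colnames(qm)[n_ok < 2], collapse = ", ")))
  }
  apply(qm, 2, function(x) rank(x, ties.method = "average", na.last = "keep"))
}

# order of models for one gene: by ascending within-model fitness rank of
# the gene (most dependent first), ties broken by model identifier; models
# where the gene's score is missing are dropped. Ranking within each model
# before comparing across models makes the ordering - hence every FiPer
# curve and score - invariant to per-screen monotone rescalings, which is
# the property that lets screens with different score scales be pooled.
dependency_order <- function(gene_ranks, model_ids) {
  ok <- !is.na(gene_ranks)
  which(ok)[order(gene_ranks[ok], model_ids[ok])]
}

#' Fitness-rank versus dependency-percentile curve of one gene
#'
#' @param qm Quantitative dependency matrix.
#' @param gene Gene symbol present in `qm`.
#' @param ranks Optional precomputed output of [gene_ranks_per_model()] (to
#'   avoid recomputation when extracting many curves).
#' @return An object of class `fiper_curve`: list with `gene`,
#'   `ordered_models` (most dependent first), `ranks` (the gene's fitness
#'   rank in each of those models), `n_models`, `n_genes`.
#' @export
fiper_curve <- function(qm, gene, ranks = NULL) {
  validate_quantitative_matrix(qm)
  if (!gene %in% rownames(qm)) stop(sprintf("unknown gene '%s'", gene))
  if (is.null(ranks)) ranks <- gene_ranks_per_model(qm)
  idx <- dependency_order(ranks[gene, ], colnames(qm))
  if (length(idx) < 2L) stop(sprintf("gene '%s' has fewer than 2 non-missing scores", gene))
  structure(list(
    gene = gene,
    ordered_models = colnames(qm)[idx],
    ranks = unname(ranks[gene, idx]),
    n_models = length(idx),
    n_genes = nrow(qm)
  ), class = "fiper_curve")
}

#' FiPer score of one curve
#'
#' Variants, with `N = n_models`, `G = n_genes`, `p = ceiling(percentile*N)`
#' (1-based position of the highest boundary of the dependency percentile):
#' \describe{
#'   \item{fixed}{the fitness rank at position `p` (the gene's rank in the
#'     cell line at the 90th dependency percentile, by default).}
#'   \item{average}{mean of the ranks at positions `p..N` (all lines over the
#'     percentile).}
#'   \item{slope}{least-squares slope of the normalized curve, rank/G versus
#'     position/N.}
#'   \item{auc}{area under the normalized curve by the trapezoid rule,
#'     divided by the x-span so the score lies in (0, 1\] (a curve flat at
#'     rank r scores r/G).}
#' }
#'
#' @param curve A `fiper_curve`.
#' @param variant One of `"auc"`, `"average"`, `"slope"`, `"fixed"`.
#' @param percentile Dependency percentile in (0, 1); default 0.9.
#' @return A single numeric score (lower = more common-essential).
#' @export
fiper_score <- function(curve, variant = FIPER_VARIANTS, percentile = 0.9) {
  variant <- match.arg(variant)
  if (!inherits(curve, "fiper_curve")) stop("curve must be a fiper_curve")
  N <- curve$n_models
  G <- curve$n_genes
  r <- curve$ranks
  if (N < 2L) stop("FiPer scores need at least 2 models")
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0, 1)")
  p <- ceiling(percentile * N)
  switch(variant,
    fixed = r[p],
    average = mean(r[p:N]),
    slope = {
      x <- seq_len(N) / N
      y <- r / G
      sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    },
    auc = {
      x <- seq_len(N) / N
      y <- r / G
      sum(diff(x) * (y[-N] + y[-1]) / 2) / (x[N] - x[1])
    }
  )
}

#' Density-minimum threshold between the two main modes of a score
#' distribution
#'
#' Fits a Gaussian-kernel density (Silverman's rule-of-thumb bandwidth,
#' 512-point grid spanning the data extended by three bandwidths) to the
#' FiPer scores, locates the local maxima, and returns the grid point of
#' minimal density strictly between the two highest-density modes.
#'
#' @param scores Numeric vector of at least 50 finite scores with nonzero
#'   spread.
#' @return The threshold (a single numeric value, strictly inside the
#'   observed score range).
#' @export
density_minimum_threshold <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 50L) stop("need at least 50 finite scores")
  if (max(scores) == min(scores)) stop("scores have zero spread")
  d <- stats::density(scores, bw = "nrd0", n = 512, cut = 3)
  y <- d$y
  interior <- 2:(length(y) - 1L)
  is_max <- y[interior] > y[interior - 1L] & y[interior] >= y[interior + 1L]
  maxima <- interior[is_max]
  if (length(maxima) < 2L) stop("distribution not bimodal: fewer than two local density maxima")
  top2 <- maxima[order(y[maxima], decreasing = TRUE)][1:2]
  lo <- min(top2)
  hi <- max(top2)
  between <- (lo + 1L):(hi - 1L)
  d$x[between[which.min(y[between])]]
}

fiper_scores_all <- function(qm, variant, percentile, ranks) {
  G <- nrow(qm)
  model_ids <- colnames(qm)
  vapply(seq_len(G), function(g) {
    idx <- dependency_order(ranks[g, ], model_ids)
    if (length(idx) < 2L) {
      stop(sprintf("gene '%s' has fewer than 2 non-missing scores", rownames(qm)[g]))
    }
    curve <- structure(list(gene = rownames(qm)[g],
                            ordered_models = model_ids[idx],
                            ranks = unname(ranks[g, idx]),
                            n_models = length(idx),
                            n_genes = G), class = "fiper_curve")
    fiper_score(curve, variant, percentile)
  }, numeric(1))
}

#' Fitness Percentile classification of common-essential genes
#'
#' Scores every gene with the chosen FiPer variant, fits the kernel-density
#' classifier to the score distribution, and classifies as common-essential
#' the genes whose score is less than or equal to the density-minimum
#' threshold.
#'
#' @param qm Quantitative dependency matrix.
#' @param variant FiPer variant (default `"auc"`, the variant executed by
#'   default).
#' @param percentile Dependency percentile in (0, 1); default 0.9.
#' @return An object of class `fiper_result`: list with `variant`,
#'   `percentile`, `scores` (named numeric vector over all genes),
#'   `threshold` and `cegs`.
#' @export
fiper <- function(qm, variant = FIPER_VARIANTS, percentile = 0.9) {
  validate_quantitative_matrix(qm)
  variant <- match.arg(variant)
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0, 1)")
  ranks <- gene_ranks_per_model(qm)
  scores <- fiper_scores_all(qm, variant, percentile, ranks)
  names(scores) <- rownames(qm)
  threshold <- density_minimum_threshold(scores)
  res <- list(
    variant = variant,
    percentile = percentile,
    scores = scores,
    threshold = threshold,
    cegs = names(scores)[scores <= threshold]
  )
  class(res) <- "fiper_result"
  res
}

#' @export
print.fiper_result <- function(x, ...) {
  cat(sprintf("FiPer (%s, percentile %.2f): %d of %d genes common-essential (threshold %.4g)\n",
              x$variant, x$percentile, length(x$cegs), length(x$scores), x$threshold))
  invisible(x)
}

#' Consensus common-essential set across the Fixed, Slope and AUC variants
#'
#' Intersection of the CEG sets of the three variants, all computed on the
#' same gene universe.
#'
#' @param fixed,slope,auc `fiper_result` objects for the respective variants.
#' @return Character vector of consensus common-essential genes.
#' @export
fiper_consensus <- function(fixed, slope, auc) {
  results <- list(fixed = fixed, slope = slope, auc = auc)
  for (v in names(results)) {
    r <- results[[v]]
    if (!inherits(r, "fiper_result") || r$variant != v) {
      stop(sprintf("argument '%s' must be a fiper_result of variant '%s'", v, v))
    }
  }
  universes <- lapply(results, function(r) names(r$scores))
  if (!all(vapply(universes[-1], identical, logical(1), y = universes[[1]]))) {
    stop("FiPer results were not computed on the same gene universe")
  }
  consensus <- intersect(intersect(fixed$cegs, slope$cegs), auc$cegs)
  if (length(consensus) == 0L) {
    warning("FiPer consensus set is empty")
  }
  consensus
}

#' Compare a gene's common-essentiality tendency against controls
#'
#' Extracts the FiPer curves of a gene of interest, a positive control (a
#' well-established common-essential gene; RPL8 by default) and a negative
#' control (a context-specific dependency; MAP2K1 by default), together with
#' their FiPer scores under the chosen variant. The returned object has a
#' `plot()` method drawing the three curves.
#'
#' @param qm Quantitative dependency matrix.
#' @param gene Gene of interest.
#' @param positive_control,negative_control Control gene symbols; both must
#'   be present in the matrix (override the defaults otherwise).
#' @param variant,percentile Scoring parameters, as in [fiper()].
#' @return An object of class `cfness_comparison`: list of `fiper_curve`s
#'   (`gene`, `positive`, `negative`) plus the matching named `scores`.
#' @export
vis_cfness <- function(qm, gene, positive_control = "RPL8",
                       negative_control = "MAP2K1",
                       variant = FIPER_VARIANTS, percentile = 0.9) {
  validate_quantitative_matrix(qm)
  variant <- match.arg(variant)
  wanted <- c(gene, positive_control, negative_control)
  missing <- setdiff(wanted, rownames(qm))
  if (length(missing) > 0) {
    stop(sprintf("gene(s) absent from the matrix: %s", paste(missing, collapse = ", ")))
  }
  ranks <- gene_ranks_per_model(qm)
  curves <- lapply(wanted, function(g) fiper_curve(qm, g, ranks = ranks))
  names(curves) <- c("gene", "positive", "negative")
  scores <- vapply(curves, fiper_score, numeric(1),
                   variant = variant, percentile = percentile)
  structure(list(curves = curves, scores = scores, variant = variant,
                 percentile = percentile), class = "cfness_comparison")
}

#' @export
plot.cfness_comparison <- function(x, ...) {
  cols <- c(gene = "black", positive = "#2166AC", negative = "#B2182B")
  ylim <- c(1, max(vapply(x$curves, function(c) max(c$ranks), numeric(1))))
  plot(NULL, xlim = c(0, 1), ylim = ylim,
       xlab = "dependency percentile of cell lines",
       ylab = "fitness rank of gene in cell line", ...)
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    graphics::lines(seq_len(cv$n_models) / cv$n_models, cv$ranks,
                    col = cols[nm], lwd = 2)
  }
  graphics::abline(v = x$percentile, lty = 2, col = "grey40")
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (%s score %.3g)",
                                    vapply(x$curves, `[[`, "", "gene"),
                                    x$variant, x$scores))
  invisible(x)
}
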