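# Synthetic pooled-screen generator with planted structure.
#
# Emulates a quantitative gene-by-model dependency matrix over several
# tissues with four planted gene classes: core-fitness genes (strong
# negative effect in every line), weak core genes (moderate negative effect
# everywhere; these create the low-score shoulder that makes the FiPer score
# distribution bimodal), context-specific essentials (strong effect only in
# the models of one tissue) and never-essential genes. Scores are Gaussian
# around the class mean, on the conventional scale where reference
# essentials centre near -1 and non-essentials near 0.

#' Configuration for the synthetic screen generator
#'
#' Defaults are the package's reference recovery scenario: 2000 genes, 100
#' models over 5 tissues, 200 core, 100 weak-core and 50 context-specific
#' genes per tissue, Gaussian noise sd 0.15.
#'
#' @param n_genes,n_models,n_tissues Dimensions; models are split across
#'   tissues as evenly as possible.
#' @param n_core,n_weak_core,n_context_per_tissue Planted class sizes.
#' @param mu_core,mu_weak,mu_null Class mean scaled fitness effects
#'   (defaults -1, -0.6, 0).
#' @param sigma Noise standard deviation (> 0; default 0.15).
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_models = 100, n_tissues = 5,
                             n_core = 200, n_weak_core = 100,
                             n_context_per_tissue = 50,
                             mu_core = -1.0, mu_weak = -0.6, mu_null = 0.0,
                             sigma = 0.15, seed = 1) {
  cfg <- list(n_genes = n_genes, n_models = n_models, n_tissues = n_tissues,
              n_core = n_core, n_weak_core = n_weak_core,
              n_context_per_tissue = n_context_per_tissue,
              mu_core = mu_core, mu_weak = mu_weak, mu_null = mu_null,
              sigma = sigma, seed = seed)
  if (sigma <= 0) stop("sigma must be > 0")
  if (n_tissues < 1 || n_models < n_tissues) stop("need n_models >= n_tissues >= 1")
  planted <- n_core + n_weak_core + n_tissues * n_context_per_tissue
  if (planted > n_genes) {
    stop(sprintf("planted genes (%d) exceed n_genes (%d)", planted, n_genes))
  }
  if (is.null(seed) || !is.finite(seed)) stop("seed is required")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate synthetic screens with planted truth labels
#'
#' Every cell is drawn as `Normal(mu(gene, model), sigma)` where the mean is
#' the planted class effect: `mu_core` everywhere for core genes, `mu_weak`
#' everywhere for weak cores, `mu_core` in the matching tissue (and
#' `mu_null` elsewhere) for context-specific genes, `mu_null` for
#' never-essential genes. Fully reproducible given the configured seed.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_screens`: list with `matrix`
#'   (quantitative dependency matrix), `annotation` (model_id, tissue,
#'   cancer_type), `truth` (data.frame gene, label in core / weak_core /
#'   context / never, tissue for context genes) and `config`.
#' @export
generate_screens <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) stop("config must be a synthetic_config")
  G <- config$n_genes
  N <- config$n_models
  T <- config$n_tissues

  genes <- sprintf("gene_%04d", seq_len(G))
  models <- sprintf("model_%03d", seq_len(N))
  tissues <- sprintf("tissue_%02d", seq_len(T))
  model_tissue <- rep(tissues, length.out = N)  # as even a split as possible

  label <- rep("never", G)
  gene_tissue <- rep(NA_character_, G)
  i <- 0L
  if (config$n_core > 0) {
    label[i + seq_len(config$n_core)] <- "core"
    i <- i + config$n_core
  }
  if (config$n_weak_core > 0) {
    label[i + seq_len(config$n_weak_core)] <- "weak_core"
    i <- i + config$n_weak_core
  }
  if (config$n_context_per_tissue > 0) {
    for (t in seq_len(T)) {
      idx <- i + seq_len(config$n_context_per_tissue)
      label[idx] <- "context"
      gene_tissue[idx] <- tissues[t]
      i <- i + config$n_context_per_tissue
    }
  }

  mu <- matrix(config$mu_null, nrow = G, ncol = N)
  mu[label == "core", ] <- config$mu_core
  mu[label == "weak_core", ] <- config$mu_weak
  for (t in seq_len(T)) {
    ctx <- which(label == "context" & gene_tissue == tissues[t])
    mu[ctx, model_tissue == tissues[t]] <- config$mu_core
  }

  set.seed(config$seed)
  scores <- mu + matrix(stats::rnorm(G * N, 0, config$sigma), nrow = G)
  dimnames(scores) <- list(genes, models)

  structure(list(
    matrix = scores,
    annotation = data.frame(model_id = models, tissue = model_tissue,
                            cancer_type = model_tissue,
                            stringsAsFactors = FALSE),
    truth = data.frame(gene = genes, label = label, tissue = gene_tissue,
                       stringsAsFactors = FALSE),
    config = config
  ), class = "synthetic_screens")
}

#' @export
print.synthetic_screens <- function(x, ...) {
  cat(sprintf("synthetic screens: %d genes x %d models, %d tissues (seed %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$config$n_tissues,
              format(x$config$seed)))
  print(table(x$truth$label))
  invisible(x)
}

#' Recovery metrics of a predicted gene set against planted truth
#'
#' @param predicted Predicted gene set.
#' @param truth Truth data.frame from [generate_screens()] (columns `gene`,
#'   `label`).
#' @return Named list: `recall` (named vector, per planted label),
#'   `contamination` (fraction of the predicted set labelled never) and
#'   `n_predicted`.
#' @export
recovery_metrics <- function(predicted, truth) {
  if (!all(c("gene", "label") %in% colnames(truth))) {
    stop("truth must have columns 'gene' and 'label'")
  }
  unknown <- setdiff(predicted, truth$gene)
  if (length(unknown) > 0) {
    stop(sprintf("%d predicted gene(s) absent from the truth labels", length(unknown)))
  }
  labels <- sort(unique(truth$label))
  recall <- vapply(labels, function(l) {
    members <- truth$gene[truth$label == l]
    length(intersect(predicted, members)) / length(members)
  }, numeric(1))
  never <- truth$gene[truth$label == "never"]
  contamination <- if (length(predicted) == 0L) 0 else
    length(intersect(predicted, never)) / length(predicted)
  list(recall = recall, contamination = contamination,
       n_predicted = length(predicted))
}
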