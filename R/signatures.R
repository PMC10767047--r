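## ---------------------------------------------------------------------------
## Binned-control module scoring of gene signatures (DAM, DAA, ...).
## ---------------------------------------------------------------------------

#' Per-spot module score with binned control genes
#'
#' All genes are binned into `n_bins` equal-frequency bins by average
#' log-normalized expression; for each signature gene, `n_ctrl` control genes
#' are sampled from its bin (with replacement when the bin holds fewer than
#' `n_ctrl` genes). The score of a spot is the mean expression of the
#' signature genes minus the mean expression of the drawn control genes
#' (with multiplicity). Deterministic under a fixed seed; signature genes
#' absent from the matrix are dropped with a warning.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param gene_set character vector of signature gene symbols
#' @param n_bins number of expression bins (>= 2)
#' @param n_ctrl control genes sampled per signature gene
#' @param seed RNG seed for the control draw
#' @return numeric per-spot score vector with attributes `genes_used`,
#'   `control_genes`, and the parameters
#' @export
module_score <- function(normalized, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 0) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  genes <- rownames(normalized)
  missing <- setdiff(gene_set, genes)
  sig <- intersect(gene_set, genes)
  if (!length(sig))
    stopf("no signature genes present in matrix; missing: %s",
          paste(missing, collapse = ", "))
  if (length(missing))
    warnf("signature gene(s) absent from matrix, dropped: %s",
          paste(missing, collapse = ", "))
  avg <- Matrix::rowMeans(normalized)
  n_bins_eff <- min(n_bins, length(avg))
  bin <- floor((rank(avg, ties.method = "first") - 1) * n_bins_eff /
                 length(avg)) + 1L
  names(bin) <- genes
  set.seed(seed)
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- genes[bin == bin[g]]
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }), use.names = FALSE)
  score <- as.numeric(Matrix::colMeans(normalized[sig, , drop = FALSE]) -
                        Matrix::colMeans(normalized[ctrl, , drop = FALSE]))
  attr(score, "genes_used") <- sig
  attr(score, "control_genes") <- ctrl
  attr(score, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  score
}

#' Compare signature scores across clusters and groups
#'
#' Summarizes a per-spot score by (cluster, genotype, age) and, for each
#' cluster x age stratum holding both genotypes, runs a two-sided Wilcoxon
#' test of AD vs WT scores.
#'
#' @param scores per-spot numeric score
#' @param clusters,genotype,age per-spot labels
#' @return list with `summary` (mean/median/n per cluster x genotype x age)
#'   and `tests` (per cluster x age: Wilcoxon p and AD - WT mean difference)
#' @export
score_by_group <- function(scores, clusters, genotype, age) {
  if (inherits(clusters, "cluster_result")) clusters <- clusters$labels
  key <- data.frame(cluster = clusters, genotype = genotype, age = age)
  summary <- stats::aggregate(scores, key,
                              FUN = function(v) c(mean = mean(v),
                                                  median = stats::median(v),
                                                  n = length(v)))
  summary <- cbind(summary[1:3], as.data.frame(summary$x))
  tests <- list()
  for (cl in sort(unique(clusters))) for (ag in sort(unique(age))) {
    sa <- scores[clusters == cl & age == ag & genotype == "AD"]
    sw <- scores[clusters == cl & age == ag & genotype == "WT"]
    if (!length(sa) || !length(sw)) next
    p <- suppressWarnings(stats::wilcox.test(sa, sw)$p.value)
    tests[[length(tests) + 1]] <- data.frame(
      cluster = cl, age = ag, mean_diff = mean(sa) - mean(sw),
      p = ifelse(is.na(p), 1, p))
  }
  list(summary = summary,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(cluster = character(), age = character(),
                    mean_diff = numeric(), p = numeric()))
}

#' Export scores with spatial coordinates
#'
#' One record per spot, in spot order, with scores bit-equal to the input —
#' no resampling or smoothing.
#'
#' @param scores per-spot numeric score
#' @param positions positions data.frame (from a `spot_dataset`)
#' @return data.frame with `barcode`, `x_px`, `y_px`, `score`
#' @export
map_scores_spatial <- function(scores, positions) {
  if (length(scores) != nrow(positions))
    stopf("scores (%d) and positions (%d) lengths differ",
          length(scores), nrow(positions))
  data.frame(barcode = positions$barcode, x_px = positions$x_px,
             y_px = positions$y_px, score = as.numeric(scores))
}
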