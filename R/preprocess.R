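## ---------------------------------------------------------------------------
## Normalization, HVG selection, scaling with covariate regression, PCA,
## SNN-Louvain clustering, cluster markers, replicate QC.
## ---------------------------------------------------------------------------

#' Log-normalize spot counts
#'
#' Per-spot depth normalization followed by a natural-log transform:
#' `entry = ln(1 + count / spot_total * scale_factor)`. Zeros stay zero, so
#' sparsity is preserved.
#'
#' @param x gene x spot count matrix (sparse or dense) or a `spot_dataset`
#' @param scale_factor library-size scale factor (default 10,000)
#' @return sparse gene x spot matrix of log-normalized expression
#' @export
log_normalize <- function(x, scale_factor = 10000) {
  counts <- if (inherits(x, "spot_dataset")) x$counts else as_csparse(x)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stopf("spot(s) with zero total counts: %s",
          paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  out <- counts
  per_col <- rep.int(totals, diff(out@p))
  out@x <- log1p(out@x / per_col * scale_factor)
  out
}

#' Select highly variable genes (vst flavour)
#'
#' Fits a variance~mean trend on the log10 scale (loess), standardizes raw
#' counts by the trend-predicted sd, clips standardized values at
#' `sqrt(n_spots)`, and ranks genes by the variance of the clipped
#' standardized counts, in descending order. Deterministic.
#'
#' @param counts gene x spot raw count matrix (sparse or dense)
#' @param n number of genes to return (>= 1)
#' @param loess_span span of the trend fit
#' @return character vector of gene names, best first; carries the full
#'   ranking table as attribute `"table"`
#' @export
select_hvg_vst <- function(counts, n = 2000, loess_span = 0.3) {
  if (n < 1) stopf("n must be >= 1")
  counts <- as_csparse(counts)
  n_s <- ncol(counts)
  m <- Matrix::rowSums(counts) / n_s
  ex2 <- Matrix::rowSums(counts^2) / n_s
  v <- (ex2 - m^2) * n_s / (n_s - 1)
  fit_ok <- v > 0 & m > 0
  sd_pred <- rep(NA_real_, length(m))
  if (sum(fit_ok) >= 10) {
    lf <- stats::loess(log10(v[fit_ok]) ~ log10(m[fit_ok]), span = loess_span,
                       degree = 2)
    sd_pred[fit_ok] <- sqrt(10^stats::fitted(lf))
  } else {
    sd_pred[fit_ok] <- sqrt(v[fit_ok])
  }
  clip <- sqrt(n_s)
  std_var <- numeric(length(m))
  ## sparse-aware variance of clipped standardized counts
  gene_of <- rep.int(seq_len(nrow(counts)),
                     tabulate(counts@i + 1L, nbins = nrow(counts)))
  cs <- counts
  idx <- order(cs@i)  # group nonzeros by gene
  xi <- cs@x[idx]; gi <- cs@i[idx] + 1L
  z <- (xi - m[gi]) / sd_pred[gi]
  z <- pmin(z, clip)
  z0 <- pmin((0 - m) / sd_pred, clip)
  k_nz <- tabulate(gi, nbins = nrow(counts))
  sum_z <- rowsum(z, gi, reorder = FALSE)
  sum_z2 <- rowsum(z * z, gi, reorder = FALSE)
  full_sum <- full_sum2 <- numeric(nrow(counts))
  full_sum[sort(unique(gi))] <- sum_z
  full_sum2[sort(unique(gi))] <- sum_z2
  full_sum <- full_sum + (n_s - k_nz) * z0
  full_sum2 <- full_sum2 + (n_s - k_nz) * z0^2
  ok <- fit_ok
  std_var[ok] <- (full_sum2[ok] - full_sum[ok]^2 / n_s) / (n_s - 1)
  std_var[!ok] <- 0
  ord <- order(-std_var)
  tab <- data.frame(gene = rownames(counts)[ord], mean = m[ord],
                    variance = v[ord], std_variance = std_var[ord])
  n_eff <- min(n, sum(std_var > 0))
  if (n_eff < n)
    warnf("only %d gene(s) with nonzero standardized variance (requested %d)",
          n_eff, n)
  out <- tab$gene[seq_len(max(n_eff, 1L))]
  attr(out, "table") <- tab
  out
}

#' Scale expression with covariate regression
#'
#' Per gene: residualize log-normalized expression on the covariates by least
#' squares, then z-score using the population sd (ddof 0) and clip at
#' `+/- clip`. Constant covariates are dropped with a warning; genes left with
#' zero variance become all-zero rows (flagged in attribute
#' `"zero_variance"`).
#'
#' @param normalized gene x spot matrix of log-normalized expression
#' @param covariates data.frame / matrix of per-spot covariates (e.g. total
#'   counts, mitochondrial fraction), or NULL for plain z-scoring
#' @param clip absolute clip value for the scaled matrix
#' @return dense gene x spot scaled matrix
#' @export
scale_and_regress <- function(normalized, covariates = NULL, clip = 10) {
  x <- as.matrix(normalized)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (any(!is.finite(cv))) stopf("covariates must be finite")
    const <- apply(cv, 2, function(z) stats::sd(z) == 0)
    if (any(const)) {
      warnf("dropping constant covariate(s): %s",
            paste(colnames(cv)[const] %||% which(const), collapse = ", "))
      cv <- cv[, !const, drop = FALSE]
    }
    if (ncol(cv) > 0) {
      C <- cbind(1, scale(cv))
      beta <- x %*% C %*% solve(crossprod(C))
      x <- x - beta %*% t(C)
    }
  }
  x <- x - rowMeans(x)
  s <- row_sd_pop(x)
  zero_var <- s < 1e-12
  s[zero_var] <- 1
  x <- x / s
  x[zero_var, ] <- 0
  x <- pmin(pmax(x, -clip), clip)
  attr(x, "zero_variance") <- rownames(x)[zero_var] %||% which(zero_var)
  x
}

#' Principal-component embedding of spots
#'
#' Eigendecomposition of the gene-gene covariance of the (already centred and
#' scaled) matrix. Components are ordered by decreasing explained variance and
#' signs are fixed so the gene with the largest absolute loading on each
#' component has a positive loading.
#'
#' @param scaled gene x spot scaled matrix (e.g. from [scale_and_regress()]),
#'   optionally pre-subset to HVGs
#' @param hvg optional gene subset to use
#' @param n_pcs number of components (<= min(n genes, n spots))
#' @return list with `scores` (spots x n_pcs, columns `PC1`...), `loadings`
#'   (genes x n_pcs, pairwise orthonormal), `sdev`, `var_explained`
#' @export
embed_pca <- function(scaled, hvg = NULL, n_pcs = 30) {
  x <- as.matrix(scaled)
  if (!is.null(hvg)) x <- x[intersect(hvg, rownames(x)), , drop = FALSE]
  if (n_pcs > min(dim(x)))
    stopf("n_pcs (%d) exceeds min(n genes, n spots) = %d", n_pcs, min(dim(x)))
  x <- x - rowMeans(x)
  cv <- tcrossprod(x) / (ncol(x) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  k <- n_pcs
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  ## sign convention: largest-|loading| gene positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- crossprod(x, V)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(V) <- rownames(x)
  colnames(V) <- colnames(scores)
  ev <- pmax(eig$values, 0)
  list(scores = scores, loadings = V, sdev = sqrt(ev[seq_len(k)]),
       var_explained = ev[seq_len(k)] / sum(ev))
}

## exact k-nearest-neighbour indices by blockwise Euclidean distance
knn_indices <- function(emb, k, block = 1024L) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(start + block - 1, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(emb[rows, , drop = FALSE], emb)
    d2[cbind(seq_along(rows), rows)] <- Inf  # exclude self
    for (j in seq_along(rows)) {
      dj <- d2[j, ]
      th <- sort.int(dj, partial = k)[k]
      cand <- which(dj <= th)
      idx[rows[j], ] <- cand[order(dj[cand])][seq_len(k)]
    }
  }
  idx
}

#' Graph-based clustering of spots
#'
#' Builds an exact k-nearest-neighbour graph in the embedding (Euclidean),
#' re-weights edges by shared-nearest-neighbour Jaccard similarity
#' (`shared / (2k - shared)`, pruned below `prune`), and partitions with
#' Louvain community detection at the given resolution. Labels are integers
#' from 0, relabelled by decreasing cluster size; the run is deterministic
#' under a fixed seed.
#'
#' @param embedding spots x dims matrix (e.g. `embed_pca(...)$scores`)
#' @param k_neighbors neighbours per spot (< n spots)
#' @param resolution Louvain resolution parameter
#' @param seed RNG seed
#' @param prune SNN weights below this Jaccard value are dropped
#' @return list of class `cluster_result` with `labels` (0-based integers),
#'   `sizes`, `resolution`, `k_neighbors`, `seed`
#' @export
cluster_spots <- function(embedding, k_neighbors = 20, resolution = 0.2,
                          seed = 0, prune = 1 / 15) {
  emb <- as.matrix(embedding)
  n <- nrow(emb)
  if (k_neighbors >= n) stopf("k_neighbors (%d) must be < n spots (%d)",
                              k_neighbors, n)
  idx <- knn_indices(emb, k_neighbors)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                              j = as.integer(idx), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  snn <- shared
  snn@x <- snn@x / (2 * k_neighbors - snn@x)
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  structure(list(labels = labels, sizes = as.integer(sizes),
                 resolution = resolution, k_neighbors = k_neighbors,
                 seed = seed),
            class = "cluster_result")
}

#' End-to-end clustering pipeline
#'
#' Convenience wrapper chaining [log_normalize()], [select_hvg_vst()],
#' [scale_and_regress()] (per-spot total counts, and mitochondrial fraction
#' when `mt-` genes exist, as covariates), [embed_pca()] and
#' [cluster_spots()]. Optionally centres each sample's scaled matrix
#' (a simple multi-sample alignment step).
#'
#' @param dataset a `spot_dataset`
#' @param n_hvg,n_pcs,k_neighbors,resolution,seed pipeline parameters
#' @param center_samples centre scaled expression per sample if TRUE
#' @return list with `normalized`, `hvg`, `embedding`, `clusters`
#'   (a `cluster_result`)
#' @export
cluster_pipeline <- function(dataset, n_hvg = 2000, n_pcs = 30,
                             k_neighbors = 20, resolution = 0.2, seed = 0,
                             center_samples = FALSE) {
  normalized <- log_normalize(dataset)
  hvg <- select_hvg_vst(dataset$counts, n = min(n_hvg, nrow(dataset$counts)))
  covs <- data.frame(total_counts = Matrix::colSums(dataset$counts))
  mito <- grep("^mt-", rownames(dataset$counts), value = TRUE)
  if (length(mito))
    covs$mito_fraction <- Matrix::colSums(dataset$counts[mito, , drop = FALSE]) /
      covs$total_counts
  scaled <- suppressWarnings(
    scale_and_regress(normalized[hvg, , drop = FALSE], covs))
  if (center_samples)
    for (sm in unique(dataset$meta$sample)) {
      j <- dataset$meta$sample == sm
      scaled[, j] <- scaled[, j] - rowMeans(scaled[, j, drop = FALSE])
    }
  pca <- embed_pca(scaled, n_pcs = min(n_pcs, min(dim(scaled))))
  clusters <- cluster_spots(pca$scores, k_neighbors = k_neighbors,
                            resolution = resolution, seed = seed)
  list(normalized = normalized, hvg = hvg, embedding = pca,
       clusters = clusters)
}

## shared-rank Wilcoxon: per-gene ranks computed once, rank-sum z-test with
## tie correction for each one-vs-rest contrast (exact wilcox.test for small n)
wilcox_p_from_ranks <- function(r, in_group, tie_term) {
  n <- length(r)
  n1 <- sum(in_group); n2 <- n - n1
  W <- sum(r[in_group]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-max(z, 0))
}

#' Cluster marker genes (one-vs-rest Wilcoxon)
#'
#' For each cluster, compares every gene's log-normalized expression in the
#' cluster against all other spots with a two-sided Wilcoxon rank-sum test
#' (exact when total n <= 50 and there are no ties, normal approximation with
#' tie correction otherwise), computes the log fold change (see
#' [log_fold_change()]), adjusts p-values by Benjamini-Hochberg within each
#' cluster, and retains genes with `p_adj < alpha` and `logFC > min_logfc`.
#' Clusters with fewer than 3 spots are skipped with a warning.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param clusters per-spot cluster labels (vector or `cluster_result`)
#' @param min_logfc,alpha retention thresholds
#' @return data.frame with columns `cluster`, `gene`, `logFC`, `p`, `p_adj`,
#'   `pct_in`, `pct_out`, sorted by cluster then p
#' @export
find_all_markers <- function(normalized, clusters, min_logfc = 0.3,
                             alpha = 0.05) {
  if (inherits(clusters, "cluster_result")) clusters <- clusters$labels
  labs <- sort(unique(clusters))
  if (length(labs) < 2) stopf("need >= 2 clusters")
  x <- as.matrix(normalized)
  n <- ncol(x)
  small <- n <= 50
  ranks <- NULL; tie_terms <- NULL
  if (!small) {
    ranks <- t(apply(x, 1, rank))
    tie_terms <- apply(x, 1, function(v) {
      t <- table(v); sum(t^3 - t)
    })
  }
  out <- list()
  for (cl in labs) {
    in_cl <- clusters == cl
    if (sum(in_cl) < 3) {
      warnf("cluster %s has < 3 spots; skipped", cl)
      next
    }
    lfc <- log_fold_change(x, in_cl, !in_cl)
    if (small) {
      p <- apply(x, 1, function(v)
        suppressWarnings(stats::wilcox.test(v[in_cl], v[!in_cl])$p.value))
    } else {
      p <- vapply(seq_len(nrow(x)), function(g)
        wilcox_p_from_ranks(ranks[g, ], in_cl, tie_terms[g]), numeric(1))
    }
    p[is.na(p)] <- 1
    p_adj <- stats::p.adjust(p, method = "BH")
    keep <- p_adj < alpha & lfc > min_logfc
    if (any(keep))
      out[[as.character(cl)]] <- data.frame(
        cluster = cl, gene = rownames(x)[keep], logFC = lfc[keep],
        p = p[keep], p_adj = p_adj[keep],
        pct_in = rowMeans(x[keep, in_cl, drop = FALSE] > 0),
        pct_out = rowMeans(x[keep, !in_cl, drop = FALSE] > 0))
  }
  if (!length(out))
    return(data.frame(cluster = integer(), gene = character(),
                      logFC = numeric(), p = numeric(), p_adj = numeric(),
                      pct_in = numeric(), pct_out = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$p), ]
}

#' Replicate reproducibility (Pearson r of per-gene averages)
#'
#' For each sample pair, averages log-normalized expression over each
#' sample's spots and reports the Pearson correlation of the two per-gene
#' average vectors.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param sample_labels per-spot sample labels
#' @param pairs list of length-2 character vectors of sample names
#' @return data.frame with `sample_a`, `sample_b`, `pearson_r`
#' @export
replicate_correlation <- function(normalized, sample_labels, pairs) {
  if (nrow(normalized) < 2) stopf("need >= 2 genes")
  avg <- vapply(unique(sample_labels), function(sm)
    Matrix::rowMeans(normalized[, sample_labels == sm, drop = FALSE]),
    numeric(nrow(normalized)))
  res <- do.call(rbind, lapply(pairs, function(pr)
    data.frame(sample_a = pr[1], sample_b = pr[2],
               pearson_r = stats::cor(avg[, pr[1]], avg[, pr[2]]))))
  rownames(res) <- NULL
  res
}

#' Annotate clusters by majority ground-truth region
#'
#' @param clusters per-spot cluster labels (vector or `cluster_result`)
#' @param regions per-spot region labels
#' @return named character vector: cluster label -> majority region
#' @export
majority_region <- function(clusters, regions) {
  if (inherits(clusters, "cluster_result")) clusters <- clusters$labels
  tab <- table(clusters, regions)
  stats::setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
}
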