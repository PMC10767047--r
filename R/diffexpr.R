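## ---------------------------------------------------------------------------
## Two-part (hurdle) differential expression, fold-change and threshold rules,
## cross-cluster intersections, pseudobulk + label-shuffle robustness.
## ---------------------------------------------------------------------------

#' Log fold change between two spot groups
#'
#' `logFC = ln( (mean(expm1(xA)) + 1) / (mean(expm1(xB)) + 1) )` on
#' log-normalized expression: means are taken on the de-logged scale with a
#' +1 pseudocount, matching the scale on which the standard marker thresholds
#' are stated. Antisymmetric under swapping the groups.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param maskA,maskB non-empty logical (or index) spot selections
#' @return numeric vector, one value per gene
#' @export
log_fold_change <- function(normalized, maskA, maskB) {
  a <- normalized[, maskA, drop = FALSE]
  b <- normalized[, maskB, drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0) stopf("both masks must be non-empty")
  ma <- if (inherits(a, "sparseMatrix")) Matrix::rowMeans(expm1_sparse(a))
        else rowMeans(expm1(as.matrix(a)))
  mb <- if (inherits(b, "sparseMatrix")) Matrix::rowMeans(expm1_sparse(b))
        else rowMeans(expm1(as.matrix(b)))
  unname(log((ma + 1) / (mb + 1)))
}

## expm1 on the nonzero entries of a sparse matrix
expm1_sparse <- function(x) {
  x <- as_csparse(x)
  x@x <- expm1(x@x)
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Input p-values must lie in
#' [0, 1]; NaN is an error.
#'
#' @param p_values numeric vector of raw p-values
#' @return adjusted p-values in [0, 1], order-preserving after the monotone
#'   enforcement step
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values))) stopf("NaN/NA p-values")
  if (any(p_values < 0 | p_values > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

## deviance of a logistic fit (clamped probabilities guard separation)
logistic_deviance <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  mu <- pmin(pmax(fit$fitted.values, 1e-6), 1 - 1e-6)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

## Gaussian residual sum of squares of a least-squares fit
lm_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-part hurdle differential expression test
#'
#' Per gene, fits a logistic model on detection (expression > 0) and a
#' Gaussian model on the positive log-normalized values, each with a group
#' term plus optional per-spot covariates (by default the detection rate, the
#' fraction of genes detected per spot). The combined likelihood-ratio
#' statistic is the sum of the two component LR statistics, referred to a
#' chi-square with 2 degrees of freedom. Logistic separation is handled by
#' clamping fitted probabilities to [1e-6, 1 - 1e-6]; a component whose group
#' term is inestimable (e.g. too few positive spots) contributes LR = 0.
#' Genes that are all-zero in both groups get p = 1 and logFC = 0.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param group per-spot two-level factor (or coercible); the first level is
#'   the reference, logFC is level2 vs level1... see `contrast`
#' @param covariates `"detection_rate"` (default), a per-spot numeric
#'   matrix/data.frame, or NULL for no covariates
#' @param contrast length-2 character: (groupA, groupB); logFC is A vs B
#' @return data.frame with `gene`, `logFC`, `p_raw`, `p_adj` (BH), `pct_A`,
#'   `pct_B`
#' @export
hurdle_test <- function(normalized, group, covariates = "detection_rate",
                        contrast = NULL) {
  x <- as_csparse(normalized)
  group <- as.character(group)
  levs <- unique(group)
  if (length(levs) != 2) stopf("group must have exactly 2 levels")
  if (is.null(contrast)) contrast <- rev(sort(levs))
  gA <- group == contrast[1]; gB <- group == contrast[2]
  if (sum(gA) < 3 || sum(gB) < 3) stopf("both groups need >= 3 spots")
  n <- ncol(x)
  if (identical(covariates, "detection_rate")) {
    covs <- matrix(Matrix::colMeans(x > 0), ncol = 1,
                   dimnames = list(NULL, "detection_rate"))
  } else if (is.null(covariates)) {
    covs <- NULL
  } else {
    covs <- as.matrix(covariates)
  }
  if (!is.null(covs)) {
    keep <- apply(covs, 2, function(z) stats::sd(z) > 0)
    covs <- covs[, keep, drop = FALSE]
    if (!ncol(covs)) covs <- NULL
  }
  Xnull <- cbind(`(Intercept)` = rep(1, n), covs)
  Xfull <- cbind(Xnull, group = as.numeric(gA))
  xm <- as.matrix(x)
  genes <- rownames(x) %||% as.character(seq_len(nrow(x)))
  p_raw <- numeric(nrow(x)); lfc <- numeric(nrow(x))
  pct_A <- numeric(nrow(x)); pct_B <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    v <- xm[g, ]
    det <- as.numeric(v > 0)
    pct_A[g] <- mean(det[gA]); pct_B[g] <- mean(det[gB])
    if (sum(det) == 0) { p_raw[g] <- 1; lfc[g] <- 0; next }
    lfc[g] <- log((mean(expm1(v[gA])) + 1) / (mean(expm1(v[gB])) + 1))
    lr_d <- 0
    if (stats::var(det) > 0)
      lr_d <- max(logistic_deviance(Xnull, det) -
                    logistic_deviance(Xfull, det), 0)
    lr_c <- 0
    pos <- det == 1
    if (sum(pos & gA) >= 2 && sum(pos & gB) >= 2 && stats::var(v[pos]) > 0) {
      rss0 <- lm_rss(Xnull[pos, , drop = FALSE], v[pos])
      rss1 <- lm_rss(Xfull[pos, , drop = FALSE], v[pos])
      if (rss1 > 0 && rss0 >= rss1)
        lr_c <- sum(pos) * log(rss0 / rss1)
    }
    p_raw[g] <- stats::pchisq(lr_d + lr_c, df = 2, lower.tail = FALSE)
  }
  data.frame(gene = genes, logFC = lfc, p_raw = p_raw,
             p_adj = bh_adjust(p_raw), pct_A = pct_A, pct_B = pct_B)
}

#' Per-cluster AD-vs-WT differential expression
#'
#' Runs [hurdle_test()] within each cluster for the genotype contrast and
#' applies the retention thresholds (FDR-adjusted p < `alpha` and
#' |logFC| > `min_logfc`, sign giving the direction). Clusters missing a
#' genotype (or with < 3 spots in one) are skipped with a warning.
#'
#' @param normalized gene x spot log-normalized matrix
#' @param clusters per-spot cluster labels
#' @param genotype per-spot genotype labels
#' @param contrast length-2 character (A, B); `up` genes are higher in A
#' @param alpha adjusted-p threshold
#' @param min_logfc log-fold-change threshold (0.25 for AD-vs-WT contrasts;
#'   use 0.3 for cluster-vs-cluster marker style contrasts)
#' @param covariates passed to [hurdle_test()]
#' @return named list per cluster: `result` (full table), `up`, `down`
#'   (character gene vectors)
#' @export
deg_per_cluster <- function(normalized, clusters, genotype,
                            contrast = c("AD", "WT"), alpha = 0.05,
                            min_logfc = 0.25, covariates = "detection_rate") {
  if (inherits(clusters, "cluster_result")) clusters <- clusters$labels
  out <- list()
  for (cl in sort(unique(clusters))) {
    sel <- clusters == cl
    gt <- genotype[sel]
    if (sum(gt == contrast[1]) < 3 || sum(gt == contrast[2]) < 3) {
      warnf("cluster %s lacks >= 3 spots of both genotypes; skipped", cl)
      next
    }
    res <- hurdle_test(normalized[, sel, drop = FALSE], gt,
                       covariates = covariates, contrast = contrast)
    out[[as.character(cl)]] <- list(
      result = res,
      up = sort(res$gene[res$p_adj < alpha & res$logFC > min_logfc]),
      down = sort(res$gene[res$p_adj < alpha & res$logFC < -min_logfc]))
  }
  out
}

#' Genes upregulated in every list
#'
#' @param up_sets list of >= 2 character vectors (or 1, returned as-is)
#' @return sorted character vector: the exact intersection
#' @export
common_upregulated <- function(up_sets) {
  stopifnot(length(up_sets) >= 1)
  sort(Reduce(intersect, up_sets))
}

#' Pseudobulk contrast with label shuffling
#'
#' Sums raw counts over the spots of each sample within a cluster, contrasts
#' the two groups of samples by a two-sided Student t-test on log2 CPM
#' (descriptive given the small per-group n), and repeats the DEG count under
#' random shuffles of the sample group labels (shuffles equal to the true
#' labelling or its complement are excluded).
#'
#' @param counts gene x spot raw count matrix
#' @param spot_mask logical spot selection (the cluster)
#' @param sample per-spot sample labels
#' @param sample_group named character: sample -> group (2 groups, >= 2
#'   samples each)
#' @param n_shuffles number of shuffled labelings (>= 1)
#' @param alpha raw-p threshold for the descriptive DEG count
#' @param seed RNG seed
#' @return list with `true_count`, `shuffled_counts` (length `n_shuffles`),
#'   and `pseudobulk` (the gene x sample sum matrix)
#' @export
pseudobulk_and_shuffle <- function(counts, spot_mask, sample, sample_group,
                                   n_shuffles = 10, alpha = 0.05, seed = 1) {
  if (n_shuffles < 1) stopf("n_shuffles must be >= 1")
  counts <- as_csparse(counts)
  sel <- which(spot_mask)
  sm <- sample[sel]
  samples <- names(sample_group)
  ind <- Matrix::sparseMatrix(i = seq_along(sel),
                              j = match(sm, samples),
                              x = 1, dims = c(length(sel), length(samples)))
  pb <- as.matrix(counts[, sel, drop = FALSE] %*% ind)
  colnames(pb) <- samples
  grp <- factor(unname(sample_group))
  if (nlevels(grp) != 2 || any(table(grp) < 2))
    stopf("need 2 groups with >= 2 samples each")
  logcpm <- log2(t(t(pb) / colSums(pb)) * 1e6 + 1)
  count_degs <- function(is_a) {
    a <- logcpm[, is_a, drop = FALSE]; b <- logcpm[, !is_a, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2); vb <- rowSums((b - mb)^2)
    sp2 <- (va + vb) / (na + nb - 2)
    tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tt), df = na + nb - 2)
    sum(p < alpha, na.rm = TRUE)
  }
  true_a <- grp == levels(grp)[1]
  true_count <- count_degs(true_a)
  set.seed(seed)
  shuffled <- integer(n_shuffles)
  n_a <- sum(true_a)
  for (i in seq_len(n_shuffles)) {
    repeat {
      is_a <- seq_along(samples) %in% sample(seq_along(samples), n_a)
      if (!identical(is_a, as.logical(true_a)) &&
          !identical(is_a, !as.logical(true_a))) break
    }
    shuffled[i] <- count_degs(is_a)
  }
  list(true_count = true_count, shuffled_counts = shuffled, pseudobulk = pb)
}
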