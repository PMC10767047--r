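test_that("log_normalize matches the stated formula", {
  cnt <- matrix(c(1, 99, 100, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- log_normalize(cnt, scale_factor = 10000)
  expect_equal(norm["g1", "s1"], log(101), tolerance = 1e-12)   # ln(1 + 1/100*1e4)
  expect_equal(norm["g2", "s2"], 0)
  expect_equal(norm["g1", "s2"], log(10001), tolerance = 1e-12) # count = total
})

test_that("log_normalize errors on zero-total spots and is depth-invariant", {
  cnt <- matrix(c(1, 0, 0, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(log_normalize(cnt), "s2")
  ## doubling a spot's counts leaves its normalized profile unchanged
  cnt <- matrix(rpois(40, 5) + 1, 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  doubled <- cnt; doubled[, 1] <- doubled[, 1] * 2
  expect_equal(as.matrix(log_normalize(cnt))[, 1],
               as.matrix(log_normalize(doubled))[, 1], tolerance = 1e-12)
})

test_that("vst HVG ranking matches a brute-force standardized variance oracle", {
  set.seed(7)
  n_genes <- 50; n_spots <- 300
  mu <- exp(rnorm(n_genes, 1, 0.5))
  cnt <- matrix(rnbinom(n_genes * n_spots, mu = mu, size = 5), n_genes, n_spots,
                dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:n_spots)))
  ## one gene with ~10x the variance of its mean-matched peers
  cnt[25, ] <- rnbinom(n_spots, mu = mu[25], size = 0.2)
  hvg <- select_hvg_vst(cnt, n = 10)
  expect_identical(hvg[1], "g25")
  ## oracle: recompute standardized variances directly from the table trend
  tab <- attr(hvg, "table")
  expect_identical(tab$gene[1], "g25")
  expect_true(all(diff(tab$std_variance) <= 1e-12))
})

test_that("constant genes rank last and n = n_genes returns everything", {
  set.seed(1)
  cnt <- matrix(rpois(30 * 100, 5), 30, 100,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:100)))
  cnt[30, ] <- 7  # constant
  hvg <- suppressWarnings(select_hvg_vst(cnt, n = 30))
  expect_false("g30" %in% hvg)  # zero standardized variance genes drop off
  tab <- attr(hvg, "table")
  expect_equal(tab$std_variance[tab$gene == "g30"], 0)
  expect_error(select_hvg_vst(cnt, n = 0), ">= 1")
})

test_that("scale_and_regress z-scores with population sd and clips", {
  x <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  z <- scale_and_regress(x)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)

  ## a gene exactly linear in a covariate is flagged zero-variance
  cov <- data.frame(tot = c(1, 2, 3, 4))
  x2 <- rbind(g1 = c(2, 4, 6, 8), g2 = c(5, 1, 4, 2))
  colnames(x2) <- paste0("s", 1:4)
  z2 <- scale_and_regress(x2, cov)
  expect_identical(attr(z2, "zero_variance"), "g1")
  expect_true(all(z2["g1", ] == 0))

  ## clipping at +/- 10: a 20-sd outlier is clipped to 10
  x3 <- matrix(c(rep(0, 399), 400), 1, 400,
               dimnames = list("g1", paste0("s", 1:400)))
  expect_equal(max(scale_and_regress(x3)), 10)
})

test_that("constant covariates are dropped with a warning", {
  x <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  expect_warning(scale_and_regress(x, data.frame(flat = rep(1, 10))), "constant")
})

test_that("embed_pca satisfies variance ordering, orthonormality and sign rules", {
  set.seed(5)
  ## rank-1 structure
  u <- rnorm(20); v <- rnorm(50)
  x <- outer(u, v)
  rownames(x) <- paste0("g", 1:20)
  pca <- embed_pca(x, n_pcs = 3)
  expect_gt(pca$var_explained[1], 0.999)
  ## loadings pairwise orthonormal
  g <- crossprod(pca$loadings)
  expect_lt(max(abs(g - diag(3))), 1e-8)
  expect_true(all(diff(pca$sdev) <= 1e-12))
  expect_error(embed_pca(x, n_pcs = 21), "n_pcs")
})

test_that("PCA separates two blobs along PC1 with a deterministic sign", {
  ## oracle: eigendecomposition of the 2x2 covariance of a two-blob layout
  set.seed(2)
  n <- 100
  shift <- c(rep(0, n / 2), rep(10, n / 2))
  x <- rbind(g1 = shift + rnorm(n, 0, 0.1), g2 = -shift + rnorm(n, 0, 0.1))
  colnames(x) <- paste0("s", 1:n)
  xc <- x - rowMeans(x)
  ev <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
  pca <- embed_pca(x, n_pcs = 2)
  expect_gt(abs(cor(pca$scores[, 1], as.numeric(crossprod(xc, ev$vectors[, 1])))),
            0.999999)
  ## blob separation
  expect_gt(min(abs(pca$scores[1:(n / 2), 1] - pca$scores[(n / 2 + 1):n, 1])), 1)
  ## sign convention: the largest-|loading| gene has a positive loading
  i <- which.max(abs(pca$loadings[, 1]))
  expect_gt(pca$loadings[i, 1], 0)
})

test_that("cluster_spots recovers well-separated blobs and degenerate cases", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(100 * 2, 0, 1), ncol = 2),
               matrix(rnorm(100 * 2, 10, 1), ncol = 2))
  truth <- rep(0:1, each = 100)
  cl <- cluster_spots(emb, k_neighbors = 15, resolution = 0.2, seed = 1)
  expect_identical(length(cl$sizes), 2L)
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1.0)
  ## labels are contiguous integers from 0, size-ranked
  expect_identical(sort(unique(cl$labels)), 0:1)
  ## determinism under seed
  cl2 <- cluster_spots(emb, k_neighbors = 15, resolution = 0.2, seed = 1)
  expect_identical(cl$labels, cl2$labels)

  ## all spots identical -> a single cluster
  flat <- matrix(1, 50, 2)
  cl3 <- cluster_spots(flat, k_neighbors = 5, seed = 1)
  expect_identical(length(cl3$sizes), 1L)

  expect_error(cluster_spots(emb, k_neighbors = 200), "k_neighbors")
})

test_that("cluster count is non-decreasing in resolution on a fixed embedding", {
  set.seed(11)
  centers <- matrix(rnorm(8 * 3, sd = 6), 8, 3)
  emb <- centers[rep(1:8, each = 40), ] + matrix(rnorm(320 * 3), 320, 3)
  ks <- vapply(c(0.05, 0.2, 1.0), function(res)
    length(cluster_spots(emb, k_neighbors = 15, resolution = res, seed = 2)$sizes),
    numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("find_all_markers uses the exact Wilcoxon for small n and finds spikes", {
  ## exact two-sided Wilcoxon p for {1,2,3} vs {4,5,6} is 0.1 by enumeration
  expect_equal(oracle_wilcox(c(1, 2, 3), c(4, 5, 6)), 0.1)
  x <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = c(6, 5, 4, 3, 2, 1))
  colnames(x) <- paste0("s", 1:6)
  cl <- rep(0:1, each = 3)
  mk <- find_all_markers(x, cl, min_logfc = 0, alpha = 0.2)
  expect_equal(mk$p[mk$cluster == 1 & mk$gene == "g1"], 0.1, tolerance = 1e-12)

  ## a spiked gene lands in its cluster's marker table
  set.seed(8)
  n <- 200
  xs <- matrix(rnbinom(50 * n, mu = 4, size = 5), 50, n,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:n)))
  cl <- rep(0:1, each = n / 2)
  xs["g7", cl == 1] <- rnbinom(n / 2, mu = 16, size = 5)
  norm <- log_normalize(xs)
  mk <- find_all_markers(as.matrix(norm), cl)
  expect_true("g7" %in% mk$gene[mk$cluster == 1])
  ## markers never include zero-variance genes
  flat_genes <- rownames(xs)[apply(as.matrix(norm), 1, var) == 0]
  expect_false(any(mk$gene %in% flat_genes))
})

test_that("null data yield no markers and tiny clusters are skipped", {
  set.seed(9)
  x <- matrix(rnorm(40 * 60, 5), 40, 60,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:60)))
  cl <- rep(0:1, each = 30)
  mk <- find_all_markers(x, cl, min_logfc = 0.3, alpha = 0.05)
  expect_lte(nrow(mk), 2)
  expect_warning(find_all_markers(x, c(rep(0, 58), 1, 1)), "skipped")
})

test_that("replicate correlation behaves at its fixed points", {
  x <- rbind(g1 = c(1, 1, 3, 3), g2 = c(2, 2, 2, 2), g3 = c(3, 3, 1, 1))
  colnames(x) <- paste0("s", 1:4)
  sm <- c("A", "A", "B", "B")
  r <- replicate_correlation(x, sm, list(c("A", "A"), c("A", "B")))
  expect_equal(r$pearson_r[1], 1.0)
  expect_equal(r$pearson_r[2], -1.0)  # per-gene averages {1,2,3} vs {3,2,1}
  expect_error(replicate_correlation(x[1, , drop = FALSE], sm,
                                     list(c("A", "B"))), "genes")
})

test_that("two seeded replicates of one program correlate above 0.95", {
  ds <- simulate_study(seed = 21, n_rows = 12, n_cols = 10, n_genes = 300,
                       n_region_markers = 12,
                       samples = c("WT_3M_r1", "WT_3M_r2"))
  norm <- log_normalize(ds)
  r <- replicate_correlation(norm, ds$meta$sample,
                             list(c("WT_3M_r1", "WT_3M_r2")))
  expect_gt(r$pearson_r, 0.95)
})

test_that("majority_region annotates clusters by their dominant truth label", {
  cl <- c(0, 0, 0, 1, 1)
  rg <- c("WM", "WM", "cortex_outer", "thalamus", "thalamus")
  expect_identical(majority_region(cl, rg),
                   c(`0` = "WM", `1` = "thalamus"))
})
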