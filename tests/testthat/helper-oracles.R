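## Independent oracles used to freeze expected values; each is a brute-force
## or closed-form computation kept separate from the implementation path.

## Benjamini-Hochberg step-up, written directly from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## two-sided Wilcoxon rank-sum p by enumeration of all group assignments
oracle_wilcox <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(v), n1)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

## hypergeometric upper tail P(X >= k) by exhaustive draw enumeration (N <= 12)
oracle_hyper_exhaustive <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% in_set) >= k))
}

## hypergeometric upper tail by direct binomial-coefficient tail sum
oracle_hyper_tailsum <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## Otsu threshold by brute-force maximization of between-class variance
oracle_otsu <- function(img, levels = 256) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(img, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; th <- 0
  for (t in seq_len(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; th <- breaks[t + 1] }
  }
  th
}

## rank-based AUC of `score` separating positives from negatives
helper_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## tiny spot_dataset fixture built in code
helper_tiny_dataset <- function(counts = NULL, n_genes = 4, n_spots = 3) {
  if (is.null(counts)) {
    counts <- matrix(seq_len(n_genes * n_spots), n_genes, n_spots)
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  pos <- data.frame(barcode = colnames(counts), in_tissue = 1L,
                    array_row = seq_len(ncol(counts)) - 1L, array_col = 0L,
                    y_px = (seq_len(ncol(counts)) - 1) * 8.66, x_px = 1.0)
  meta <- data.frame(barcode = colnames(counts), sample = "sample1",
                     genotype = "WT", age = "3M")
  spot_dataset(counts, pos, meta)
}
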