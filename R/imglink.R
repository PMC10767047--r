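## ---------------------------------------------------------------------------
## Patch extraction at spots, training-free image features, latent PCA, and
## gene <-> latent association.
## ---------------------------------------------------------------------------

#' Extract square image patches centred at spots
#'
#' For a spot at (x, y) and even `size` the patch covers rows
#' [y - size/2, y + size/2) and columns [x - size/2, x + size/2) (half-open
#' convention; centres rounded to the nearest pixel). With `border = "pad"`
#' out-of-image pixels are zero-filled; with `border = "error"` an
#' out-of-bounds spot is an error naming the spot.
#'
#' @param image image matrix
#' @param spot_xy n x 2 matrix of spot (x, y) pixel coordinates (0-based)
#' @param size patch side length in pixels (even)
#' @param border `"pad"` or `"error"`
#' @return n x size x size array of patches
#' @export
extract_patches <- function(image, spot_xy, size = 32,
                            border = c("pad", "error")) {
  border <- match.arg(border)
  if (is.null(dim(spot_xy))) spot_xy <- matrix(spot_xy, 1, 2)
  half <- size %/% 2
  h <- nrow(image); w <- ncol(image)
  n <- nrow(spot_xy)
  out <- array(0, dim = c(n, size, size))
  cx <- round(spot_xy[, 1]); cy <- round(spot_xy[, 2])
  for (i in seq_len(n)) {
    rows <- (cy[i] - half):(cy[i] + half - 1)  # 0-based
    cols <- (cx[i] - half):(cx[i] + half - 1)
    if (border == "error" &&
        (rows[1] < 0 || cols[1] < 0 || rows[size] > h - 1 || cols[size] > w - 1))
      stopf("spot %d at (%g, %g) is out of image bounds", i,
            spot_xy[i, 1], spot_xy[i, 2])
    rok <- rows >= 0 & rows <= h - 1
    cok <- cols >= 0 & cols <= w - 1
    out[i, which(rok), which(cok)] <- image[rows[rok] + 1, cols[cok] + 1]
  }
  out
}

## gradient magnitude via central differences with replicated edges
grad_mag <- function(p) {
  s <- ncol(p)
  gx <- (p[, c(2:s, s)] - p[, c(1, 1:(s - 1))]) / 2
  gy <- (p[c(2:s, s), ] - p[c(1, 1:(s - 1)), ]) / 2
  sqrt(gx^2 + gy^2)
}

#' Training-free patch feature bank
#'
#' Per patch: mean, sd, 10/50/90% quantiles, mean and sd of the
#' gradient-magnitude image (central differences, replicated edges), and the
#' mean Gaussian-smoothed response at sigma in {1, 2, 4} — a fixed
#' 10-dimensional descriptor. The extractor is pluggable: pass a function
#' `patch -> named numeric vector` to use another feature bank (e.g. an
#' external CNN embedding computed offline).
#'
#' @param patches n x s x s array from [extract_patches()]
#' @param extractor `"bank"` or a function of one patch matrix
#' @return n x n_features matrix (deterministic; NaN pixels are an error)
#' @export
patch_features <- function(patches, extractor = "bank") {
  if (!length(patches)) stopf("need >= 1 patch")
  if (any(is.na(patches))) stopf("NaN pixels in patches")
  fun <- if (is.function(extractor)) extractor else function(p) {
    gm <- grad_mag(p)
    feats <- c(mean = mean(p), sd = stats::sd(p),
               q10 = unname(stats::quantile(p, 0.10)),
               q50 = unname(stats::quantile(p, 0.50)),
               q90 = unname(stats::quantile(p, 0.90)),
               grad_mean = mean(gm), grad_sd = stats::sd(gm))
    for (s in c(1, 2, 4))
      feats[paste0("blur", s, "_mean")] <- mean(EBImage::gblur(p, sigma = s))
    feats
  }
  out <- t(apply(patches, 1, fun))
  if (nrow(out) != dim(patches)[1]) out <- t(out)
  out
}

#' Latent principal components of patch features
#'
#' Features are z-scored (zero-variance features dropped with a warning) and
#' decomposed by PCA; component j is named `ImageLatent_j`, components are
#' ordered by explained variance, and the sign of `ImageLatent_1` is fixed so
#' it correlates positively with mean patch intensity.
#'
#' @param features n x p feature matrix from [patch_features()]
#' @param n_components number of components to keep
#' @return list with `scores` (spots x components), `loadings`, `sdev`
#' @export
latent_pca <- function(features, n_components = min(dim(features))) {
  f <- as.matrix(features)
  if (nrow(f) < 2 || ncol(f) < 1) stopf("need >= 2 spots and >= 1 feature")
  sds <- apply(f, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping zero-variance feature(s): %s",
          paste(colnames(f)[sds == 0] %||% which(sds == 0), collapse = ", "))
    f <- f[, sds > 0, drop = FALSE]
  }
  if (ncol(f) < 1) stopf("no features with variance")
  mean_int <- if ("mean" %in% colnames(features)) features[, "mean"]
              else rowMeans(features)
  z <- scale(f)
  k <- min(n_components, ncol(z), nrow(z) - 1)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  if (stats::cor(scores[, 1], mean_int) < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  colnames(scores) <- colnames(loadings) <- paste0("ImageLatent_", seq_len(k))
  list(scores = scores, loadings = loadings, sdev = pc$sdev[seq_len(k)])
}

#' Associate genes with an image latent component
#'
#' Per gene, the simple linear-regression slope of log-normalized expression
#' on the z-scored latent component; genes are ranked by coefficient in
#' descending order and the top `top_k` form the selected set. A constant
#' gene gets coefficient 0.
#'
#' @param normalized gene x spot log-normalized matrix (spots aligned with
#'   the latent)
#' @param latent per-spot latent values (e.g. `ImageLatent_1`)
#' @param top_k size of the selected gene set
#' @return data.frame `gene`, `coef`, `rank` with attribute `"top"` (the
#'   selected gene vector, best first)
#' @export
associate_genes <- function(normalized, latent, top_k = 100) {
  latent <- as.numeric(latent)
  if (length(latent) != ncol(normalized))
    stopf("latent (%d) not aligned to spots (%d)", length(latent),
          ncol(normalized))
  lz <- (latent - mean(latent)) / stats::sd(latent)
  n <- length(lz)
  ## slope of x on z-scored latent = sum(x * lz_centred) / (n - 1)
  coefs <- as.numeric(normalized %*% lz) / (n - 1) -
    as.numeric(Matrix::rowMeans(normalized)) * sum(lz) / (n - 1)
  rk <- rank(-coefs, ties.method = "first")
  res <- data.frame(gene = rownames(normalized), coef = coefs, rank = rk)
  top <- res$gene[order(res$rank)][seq_len(min(top_k, nrow(res)))]
  attr(res, "top") <- top
  res
}
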