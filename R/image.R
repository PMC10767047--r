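## ---------------------------------------------------------------------------
## 2-D coordinate transforms, image warping, and intensity-based registration.
## Coordinates are 0-based pixels, x rightwards (columns), y downwards (rows).
## ---------------------------------------------------------------------------

#' Rigid / affine coordinate transforms and chains
#'
#' Transforms map (x, y) points from one frame to another. A rigid transform
#' rotates by `theta` degrees about `center` then translates by (tx, ty); an
#' affine transform applies `p -> A (p - center) + center + t`. A chain
#' applies its members in order. All of these compose and invert in closed
#' form; `apply_transform(invert_transform(tf), apply_transform(tf, p))`
#' recovers `p` to machine precision.
#'
#' @param theta rotation angle, degrees (counter-clockwise in the x-right /
#'   y-down frame)
#' @param tx,ty translation, pixels
#' @param center 2-vector rotation centre
#' @param A 2x2 linear part
#' @param t 2-vector translation
#' @param ... transforms to chain, applied first to last
#' @return a `transform` (or `transform_chain`) object
#' @export
tf_rigid <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  r <- theta * pi / 180
  A <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  structure(list(type = "rigid", A = A,
                 b = c(tx, ty) + center - A %*% center),
            class = "transform")
}

#' @rdname tf_rigid
#' @export
tf_affine <- function(A, t = c(0, 0), center = c(0, 0)) {
  A <- matrix(A, 2, 2)
  structure(list(type = "affine", A = A, b = t + center - A %*% center),
            class = "transform")
}

#' @rdname tf_rigid
#' @export
tf_translation <- function(tx, ty) tf_rigid(0, tx, ty)

#' @rdname tf_rigid
#' @export
tf_chain <- function(...) {
  tfs <- list(...)
  if (length(tfs) == 1 && is.list(tfs[[1]]) && !inherits(tfs[[1]], "transform"))
    tfs <- tfs[[1]]
  structure(tfs, class = "transform_chain")
}

#' Apply / invert transforms
#'
#' @param tf a `transform` or `transform_chain`
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) points
#' @return `apply_transform`: n x 2 matrix of mapped points;
#'   `invert_transform`: the inverse transform
#' @export
apply_transform <- function(tf, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, 1, 2)
  if (inherits(tf, "transform_chain")) {
    for (t1 in tf) xy <- apply_transform(t1, xy)
    return(xy)
  }
  sweep(xy %*% t(tf$A), 2, as.numeric(tf$b), "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  if (inherits(tf, "transform_chain"))
    return(tf_chain(lapply(rev(unclass(tf)), invert_transform)))
  Ai <- solve(tf$A)
  structure(list(type = tf$type, A = Ai, b = -Ai %*% tf$b),
            class = "transform")
}

#' Bilinear interpolation of an image at float coordinates
#'
#' @param img matrix (rows = y, cols = x)
#' @param x,y 0-based float coordinates; samples outside the image return 0
#' @return numeric vector of sampled intensities
#' @export
interp_bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  at <- function(yy, xx) {
    ok <- xx >= 0 & xx <= w - 1 & yy >= 0 & yy <= h - 1
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  val <- at(y0, x0) * (1 - fx) * (1 - fy) + at(y0, x0 + 1) * fx * (1 - fy) +
    at(y0 + 1, x0) * (1 - fx) * fy + at(y0 + 1, x0 + 1) * fx * fy
  val
}

#' Warp an image through a coordinate map
#'
#' `out[q] = img[map(q)]` for every output pixel q, with bilinear sampling:
#' `map` must take output-frame coordinates to input-frame coordinates.
#'
#' @param img input image matrix
#' @param map a `transform` / `transform_chain` (output frame -> input frame)
#' @param dim_out c(height, width) of the output
#' @return warped image matrix
#' @export
warp_image <- function(img, map, dim_out = dim(img)) {
  h <- dim_out[1]; w <- dim_out[2]
  grid <- cbind(x = rep(seq_len(w) - 1, each = h),
                y = rep(seq_len(h) - 1, times = w))
  src <- apply_transform(map, grid)
  matrix(interp_bilinear(img, src[, 1], src[, 2]), h, w)
}

## block-mean downsampling by a factor of 2 (odd trailing row/col dropped)
downsample2 <- function(img) {
  h <- 2 * (nrow(img) %/% 2); w <- 2 * (ncol(img) %/% 2)
  img <- img[seq_len(h), seq_len(w)]
  (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
     img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)]) / 4
}

#' Preprocess an image for registration
#'
#' Converts to grayscale (luminance weights for RGB), rescales to [0, 1],
#' computes a tissue mask by Otsu thresholding, and returns a Gaussian-smoothed
#' copy for use inside the registration pipeline.
#'
#' @param img matrix, or h x w x 3 RGB array
#' @param sigma Gaussian smoothing sigma in pixels
#' @return list with `gray` (float matrix in [0, 1]), `mask` (logical matrix),
#'   `smooth` (smoothed grayscale)
#' @export
preprocess_image <- function(img, sigma = 5) {
  if (length(dim(img)) == 3) {
    wts <- c(0.2126, 0.7152, 0.0722)
    img <- img[, , 1] * wts[1] + img[, , 2] * wts[2] + img[, , 3] * wts[3]
  }
  mx <- max(img)
  if (mx <= 0) stopf("all-zero image: empty mask")
  if (mx > 1) img <- img / mx
  th <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  mask <- img > th
  if (!any(mask)) mask <- img > 0  # flat image: keep every nonzero pixel
  list(gray = img, mask = mask, smooth = EBImage::gblur(img, sigma = sigma))
}

## mean-squared-error between fixed and moving sampled through an affine map
## (params -> transform builder supplied per stage)
mse_metric <- function(fixed, moving, A, b) {
  warped <- warp_image(moving, structure(list(type = "affine", A = A, b = b),
                                         class = "transform"), dim(fixed))
  mean((fixed - warped)^2)
}

#' Register a moving image to a fixed image
#'
#' Multi-resolution (image-pyramid) intensity-based registration with a
#' mean-squared-error metric and Nelder-Mead optimization, in stages:
#' `"rigid"` (rotation + translation), `"affine"` (full 2x2 + translation),
#' and optionally `"nonlinear"` (a Gaussian-regularized demons refinement
#' returning a dense displacement field). Both images should already be
#' preprocessed (see [preprocess_image()]; registration is usually run on the
#' smoothed copies).
#'
#' The estimated map takes fixed-frame coordinates to moving-frame
#' coordinates; the returned `chain` element is its inverse (moving -> fixed).
#' When `landmarks` are supplied (data.frame with `fixed_x`, `fixed_y`,
#' `moving_x`, `moving_y`), the root-mean-square distance between mapped fixed
#' landmarks and the true moving landmarks is reported in pixels.
#'
#' @param moving,fixed image matrices on a comparable intensity scale
#' @param stages subset of c("rigid", "affine", "nonlinear"), run in order
#' @param n_levels pyramid depth (coarsest level downsampled 2^(n_levels-1))
#' @param landmarks optional landmark table for scoring
#' @param max_iter Nelder-Mead iteration cap per stage and level
#' @return list with `fixed_to_moving` (estimated transform), `chain`
#'   (inverse, moving -> fixed), `metric` (final MSE), `landmark_rmse`
#'   (or NA), `converged` (logical; FALSE triggers a warning and returns the
#'   best-so-far transform), and for the nonlinear stage `displacement`
#'   (h x w x 2 field added to the affine map)
#' @export
register_images <- function(moving, fixed, stages = c("rigid", "affine"),
                            n_levels = 3, landmarks = NULL, max_iter = 400) {
  stopifnot(all(stages %in% c("rigid", "affine", "nonlinear")))
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(n_levels - 1)) {
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
  }
  converged <- TRUE
  ## rigid stage parameters at current level: (theta_deg, tx, ty)
  par_rigid <- c(0, 0, 0)
  run_level <- function(par, builder, parscale, fx, mv) {
    obj <- function(p) {
      tf <- builder(p, dim(fx))
      mse_metric(fx, mv, tf$A, tf$b)
    }
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter, parscale = parscale,
                                       reltol = 1e-9))
    if (fit$convergence != 0) converged <<- FALSE
    fit$par
  }
  build_rigid <- function(p, dm) {
    ctr <- c((dm[2] - 1) / 2, (dm[1] - 1) / 2)
    tf_rigid(p[1], p[2], p[3], center = ctr)
  }
  build_affine <- function(p, dm) {
    ctr <- c((dm[2] - 1) / 2, (dm[1] - 1) / 2)
    tf_affine(matrix(p[1:4], 2, 2), p[5:6], center = ctr)
  }
  if ("rigid" %in% stages) {
    for (l in rev(seq_len(n_levels))) {
      par_rigid[2:3] <- par_rigid[2:3] * if (l == n_levels) 1 else 2
      par_rigid <- run_level(par_rigid, build_rigid, c(2, 2, 2),
                             pyr_f[[l]], pyr_m[[l]])
    }
  }
  r <- par_rigid[1] * pi / 180
  par_aff <- c(cos(r), sin(r), -sin(r), cos(r), par_rigid[2], par_rigid[3])
  if ("affine" %in% stages) {
    if (!("rigid" %in% stages)) par_aff <- c(1, 0, 0, 1, 0, 0)
    ## restart the pyramid: translations estimated at full resolution so far
    for (l in rev(seq_len(n_levels))) {
      sc <- 2^(l - 1)
      p_l <- c(par_aff[1:4], par_aff[5:6] / sc)
      p_l <- run_level(p_l, build_affine, c(0.05, 0.05, 0.05, 0.05, 1, 1),
                       pyr_f[[l]], pyr_m[[l]])
      par_aff <- c(p_l[1:4], p_l[5:6] * sc)
    }
  } else if ("rigid" %in% stages) {
    ## express the rigid result in full-resolution pixels
    par_aff[5:6] <- par_rigid[2:3]
  }
  fixed_to_moving <- build_affine(par_aff, dim(fixed))
  displacement <- NULL
  if ("nonlinear" %in% stages) {
    dem <- demons_refine(fixed, moving, fixed_to_moving)
    displacement <- dem$displacement
  }
  metric <- mse_metric(fixed, moving, fixed_to_moving$A, fixed_to_moving$b)
  if (!converged)
    warnf("registration optimizer hit the iteration cap; returning best-so-far")
  landmark_rmse <- NA_real_
  if (!is.null(landmarks)) {
    pred <- apply_transform(fixed_to_moving,
                            cbind(landmarks$fixed_x, landmarks$fixed_y))
    landmark_rmse <- sqrt(mean((pred[, 1] - landmarks$moving_x)^2 +
                                 (pred[, 2] - landmarks$moving_y)^2))
  }
  list(fixed_to_moving = fixed_to_moving,
       chain = invert_transform(fixed_to_moving),
       metric = metric, landmark_rmse = landmark_rmse,
       converged = converged, displacement = displacement)
}

## Gaussian-regularized demons refinement on top of an affine map: iteratively
## pushes the warped moving image towards the fixed image along its gradient.
demons_refine <- function(fixed, moving, affine_map, n_iter = 30,
                          smooth_sigma = 2) {
  h <- nrow(fixed); w <- ncol(fixed)
  ux <- matrix(0, h, w); uy <- matrix(0, h, w)
  gx0 <- rep(seq_len(w) - 1, each = h)
  gy0 <- rep(seq_len(h) - 1, times = w)
  for (it in seq_len(n_iter)) {
    src <- apply_transform(affine_map, cbind(gx0 + as.numeric(ux),
                                             gy0 + as.numeric(uy)))
    warped <- matrix(interp_bilinear(moving, src[, 1], src[, 2]), h, w)
    diffi <- fixed - warped
    gx <- (cbind(warped[, -1], warped[, w]) - cbind(warped[, 1], warped[, -w])) / 2
    gy <- (rbind(warped[-1, ], warped[h, ]) - rbind(warped[1, ], warped[-h, ])) / 2
    den <- gx^2 + gy^2 + diffi^2 + 1e-9
    ux <- EBImage::gblur(ux + diffi * gx / den, sigma = smooth_sigma)
    uy <- EBImage::gblur(uy + diffi * gy / den, sigma = smooth_sigma)
  }
  list(displacement = array(c(ux, uy), dim = c(h, w, 2)))
}
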