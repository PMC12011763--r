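# Preprocessing: grayscale conversion, resizing, Gaussian-derivative edge
# magnitude, channel concatenation and training-time augmentation.

#' Configuration for Gaussian-derivative preprocessing
#'
#' @param sigma standard deviation of the Gaussian kernel, in pixels. The
#'   default (1.5) targets lesion-scale boundaries at 128x128 resolution.
#' @param kernel_radius kernel truncation radius in units of `sigma`.
#' @return a `derivative_config` list.
#' @export
derivative_config <- function(sigma = 1.5, kernel_radius = 4) {
  assert_that(is.numeric(sigma) && sigma > 0, "sigma must be > 0")
  assert_that(kernel_radius >= 2, "kernel_radius must be >= 2")
  structure(list(sigma = sigma, kernel_radius = kernel_radius),
            class = "derivative_config")
}

#' Convert an RGB image to grayscale
#'
#' Luminance-weighted average with Rec.709 weights (0.2126, 0.7152, 0.0722).
#'
#' @param image H x W x 3 array with values in `[0, 1]`.
#' @return H x W grayscale matrix.
#' @export
to_grayscale <- function(image) {
  assert_that(length(dim(image)) == 3 && dim(image)[3] == 3,
              "to_grayscale expects an H x W x 3 array, got dims [%s]",
              paste(dim(image), collapse = ", "),
              class = "mtloca_shape_error")
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}

#' Discrete 2D Gaussian kernel
#'
#' Samples `exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)` on an odd
#' integer grid truncated at `kernel_radius * sigma`. The kernel is returned
#' unnormalized so its center value is exactly `1 / (2 pi sigma^2)`.
#'
#' @param cfg a [derivative_config()].
#' @return a square numeric matrix with odd side length.
#' @export
gaussian_kernel_2d <- function(cfg = derivative_config()) {
  r <- ceiling(cfg$kernel_radius * cfg$sigma)
  g <- seq(-r, r)
  xx <- matrix(g, 2 * r + 1, 2 * r + 1, byrow = TRUE)  # x along columns
  yy <- matrix(g, 2 * r + 1, 2 * r + 1)
  exp(-(xx^2 + yy^2) / (2 * cfg$sigma^2)) / (2 * pi * cfg$sigma^2)
}

#' Partial-derivative Gaussian kernels
#'
#' Samples of `-x / (2 pi sigma^4) * exp(-(x^2 + y^2) / (2 sigma^2))` and
#' its y counterpart. Rows index y, columns index x; `dy` is `dx`
#' transposed. Each kernel sums to zero by antisymmetry.
#'
#' @inheritParams gaussian_kernel_2d
#' @return `list(dx = , dy = )` of square matrices.
#' @export
gaussian_derivative_kernels <- function(cfg = derivative_config()) {
  r <- ceiling(cfg$kernel_radius * cfg$sigma)
  g <- seq(-r, r)
  xx <- matrix(g, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  yy <- matrix(g, 2 * r + 1, 2 * r + 1)
  env <- exp(-(xx^2 + yy^2) / (2 * cfg$sigma^2))
  dx <- -xx / (2 * pi * cfg$sigma^4) * env
  list(dx = dx, dy = t(dx))
}

#' Same-size 2D convolution
#'
#' True convolution (kernel flipped) with reflected or zero boundary.
#'
#' @param image numeric matrix.
#' @param kernel numeric matrix with odd sides.
#' @param pad `"reflect"` (default) or `"zero"`.
#' @return matrix of the same size as `image`.
#' @export
conv2d_same <- function(image, kernel, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  assert_that(nrow(kernel) %% 2 == 1 && ncol(kernel) %% 2 == 1,
              "kernel sides must be odd")
  assert_that(nrow(image) >= nrow(kernel) && ncol(image) >= ncol(kernel),
              "image (%d x %d) smaller than kernel (%d x %d)",
              nrow(image), ncol(image), nrow(kernel), ncol(kernel),
              class = "mtloca_shape_error")
  flipped <- kernel[rev(seq_len(nrow(kernel))), rev(seq_len(ncol(kernel))),
                    drop = FALSE]
  cpp_correlate2d(image, flipped,
                  if (pad == "reflect") PAD_REFLECT else PAD_ZERO)
}

#' Gaussian-derivative gradient magnitude
#'
#' Convolves the image with the x and y derivative-of-Gaussian kernels and
#' returns `sqrt(gx^2 + gy^2)`, a boundary-strength map.
#'
#' @param image numeric matrix with finite values.
#' @inheritParams gaussian_kernel_2d
#' @return non-negative matrix of the same size as `image`.
#' @export
gradient_magnitude <- function(image, cfg = derivative_config()) {
  assert_that(all(is.finite(image)), "image contains non-finite values")
  ks <- gaussian_derivative_kernels(cfg)
  gx <- conv2d_same(image, ks$dx)
  gy <- conv2d_same(image, ks$dy)
  sqrt(gx^2 + gy^2)
}

# Resampling ----------------------------------------------------------------

.resize_coords <- function(n_out, n_in) {
  s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  s
}

#' Bilinear image resize
#' @param image numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(image, out_h, out_w) {
  H <- nrow(image); W <- ncol(image)
  if (H == out_h && W == out_w) return(image)
  ys <- .resize_coords(out_h, H)
  xs <- .resize_coords(out_w, W)
  y0 <- pmin(pmax(floor(ys), 0), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(pmax(floor(xs), 0), W - 1); x1 <- pmin(x0 + 1, W - 1)
  fy <- pmin(pmax(ys - floor(ys), 0), 1); fy[ys < 0] <- 0
  fx <- pmin(pmax(xs - floor(xs), 0), 1); fx[xs < 0] <- 0
  a <- image[y0 + 1, x0 + 1, drop = FALSE]
  b <- image[y1 + 1, x0 + 1, drop = FALSE]
  cc <- image[y0 + 1, x1 + 1, drop = FALSE]
  d <- image[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w)
  wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  (1 - wy) * (1 - wx) * a + wy * (1 - wx) * b +
    (1 - wy) * wx * cc + wy * wx * d
}

#' Nearest-neighbour resize (mask-safe)
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(image, out_h, out_w) {
  H <- nrow(image); W <- ncol(image)
  if (H == out_h && W == out_w) return(image)
  yi <- pmin(pmax(round(.resize_coords(out_h, H)), 0), H - 1) + 1
  xi <- pmin(pmax(round(.resize_coords(out_w, W)), 0), W - 1) + 1
  image[yi, xi, drop = FALSE]
}

#' Rotate an image about its center
#'
#' @param image numeric matrix.
#' @param angle rotation in degrees (counter-clockwise).
#' @param interp `"bilinear"` (edge-replicated fill) or `"nearest"`
#'   (zero fill) — the latter keeps masks binary.
#' @return rotated matrix, same size.
#' @export
rotate_image <- function(image, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (angle == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  th <- -angle * pi / 180  # inverse mapping
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  yy <- rep(0:(H - 1), W) - cy
  xx <- rep(0:(W - 1), each = H) - cx
  ys <- cos(th) * yy - sin(th) * xx + cy
  xs <- sin(th) * yy + cos(th) * xx + cx
  out <- cpp_warp(matrix(image, H * W, 1), H, W, ys, xs,
                  interp == "nearest")
  matrix(out, H, W)
}

# Model input ----------------------------------------------------------------

#' Build the two-channel network input from a labelled sample
#'
#' Resizes the intensity image (bilinear) and mask (nearest-neighbour) to
#' `size` x `size`, computes the Gaussian-derivative magnitude of the
#' resized intensity, rescales it to `[0, 1]` by its per-image maximum and
#' stacks intensity + magnitude as channels.
#'
#' @param sample a `labeled_sample` (see [generate_sample()]), or any list
#'   with `image`, `mask`, `label`, `id`.
#' @param cfg a [derivative_config()].
#' @param size output spatial side (default 128).
#' @return a `model_input` list with `channels` (size x size x 2 array),
#'   `mask`, `label`, `id`.
#' @export
build_model_input <- function(sample, cfg = derivative_config(),
                              size = 128L) {
  img <- sample$image
  if (length(dim(img)) == 3) img <- to_grayscale(img)
  img <- resize_bilinear(img, size, size)
  mask <- resize_nearest(sample$mask, size, size)
  mag <- gradient_magnitude(img, cfg)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  channels <- array(0, dim = c(size, size, 2L))
  channels[, , 1] <- img
  channels[, , 2] <- mag
  structure(list(channels = channels, mask = mask,
                 label = sample$label, id = sample$id),
            class = "model_input")
}

#' Training-time augmentation configuration
#'
#' Defaults follow the training protocol: rotations in (-45, 45) degrees,
#' random horizontal/vertical flips, random center cropping with 50%
#' probability (retaining 80% of the side), and random gamma contrast in
#' `[0.7, 1.4]` applied to the intensity channel only.
#'
#' @param rotation_range length-2 numeric, degrees.
#' @param flip_h,flip_v enable the two flips (each applied with prob. 0.5).
#' @param crop_prob probability of a random center crop.
#' @param crop_fraction side fraction retained by the crop.
#' @param gamma_range contrast-enhancement gamma range (intensity channel).
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotation_range = c(-45, 45), flip_h = TRUE,
                           flip_v = TRUE, crop_prob = 0.5,
                           crop_fraction = 0.8,
                           gamma_range = c(0.7, 1.4)) {
  assert_that(crop_prob >= 0 && crop_prob <= 1, "crop_prob must be in [0,1]")
  assert_that(length(rotation_range) == 2 &&
                isTRUE(all.equal(rotation_range[1], -rotation_range[2])),
              "rotation bounds must be symmetric")
  structure(list(rotation_range = rotation_range, flip_h = flip_h,
                 flip_v = flip_v, crop_prob = crop_prob,
                 crop_fraction = crop_fraction, gamma_range = gamma_range),
            class = "augment_config")
}

#' Randomly augment a model input
#'
#' The same geometric transform (rotation, flips, optional center crop
#' resized back) is applied to every channel and to the mask; the contrast
#' (gamma) transform touches the intensity channel only. The mask stays
#' binary via nearest-neighbour resampling with zero fill.
#'
#' @param input a `model_input` from [build_model_input()].
#' @param cfg an [augment_config()].
#' @param seed optional integer; when given the draw is deterministic.
#' @return an augmented `model_input`.
#' @export
augment <- function(input, cfg = augment_config(), seed = NULL) {
  run <- function() {
    size <- nrow(input$mask)
    nc <- dim(input$channels)[3]
    angle <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
    do_fh <- cfg$flip_h && runif(1) < 0.5
    do_fv <- cfg$flip_v && runif(1) < 0.5
    do_crop <- runif(1) < cfg$crop_prob
    gamma <- runif(1, cfg$gamma_range[1], cfg$gamma_range[2])

    # compose rotate -> flip -> crop(+resize back) into one inverse map
    ys <- rep(0:(size - 1), size)       # h fastest, matching matrix layout
    xs <- rep(0:(size - 1), each = size)
    if (do_crop) {
      side <- round(size * cfg$crop_fraction)
      lo <- floor((size - side) / 2)
      ys <- (ys + 0.5) * side / size - 0.5 + lo
      xs <- (xs + 0.5) * side / size - 0.5 + lo
    }
    if (do_fh) xs <- (size - 1) - xs
    if (do_fv) ys <- (size - 1) - ys
    if (angle != 0) {
      th <- -angle * pi / 180
      cc <- (size - 1) / 2
      y0 <- ys - cc; x0 <- xs - cc
      ys <- cos(th) * y0 - sin(th) * x0 + cc
      xs <- sin(th) * y0 + cos(th) * x0 + cc
    }
    stack <- cbind(matrix(input$channels, size * size, nc), c(input$mask))
    warped <- cpp_warp(stack, size, size, ys, xs,
                       c(rep(FALSE, nc), TRUE))
    ch <- array(warped[, seq_len(nc)], dim = c(size, size, nc))
    mask <- matrix(warped[, nc + 1], size, size)
    ch[, , 1] <- clamp01(ch[, , 1])^gamma
    ch[, , 2] <- clamp01(ch[, , 2])
    out <- input
    out$channels <- ch
    out$mask <- mask
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Global histogram equalization
#'
#' Optional dataset-level contrast normalization: maps intensities through
#' their empirical CDF (256 bins).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @return equalized matrix in `[0, 1]`.
#' @export
equalize_hist <- function(image) {
  q <- floor(clamp01(image) * 255)
  cdf <- cumsum(tabulate(q + 1, nbins = 256))
  cdf <- (cdf - cdf[1]) / max(cdf[256] - cdf[1], 1)
  matrix(cdf[q + 1], nrow(image), ncol(image))
}
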