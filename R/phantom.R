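# Synthetic breast-ultrasound-like speckle phantoms with pixel-exact ground
# truth, so every downstream stage is testable without external data.
#
# The stated world: speckled grayscale images containing either no lesion
# (normal), a smooth hypoechoic ellipse (benign) or an irregular spiculated
# dark region (malignant). Speckle is multiplicative, Rayleigh-derived,
# normalized to mean 1 and lightly blurred to mimic the spatial correlation
# of real B-mode speckle.

#' Phantom generator specification
#'
#' Defaults emulate a three-class breast-ultrasound dataset: the class mix
#' follows the published 437 benign / 210 malignant / 133 normal composition
#' (as proportions of 780), lesions are hypoechoic (darker than background),
#' benign lesions are smooth ellipses and malignant lesions carry a
#' spiculated sinusoidal boundary perturbation.
#'
#' @param image_size pixels per side (default 128).
#' @param class_mix named proportions for normal/benign/malignant; must sum
#'   to 1.
#' @param benign_shape list: `axes` — semi-axis range in pixels,
#'   `ratio_max` — maximum axis ratio, `contrast` — fractional intensity
#'   drop inside the lesion, in `[0, 1]`.
#' @param malignant_shape list: `radius` — base radius range (pixels),
#'   `amplitude` — boundary perturbation amplitude (pixels), `spikes` —
#'   number of sinusoidal boundary harmonics, `contrast` — intensity drop.
#' @param speckle list: `sd` — relative standard deviation of the
#'   multiplicative speckle field, `blur_sigma` — Gaussian smoothing of the
#'   raw Rayleigh field (pixels).
#' @param background_intensity mean background level in `[0, 1]`.
#' @param seed RNG seed used by [generate_dataset()].
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 128L,
                         class_mix = c(normal = 133, benign = 437,
                                       malignant = 210) / 780,
                         benign_shape = list(axes = c(9, 24),
                                             ratio_max = 1.8,
                                             contrast = 0.45),
                         malignant_shape = list(radius = c(10, 22),
                                                amplitude = 5,
                                                spikes = 7,
                                                contrast = 0.65),
                         speckle = list(sd = 0.18, blur_sigma = 0.7),
                         background_intensity = 0.45,
                         seed = 1L) {
  spec <- structure(list(image_size = as.integer(image_size),
                         class_mix = class_mix,
                         benign_shape = benign_shape,
                         malignant_shape = malignant_shape,
                         speckle = speckle,
                         background_intensity = background_intensity,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @param spec object to validate.
#' @export
validate_phantom_spec <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "not a phantom_spec")
  assert_that(abs(sum(spec$class_mix) - 1) < 1e-8, "class_mix must sum to 1")
  assert_that(all(names(spec$class_mix) %in% CLASS_LEVELS) &&
                !anyDuplicated(names(spec$class_mix)),
              "class_mix names must be among normal/benign/malignant")
  assert_that(spec$background_intensity >= 0 &&
                spec$background_intensity <= 1,
              "background_intensity must be in [0,1]")
  assert_that(spec$benign_shape$contrast >= 0 &&
                spec$benign_shape$contrast <= 1 &&
                spec$malignant_shape$contrast >= 0 &&
                spec$malignant_shape$contrast <= 1,
              "lesion contrast values must be in [0,1]")
  margin <- 4
  half <- spec$image_size / 2
  if (max(spec$benign_shape$axes) > half - margin)
    stop_mtloca("benign lesion cannot fit: max semi-axis %.1f > %.1f",
                max(spec$benign_shape$axes), half - margin,
                class = "mtloca_sizing_error")
  if (max(spec$malignant_shape$radius) + spec$malignant_shape$amplitude >
        half - margin)
    stop_mtloca("malignant lesion cannot fit: radius + amplitude %.1f > %.1f",
                max(spec$malignant_shape$radius) +
                  spec$malignant_shape$amplitude, half - margin,
                class = "mtloca_sizing_error")
  invisible(spec)
}

# Multiplicative speckle field: Rayleigh draws normalized to mean 1, blurred,
# then standardized so the field has mean 1 and standard deviation spec sd.
.speckle_field <- function(n, speckle) {
  u <- matrix(runif(n * n), n, n)
  ray <- sqrt(-2 * log(pmax(u, 1e-12)))      # Rayleigh(sigma = 1)
  ray <- ray / sqrt(pi / 2)                  # mean 1
  if (speckle$blur_sigma > 0) {
    k <- gaussian_kernel_2d(derivative_config(sigma = speckle$blur_sigma,
                                              kernel_radius = 3))
    k <- k / sum(k)
    ray <- conv2d_same(ray, k)
  }
  s <- stats::sd(ray)
  field <- 1 + speckle$sd * (ray - mean(ray)) / max(s, 1e-12)
  pmax(field, 0)
}

.place_center <- function(size, bound_radius, margin = 4) {
  lo <- bound_radius + margin
  hi <- size - 1 - bound_radius - margin
  if (hi < lo)
    stop_mtloca("lesion of bounding radius %.1f cannot fit in a %d-px image",
                bound_radius, size, class = "mtloca_sizing_error")
  c(runif(1, lo, hi), runif(1, lo, hi))  # (cy, cx), 0-based
}

.benign_mask <- function(size, shape) {
  a <- runif(1, shape$axes[1], shape$axes[2])
  ratio <- runif(1, 1, shape$ratio_max)
  b <- max(a / ratio, shape$axes[1])
  phi <- runif(1, 0, pi)
  ctr <- .place_center(size, max(a, b))
  yy <- matrix(0:(size - 1), size, size) - ctr[1]
  xx <- matrix(0:(size - 1), size, size, byrow = TRUE) - ctr[2]
  xr <- cos(phi) * xx + sin(phi) * yy
  yr <- -sin(phi) * xx + cos(phi) * yy
  (xr / a)^2 + (yr / b)^2 <= 1
}

.malignant_mask <- function(size, shape) {
  r0 <- runif(1, shape$radius[1], shape$radius[2])
  J <- shape$spikes
  freqs <- 2 + seq_len(J)              # harmonics 3 .. J+2, integer
  phases <- runif(J, 0, 2 * pi)
  perturb <- function(theta) {
    p <- 0
    for (j in seq_len(J)) p <- p + sin(freqs[j] * theta + phases[j])
    p
  }
  grid <- seq(0, 2 * pi, length.out = 2048)
  pmax_abs <- max(abs(perturb(grid)))
  ctr <- .place_center(size, r0 + shape$amplitude)
  yy <- matrix(0:(size - 1), size, size) - ctr[1]
  xx <- matrix(0:(size - 1), size, size, byrow = TRUE) - ctr[2]
  dist <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  rtheta <- r0 + shape$amplitude * perturb(theta) / max(pmax_abs, 1e-9)
  dist <= rtheta
}

#' Generate one labelled phantom sample
#'
#' @param spec a [phantom_spec()].
#' @param label one of `"normal"`, `"benign"`, `"malignant"`.
#' @param seed optional integer seed making the draw deterministic.
#' @param id sample identifier string.
#' @return a `labeled_sample`: list with `image` (H x W in `[0, 1]`),
#'   `mask` (H x W binary, all-zero iff normal), `label`, `id`.
#' @export
generate_sample <- function(spec, label, seed = NULL, id = label) {
  validate_phantom_spec(spec)
  label <- match.arg(label, CLASS_LEVELS)
  run <- function() {
    n <- spec$image_size
    mask <- matrix(0, n, n)
    clean <- matrix(spec$background_intensity, n, n)
    if (label != "normal") {
      shape <- if (label == "benign") spec$benign_shape
               else spec$malignant_shape
      m <- if (label == "benign") .benign_mask(n, shape)
           else .malignant_mask(n, shape)
      mask[m] <- 1
      clean[m] <- spec$background_intensity * (1 - shape$contrast)
      blur <- gaussian_kernel_2d(derivative_config(sigma = 1,
                                                   kernel_radius = 3))
      clean <- conv2d_same(clean, blur / sum(blur))
    }
    img <- clamp01(clean * .speckle_field(n, spec$speckle))
    structure(list(image = img, mask = mask, label = label, id = id),
              class = "labeled_sample")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Inverse circularity (shape factor) of a binary mask
#'
#' `perimeter^2 / (4 pi area)` with the perimeter taken as the total length
#' of exposed pixel edges (4-neighbourhood). Equals ~1.6 for a rasterized
#' disk and grows with boundary irregularity; used to check that spiculated
#' malignant masks are measurably less circular than benign ellipses.
#'
#' @param mask binary matrix.
#' @return a positive number, or `NA` for an empty mask.
#' @export
mask_shape_factor <- function(mask) {
  area <- sum(mask)
  if (area == 0) return(NA_real_)
  up <- rbind(mask[-1, , drop = FALSE], 0)
  dn <- rbind(0, mask[-nrow(mask), , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], 0)
  rt <- cbind(0, mask[, -ncol(mask), drop = FALSE])
  perim <- sum(mask * ((1 - up) + (1 - dn) + (1 - lf) + (1 - rt)))
  perim^2 / (4 * pi * area)
}

# Largest-remainder apportionment of n among class_mix proportions.
.class_counts <- function(class_mix, n) {
  raw <- class_mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_frac[seq_len(rem)]] <- counts[order_frac[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Generate a phantom dataset with manifest
#'
#' Class counts follow `spec$class_mix` with largest-remainder rounding.
#' When `out_dir` is given, images and masks are written as 8-bit PNG
#' (masks use 0/255 on disk) under `images/` and `masks/`, with a
#' `manifest.csv` listing `id,label,image_path,mask_path` (paths relative to
#' `out_dir`). Identical `(spec, n)` produce byte-identical datasets.
#'
#' @param spec a [phantom_spec()]; `spec$seed` drives all randomness.
#' @param n number of samples (>= 1).
#' @param out_dir optional output directory.
#' @return a `phantom_dataset`: list with `samples` (list of
#'   `labeled_sample`) and `manifest` (data.frame).
#' @export
generate_dataset <- function(spec, n, out_dir = NULL) {
  validate_phantom_spec(spec)
  assert_that(n >= 1, "n must be >= 1")
  counts <- .class_counts(spec$class_mix, n)
  labels <- rep(names(spec$class_mix), counts)
  ids <- sprintf("s%04d_%s", seq_len(n), labels)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- generate_sample(spec, labels[i],
                                    seed = derive_seed(spec$seed, i),
                                    id = ids[i])
  }
  manifest <- data.frame(id = ids, label = labels,
                         image_path = file.path("images",
                                                paste0(ids, ".png")),
                         mask_path = file.path("masks", paste0(ids, ".png")),
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
    if (!ok || file.access(out_dir, 2) != 0)
      stop_mtloca("output directory '%s' is not writable", out_dir,
                  class = "mtloca_io_error")
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(samples[[i]]$image,
                    file.path(out_dir, manifest$image_path[i]))
      png::writePNG(samples[[i]]$mask,
                    file.path(out_dir, manifest$mask_path[i]))
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  structure(list(samples = samples, manifest = manifest, spec = spec),
            class = "phantom_dataset")
}

#' Load a phantom-layout dataset from disk
#'
#' Reads `manifest.csv` plus the PNGs it references. Mask pixels above 0.5
#' map to 1. RGB images are converted to grayscale.
#'
#' @param dir dataset directory (the `out_dir` of [generate_dataset()] or an
#'   equivalent user layout).
#' @return a `phantom_dataset` (without a `spec`).
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  assert_that(file.exists(mpath), "no manifest.csv under '%s'", dir,
              class = "mtloca_io_error")
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("id", "label", "image_path", "mask_path")
  assert_that(all(need %in% names(manifest)),
              "manifest must have columns id,label,image_path,mask_path")
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$image_path[i]))
    if (length(dim(img)) == 3) img <- to_grayscale(img[, , 1:3, drop = TRUE])
    msk <- png::readPNG(file.path(dir, manifest$mask_path[i]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    msk <- (msk > 0.5) * 1
    structure(list(image = img, mask = msk,
                   label = manifest$label[i], id = manifest$id[i]),
              class = "labeled_sample")
  })
  structure(list(samples = samples, manifest = manifest),
            class = "phantom_dataset")
}

#' Check a dataset's class/mask consistency
#'
#' Verifies every sample: matching image/mask shapes, binary mask, values in
#' `[0,1]`, and the class-mask rule (all-zero mask iff label is normal).
#'
#' @param ds a `phantom_dataset`.
#' @return `TRUE` invisibly; errors on the first violation.
#' @export
check_dataset <- function(ds) {
  for (s in ds$samples) {
    assert_that(identical(dim(s$image), dim(s$mask)),
                "sample %s: image/mask shape mismatch", s$id)
    assert_that(is_binary(s$mask), "sample %s: mask not binary", s$id)
    assert_that(min(s$image) >= 0 && max(s$image) <= 1,
                "sample %s: intensities outside [0,1]", s$id)
    empty <- sum(s$mask) == 0
    assert_that(empty == (s$label == "normal"),
                "sample %s: label '%s' inconsistent with mask", s$id, s$label)
  }
  invisible(TRUE)
}
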