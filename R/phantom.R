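#' Specification of a synthetic brain-slice phantom
#'
#' Describes a family of seedable 2-D phantoms that emulate the intensity
#' structure the segmentation-and-texture pipeline assumes: a bright
#' elliptical region of interest on a dark background (a learnable bimodal
#' histogram) whose interior carries class-dependent texture. Each class is
#' an oriented sinusoidal grating of distinct period and orientation plus
#' class-specific speckle noise, so the classes are discriminable by local
#' texture descriptors by construction.
#'
#' The default contrast regime (background 40, foreground 180, noise SD 10)
#' satisfies `foreground_mean - background_mean >= 4 * noise_sd`, which
#' guarantees well-separated histogram modes.
#'
#' @param image_size `c(H, W)` in pixels (default 128 x 128).
#' @param background_mean,foreground_mean mean gray levels (defaults 40,
#'   180).
#' @param noise_sd global Gaussian noise SD in gray levels (default 10).
#' @param n_classes number of texture classes (default 3).
#' @param texture_params optional list of per-class lists with
#'   `grating_period` (pixels), `grating_orientation` (degrees),
#'   `grating_contrast` (gray levels) and `speckle_sd` (gray levels);
#'   defaults are pairwise distinct per class.
#' @param foreground_axes ellipse semi-axes as fractions of `H/2` and `W/2`
#'   (default `c(0.7, 0.55)`).
#' @param seed master seed for dataset generation.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_size = c(128L, 128L),
                         background_mean = 40, foreground_mean = 180,
                         noise_sd = 10, n_classes = 3L,
                         texture_params = NULL,
                         foreground_axes = c(0.7, 0.55), seed = NULL) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            n_classes >= 1, length(foreground_axes) == 2L,
            all(foreground_axes > 0), all(foreground_axes <= 1))
  if (foreground_mean - background_mean < 4 * noise_sd)
    stop("foreground/background contrast must be at least 4 * noise_sd ",
         "for a learnable bimodal histogram", call. = FALSE)
  if (is.null(texture_params)) {
    texture_params <- lapply(seq_len(n_classes), function(k)
      list(grating_period = 5 + 7 * (k - 1),
           grating_orientation = 180 * (k - 1) / n_classes,
           grating_contrast = 30,
           speckle_sd = 4 + 7 * (k - 1)))
  }
  if (length(texture_params) != n_classes)
    stop("`texture_params` must have one entry per class", call. = FALSE)
  keys <- vapply(texture_params, function(p)
    paste(p$grating_period, p$grating_orientation, p$speckle_sd), "")
  if (anyDuplicated(keys))
    stop("per-class texture parameters must be pairwise distinct",
         call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 background_mean = background_mean,
                 foreground_mean = foreground_mean,
                 noise_sd = noise_sd, n_classes = as.integer(n_classes),
                 texture_params = texture_params,
                 foreground_axes = foreground_axes,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phantom_spec")
}

# centred ellipse mask for a spec
.phantom_mask <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ay <- spec$foreground_axes[1] * h / 2
  ax <- spec$foreground_axes[2] * w / 2
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  (((r - cy) / ay)^2 + ((c_ - cx) / ax)^2 <= 1) * 1L
}

#' Generate one phantom image with ground truth
#'
#' Renders the centred ellipse at `foreground_mean` overlaid with the
#' class's oriented grating and speckle, the background at
#' `background_mean`, Gaussian noise of `noise_sd` everywhere, then clips
#' to \[0, 255\] and rounds. The returned mask is exactly the generating
#' ellipse, so segmentation metrics against it are exact.
#'
#' @param spec a [phantom_spec()].
#' @param class_label class index in `1..n_classes`.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return object of class `"phantom_sample"`: list with `image`, `mask`,
#'   `label`, `seed`.
#' @export
generate_phantom <- function(spec, class_label, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (class_label < 1 || class_label > spec$n_classes)
    stop("`class_label` must be in 1..", spec$n_classes, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  mask <- .phantom_mask(spec)
  p <- spec$texture_params[[class_label]]
  theta <- p$grating_orientation * pi / 180
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  phase <- (r * sin(theta) + c_ * cos(theta)) / p$grating_period
  grating <- p$grating_contrast * sin(2 * pi * phase)
  img <- matrix(spec$background_mean, h, w)
  img[mask == 1L] <- spec$foreground_mean + grating[mask == 1L]
  if (p$speckle_sd > 0)
    img[mask == 1L] <- img[mask == 1L] +
      stats::rnorm(sum(mask), sd = p$speckle_sd)
  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  img <- pmin(pmax(.half_up(img), 0L), 255L)
  storage.mode(img) <- "integer"
  structure(list(image = img, mask = mask,
                 label = as.integer(class_label), seed = seed),
            class = "phantom_sample")
}

# deterministic per-sample seed derived from a master seed (kept < 2^31)
.derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + index * 7919) %% 2147483629)
}

#' Generate a balanced phantom dataset
#'
#' Produces `n_per_class` samples of every class, each from a per-sample
#' seed derived deterministically from the spec's master seed, so any
#' sample (or the whole dataset) can be regenerated byte-for-byte from the
#' manifest alone. Optionally writes images and masks as PNG plus a
#' `manifest.csv`.
#'
#' @param spec a [phantom_spec()] (its `seed` is the master seed;
#'   default 0).
#' @param n_per_class samples per class (>= 1).
#' @param dir optional output directory for PNGs and the manifest.
#' @return list with `samples` (list of [generate_phantom()] results) and
#'   `manifest` (data frame with id, label, seed and file names).
#' @export
generate_dataset <- function(spec, n_per_class, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n_per_class >= 1)
  master <- if (is.null(spec$seed)) 0L else spec$seed
  labels <- rep(seq_len(spec$n_classes), each = n_per_class)
  n <- length(labels)
  seeds <- vapply(seq_len(n), function(i) .derive_seed(master, i), 0L)
  samples <- lapply(seq_len(n), function(i)
    generate_phantom(spec, labels[i], seed = seeds[i]))
  manifest <- data.frame(
    id = sprintf("phantom_%03d", seq_len(n)),
    label = labels, seed = seeds,
    image_file = sprintf("phantom_%03d.png", seq_len(n)),
    mask_file = sprintf("phantom_%03d_mask.png", seq_len(n)),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(samples[[i]]$image / 255,
                    file.path(dir, manifest$image_file[i]))
      write_mask(samples[[i]]$mask, file.path(dir, manifest$mask_file[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' Simulate a bimodal gray-level histogram
#'
#' Draws a two-Gaussian mixture histogram of the kind produced by a bright
#' tissue class over a dark background. The default parameter ranges give
#' overlapping modes whose valley bins stay populated — as in real MRI,
#' where partial-volume pixels fill the space between tissue modes — so the
#' within-class-variance objective has a strict minimum.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param n_pixels total pixel count (default 32768, a 181 x 181 slice).
#' @param mean_ranges list of two `c(lo, hi)` ranges for the dark and
#'   bright mode means.
#' @param sd_range `c(lo, hi)` range for both mode SDs.
#' @return length-256 histogram of counts.
#' @export
simulate_bimodal_histogram <- function(seed = NULL, n_pixels = 32768L,
                                       mean_ranges = list(c(60, 100),
                                                          c(140, 190)),
                                       sd_range = c(15, 30)) {
  if (!is.null(seed)) set.seed(seed)
  m1 <- stats::runif(1, mean_ranges[[1]][1], mean_ranges[[1]][2])
  m2 <- stats::runif(1, mean_ranges[[2]][1], mean_ranges[[2]][2])
  s1 <- stats::runif(1, sd_range[1], sd_range[2])
  s2 <- stats::runif(1, sd_range[1], sd_range[2])
  half <- floor(n_pixels / 2)
  x <- c(stats::rnorm(half, m1, s1), stats::rnorm(n_pixels - half, m2, s2))
  tabulate(pmin(pmax(.half_up(x), 0), 255) + 1, nbins = 256L)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Phantom spec: %dx%d, bg %g / fg %g (noise sd %g), %d classes\n",
    x$image_size[1], x$image_size[2], x$background_mean,
    x$foreground_mean, x$noise_sd, x$n_classes))
  invisible(x)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("Phantom sample: %dx%d image, class %d, %d foreground px\n",
              nrow(x$image), ncol(x$image), x$label, sum(x$mask)))
  invisible(x)
}
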