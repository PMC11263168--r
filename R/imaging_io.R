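#' adseg: swarm-optimised Otsu segmentation, texture fusion and DBN
#' classification for brain MRI slices
#'
#' The package implements a complete region-of-interest analysis chain for
#' 2-D 8-bit grayscale images: histogram-based Otsu thresholding whose
#' threshold is located by the Tunicate Swarm Algorithm
#' ([otsu_tsa()], [tsa_optimize()]), local binary pattern and local
#' directional pattern variance texture descriptors fused at feature level
#' ([extract_features()]), a deep belief network classifier ([dbn()]),
#' segmentation and classification metrics ([dice()],
#' [classification_metrics()]), a synthetic phantom generator
#' ([generate_dataset()]) and an end-to-end driver ([run_pipeline()]).
#'
#' @keywords internal
"_PACKAGE"

# round-half-up; base round() is round-half-even
.half_up <- function(x) floor(x + 0.5)

#' Validate and coerce a 2-D 8-bit intensity image
#'
#' An intensity image is an integer matrix with values in 0..255 and at
#' least 3 rows and 3 columns (texture descriptors need a full 3x3
#' neighbourhood). Rows index image rows, columns index image columns.
#'
#' @param pixels numeric or integer matrix.
#' @return integer matrix of the same shape.
#' @export
as_intensity_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (any(pixels != floor(pixels)))
    stop("pixel values must be integers", call. = FALSE)
  storage.mode(pixels) <- "integer"
  pixels
}

# map an arbitrary numeric matrix to 8-bit by min-max rescaling;
# a zero-range (constant) input maps to all-zero by convention
.rescale_8bit <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) {
    out <- matrix(0L, nrow(x), ncol(x))
  } else {
    out <- .half_up((x - rng[1]) / (rng[2] - rng[1]) * 255)
    storage.mode(out) <- "integer"
  }
  out
}

#' Read a grayscale image as an 8-bit intensity matrix
#'
#' Reads PNG, TIFF or NIfTI sources. Inputs that are already 8-bit are
#' returned unchanged; other bit depths are min-max rescaled to \[0, 255\]
#' and rounded half-up, with constant images mapping to all zeros.
#' Multi-channel rasters are averaged to a single luminance channel.
#' 3-D NIfTI volumes require an explicit `slice` index along `axis`.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param slice slice index for 3-D NIfTI volumes.
#' @param axis axis (1, 2 or 3) along which `slice` is taken; default 3.
#' @return integer matrix, see [as_intensity_image()].
#' @export
read_grayscale <- function(path, slice = NULL, axis = 3) {
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      nc <- min(dim(a)[3], 3L) # drop alpha
      a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
    }
    x <- a * 255
    if (max(abs(x - .half_up(x))) < 1e-6) {
      # 8-bit quantised source: identity
      x <- .half_up(x)
      storage.mode(x) <- "integer"
    } else {
      x <- .rescale_8bit(x)
    }
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF files", call. = FALSE)
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(a)) == 3L) {
      nc <- min(dim(a)[3], 3L)
      a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
    }
    if (min(a) >= 0 && max(a) <= 255 && all(a == floor(a))) {
      x <- a
      storage.mode(x) <- "integer"
    } else {
      x <- .rescale_8bit(a)
    }
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("package 'RNifti' is required to read NIfTI files", call. = FALSE)
    a <- as.array(RNifti::readNifti(path))
    a <- drop(a)
    if (length(dim(a)) == 3L) {
      if (is.null(slice))
        stop("3-D NIfTI volume: supply `slice` (and optionally `axis`)",
             call. = FALSE)
      a <- switch(as.character(axis),
                  "1" = a[slice, , ],
                  "2" = a[, slice, ],
                  "3" = a[, , slice],
                  stop("`axis` must be 1, 2 or 3", call. = FALSE))
    } else if (length(dim(a)) != 2L) {
      stop("unsupported NIfTI dimensionality: ", length(dim(a)), call. = FALSE)
    }
    if (min(a) >= 0 && max(a) <= 255 && all(a == floor(a))) {
      x <- a
      storage.mode(x) <- "integer"
    } else {
      x <- .rescale_8bit(a)
    }
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  as_intensity_image(x)
}

#' Gray-level histogram of an 8-bit image
#'
#' @param image intensity image, see [as_intensity_image()].
#' @return integer vector of length 256; element `i + 1` counts the pixels
#'   with gray level `i`. The counts sum to the number of pixels.
#' @examples
#' img <- matrix(c(0L, 0L, 255L, 255L, 7L, 7L, 7L, 7L, 7L), 3, 3)
#' h <- compute_histogram(img)
#' sum(h) == length(img)
#' @export
compute_histogram <- function(image) {
  image <- as_intensity_image(image)
  tabulate(as.vector(image) + 1L, nbins = 256L)
}

#' Write a binary segmentation mask as an 8-bit PNG
#'
#' Foreground (1) is stored as gray level 255, background (0) as 0, so the
#' mask is viewable in any image tool and round-trips exactly through
#' [read_mask()].
#'
#' @param mask integer matrix of 0/1 labels.
#' @param path output PNG path.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stop("`mask` must be a matrix of 0/1 labels", call. = FALSE)
  png::writePNG(mask * 1.0, path) # [0,1] maps to bytes {0,255}
  invisible(path)
}

#' Read a binary segmentation mask from an 8-bit PNG
#'
#' @param path PNG path holding only gray levels 0 and 255.
#' @return integer matrix of 0/1 labels.
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop("cannot read mask: no such file: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  v <- .half_up(a * 255)
  if (!all(v %in% c(0, 255)))
    stop("not a binary mask: found gray levels other than {0, 255} in ",
         path, call. = FALSE)
  m <- (v == 255) * 1L
  dim(m) <- dim(v)
  m
}
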