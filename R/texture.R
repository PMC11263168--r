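# Fixed 8-neighbour geometry shared by LBP and the directional masks:
# p = 0 at the East neighbour, proceeding counter-clockwise
# (E, NE, N, NW, W, SW, S, SE). Offsets are (row, col) with rows growing
# downwards.
.NBR_DR <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.NBR_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

# Kirsch compass masks in the same direction order; each mask's
# coefficients sum to zero, so responses are invariant to adding a
# constant to the patch.
.kirsch_masks <- local({
  east <- matrix(c(-3, -3, 5,
                   -3,  0, 5,
                   -3, -3, 5), 3, 3, byrow = TRUE)
  rot <- function(m) { # one 45-degree counter-clockwise step of the 5-arc
    ring <- c(m[1, 2], m[1, 3], m[2, 3], m[3, 3],
              m[3, 2], m[3, 1], m[2, 1], m[1, 1])
    ring <- c(ring[-1], ring[1])
    out <- m
    out[1, 2] <- ring[1]; out[1, 3] <- ring[2]; out[2, 3] <- ring[3]
    out[3, 3] <- ring[4]; out[3, 2] <- ring[5]; out[3, 1] <- ring[6]
    out[2, 1] <- ring[7]; out[1, 1] <- ring[8]
    out
  }
  masks <- vector("list", 8L)
  masks[[1]] <- east
  for (i in 2:8) masks[[i]] <- rot(masks[[i - 1]])
  masks
})

# interior shifted view: neighbour at offset (dr, dc) for every interior pixel
.shift_interior <- function(image, dr, dc) {
  h <- nrow(image); w <- ncol(image)
  image[(2L + dr):(h - 1L + dr), (2L + dc):(w - 1L + dc), drop = FALSE]
}

#' Local binary pattern code of one neighbourhood
#'
#' `sum_p s(g_p - g_c) 2^p` with `s(x) = 1` iff `x >= 0` (a neighbour equal
#' to the centre sets its bit) and `p = 0` at the East neighbour proceeding
#' counter-clockwise.
#'
#' @param center centre gray value.
#' @param neighbors length-8 vector of neighbour gray values in the fixed
#'   circular order E, NE, N, NW, W, SW, S, SE.
#' @return integer code in \[0, 255\].
#' @examples
#' lbp_code(5, c(6, 4, 5, 3, 7, 2, 5, 1)) # 85
#' @export
lbp_code <- function(center, neighbors) {
  if (length(neighbors) != 8L)
    stop("`neighbors` must have exactly 8 values", call. = FALSE)
  as.integer(sum((neighbors >= center) * 2^(0:7)))
}

#' Local binary pattern code map of an image
#'
#' Computes the radius-1, 8-neighbour LBP code at every interior pixel;
#' border pixels are skipped (no padding), so the map is `(H-2) x (W-2)`.
#'
#' @param image intensity image, at least 3x3.
#' @return integer matrix of codes in \[0, 255\].
#' @export
lbp_map <- function(image) {
  image <- as_intensity_image(image)
  centre <- .shift_interior(image, 0L, 0L)
  code <- matrix(0L, nrow(centre), ncol(centre))
  for (p in 1:8) {
    nb <- .shift_interior(image, .NBR_DR[p], .NBR_DC[p])
    code <- code + (nb >= centre) * 2L^(p - 1L)
  }
  code
}

#' Kirsch compass edge responses of a 3x3 patch
#'
#' Absolute responses of the eight Kirsch compass masks (East first,
#' counter-clockwise), the directional responses underlying the local
#' directional pattern.
#'
#' @param patch 3x3 numeric matrix of gray values.
#' @return length-8 non-negative numeric vector.
#' @export
kirsch_responses <- function(patch) {
  if (!is.matrix(patch) || any(dim(patch) != c(3L, 3L)))
    stop("`patch` must be a 3x3 matrix", call. = FALSE)
  vapply(.kirsch_masks, function(m) abs(sum(m * patch)), 0)
}

#' Local directional pattern code from directional responses
#'
#' Sets the bits of the `k` most prominent of the 8 directional responses
#' (bit `p` = direction `p`, East first, counter-clockwise); ties are broken
#' towards the lower direction index. At `k = 3` exactly `choose(8, 3) = 56`
#' codes are attainable.
#'
#' @param responses length-8 numeric vector, e.g. from [kirsch_responses()].
#' @param k number of prominent directions, 1..7 (default 3) or 8.
#' @return integer code.
#' @export
ldp_code <- function(responses, k = 3L) {
  if (length(responses) != 8L)
    stop("`responses` must have exactly 8 values", call. = FALSE)
  stopifnot(k >= 1, k <= 8)
  # order() is stable: equal responses rank by lower index
  top <- order(responses, decreasing = TRUE)[seq_len(k)]
  as.integer(sum(2L^(top - 1L)))
}

#' Variance of the 8 directional responses
#'
#' `(1/8) sum_i (m_i - mean(m))^2`, the adaptive weight attached to each
#' pattern code in the LDPv histogram: neighbourhoods with strong,
#' anisotropic edge structure contribute more than flat ones.
#'
#' @inheritParams ldp_code
#' @return non-negative scalar.
#' @export
ldp_variance <- function(responses) {
  if (length(responses) != 8L)
    stop("`responses` must have exactly 8 values", call. = FALSE)
  mean((responses - mean(responses))^2)
}

# all attainable k-of-8 codes in ascending order
.ldp_codebook <- function(k) {
  sort(apply(utils::combn(8L, k), 2L, function(ix) sum(2L^(ix - 1L))))
}

# block id (1..g) of position i among n, near-equal partition
.block_of <- function(i, n, g) ceiling(i * g / n)

# per-pixel maps over the interior: 8 Kirsch responses as an N x 8 matrix
.kirsch_response_matrix <- function(image) {
  h <- nrow(image) - 2L
  w <- ncol(image) - 2L
  out <- matrix(0, h * w, 8L)
  for (p in 1:8) {
    m <- .kirsch_masks[[p]]
    acc <- matrix(0, h, w)
    for (a in -1:1) for (b in -1:1) {
      co <- m[a + 2L, b + 2L]
      if (co != 0) acc <- acc + co * .shift_interior(image, a, b)
    }
    out[, p] <- abs(as.vector(acc))
  }
  out
}

# row-wise top-k index sets as a bit code, tie towards lower index
.ldp_code_rows <- function(resp, k) {
  code <- integer(nrow(resp))
  x <- resp
  for (j in seq_len(k)) {
    ix <- max.col(x, ties.method = "first")
    code <- code + 2L^(ix - 1L)
    x[cbind(seq_len(nrow(x)), ix)] <- -Inf
  }
  code
}

#' Block-wise LDPv histograms of an image
#'
#' For every interior pixel the 8 Kirsch responses give a k-of-8 local
#' directional pattern code and a response variance ([ldp_variance()]).
#' Within each block of a `grid_rows x grid_cols` partition of the interior,
#' bin `tau` accumulates the summed response variance of the pixels whose
#' code is `tau`, over the `choose(8, k)` attainable codes in ascending
#' code order.
#'
#' @param image intensity image, at least 3x3.
#' @param k number of prominent directions (default 3, giving 56 bins).
#' @param grid_rows,grid_cols block grid of the histogram (default 4x4).
#' @return numeric matrix, one row per block (row-major block order), one
#'   column per attainable code; column names carry the code values.
#' @export
ldpv_histogram <- function(image, k = 3L, grid_rows = 4L, grid_cols = 4L) {
  image <- as_intensity_image(image)
  stopifnot(k >= 1, k <= 7, grid_rows >= 1, grid_cols >= 1)
  h <- nrow(image) - 2L
  w <- ncol(image) - 2L
  resp <- .kirsch_response_matrix(image)
  code <- .ldp_code_rows(resp, k)
  mbar <- rowMeans(resp)
  sigma <- rowMeans((resp - mbar)^2)
  book <- .ldp_codebook(k)
  nbin <- length(book)
  bin <- match(code, book)
  # row-major block order: block = (rowblock - 1) * grid_cols + colblock;
  # pixel vectors are column-major over the (h x w) interior
  rb <- .block_of(rep(seq_len(h), times = w), h, grid_rows)
  cb <- .block_of(rep(seq_len(w), each = h), w, grid_cols)
  block <- (rb - 1L) * grid_cols + cb
  idx <- (block - 1L) * nbin + bin # column-major into nbin x nblocks
  acc <- rowsum(sigma, idx)
  out <- matrix(0, nbin, grid_rows * grid_cols)
  out[as.integer(rownames(acc))] <- acc
  out <- t(out)
  colnames(out) <- sprintf("c%03d", book)
  rownames(out) <- sprintf("b%02d", seq_len(nrow(out)))
  structure(out, grid = c(grid_rows, grid_cols), k = k)
}

#' Block-wise LBP count histograms of a code map
#'
#' Partitions the code map into a near-equal `grid_rows x grid_cols` grid
#' and counts codes 0..255 per block; block sums equal block pixel counts.
#'
#' @param code_map integer code matrix from [lbp_map()].
#' @param grid_rows,grid_cols block grid (default 4x4).
#' @return numeric matrix, blocks (row-major) by 256 code bins.
#' @export
lbp_histogram <- function(code_map, grid_rows = 4L, grid_cols = 4L) {
  stopifnot(is.matrix(code_map), grid_rows >= 1, grid_cols >= 1,
            all(code_map >= 0), all(code_map <= 255))
  h <- nrow(code_map)
  w <- ncol(code_map)
  rb <- .block_of(rep(seq_len(h), times = w), h, grid_rows)
  cb <- .block_of(rep(seq_len(w), each = h), w, grid_cols)
  block <- (rb - 1L) * grid_cols + cb
  idx <- (block - 1L) * 256L + as.vector(code_map) + 1L
  out <- matrix(tabulate(idx, nbins = 256L * grid_rows * grid_cols),
                256L, grid_rows * grid_cols)
  out <- t(out)
  colnames(out) <- sprintf("c%03d", 0:255)
  rownames(out) <- sprintf("b%02d", seq_len(nrow(out)))
  structure(out, grid = c(grid_rows, grid_cols))
}

#' Fuse LBP and LDPv block histograms into one descriptor
#'
#' Each block histogram is L1-normalised (all-zero blocks stay zero) and
#' the blocks are concatenated, LBP blocks first, giving one fixed-length
#' non-negative feature vector per image
#' (`grid^2 * 256 + grid^2 * 56 = 4992` under the defaults).
#'
#' @param lbp_part matrix from [lbp_histogram()].
#' @param ldpv_part matrix from [ldpv_histogram()], same grid.
#' @return named numeric feature vector.
#' @export
fuse_features <- function(lbp_part, ldpv_part) {
  if (nrow(lbp_part) != nrow(ldpv_part) ||
      !identical(attr(lbp_part, "grid"), attr(ldpv_part, "grid")))
    stop("LBP and LDPv parts were computed on different block grids",
         call. = FALSE)
  l1 <- function(m) {
    s <- rowSums(m)
    m[s > 0, ] <- m[s > 0, , drop = FALSE] / s[s > 0]
    m
  }
  a <- l1(lbp_part)
  b <- l1(ldpv_part)
  flat <- function(m, tag) {
    v <- as.vector(t(m))
    names(v) <- paste0(tag, "_", rep(rownames(m), each = ncol(m)), "_",
                       rep(colnames(m), times = nrow(m)))
    v
  }
  c(flat(a, "lbp"), flat(b, "ldpv"))
}

#' Fused LBP + LDPv texture descriptor of a (masked) image
#'
#' Convenience wrapper running the full descriptor chain: optionally zero
#' the background with a segmentation mask, compute the [lbp_map()] and its
#' block histograms, the [ldpv_histogram()], and fuse both parts.
#'
#' @param image intensity image.
#' @param mask optional 0/1 matrix of the same shape; background (0) pixels
#'   are set to gray level 0 before descriptor extraction.
#' @param k prominent directions for the LDP code (default 3).
#' @param grid_rows,grid_cols block grid (default 4x4).
#' @return named numeric feature vector (length 4992 under the defaults).
#' @export
extract_features <- function(image, mask = NULL, k = 3L,
                             grid_rows = 4L, grid_cols = 4L) {
  image <- as_intensity_image(image)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(image)))
      stop("`mask` shape must match the image", call. = FALSE)
    image[mask == 0L] <- 0L
  }
  lbp <- lbp_histogram(lbp_map(image), grid_rows, grid_cols)
  ldpv <- ldpv_histogram(image, k, grid_rows, grid_cols)
  fuse_features(lbp, ldpv)
}
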