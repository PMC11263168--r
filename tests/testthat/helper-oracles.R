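# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code with the vectorised implementations they
# check.

random_image <- function(h, w, lo = 0, hi = 255, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(lo:hi, h * w, replace = TRUE), h, w)
}

# per-pixel LBP with explicit neighbour coordinates (E, CCW)
naive_lbp_map <- function(img) {
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0L, h - 2, w - 2)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    code <- 0L
    for (p in 1:8) {
      if (img[r + dr[p], c + dc[p]] >= img[r, c])
        code <- code + 2L^(p - 1L)
    }
    out[r - 1, c - 1] <- code
  }
  out
}

# whole-image (1x1 grid) LDPv histogram by direct accumulation
naive_ldpv <- function(img, k = 3) {
  book <- sort(apply(utils::combn(8, k), 2, function(ix) sum(2^(ix - 1))))
  acc <- stats::setNames(numeric(length(book)), book)
  h <- nrow(img); w <- ncol(img)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    patch <- img[(r - 1):(r + 1), (c - 1):(c + 1)]
    m <- kirsch_responses(patch)
    code <- ldp_code(m, k)
    sigma <- mean((m - mean(m))^2)
    acc[as.character(code)] <- acc[as.character(code)] + sigma
  }
  unname(acc)
}

random_histogram <- function(seed = NULL, n_levels = 256) {
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(n_levels, lambda = runif(1, 1, 50))
  if (sum(counts) == 0) counts[1] <- 1
  counts
}

# population total variance of a histogram
hist_total_variance <- function(h) {
  lv <- 0:255
  mu <- sum(lv * h) / sum(h)
  sum((lv - mu)^2 * h) / sum(h)
}

# between-class variance at threshold t from first principles
hist_between_variance <- function(h, t) {
  lv <- 0:255
  tot <- sum(h)
  bg <- 1:(t + 1)
  wb <- sum(h[bg]) / tot
  wf <- 1 - wb
  mu <- sum(lv * h) / tot
  mb <- if (wb > 0) sum(lv[bg] * h[bg]) / sum(h[bg]) else 0
  mf <- if (wf > 0) sum(lv[-bg] * h[-bg]) / sum(h[-bg]) else 0
  wb * (mb - mu)^2 + wf * (mf - mu)^2
}

# two-cluster feature set for classifier tests: 5 sigma separation per
# dimension between the class means
separable_clusters <- function(seed, n_per_class = 100, dim = 100,
                               delta = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * dim, 0), n_per_class),
             matrix(rnorm(n_per_class * dim, delta), n_per_class))
  list(x = x, y = rep(0:1, each = n_per_class))
}
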