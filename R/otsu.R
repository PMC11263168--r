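.check_hist <- function(hist) {
  if (length(hist) != 256L || anyNA(hist) || any(hist < 0))
    stop("`hist` must be a length-256 vector of non-negative counts",
         call. = FALSE)
  as.numeric(hist)
}

.check_t <- function(t) {
  if (any(t != floor(t)) || any(t < 0) || any(t > 254))
    stop("threshold `t` must be an integer in [0, 254]", call. = FALSE)
  as.integer(t)
}

#' Otsu class statistics at a candidate threshold
#'
#' Splits the gray-level axis into background `[0..t]` and foreground
#' `[t+1..255]` and returns the count weight, count-weighted mean and
#' count-weighted (population) variance of each class. An empty class has
#' weight, mean and variance 0, so downstream objectives stay finite over
#' the whole threshold range.
#'
#' @param hist length-256 histogram (see [compute_histogram()]).
#' @param t integer threshold in \[0, 254\].
#' @return list with `w_b`, `w_f` (pixel counts), `mu_b`, `mu_f`, `var_b`,
#'   `var_f`.
#' @export
otsu_class_stats <- function(hist, t) {
  hist <- .check_hist(hist)
  t <- .check_t(t)
  lv <- 0:255
  bg <- seq_len(t + 1L)
  wb <- sum(hist[bg]); wf <- sum(hist[-bg])
  mb <- if (wb > 0) sum(lv[bg] * hist[bg]) / wb else 0
  mf <- if (wf > 0) sum(lv[-bg] * hist[-bg]) / wf else 0
  vb <- if (wb > 0) sum((lv[bg] - mb)^2 * hist[bg]) / wb else 0
  vf <- if (wf > 0) sum((lv[-bg] - mf)^2 * hist[-bg]) / wf else 0
  list(w_b = wb, w_f = wf, mu_b = mb, mu_f = mf, var_b = vb, var_f = vf)
}

#' Within-class variance of a thresholded histogram
#'
#' The Otsu minimisation objective
#' `sigma_w^2(t) = w_b(t) sigma_b^2(t) + w_f(t) sigma_f^2(t)` with class
#' weights normalised by the total pixel count, so the value is a variance
#' in squared gray levels and comparable across image sizes. Vectorised
#' over `t`.
#'
#' @inheritParams otsu_class_stats
#' @param t integer threshold(s) in \[0, 254\].
#' @return non-negative numeric, one value per threshold.
#' @export
within_class_variance <- function(hist, t) {
  hist <- .check_hist(hist)
  t <- .check_t(t)
  .wcv_sweep(hist)[t + 1L]
}

# sigma_w^2 for every t in 0..254 via cumulative moments
.wcv_sweep <- function(hist) {
  lv <- 0:255
  tot <- sum(hist)
  cw <- cumsum(hist)
  cm <- cumsum(lv * hist)
  cm2 <- cumsum(lv^2 * hist)
  i <- 1:255 # threshold t = i - 1
  wb <- cw[i]
  mb <- ifelse(wb > 0, cm[i] / wb, 0)
  vb <- ifelse(wb > 0, pmax(cm2[i] / wb - mb^2, 0), 0)
  wf <- tot - wb
  mf <- ifelse(wf > 0, (cm[256] - cm[i]) / wf, 0)
  vf <- ifelse(wf > 0, pmax((cm2[256] - cm2[i]) / wf - mf^2, 0), 0)
  (wb * vb + wf * vf) / tot
}

#' Exhaustive Otsu threshold search
#'
#' Sweeps every threshold in 0..254 and returns the minimiser of the
#' within-class variance; ties are broken towards the smallest threshold.
#'
#' @inheritParams otsu_class_stats
#' @return object of class `"threshold_result"`: list with `threshold`,
#'   `objective_value` and `method = "exhaustive"`.
#' @export
otsu_exhaustive <- function(hist) {
  hist <- .check_hist(hist)
  if (sum(hist) <= 0)
    stop("histogram has no pixels", call. = FALSE)
  sw <- .wcv_sweep(hist)
  t <- which.min(sw) - 1L # which.min breaks ties towards the smallest index
  structure(list(threshold = t, objective_value = sw[t + 1L],
                 method = "exhaustive"),
            class = "threshold_result")
}

#' Swarm-optimised Otsu threshold search
#'
#' Minimises the within-class variance over continuous positions in
#' \[0, 254\] with the Tunicate Swarm Algorithm; positions are rounded to
#' the nearest integer threshold before evaluation, which keeps the
#' optimiser generic while the objective stays the discrete Otsu criterion.
#'
#' @inheritParams otsu_class_stats
#' @param config a [tsa_config()]; the defaults are the published swarm
#'   settings.
#' @return object of class `"threshold_result"`: list with `threshold`,
#'   `objective_value`, `method = "tsa"` and the underlying
#'   [tsa_optimize()] result in `optimization`.
#' @export
otsu_tsa <- function(hist, config = tsa_config()) {
  hist <- .check_hist(hist)
  if (sum(hist) <= 0)
    stop("histogram has no pixels", call. = FALSE)
  sw <- .wcv_sweep(hist)
  objective <- function(x) sw[min(max(round(x), 0), 254) + 1L]
  res <- tsa_optimize(objective, c(0, 254), config)
  t <- as.integer(min(max(round(res$best_position), 0), 254))
  structure(list(threshold = t, objective_value = sw[t + 1L],
                 method = "tsa", optimization = res),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Otsu threshold (%s): t = %d, within-class variance = %.6g\n",
              x$method, x$threshold, x$objective_value))
  invisible(x)
}

#' Binarise an image at a threshold
#'
#' Pixels strictly brighter than `t` are labelled 1 (foreground / region of
#' interest), the rest 0. The bright region is taken as foreground because
#' the segmented brain tissue is the high-intensity class in the imaging
#' convention used throughout the package.
#'
#' @param image intensity image.
#' @param t integer threshold in \[0, 255\].
#' @return integer 0/1 matrix of the same shape.
#' @export
apply_threshold <- function(image, t) {
  image <- as_intensity_image(image)
  stopifnot(length(t) == 1L, t >= 0, t <= 255)
  m <- (image > t) * 1L
  dim(m) <- dim(image)
  m
}
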