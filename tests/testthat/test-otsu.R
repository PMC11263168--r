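test_that("class statistics match direct weighted moments", {
  # two delta peaks
  h <- integer(256); h[1] <- 2L; h[256] <- 2L
  s <- otsu_class_stats(h, 128)
  expect_equal(s[c("w_b", "mu_b", "var_b", "w_f", "mu_f", "var_f")],
               list(w_b = 2, mu_b = 0, var_b = 0,
                    w_f = 2, mu_f = 255, var_f = 0))
  # empty foreground defines zero statistics
  h <- integer(256); h[101] <- 5L
  s <- otsu_class_stats(h, 200)
  expect_equal(s$w_b, 5); expect_equal(s$mu_b, 100); expect_equal(s$var_b, 0)
  expect_equal(s$w_f, 0); expect_equal(s$mu_f, 0); expect_equal(s$var_f, 0)
  expect_error(otsu_class_stats(h, 255), "\\[0, 254\\]")
  # random histogram vs an expansion into raw pixel values
  h <- random_histogram(seed = 4)
  x <- rep(0:255, h)
  for (t in c(0, 63, 127, 200, 254)) {
    s <- otsu_class_stats(h, t)
    bg <- x[x <= t]; fg <- x[x > t]
    expect_equal(s$w_b, length(bg))
    expect_equal(s$mu_b, mean(bg))
    expect_equal(s$var_b, mean((bg - mean(bg))^2))
    expect_equal(s$w_f, length(fg))
    expect_equal(s$mu_f, mean(fg))
    expect_equal(s$var_f, mean((fg - mean(fg))^2))
  }
})

test_that("within-class variance vanishes for pure classes", {
  h <- integer(256); h[1] <- 2L; h[256] <- 2L
  expect_equal(within_class_variance(h, 128), 0)
  h2 <- integer(256); h2[50] <- 9L
  expect_true(all(within_class_variance(h2, 0:254) == 0))
})

test_that("within- and between-class variance decompose the total variance", {
  for (s in 1:50) {
    h <- random_histogram(seed = s)
    tot <- hist_total_variance(h)
    wcv <- within_class_variance(h, 0:254)
    bcv <- vapply(0:254, function(t) hist_between_variance(h, t), 0)
    expect_equal(wcv + bcv, rep(tot, 255), tolerance = 1e-9)
  }
})

test_that("exhaustive search minimises and breaks ties towards small t", {
  h <- integer(256); h[51] <- 100L; h[201] <- 100L
  r <- otsu_exhaustive(h)
  expect_identical(r$threshold, 50L)
  expect_equal(r$objective_value, 0)
  # single occupied level
  h2 <- integer(256); h2[1] <- 1L
  r2 <- otsu_exhaustive(h2)
  expect_identical(r2$threshold, 0L)
  expect_equal(r2$objective_value, 0)
  expect_error(otsu_exhaustive(integer(256)), "no pixels")
})

test_that("minimising within-class equals maximising between-class variance", {
  for (s in 1:10) {
    h <- random_histogram(seed = 100 + s)
    bcv <- vapply(0:254, function(t) hist_between_variance(h, t), 0)
    expect_identical(otsu_exhaustive(h)$threshold,
                     as.integer(which.max(bcv) - 1L))
  }
})

test_that("the exhaustive threshold is invariant to count scaling", {
  h <- random_histogram(seed = 9)
  expect_identical(otsu_exhaustive(h)$threshold,
                   otsu_exhaustive(h * 7L)$threshold)
})

test_that("swarm-based search solves the zero-variance plateau and is reproducible", {
  h <- integer(256); h[51] <- 100L; h[201] <- 100L
  r <- otsu_tsa(h, tsa_config(seed = 1))
  expect_equal(r$objective_value, 0)
  expect_identical(r$objective_value, within_class_variance(h, r$threshold))
  r2 <- otsu_tsa(h, tsa_config(seed = 1))
  expect_identical(r$threshold, r2$threshold)
})

test_that("swarm search matches the exhaustive sweep on bimodal histograms", {
  hits <- 0L
  for (s in 1:20) {
    h <- simulate_bimodal_histogram(seed = s)
    te <- otsu_exhaustive(h)
    tt <- otsu_tsa(h, tsa_config(seed = 500 + s))
    expect_gte(tt$objective_value, te$objective_value - 1e-12)
    if (abs(tt$threshold - te$threshold) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("thresholding partitions the image by strict brightness", {
  img <- as_intensity_image(matrix(c(0L, 128L, 77L, 255L, 64L, 12L, 1L, 0L,
                                     200L), 3, 3))
  m <- apply_threshold(img, 127)
  expect_identical(m, (img > 127) * 1L)
  expect_true(all(apply_threshold(img, 255) == 0L))
  img2 <- as_intensity_image(matrix(5L, 3, 3))
  expect_true(all(apply_threshold(img2, 0) == 1L))
  # partition: foreground and background are disjoint and cover the image
  expect_identical(sum(m == 1L) + sum(m == 0L), length(img))
})
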