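test_that("single-neighbourhood LBP codes follow the sign convention", {
  # equality sets the bit: all-equal neighbourhood codes to 255
  expect_identical(lbp_code(10, rep(10, 8)), 255L)
  expect_identical(lbp_code(10, rep(9, 8)), 0L)
  # bits 0, 2, 4, 6 set -> 1 + 4 + 16 + 64
  expect_identical(lbp_code(5, c(6, 4, 5, 3, 7, 2, 5, 1)), 85L)
  expect_error(lbp_code(5, 1:7), "8")
})

test_that("the LBP map equals the per-pixel oracle and shifts with gray level", {
  expect_true(all(lbp_map(matrix(9L, 5, 5)) == 255L))
  for (s in 1:10) {
    img <- random_image(64, 64, seed = s)
    expect_identical(lbp_map(img), naive_lbp_map(img))
  }
  img <- random_image(32, 32, lo = 40, hi = 200, seed = 90)
  expect_identical(lbp_map(img), lbp_map(img + 30L))
})

test_that("Kirsch responses are zero-sum, directional and shift invariant", {
  expect_equal(kirsch_responses(matrix(7, 3, 3)), rep(0, 8))
  step <- matrix(c(0, 0, 0, 0, 0, 0, 255, 255, 255), 3, 3) # bright east col
  r <- kirsch_responses(step)
  expect_identical(which.max(r), 1L) # East mask dominates
  expect_equal(r[5], max(r[-1])) # West ties for the runner-up arc
  expect_equal(r[1], 5 * 255 * 3) # direct convolution of the East mask
  patch <- matrix(sample(0:255, 9), 3, 3)
  expect_equal(kirsch_responses(patch), kirsch_responses(patch + 17))
  expect_error(kirsch_responses(matrix(0, 2, 3)), "3x3")
})

test_that("LDP codes take the k most prominent directions with stable ties", {
  expect_identical(ldp_code(c(10, 9, 8, 1, 2, 3, 4, 5), 3), 7L)
  expect_identical(ldp_code(rep(1, 8), 3), 7L) # ties resolve to low bits
  expect_identical(ldp_code(runif(8), 8), 255L)
  expect_identical(ldp_code(c(0, 5, 0, 0, 9, 0, 0, 1), 2), 18L) # bits 1, 4
})

test_that("response variance follows the population formula and scaling law", {
  expect_equal(ldp_variance(rep(3, 8)), 0)
  expect_equal(ldp_variance(c(8, 0, 0, 0, 0, 0, 0, 0)), 7)
  m <- runif(8, 0, 50)
  expect_equal(ldp_variance(3 * m), 9 * ldp_variance(m))
})

test_that("LDPv histograms match the double-sum oracle and conserve mass", {
  expect_true(all(ldpv_histogram(matrix(5L, 8, 8)) == 0))
  for (s in 1:5) {
    img <- random_image(32, 32, seed = 20 + s)
    got <- ldpv_histogram(img, k = 3, grid_rows = 1, grid_cols = 1)
    expect_equal(as.vector(got), naive_ldpv(img), tolerance = 1e-9)
  }
  # conservation across a non-trivial grid
  img <- random_image(30, 30, seed = 31)
  hb <- ldpv_histogram(img, grid_rows = 4, grid_cols = 4)
  expect_equal(sum(hb), sum(naive_ldpv(img)), tolerance = 1e-9)
})

test_that("block LBP histograms partition the code map", {
  hmap <- lbp_map(matrix(9L, 6, 6))
  hist1 <- lbp_histogram(hmap, 1, 1)
  expect_equal(as.vector(hist1[1, ]), c(rep(0, 255), 16))
  cm <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  h22 <- lbp_histogram(cm, 2, 2)
  expect_equal(dim(h22), c(4L, 256L))
  expect_true(all(rowSums(h22) == 25))
  expect_equal(sum(h22), 100)
})

test_that("feature fusion concatenates L1-normalised blocks, LBP first", {
  img <- random_image(64, 64, seed = 40)
  lbp <- lbp_histogram(lbp_map(img))
  ldpv <- ldpv_histogram(img)
  f <- fuse_features(lbp, ldpv)
  expect_length(f, 4 * 4 * 256 + 4 * 4 * 56)
  expect_true(all(f >= 0))
  expect_true(startsWith(names(f)[1], "lbp"))
  expect_true(startsWith(names(f)[4097], "ldpv"))
  # per-block L1 normalisation
  expect_equal(sum(f[1:256]), 1)
  # zero LDPv part leaves a zero tail
  fz <- fuse_features(lbp, ldpv * 0)
  expect_true(all(fz[4097:4992] == 0))
  expect_error(fuse_features(lbp, ldpv_histogram(img, grid_rows = 2,
                                                 grid_cols = 2)),
               "grid")
})

test_that("both descriptors are invariant to a global gray shift", {
  img <- random_image(48, 48, lo = 60, hi = 180, seed = 50)
  expect_equal(extract_features(img), extract_features(img + 40L))
  # constant images give identical fused vectors regardless of the constant
  expect_identical(extract_features(matrix(10L, 16, 16)),
                   extract_features(matrix(200L, 16, 16)))
})

test_that("masking the background changes the descriptor", {
  s <- generate_phantom(phantom_spec(image_size = c(48L, 48L)), 1, seed = 6)
  f_raw <- extract_features(s$image)
  f_roi <- extract_features(s$image, s$mask)
  expect_false(isTRUE(all.equal(f_raw, f_roi)))
  expect_error(extract_features(s$image, s$mask[1:10, 1:10]), "shape")
})
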