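test_that("min-max scaling maps to the unit interval and is reusable", {
  x <- cbind(c(0, 5, 10), c(3, 3, 3))
  s <- scale_features(x)
  expect_equal(s$x[, 1], c(0, 0.5, 1))
  expect_equal(s$x[, 2], c(0, 0, 0)) # constant column
  expect_equal(scale_features(x, s$scaler)$x, s$x) # idempotent re-apply
  # out-of-range values at predict time are clamped
  expect_equal(scale_features(rbind(c(20, 3)), s$scaler)$x[1, 1], 1)
  expect_error(scale_features(matrix(c(1, NA), 1)), "finite")
})

test_that("hidden probabilities are a sigmoid affine map", {
  rbm <- list(W = matrix(0, 4, 3), vbias = numeric(4), hbias = numeric(3))
  v <- matrix(runif(8), 2, 4)
  expect_true(all(rbm_hidden_probs(rbm, v) == 0.5))
  rbm$hbias <- rep(50, 3)
  expect_true(all(rbm_hidden_probs(rbm, v) > 0.999999))
  set.seed(2)
  rbm <- list(W = matrix(rnorm(12), 4, 3), vbias = rnorm(4),
              hbias = rnorm(3))
  expect_equal(rbm_hidden_probs(rbm, v),
               plogis(v %*% rbm$W + rep(1, 2) %o% rbm$hbias))
  expect_error(rbm_hidden_probs(rbm, matrix(0, 2, 5)), "mismatch")
})

test_that("a zero learning rate makes the CD epoch a reporting no-op", {
  set.seed(3)
  rbm <- list(W = matrix(rnorm(6, sd = 0.1), 3, 2), vbias = rnorm(3),
              hbias = rnorm(2))
  data <- matrix(runif(30), 10, 3)
  out <- rbm_cd1_epoch(rbm, data, learning_rate = 0, batch_size = 5)
  expect_identical(out$rbm, rbm)
  expect_true(is.finite(out$recon_error) && out$recon_error > 0)
})

test_that("CD-1 training reduces reconstruction error on prototype data", {
  worse <- 0L
  for (s in 1:10) {
    set.seed(s)
    proto <- rbind(rep(c(1, 0), each = 8), rep(c(0, 1), each = 8))
    data <- proto[sample(1:2, 200, replace = TRUE), ] +
      matrix(rnorm(200 * 16, sd = 0.05), 200)
    data <- pmin(pmax(data, 0), 1)
    rbm <- adseg:::.rbm_init(16, 4)
    e <- numeric(10)
    vel <- NULL
    for (ep in 1:10) {
      fit <- rbm_cd1_epoch(rbm, data, learning_rate = 0.1, batch_size = 20,
                           velocity = vel)
      rbm <- fit$rbm; vel <- fit$velocity; e[ep] <- fit$recon_error
    }
    if (e[10] >= e[1]) worse <- worse + 1L
  }
  expect_lte(worse, 1L)
})

test_that("the deterministic CD-1 gradient matches finite differences of the free-energy gap", {
  set.seed(4)
  rbm <- list(W = matrix(rnorm(6, sd = 0.5), 3, 2), vbias = rnorm(3),
              hbias = rnorm(2))
  v0 <- matrix(runif(15), 5, 3)
  g <- rbm_cd1_gradient(rbm, v0)
  v1 <- g$v1
  gap <- function(r) mean(rbm_free_energy(r, v0) - rbm_free_energy(r, v1))
  eps <- 1e-6
  num <- function(set) {
    r1 <- set(rbm, eps); r2 <- set(rbm, -eps)
    -(gap(r1) - gap(r2)) / (2 * eps)
  }
  for (i in 1:3) for (j in 1:2) {
    nd <- num(function(r, e) { r$W[i, j] <- r$W[i, j] + e; r })
    expect_equal(nd, g$dW[i, j], tolerance = 1e-4)
  }
  for (i in 1:3) {
    nd <- num(function(r, e) { r$vbias[i] <- r$vbias[i] + e; r })
    expect_equal(nd, g$dvbias[i], tolerance = 1e-4)
  }
  for (j in 1:2) {
    nd <- num(function(r, e) { r$hbias[j] <- r$hbias[j] + e; r })
    expect_equal(nd, g$dhbias[j], tolerance = 1e-4)
  }
})

test_that("pretraining stacks layer dimensions and is seed-reproducible", {
  x <- matrix(runif(50 * 20), 50, 20)
  m <- dbn_pretrain(x, layers = c(8, 6), n_classes = 3, rbm_epochs = 2,
                    seed = 7)
  expect_equal(dim(m$rbms[[1]]$W), c(20L, 8L))
  expect_equal(dim(m$rbms[[2]]$W), c(8L, 6L))
  expect_equal(dim(m$top$W), c(6L, 3L))
  expect_true(all(m$top$W == 0))
  m2 <- dbn_pretrain(x, layers = c(8, 6), n_classes = 3, rbm_epochs = 2,
                     seed = 7)
  expect_identical(m, m2)
  # zero training epochs returns the (reproducible) initial stack
  m0a <- dbn_pretrain(x, layers = c(4), n_classes = 2, rbm_epochs = 0,
                      seed = 1)
  m0b <- dbn_pretrain(x, layers = c(4), n_classes = 2, rbm_epochs = 0,
                      seed = 1)
  expect_identical(m0a, m0b)
  expect_error(dbn_pretrain(x[0, ], layers = 4), "at least one sample")
})

test_that("an untuned zero top layer predicts uniform class probabilities", {
  x <- matrix(runif(30), 10, 3)
  m <- dbn_pretrain(x, layers = c(4), n_classes = 4, rbm_epochs = 1,
                    seed = 2)
  p <- predict(m, x, type = "prob")
  expect_true(all(abs(p - 0.25) < 1e-12))
  expect_equal(rowSums(p), rep(1, 10))
})

test_that("prediction is deterministic and validates dimensions", {
  d <- separable_clusters(1, n_per_class = 20, dim = 10)
  m <- dbn(d$x, d$y, layers = c(4), finetune_epochs = 10, seed = 3)
  p1 <- predict(m, d$x, type = "prob")
  p2 <- predict(m, d$x, type = "prob")
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, 40), tolerance = 1e-9)
  expect_error(predict(m, d$x[, 1:5]), "mismatch")
})

test_that("backprop gradients match central finite differences of the summed cross-entropy", {
  # tiny model: 3 features -> 2 hidden -> 2 classes, 5-sample batch,
  # single full batch so one fine-tune step is exactly -lr * gradient
  set.seed(8)
  x <- matrix(runif(15), 5, 3)
  y <- c(0L, 1L, 0L, 1L, 1L)
  m <- dbn_pretrain(x, layers = c(2), n_classes = 2, rbm_epochs = 1,
                    seed = 8)
  m$top$W <- matrix(rnorm(4, sd = 0.3), 2, 2)
  m$top$b <- rnorm(2)
  ce <- function(model) {
    xs <- scale_features(x, model$scaler)$x
    p <- adseg:::.dbn_forward(model, xs)$probs
    -sum(log(p[cbind(1:5, y + 1L)]))
  }
  lr <- 1e-3
  m1 <- dbn_finetune(m, x, y, finetune_epochs = 1, batch_size = 5,
                     learning_rate = lr, seed = 9)
  eps <- 1e-5
  check <- function(get, set, analytic, tol) {
    for (idx in seq_along(get(m))) {
      mp <- set(m, idx, eps); mm <- set(m, idx, -eps)
      nd <- (ce(mp) - ce(mm)) / (2 * eps)
      expect_equal(analytic(idx), nd, tolerance = tol)
    }
  }
  # analytic gradient recovered from the parameter update
  check(function(m) m$top$W,
        function(m, i, e) { m$top$W[i] <- m$top$W[i] + e; m },
        function(i) (m$top$W[i] - m1$top$W[i]) / lr, 1e-5)
  check(function(m) m$top$b,
        function(m, i, e) { m$top$b[i] <- m$top$b[i] + e; m },
        function(i) (m$top$b[i] - m1$top$b[i]) / lr, 1e-5)
  check(function(m) m$rbms[[1]]$W,
        function(m, i, e) { m$rbms[[1]]$W[i] <- m$rbms[[1]]$W[i] + e; m },
        function(i) (m$rbms[[1]]$W[i] - m1$rbms[[1]]$W[i]) / lr, 1e-4)
  check(function(m) m$rbms[[1]]$hbias,
        function(m, i, e) { m$rbms[[1]]$hbias[i] <- m$rbms[[1]]$hbias[i] + e; m },
        function(i) (m$rbms[[1]]$hbias[i] - m1$rbms[[1]]$hbias[i]) / lr, 1e-4)
})

test_that("a zero fine-tuning rate leaves the model unchanged", {
  d <- separable_clusters(2, n_per_class = 10, dim = 5)
  m <- dbn_pretrain(d$x, layers = c(3), n_classes = 2, rbm_epochs = 1,
                    seed = 1)
  m1 <- dbn_finetune(m, d$x, d$y, finetune_epochs = 5, learning_rate = 0,
                     seed = 2)
  expect_identical(m1$rbms, m$rbms)
  expect_identical(m1$top, m$top)
  expect_error(dbn_finetune(m, d$x, c(0L, rep(1L, 19)) + 2L), "labels")
})

test_that("fine-tuning separates the two-cluster benchmark and lowers the loss", {
  d <- separable_clusters(5)
  fit <- dbn(d$x, d$y, seed = 5)
  expect_gte(mean(predict(fit, d$x) == d$y), 0.95)
  expect_lt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
  # factor labels round-trip through prediction
  yf <- factor(ifelse(d$y == 0, "ctrl", "case"), levels = c("ctrl", "case"))
  fit2 <- dbn(d$x, yf, finetune_epochs = 30, seed = 5)
  expect_s3_class(predict(fit2, d$x), "factor")
  expect_identical(levels(predict(fit2, d$x)), c("ctrl", "case"))
})

test_that("training is bit-reproducible from the seed", {
  d <- separable_clusters(6, n_per_class = 30, dim = 20)
  f1 <- dbn(d$x, d$y, layers = c(6, 4), finetune_epochs = 20, seed = 10)
  f2 <- dbn(d$x, d$y, layers = c(6, 4), finetune_epochs = 20, seed = 10)
  expect_identical(f1[setdiff(names(f1), "classes")],
                   f2[setdiff(names(f2), "classes")])
})

test_that("serialised models predict identically after a JSON round trip", {
  d <- separable_clusters(7, n_per_class = 15, dim = 8)
  fit <- dbn(d$x, d$y, layers = c(4, 3), finetune_epochs = 20, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  write_dbn(fit, path)
  back <- read_dbn(path)
  expect_equal(predict(back, d$x, type = "prob"),
               predict(fit, d$x, type = "prob"), tolerance = 1e-12)
})
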