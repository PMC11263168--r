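#' Min-max feature scaling to the unit interval
#'
#' Restricted Boltzmann machines with Bernoulli visible units expect inputs
#' in \[0, 1\]; this fits (or re-applies) a per-dimension min-max scaler.
#' Zero-range dimensions map to 0. At predict time values outside the
#' training range are clamped into \[0, 1\].
#'
#' @param x numeric matrix, samples in rows.
#' @param scaler optional fitted scaler (list with `min` and `range`); when
#'   `NULL` the scaler is fitted on `x`.
#' @return list with `x` (scaled matrix) and `scaler`.
#' @export
scale_features <- function(x, scaler = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("features must be finite", call. = FALSE)
  if (is.null(scaler)) {
    mins <- apply(x, 2L, min)
    rngs <- apply(x, 2L, max) - mins
    scaler <- list(min = mins, range = rngs)
  }
  out <- sweep(x, 2L, scaler$min, "-")
  nz <- scaler$range > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, scaler$range[nz], "/")
  out[, !nz] <- 0
  out <- pmin(pmax(out, 0), 1)
  list(x = out, scaler = scaler)
}

# random RBM with Glorot-style init for sigmoid units,
# W ~ U(+-4 sqrt(6 / (fan_in + fan_out))); keeps the per-layer signal gain
# near 1 so short training runs see usable gradients. Draws from the
# current RNG stream.
.rbm_init <- function(n_visible, n_hidden) {
  r <- 4 * sqrt(6 / (n_visible + n_hidden))
  list(W = matrix(stats::runif(n_visible * n_hidden, -r, r),
                  n_visible, n_hidden),
       vbias = numeric(n_visible),
       hbias = numeric(n_hidden))
}

.sigmoid <- function(x) stats::plogis(x)

#' Hidden-unit activation probabilities of an RBM
#'
#' `sigmoid(v W + hbias)`, elementwise in (0, 1).
#'
#' @param rbm list with `W` (visible x hidden), `vbias`, `hbias`.
#' @param visible matrix of \[0, 1\] rows (samples).
#' @return matrix of hidden probabilities, one row per sample.
#' @export
rbm_hidden_probs <- function(rbm, visible) {
  visible <- as.matrix(visible)
  if (ncol(visible) != nrow(rbm$W))
    stop("visible dimension mismatch: got ", ncol(visible), ", expected ",
         nrow(rbm$W), call. = FALSE)
  .sigmoid(sweep(visible %*% rbm$W, 2L, rbm$hbias, "+"))
}

.rbm_visible_probs <- function(rbm, hidden) {
  .sigmoid(sweep(hidden %*% t(rbm$W), 2L, rbm$vbias, "+"))
}

#' Free energy of visible configurations under an RBM
#'
#' `F(v) = -v . vbias - sum_j softplus(v W_j + hbias_j)`. The deterministic
#' CD-1 update direction equals the negative gradient of
#' `F(v0) - F(v1)` with the reconstruction `v1` held fixed, which is what
#' [rbm_cd1_gradient()] computes and what finite differences of this
#' function can verify.
#'
#' @inheritParams rbm_hidden_probs
#' @return numeric vector, one free energy per row of `visible`.
#' @export
rbm_free_energy <- function(rbm, visible) {
  visible <- as.matrix(visible)
  z <- sweep(visible %*% rbm$W, 2L, rbm$hbias, "+")
  sp <- ifelse(z > 30, z, log1p(exp(z))) # stable softplus
  -as.vector(visible %*% rbm$vbias) - rowSums(sp)
}

#' Deterministic CD-1 gradient of an RBM
#'
#' Mean-field contrastive divergence with one reconstruction step and no
#' sampling: hidden probabilities of the data, visible reconstruction
#' probabilities, hidden probabilities of the reconstruction, and the
#' resulting parameter gradients (averaged over the batch). Used for
#' gradient verification; the training epoch ([rbm_cd1_epoch()]) uses the
#' same expressions with sampled hidden states.
#'
#' @inheritParams rbm_hidden_probs
#' @param v0 data batch, rows in \[0, 1\].
#' @param v1 optional fixed reconstruction batch; computed by mean-field
#'   CD-1 when `NULL`.
#' @return list with `dW`, `dvbias`, `dhbias` (ascent directions) and the
#'   reconstruction `v1`.
#' @export
rbm_cd1_gradient <- function(rbm, v0, v1 = NULL) {
  v0 <- as.matrix(v0)
  h0 <- rbm_hidden_probs(rbm, v0)
  if (is.null(v1)) v1 <- .rbm_visible_probs(rbm, h0)
  h1 <- rbm_hidden_probs(rbm, v1)
  n <- nrow(v0)
  list(dW = (crossprod(v0, h0) - crossprod(v1, h1)) / n,
       dvbias = colMeans(v0) - colMeans(v1),
       dhbias = colMeans(h0) - colMeans(h1),
       v1 = v1)
}

#' One contrastive-divergence (CD-1) training epoch of an RBM
#'
#' Shuffles the data (current RNG stream), then for every mini-batch:
#' samples binary hidden states from the data's hidden probabilities,
#' reconstructs visible probabilities, computes the reconstruction's hidden
#' probabilities, and applies the CD-1 update with learning rate and
#' momentum. Real-valued inputs are treated as Bernoulli probabilities and
#' are never sampled.
#'
#' @inheritParams rbm_hidden_probs
#' @param data matrix of \[0, 1\] rows.
#' @param learning_rate step size (> 0; 0 makes the epoch a no-op that
#'   still reports the reconstruction error).
#' @param momentum momentum coefficient (default 0).
#' @param batch_size mini-batch size; clamped to the dataset size.
#' @param velocity optional momentum state from the previous epoch.
#' @return list with the updated `rbm`, the mean squared `recon_error`
#'   over the epoch, and the final `velocity`.
#' @export
rbm_cd1_epoch <- function(rbm, data, learning_rate = 0.01, momentum = 0,
                          batch_size = 100L, velocity = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  batch_size <- min(batch_size, n)
  if (is.null(velocity))
    velocity <- list(W = rbm$W * 0, vbias = rbm$vbias * 0,
                     hbias = rbm$hbias * 0)
  ord <- sample.int(n)
  starts <- seq(1L, n, by = batch_size)
  err_sum <- 0
  for (s in starts) {
    ix <- ord[s:min(s + batch_size - 1L, n)]
    v0 <- data[ix, , drop = FALSE]
    h0 <- rbm_hidden_probs(rbm, v0)
    h0s <- (h0 > matrix(stats::runif(length(h0)), nrow(h0))) * 1
    v1 <- .rbm_visible_probs(rbm, h0s)
    h1 <- rbm_hidden_probs(rbm, v1)
    nb <- nrow(v0)
    velocity$W <- momentum * velocity$W +
      learning_rate * (crossprod(v0, h0) - crossprod(v1, h1)) / nb
    velocity$vbias <- momentum * velocity$vbias +
      learning_rate * (colMeans(v0) - colMeans(v1))
    velocity$hbias <- momentum * velocity$hbias +
      learning_rate * (colMeans(h0) - colMeans(h1))
    rbm$W <- rbm$W + velocity$W
    rbm$vbias <- rbm$vbias + velocity$vbias
    rbm$hbias <- rbm$hbias + velocity$hbias
    err_sum <- err_sum + sum((v0 - v1)^2)
  }
  list(rbm = rbm, recon_error = err_sum / length(data), velocity = velocity)
}

#' Greedy layer-wise pretraining of a deep belief network
#'
#' Min-max scales the features, then trains the stack of restricted
#' Boltzmann machines bottom-up by CD-1: each layer trains on the previous
#' layer's mean-field hidden probabilities. The supervised top layer is
#' initialised to zeros, so the untuned model predicts uniform class
#' probabilities.
#'
#' @param x feature matrix, samples in rows; the number of columns sets the
#'   first visible size.
#' @param layers hidden-layer sizes of the RBM stack (default `c(8, 6)`).
#' @param n_classes number of classes of the supervised top layer.
#' @param rbm_epochs CD-1 epochs per layer (default 10; 0 returns the
#'   randomly initialised stack).
#' @param batch_size mini-batch size (default 100, clamped to the dataset).
#' @param learning_rate CD-1 step size (default 0.01).
#' @param momentum momentum coefficient (default 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return unfitted model of class `"dbn"` (see [dbn()]).
#' @export
dbn_pretrain <- function(x, layers = c(8L, 6L), n_classes = 2L,
                         rbm_epochs = 10L, batch_size = 100L,
                         learning_rate = 0.01, momentum = 0, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one sample", call. = FALSE)
  stopifnot(length(layers) >= 1, all(layers >= 1), n_classes >= 2)
  if (!is.null(seed)) set.seed(seed)
  sc <- scale_features(x)
  input <- sc$x
  sizes <- c(ncol(x), layers)
  rbms <- vector("list", length(layers))
  recon <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    rbm <- .rbm_init(sizes[l], sizes[l + 1L])
    # centering: start every hidden unit at activation 1/2 for the mean
    # input of its layer, so units are responsive rather than saturated
    rbm$hbias <- as.numeric(-colMeans(input) %*% rbm$W)
    vel <- NULL
    errs <- numeric(rbm_epochs)
    for (e in seq_len(rbm_epochs)) {
      fit <- rbm_cd1_epoch(rbm, input, learning_rate, momentum, batch_size,
                           vel)
      rbm <- fit$rbm
      vel <- fit$velocity
      errs[e] <- fit$recon_error
    }
    rbms[[l]] <- rbm
    recon[[l]] <- errs
    input <- rbm_hidden_probs(rbm, input)
  }
  structure(list(rbms = rbms,
                 top = list(W = matrix(0, layers[length(layers)], n_classes),
                            b = numeric(n_classes)),
                 scaler = sc$scaler,
                 layers = as.integer(layers),
                 n_classes = as.integer(n_classes),
                 classes = NULL,
                 pretrain_errors = recon,
                 loss_trace = numeric(0),
                 finetuned = FALSE,
                 config = list(rbm_epochs = rbm_epochs,
                               batch_size = batch_size,
                               learning_rate = learning_rate,
                               momentum = momentum)),
            class = "dbn")
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass on scaled inputs: sigmoid stack + softmax top
.dbn_forward <- function(model, x) {
  acts <- vector("list", length(model$rbms) + 1L)
  acts[[1]] <- x
  for (l in seq_along(model$rbms))
    acts[[l + 1L]] <- rbm_hidden_probs(model$rbms[[l]], acts[[l]])
  logits <- sweep(acts[[length(acts)]] %*% model$top$W, 2L, model$top$b, "+")
  list(activations = acts, probs = .softmax(logits))
}

.check_labels <- function(y, n_classes) {
  if (any(y != floor(y)) || any(y < 0) || any(y >= n_classes))
    stop("labels must be integers in [0, ", n_classes - 1L, "]",
         call. = FALSE)
  as.integer(y)
}

#' Supervised fine-tuning of a deep belief network
#'
#' Unrolls the pretrained stack into a feed-forward network (sigmoid hidden
#' layers, softmax output) and minimises the multinomial cross-entropy by
#' mini-batch gradient descent with backpropagation through the whole
#' stack, including the RBM weights. Gradients follow the classic
#' delta-rule convention and accumulate over each mini-batch (the gradient
#' of the batch-summed cross-entropy), so the step size per update grows
#' with the batch size.
#'
#' @param model a `"dbn"` from [dbn_pretrain()].
#' @param x feature matrix on the original (unscaled) scale.
#' @param y integer class labels in `0..n_classes-1`, or a factor.
#' @param finetune_epochs gradient-descent epochs (default 100).
#' @param batch_size mini-batch size (default 100, clamped).
#' @param learning_rate step size (default 0.01; 0 leaves the model
#'   unchanged).
#' @param momentum momentum coefficient (default 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return the fine-tuned `"dbn"` with a per-epoch `loss_trace`.
#' @export
dbn_finetune <- function(model, x, y, finetune_epochs = 100L,
                         batch_size = 100L, learning_rate = 0.01,
                         momentum = 0, seed = NULL) {
  stopifnot(inherits(model, "dbn"))
  x <- as.matrix(x)
  if (is.factor(y)) {
    model$classes <- levels(y)
    y <- as.integer(y) - 1L
  }
  y <- .check_labels(y, model$n_classes)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  xs <- scale_features(x, model$scaler)$x
  n <- nrow(xs)
  batch_size <- min(batch_size, n)
  K <- model$n_classes
  L <- length(model$rbms)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  vel <- list(W = lapply(model$rbms, function(r) r$W * 0),
              b = lapply(model$rbms, function(r) r$hbias * 0),
              tW = model$top$W * 0, tb = model$top$b * 0)
  trace <- numeric(finetune_epochs)
  for (e in seq_len(finetune_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    loss_sum <- 0
    for (s in starts) {
      ix <- ord[s:min(s + batch_size - 1L, n)]
      fw <- .dbn_forward(model, xs[ix, , drop = FALSE])
      p <- fw$probs
      yb <- Y[ix, , drop = FALSE]
      loss_sum <- loss_sum - sum(yb * log(pmax(p, 1e-12)))
      # delta-rule convention: gradients accumulate over the mini-batch
      # (the gradient of the batch-summed cross-entropy)
      dlog <- p - yb
      aL <- fw$activations[[L + 1L]]
      g_tW <- crossprod(aL, dlog)
      g_tb <- colSums(dlog)
      delta <- (dlog %*% t(model$top$W)) * aL * (1 - aL)
      gW <- vector("list", L)
      gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        a_in <- fw$activations[[l]]
        gW[[l]] <- crossprod(a_in, delta)
        gb[[l]] <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(model$rbms[[l]]$W)) * a_in * (1 - a_in)
      }
      vel$tW <- momentum * vel$tW - learning_rate * g_tW
      vel$tb <- momentum * vel$tb - learning_rate * g_tb
      model$top$W <- model$top$W + vel$tW
      model$top$b <- model$top$b + vel$tb
      for (l in seq_len(L)) {
        vel$W[[l]] <- momentum * vel$W[[l]] - learning_rate * gW[[l]]
        vel$b[[l]] <- momentum * vel$b[[l]] - learning_rate * gb[[l]]
        model$rbms[[l]]$W <- model$rbms[[l]]$W + vel$W[[l]]
        model$rbms[[l]]$hbias <- model$rbms[[l]]$hbias + vel$b[[l]]
      }
    }
    trace[e] <- loss_sum / n
  }
  model$loss_trace <- trace
  model$finetuned <- TRUE
  model$config <- utils::modifyList(model$config,
                                    list(finetune_epochs = finetune_epochs))
  model
}

#' Fit a deep belief network classifier
#'
#' The package's classification model: a stack of restricted Boltzmann
#' machines is greedily pretrained by contrastive divergence
#' ([dbn_pretrain()]), topped with a softmax layer and fine-tuned end to
#' end by backpropagation ([dbn_finetune()]). Defaults follow the published
#' configuration: hidden layers `c(8, 6)`, 10 CD-1 epochs per layer, 100
#' fine-tuning epochs, batch size 100, learning rate 0.01, zero momentum,
#' sigmoid activations.
#'
#' @param x numeric feature matrix, one sample per row (e.g. fused texture
#'   descriptors from [extract_features()]).
#' @param y class labels: a factor, or integers in `0..K-1`.
#' @param layers hidden-layer sizes of the RBM stack.
#' @param rbm_epochs,finetune_epochs,batch_size,learning_rate,momentum
#'   training hyperparameters (see Details in [dbn_pretrain()] and
#'   [dbn_finetune()]).
#' @param seed integer seed making the whole fit reproducible.
#' @return object of class `"dbn"` with `predict`, `print`, `summary`,
#'   `plot` and `coef` methods.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 2), 20))
#' y <- factor(rep(c("a", "b"), each = 20))
#' fit <- dbn(x, y, layers = c(8, 6), finetune_epochs = 50, seed = 1)
#' mean(predict(fit, x) == y)
#' @export
dbn <- function(x, y, layers = c(8L, 6L), rbm_epochs = 10L,
                finetune_epochs = 100L, batch_size = 100L,
                learning_rate = 0.01, momentum = 0, seed = NULL) {
  x <- as.matrix(x)
  classes <- NULL
  if (is.factor(y)) {
    classes <- levels(y)
    y <- as.integer(y) - 1L
  }
  K <- max(length(classes), length(unique(y)), max(y) + 1L)
  if (!is.null(seed)) set.seed(seed)
  model <- dbn_pretrain(x, layers, n_classes = K, rbm_epochs = rbm_epochs,
                        batch_size = batch_size,
                        learning_rate = learning_rate, momentum = momentum)
  model$classes <- classes
  dbn_finetune(model, x, y, finetune_epochs = finetune_epochs,
               batch_size = batch_size, learning_rate = learning_rate,
               momentum = momentum)
}

#' Predict classes or class probabilities from a fitted DBN
#'
#' Inference is a deterministic mean-field forward pass: hidden
#' probabilities (never samples) flow through the stack into the softmax,
#' so repeated calls give identical results.
#'
#' @param object a `"dbn"`.
#' @param newdata feature matrix on the original scale.
#' @param type `"class"` for hard labels, `"prob"` for the class
#'   probability matrix (rows sum to 1).
#' @param ... unused.
#' @return factor (or integer vector when the model was fitted on integer
#'   labels) for `type = "class"`; numeric matrix for `type = "prob"`.
#' @export
predict.dbn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$scaler$min))
    stop("feature dimension mismatch: got ", ncol(newdata), ", expected ",
         length(object$scaler$min), call. = FALSE)
  xs <- scale_features(newdata, object$scaler)$x
  p <- .dbn_forward(object, xs)$probs
  if (!is.null(object$classes)) colnames(p) <- object$classes
  if (type == "prob") return(p)
  ix <- max.col(p, ties.method = "first")
  if (!is.null(object$classes))
    factor(object$classes[ix], levels = object$classes)
  else ix - 1L
}

#' @export
print.dbn <- function(x, ...) {
  cat("Deep belief network classifier\n")
  cat(sprintf("  architecture: %s -> %s -> %d classes\n",
              length(x$scaler$min), paste(x$layers, collapse = " -> "),
              x$n_classes))
  cat(sprintf("  pretrained (CD-1), %s\n",
              if (x$finetuned) "fine-tuned by backpropagation"
              else "not fine-tuned"))
  if (length(x$loss_trace))
    cat(sprintf("  final training cross-entropy: %.4f\n",
                x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
summary.dbn <- function(object, ...) {
  npar <- sum(vapply(object$rbms, function(r)
    length(r$W) + length(r$vbias) + length(r$hbias), 0)) +
    length(object$top$W) + length(object$top$b)
  structure(list(model = object, n_parameters = npar),
            class = "summary.dbn")
}

#' @export
print.summary.dbn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  parameters: %d\n", x$n_parameters))
  for (l in seq_along(x$model$rbms)) {
    e <- x$model$pretrain_errors[[l]]
    if (length(e))
      cat(sprintf("  RBM %d reconstruction error: %.5f -> %.5f\n",
                  l, e[1], e[length(e)]))
  }
  invisible(x)
}

#' @export
plot.dbn <- function(x, ...) {
  if (!length(x$loss_trace))
    stop("model has no fine-tuning loss trace to plot", call. = FALSE)
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "DBN fine-tuning", ...)
  invisible(x)
}

#' @export
coef.dbn <- function(object, ...) {
  c(lapply(seq_along(object$rbms), function(l) object$rbms[[l]]$W),
    list(top = object$top$W))
}

#' Serialise a fitted DBN to a portable JSON container
#'
#' Stores layer sizes, all weight matrices, the feature scaler, the class
#' labels and the training configuration with full numeric precision.
#'
#' @param model a `"dbn"`.
#' @param path output file path.
#' @export
write_dbn <- function(model, path) {
  payload <- list(
    layers = model$layers, n_classes = model$n_classes,
    classes = model$classes, finetuned = model$finetuned,
    config = model$config, loss_trace = model$loss_trace,
    scaler = model$scaler,
    rbms = lapply(model$rbms, function(r)
      list(W = r$W, vbias = r$vbias, hbias = r$hbias)),
    top = model$top)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a DBN serialised by [write_dbn()]
#'
#' @param path JSON file path.
#' @return a `"dbn"` object.
#' @export
read_dbn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  rbms <- lapply(p$rbms, function(r)
    list(W = as.matrix(r$W), vbias = as.numeric(r$vbias),
         hbias = as.numeric(r$hbias)))
  structure(list(rbms = rbms,
                 top = list(W = as.matrix(p$top$W), b = unlist(p$top$b)),
                 scaler = list(min = unlist(p$scaler$min),
                               range = unlist(p$scaler$range)),
                 layers = as.integer(p$layers),
                 n_classes = as.integer(p$n_classes),
                 classes = if (length(p$classes))
                   as.character(unlist(p$classes)) else NULL,
                 pretrain_errors = list(),
                 loss_trace = unlist(p$loss_trace),
                 finetuned = isTRUE(p$finetuned),
                 config = p$config),
            class = "dbn")
}
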