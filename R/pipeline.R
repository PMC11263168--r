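#' End-to-end pipeline configuration
#'
#' Bundles the per-stage settings of [run_pipeline()]. All randomness in a
#' run (phantom generation, threshold search, train/test split, classifier
#' training) is derived deterministically from the single `seed`, so a run
#' is a pure function of its inputs and configuration.
#'
#' @param seed master seed of the run (default 7).
#' @param n_per_class phantom samples per class when simulating (default
#'   50).
#' @param method threshold search: `"tsa"` (default) or `"exhaustive"`.
#' @param phantom a [phantom_spec()]; its seed is overridden by `seed`.
#' @param tsa a [tsa_config()] used as template for per-image searches.
#' @param grid_rows,grid_cols descriptor block grid (default 4x4).
#' @param ldp_k prominent directions of the LDP code (default 3).
#' @param dbn list of [dbn()] hyperparameters.
#' @param train_fraction stratified train fraction in (0, 1), default 0.8.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 7L, n_per_class = 50L, method = "tsa",
                            phantom = phantom_spec(),
                            tsa = tsa_config(),
                            grid_rows = 4L, grid_cols = 4L, ldp_k = 3L,
                            dbn = list(layers = c(8L, 6L), rbm_epochs = 10L,
                                       finetune_epochs = 100L,
                                       batch_size = 100L,
                                       learning_rate = 0.01, momentum = 0),
                            train_fraction = 0.8) {
  method <- match.arg(method, c("tsa", "exhaustive"))
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class), method = method,
                 phantom = phantom, tsa = tsa,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 ldp_k = as.integer(ldp_k), dbn = dbn,
                 train_fraction = train_fraction),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML document whose top-level keys mirror the arguments of
#' [pipeline_config()] (with `phantom` and `tsa` as nested maps) and
#' merges it over the defaults.
#'
#' @param path YAML file path.
#' @return a `"pipeline_config"`.
#' @export
load_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("package 'yaml' is required to read configuration files",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("phantom", "tsa", "dbn"))]
  if (!is.null(y$phantom)) {
    if (!is.null(y$phantom$image_size))
      y$phantom$image_size <- as.integer(unlist(y$phantom$image_size))
    args$phantom <- do.call(phantom_spec, y$phantom)
  }
  if (!is.null(y$tsa)) args$tsa <- do.call(tsa_config, y$tsa)
  if (!is.null(y$dbn)) {
    d <- formals(pipeline_config)$dbn
    args$dbn <- utils::modifyList(eval(d), y$dbn)
    args$dbn$layers <- as.integer(unlist(args$dbn$layers))
  }
  do.call(pipeline_config, args)
}

#' Stratified train/test split
#'
#' Samples a per-class proportional split: every class contributes
#' `round(train_fraction * n_k)` training samples (at least 1, leaving at
#' least 1 for testing). The index sets are disjoint and cover all samples.
#'
#' @param labels vector of class labels.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  train <- integer(0)
  for (k in unique(labels)) {
    ix <- which(labels == k)
    if (length(ix) < 2L)
      stop("class ", k, " has fewer than 2 samples", call. = FALSE)
    n_tr <- min(max(round(train_fraction * length(ix)), 1L),
                length(ix) - 1L)
    train <- c(train, sort(sample(ix, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# read an image/mask/label dataset written by generate_dataset()
.read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop("input directory has no manifest.csv: ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (is.null(manifest$label))
    stop("manifest has no `label` column; labels are required for training",
         call. = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_grayscale(file.path(dir, manifest$image_file[i]))
    msk <- if (!is.null(manifest$mask_file) &&
               file.exists(file.path(dir, manifest$mask_file[i])))
      read_mask(file.path(dir, manifest$mask_file[i]))
    list(image = img, mask = msk, label = manifest$label[i])
  })
  list(samples = samples, manifest = manifest)
}

#' Run the full segmentation-and-classification pipeline
#'
#' Executes the processing chain on a phantom dataset (simulated from the
#' configuration) or on an image directory with a `manifest.csv`:
#' per-image Otsu threshold search (swarm or exhaustive), mask generation,
#' fused LBP + LDPv descriptor extraction from the segmented region,
#' stratified split, DBN training, held-out prediction, and segmentation /
#' classification metrics. When ground-truth masks are available the
#' per-image Jaccard, Dice and pixel-accuracy scores are aggregated.
#'
#' The returned report (also written as `report.json` when `output_dir` is
#' given) contains only run-deterministic content; wall-clock timings go to
#' a separate `log.txt` so that reports from identical runs are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param input_dir optional directory with images, optional masks and a
#'   `manifest.csv`; when `NULL` a phantom dataset is simulated.
#' @param output_dir optional directory for artifacts (masks, features
#'   CSV, model JSON, report JSON, log).
#' @return the run report (class `"adseg_report"`), invisibly a list.
#' @export
run_pipeline <- function(config = pipeline_config(), input_dir = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  if (is.null(input_dir)) {
    spec <- config$phantom
    spec$seed <- config$seed
    ds <- generate_dataset(spec, config$n_per_class)
    samples <- ds$samples
  } else {
    ds <- .read_dataset(input_dir)
    samples <- ds$samples
  }
  labels <- vapply(samples, function(s) as.integer(s$label), 0L)
  n <- length(samples)
  tick("data")

  thresholds <- integer(n)
  seg <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("jsc", "dsc", "pa")))
  pred_masks <- vector("list", n)
  for (i in seq_len(n)) {
    h <- compute_histogram(samples[[i]]$image)
    thr <- if (config$method == "tsa") {
      cfg <- config$tsa
      cfg$seed <- .derive_seed(config$seed + 1, i)
      otsu_tsa(h, cfg)
    } else {
      otsu_exhaustive(h)
    }
    thresholds[i] <- thr$threshold
    pred_masks[[i]] <- apply_threshold(samples[[i]]$image, thr$threshold)
    if (!is.null(samples[[i]]$mask)) {
      m <- segmentation_metrics(pred_masks[[i]], samples[[i]]$mask)
      seg[i, ] <- c(m$jsc, m$dsc, m$pa)
    }
  }
  tick("segment")

  features <- t(vapply(seq_len(n), function(i)
    extract_features(samples[[i]]$image, pred_masks[[i]], k = config$ldp_k,
                     grid_rows = config$grid_rows,
                     grid_cols = config$grid_cols),
    numeric((256 + choose(8, config$ldp_k)) *
              config$grid_rows * config$grid_cols)))
  tick("extract")

  split <- stratified_split(labels, config$train_fraction,
                            seed = .derive_seed(config$seed + 2, 1))
  d <- config$dbn
  model <- dbn(features[split$train, , drop = FALSE],
               labels[split$train] - 1L,
               layers = d$layers, rbm_epochs = d$rbm_epochs,
               finetune_epochs = d$finetune_epochs,
               batch_size = d$batch_size,
               learning_rate = d$learning_rate, momentum = d$momentum,
               seed = .derive_seed(config$seed + 3, 1))
  tick("train")

  pred <- predict(model, features[split$test, , drop = FALSE])
  cm <- classification_metrics(labels[split$test] - 1L, pred,
                               n_classes = max(labels))
  tick("predict")

  have_gt <- !anyNA(seg[, 1])
  report <- list(
    seed = config$seed,
    n_images = n,
    method = config$method,
    thresholds = list(mean = mean(thresholds), sd = stats::sd(thresholds),
                      min = min(thresholds), max = max(thresholds)),
    segmentation = if (have_gt)
      list(mean_jsc = mean(seg[, "jsc"]), mean_dsc = mean(seg[, "dsc"]),
           mean_pa = mean(seg[, "pa"]), sd_dsc = stats::sd(seg[, "dsc"]))
    else NULL,
    feature_dim = ncol(features),
    split = list(n_train = length(split$train), n_test = length(split$test)),
    training = list(first_loss = model$loss_trace[1],
                    final_loss = model$loss_trace[length(model$loss_trace)]),
    classification = list(accuracy = cm$accuracy,
                          sensitivity = cm$sensitivity,
                          specificity = cm$specificity))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    mask_dir <- file.path(output_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (i in seq_len(n))
      write_mask(pred_masks[[i]],
                 file.path(mask_dir, sprintf("mask_%03d.png", i)))
    utils::write.csv(
      data.frame(label = labels, threshold = thresholds, features,
                 check.names = FALSE),
      file.path(output_dir, "features.csv"), row.names = FALSE)
    write_dbn(model, file.path(output_dir, "model.json"))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    tick("write")
    writeLines(c(sprintf("adseg pipeline run, seed %d", config$seed),
                 sprintf("%-8s %8.2f s", names(timings),
                         unlist(timings))),
               file.path(output_dir, "log.txt"))
  }
  structure(report, class = c("adseg_report", class(report)))
}

#' @export
print.adseg_report <- function(x, ...) {
  cat(sprintf("adseg pipeline report (%d images, method %s, seed %d)\n",
              x$n_images, x$method, x$seed))
  cat(sprintf("  thresholds: mean %.1f (range %d..%d)\n",
              x$thresholds$mean, x$thresholds$min, x$thresholds$max))
  if (!is.null(x$segmentation))
    cat(sprintf("  segmentation: JSC %.3f, DSC %.3f, PA %.3f\n",
                x$segmentation$mean_jsc, x$segmentation$mean_dsc,
                x$segmentation$mean_pa))
  cat(sprintf("  classification (held out, n=%d): accuracy %.1f%%, ",
              x$split$n_test, x$classification$accuracy))
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%%\n",
              x$classification$sensitivity, x$classification$specificity))
  invisible(x)
}
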