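## Training, prediction and evaluation orchestration: configuration,
## Adam optimization of the deep-supervision loss, JSON-lines logging,
## checkpointing, and PNG prediction output.

#' Training configuration
#'
#' @param input_size square model input size, divisible by 32 (default
#'   352).
#' @param backbone a [backbone_spec()].
#' @param epochs,batch_size optimization schedule.
#' @param learning_rate Adam step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed RNG seed governing initialization and data order.
#' @param reduce decoder channel width.
#' @param weight_kernel,weight_gain boundary-weight-map pooling kernel and
#'   gain.
#' @param threshold binarization threshold for evaluation/prediction.
#' @param output_dir where checkpoints and logs are written.
#' @return an object of class `train_config`.
#' @export
train_config <- function(input_size = 352L, backbone = backbone_spec(),
                         epochs = 50L, batch_size = 8L,
                         learning_rate = 1e-4,
                         optimizer = c("adam", "sgd"), seed = 0L,
                         reduce = 32L, weight_kernel = 31L,
                         weight_gain = 5, threshold = 0.5,
                         output_dir = tempfile("ppaseg_run_")) {
  optimizer <- match.arg(optimizer)
  input_size <- as.integer(input_size)
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(input_size = input_size, backbone = backbone,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), reduce = as.integer(reduce),
                 weight_kernel = as.integer(weight_kernel),
                 weight_gain = weight_gain, threshold = threshold,
                 output_dir = output_dir),
            class = "train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in seq_along(params)) {
    p <- params[[k]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  st
}

sgd_step <- function(params, lr) {
  for (p in params) if (!is.null(p$grad)) p$value <- p$value - lr * p$grad
  invisible(NULL)
}

## Load training samples (image/mask/edge) from a manifest data frame or
## accept a list of in-memory fundus samples; resizes to the model input
## size (masks by nearest-equivalent thresholded bilinear).
load_training_samples <- function(manifest, input_size) {
  raw <- if (is.data.frame(manifest)) {
    lapply(seq_len(nrow(manifest)), function(i) {
      list(image = read_image_png(manifest$image_path[i]),
           mask = round(read_image_png(manifest$mask_path[i])),
           edge = round(read_image_png(manifest$edge_path[i])))
    })
  } else {
    lapply(manifest, function(s) list(image = s$image, mask = s$mask,
                                      edge = s$edge))
  }
  lapply(raw, function(s) {
    if (!identical(dim(s$image), c(input_size, input_size))) {
      s$image <- resize_matrix(s$image, input_size, input_size)
      s$mask <- (resize_matrix(s$mask, input_size, input_size) >= 0.5) * 1
      s$edge <- (resize_matrix(s$edge, input_size, input_size) >= 0.5) * 1
    }
    s
  })
}

#' Train the segmentation network
#'
#' Optimizes the deep-supervision total loss (boundary-weighted IoU + BCE
#' on the global and three side outputs, plus the edge-branch BCE) with
#' Adam (or SGD). Fully seeded: initialization, shuffling and hence the
#' final weights are reproducible.
#'
#' @param config a [train_config()].
#' @param manifest training manifest data frame (columns `image_path`,
#'   `mask_path`, `edge_path`) or list of in-memory samples with `image`,
#'   `mask`, `edge`.
#' @param steps optional cap on the total number of optimization steps
#'   (across epochs); `NULL` runs `epochs` full epochs.
#' @param verbose print per-epoch losses.
#' @return list with `model`, `log` (per-step data frame of loss terms),
#'   `config`; a checkpoint and a JSON-lines log are written to
#'   `config$output_dir`.
#' @export
train_model <- function(config, manifest, steps = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  samples <- load_training_samples(manifest, config$input_size)
  if (length(samples) == 0) stop("no training samples")
  pool <- pooling_spec(config$weight_kernel)
  model <- with_local_seed(config$seed,
                           ppa_unet(config$backbone, config$reduce))
  params <- module_params(model)
  opt <- if (config$optimizer == "adam") adam_state(params) else NULL
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "train_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_rows <- list()
  step <- 0L
  max_steps <- if (is.null(steps)) .Machine$integer.max else as.integer(steps)
  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      if (step >= max_steps) break
      order_idx <- sample(length(samples))
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / config$batch_size))
      for (bi in seq_along(batches)) {
        if (step >= max_steps) break
        idx <- batches[[bi]]
        pt_zero_grad(params)
        terms_acc <- NULL
        total_val <- 0
        for (i in idx) {
          s <- samples[[i]]
          x <- pt_const(image_to_input(s$image))
          out <- model_forward_nodes(model, x, training = TRUE)
          L <- ad_total_loss(out$up, s$mask, s$edge, pool,
                             config$weight_gain)
          if (!is.finite(L$total$value)) {
            stop(sprintf(
              "NaN/Inf loss at step %d (terms: %s)", step + 1L,
              paste(names(L$terms), signif(L$terms, 4), sep = "=",
                    collapse = ", ")))
          }
          scaled <- op_scale(L$total, 1 / length(idx))
          pt_backward(scaled)
          total_val <- total_val + L$total$value / length(idx)
          terms_acc <- if (is.null(terms_acc)) L$terms / length(idx)
                       else terms_acc + L$terms / length(idx)
        }
        if (config$optimizer == "adam") {
          opt <- adam_step(params, opt, config$learning_rate)
        } else {
          sgd_step(params, config$learning_rate)
        }
        step <- step + 1L
        row <- c(list(epoch = epoch, step = step, total = total_val),
                 as.list(terms_acc))
        log_rows[[step]] <- as.data.frame(row)
        cat(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), "\n",
            sep = "", file = log_path, append = TRUE)
      }
      if (verbose) {
        message(sprintf("epoch %d/%d: total loss %.4f", epoch,
                        config$epochs, total_val))
      }
    }
  })
  log <- do.call(rbind, log_rows)
  res <- list(model = model, log = log, config = config)
  save_checkpoint(res, file.path(config$output_dir, "checkpoint.rds"))
  res
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the numeric weight state, batch-norm running
#' statistics, the training configuration and its seed; loading rebuilds
#' the model and restores the state bit-for-bit.
#'
#' @param fit result of [train_model()] (or a list with `model`, `config`).
#' @param path RDS file path.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(list(state = module_state(fit$model),
               config = fit$config,
               log = fit$log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  ck <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot load checkpoint ", path, ": ", conditionMessage(e))
  })
  if (is.null(ck$state) || is.null(ck$config)) {
    stop("corrupt checkpoint: missing state or config")
  }
  model <- with_local_seed(ck$config$seed,
                           ppa_unet(ck$config$backbone, ck$config$reduce))
  module_set_state(model, ck$state)
  list(model = model, config = ck$config, log = ck$log)
}

#' Predict probability and binary masks for images
#'
#' Each image is resized to the configured input size, passed through the
#' network, and the probability map is resized back to the original image
#' size; an 8-bit probability PNG and a thresholded binary PNG are
#' written per image. Probabilities are clamped to the open unit interval
#' (the same epsilon the losses use), so threshold 0 yields an all-ones
#' mask and threshold 1 an all-zeros mask.
#'
#' @param fit a fit/checkpoint list with `model` and `config`.
#' @param images character vector of PNG paths, or list of matrices.
#' @param threshold binarization threshold (default from the config).
#' @param out_dir output directory; `NULL` returns maps without writing.
#' @return list per image: `prob`, `bin`, and (if written) `prob_path`,
#'   `bin_path`.
#' @export
predict_model <- function(fit, images, threshold = NULL, out_dir = NULL) {
  model <- fit$model; config <- fit$config
  if (is.null(threshold)) threshold <- config$threshold
  if (is.character(images)) {
    names_in <- tools::file_path_sans_ext(basename(images))
    images <- lapply(images, read_image_png)
  } else {
    if (is.matrix(images)) images <- list(images)
    names_in <- sprintf("image_%03d", seq_along(images))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  lapply(seq_along(images), function(i) {
    img <- images[[i]]
    d0 <- dim(img)
    x <- resize_matrix(img, config$input_size, config$input_size)
    prob <- ppa_unet_forward(model, x)$prob
    prob <- clamp01(resize_matrix(prob, d0[1], d0[2]))
    bin <- (prob >= threshold) * 1
    out <- list(prob = prob, bin = bin)
    if (!is.null(out_dir)) {
      out$prob_path <- write_image_png(
        prob, file.path(out_dir, paste0(names_in[i], "_prob.png")))
      out$bin_path <- write_image_png(
        bin, file.path(out_dir, paste0(names_in[i], "_mask.png")))
    }
    out
  })
}

#' Evaluate a checkpoint on a manifest and write metric reports
#'
#' Delegates to [evaluate_model()]; writes one CSV row per stratum and a
#' JSON report.
#'
#' @param fit a fit/checkpoint list with `model` and `config`.
#' @param manifest manifest data frame or CSV path.
#' @param threshold binarization threshold (default from the config).
#' @param out_dir where `metrics.csv` / `metrics.json` are written;
#'   `NULL` skips writing.
#' @return the metric report data frame.
#' @export
eval_checkpoint <- function(fit, manifest, threshold = NULL,
                            out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(threshold)) threshold <- fit$config$threshold
  report <- evaluate_model(fit$model, manifest, threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  report
}
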