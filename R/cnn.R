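#' 3D CNN model configuration
#'
#' The regressor is a VGG-style 3D backbone: four convolutional groups of
#' 2/2/3/3 layers (10 conv layers in total), each conv 3x3x3 with batch
#' normalization before the ReLU, each group closed by a kernel-2 max pooling;
#' the two 3-layer groups aggregate the outputs of their first and second
#' layers (elementwise sum) before the third layer (residual aggregation);
#' the pooled features are flattened into two tanh fully connected layers and
#' a sigmoid output head with a trainable sharpness `eta`, one output per
#' task. At full scale the channel plan is 16/32/64/128 with 1024-wide FC
#' layers on 112^3 inputs; the desk scale uses 4/8/16/32 channels, 64-wide FC
#' layers and 32^3 inputs.
#'
#' @param extent input spatial extent (cube side); must be divisible by 16
#'   (four pooling stages of kernel 2).
#' @param channels channel count per conv group (strictly increasing,
#'   length 4).
#' @param layers conv layers per group (default 2, 2, 3, 3).
#' @param fc_widths widths of the two fully connected layers.
#' @param n_tasks number of regression outputs (>= 1).
#' @param batch_size mini-batch size (8, as at full scale).
#' @param lr_max,lr_min learning-rate bounds of the cosine schedule. The
#'   full-scale study values are 0.01 and 0.0001; the desk default lowers the
#'   peak to 0.001 because a 200-subject cohort takes only ~20 Adam steps per
#'   epoch and the full-scale peak rate destabilizes such short epochs
#'   (the network collapses to predicting the task means).
#' @param cycle_length epochs per cosine annealing cycle (warm restart at
#'   every cycle start); the desk default is a single cycle.
#' @param epochs training epochs; a checkpoint is recorded every epoch.
#' @param eta0 initial output sharpness.
#' @return An object of class `cnn_config`.
#' @export
cnn_model_config <- function(extent = 32L,
                             channels = c(4L, 8L, 16L, 32L),
                             layers = c(2L, 2L, 3L, 3L),
                             fc_widths = c(64L, 64L),
                             n_tasks = 4L,
                             batch_size = 8L,
                             lr_max = 0.001, lr_min = 0.0001,
                             cycle_length = 15L,
                             epochs = 15L,
                             eta0 = 1.0) {
  if (extent %% 2^length(channels) != 0)
    stop("extent must be divisible by 2^", length(channels),
         " (one pooling stage per conv group)")
  if (any(diff(channels) <= 0)) stop("channel plan must be strictly increasing")
  if (n_tasks < 1) stop("n_tasks must be >= 1")
  if (lr_min > lr_max) stop("lr_min must be <= lr_max")
  if (cycle_length < 1) stop("cycle_length must be >= 1")
  structure(list(extent = as.integer(extent), channels = as.integer(channels),
                 layers = as.integer(layers),
                 fc_widths = as.integer(fc_widths),
                 n_tasks = as.integer(n_tasks),
                 batch_size = as.integer(batch_size),
                 lr_max = lr_max, lr_min = lr_min,
                 cycle_length = as.integer(cycle_length),
                 epochs = as.integer(epochs), eta0 = eta0),
            class = "cnn_config")
}

#' Full-scale model configuration
#'
#' Channel plan 16/32/64/128, 1024-wide FC layers, 112^3 single-channel
#' inputs, four tasks, learning rate annealed between 0.01 and 0.0001 in
#' 10-epoch warm-restart cycles.
#'
#' @param ... overrides passed to [cnn_model_config()].
#' @return A `cnn_config`.
#' @export
cnn_full_scale_config <- function(...) {
  cnn_model_config(extent = 112L, channels = c(16L, 32L, 64L, 128L),
                   fc_widths = c(1024L, 1024L), lr_max = 0.01,
                   lr_min = 0.0001, cycle_length = 10L, epochs = 60L, ...)
}

#' Sigmoid activation with trainable sharpness
#'
#' `1 / (1 + exp(-eta * x))`, the output activation of the regressor;
#' numerically stable for large `|eta * x|`. `eta = 0` degenerates to the
#' constant 1/2.
#'
#' @param x pre-activation values.
#' @param eta sharpness (finite).
#' @return values in (0, 1).
#' @export
custom_sigmoid <- function(x, eta = 1) {
  if (!is.finite(eta)) stop("eta must be finite")
  z <- eta * x
  out <- ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z)))
  out
}

#' Cosine-annealing learning rate with warm restarts
#'
#' `lr_min + (lr_max - lr_min) / 2 * (1 + cos(pi * t / cycle_length))` with
#' `t = step mod cycle_length`: the rate decays from `lr_max` towards `lr_min`
#' within each cycle and jumps back to `lr_max` at every cycle start.
#'
#' @param step 0-based step (here: epoch) index.
#' @param cycle_length steps per cycle (>= 1).
#' @param lr_max,lr_min learning-rate bounds, `lr_min <= lr_max`.
#' @return learning rate at `step`.
#' @export
cosine_annealing_lr <- function(step, cycle_length, lr_max = 0.01,
                                lr_min = 0.0001) {
  if (cycle_length < 1) stop("cycle_length must be >= 1")
  if (lr_min > lr_max) stop("lr_min must be <= lr_max")
  t <- step %% cycle_length
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / cycle_length))
}

#' Build the 3D CNN
#'
#' Instantiates the network described by a [cnn_model_config()] and
#' initializes its weights (He-normal for conv layers, Glorot-normal for the
#' FC layers, unit batch-norm scale, `eta = eta0`), seeded for
#' reproducibility.
#'
#' @param config a `cnn_config`.
#' @param seed integer seed for weight initialization.
#' @return An object of class `cnn_model` (external model handle plus config).
#' @export
build_cnn <- function(config, seed = 1L) {
  ptr <- cnn_create(config$extent, config$channels, config$layers,
                    config$fc_widths, config$n_tasks)
  params <- with_seed(seed, init_params(config))
  cnn_set_params(ptr, params)
  structure(list(ptr = ptr, config = config, seed = seed),
            class = "cnn_model")
}

init_params <- function(config) {
  convs <- list()
  in_ch <- 1L
  li <- 0L
  for (g in seq_along(config$channels)) {
    for (l in seq_len(config$layers[g])) {
      out_ch <- config$channels[g]
      fan_in <- 27L * in_ch
      li <- li + 1L
      convs[[li]] <- list(
        W = matrix(rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)),
                   out_ch, fan_in),
        gamma = rep(1, out_ch), beta = rep(0, out_ch),
        rmean = rep(0, out_ch), rvar = rep(1, out_ch))
      in_ch <- out_ch
    }
  }
  ext_out <- config$extent / 2^length(config$channels)
  flat <- ext_out^3 * config$channels[length(config$channels)]
  glorot <- function(fi, fo) matrix(rnorm(fi * fo, 0, sqrt(2 / (fi + fo))),
                                    fi, fo)
  list(convs = convs,
       W1 = glorot(flat, config$fc_widths[1]),
       b1 = matrix(0, 1, config$fc_widths[1]),
       W2 = glorot(config$fc_widths[1], config$fc_widths[2]),
       b2 = matrix(0, 1, config$fc_widths[2]),
       Wo = glorot(config$fc_widths[2], config$n_tasks),
       bo = matrix(0, 1, config$n_tasks),
       eta = config$eta0)
}

#' Number of convolutional layers in a built model
#'
#' Counts the 3x3x3 convolution layers of the instantiated network (pooling
#' and FC layers excluded).
#'
#' @param model a `cnn_model`.
#' @return integer count.
#' @export
n_conv_layers <- function(model) cnn_n_conv_layers(model$ptr)

#' Trace the shape of a forward pass
#'
#' Runs one volume through the built network and reports, from the actual
#' tensors, the spatial extent and channel count after each conv group and the
#' length of the flattened feature vector entering FC1.
#'
#' @param model a `cnn_model`.
#' @param volume a `brain_volume` (or a numeric array/vector of matching
#'   voxel count); defaults to a zero volume.
#' @return list with `group_extent`, `group_channels`, `flatten_length`,
#'   `prediction`.
#' @export
model_trace <- function(model, volume = NULL) {
  nvox <- model$config$extent^3
  x <- if (is.null(volume)) numeric(nvox) else volumes_to_matrix(list(volume))
  cnn_trace(model$ptr, matrix(as.numeric(x), nvox, 1))
}

#' Stack volumes into the network's input matrix
#'
#' @param volumes list of `brain_volume`s (or plain 3D arrays).
#' @return numeric matrix, one column of `nvox` voxels per volume.
#' @export
volumes_to_matrix <- function(volumes) {
  cols <- lapply(volumes, function(v) {
    d <- if (inherits(v, "brain_volume")) v$data else v
    as.numeric(d)
  })
  do.call(cbind, cols)
}

# Scale raw per-task targets to [0, 1] given the scales table.
scale_targets <- function(y_raw, tasks, scales) {
  smin <- stats::setNames(scales$min, scales$score)
  smax <- stats::setNames(scales$max, scales$score)
  sc <- sapply(tasks, function(s) (y_raw[, s] - smin[[s]]) /
                 (smax[[s]] - smin[[s]]))
  matrix(sc, ncol = length(tasks), dimnames = list(NULL, tasks))
}

unscale_targets <- function(y01, tasks, scales) {
  smin <- stats::setNames(scales$min, scales$score)
  smax <- stats::setNames(scales$max, scales$score)
  out <- sapply(seq_along(tasks), function(j)
    y01[, j] * (smax[[tasks[j]]] - smin[[tasks[j]]]) + smin[[tasks[j]]])
  matrix(out, ncol = length(tasks), dimnames = list(NULL, tasks))
}

#' Train the multi-task 3D CNN
#'
#' Minimizes the mean over tasks of the per-task MSE between the sigmoid
#' outputs and the min-max-scaled targets, using Adam under the
#' cosine-annealing schedule (one schedule step per epoch, warm restart each
#' cycle). After every epoch a checkpoint (weights + batch-norm statistics +
#' test-set MSE) is recorded. Shuffling is driven by the R RNG, so a fixed
#' seed reproduces the trajectory on a fixed machine.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param x_train,x_test `nvox x n` numeric matrices (see
#'   [volumes_to_matrix()]).
#' @param y_train,y_test `n x n_tasks` matrices of targets scaled to
#'   `[0, 1]`.
#' @param seed integer seed controlling batch order.
#' @param verbose print per-epoch progress.
#' @return list of checkpoints: each has `epoch`, `train_loss`, `test_mse`
#'   (mean over tasks), `test_mse_task`, `params`.
#' @export
train_cnn <- function(model, x_train, y_train, x_test, y_test, seed = 1L,
                      verbose = FALSE) {
  cfg <- model$config
  stopifnot(nrow(y_train) == ncol(x_train), ncol(y_train) == cfg$n_tasks)
  n <- ncol(x_train)
  checkpoints <- vector("list", cfg$epochs)
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- cosine_annealing_lr(ep - 1L, cfg$cycle_length, cfg$lr_max,
                                cfg$lr_min)
      ord <- sample.int(n)
      loss <- cnn_train_epoch(model$ptr, x_train, y_train, ord,
                              cfg$batch_size, lr)
      mse_t <- cnn_eval_mse(model$ptr, x_test, y_test, cfg$batch_size)
      checkpoints[[ep]] <- list(epoch = ep, train_loss = loss,
                                test_mse = mean(mse_t), test_mse_task = mse_t,
                                params = cnn_get_params(model$ptr))
      if (verbose)
        message(sprintf("epoch %2d lr %.5f train %.5f test %.5f",
                        ep, lr, loss, mean(mse_t)))
    }
  })
  checkpoints
}

#' Select the best-k checkpoint ensemble
#'
#' Sorts checkpoints by test-set MSE (ascending, ties broken by earlier
#' epoch) and keeps the best `min(k_max, available)` members; when fewer than
#' `k_min` checkpoints exist, all are kept with a warning.
#'
#' @param checkpoints list from [train_cnn()].
#' @param config the `cnn_config` the checkpoints were trained under.
#' @param scales per-score scale table used to map predictions back to raw
#'   units.
#' @param tasks character vector of task (sub-score) names.
#' @param k_min,k_max ensemble size bounds (5-7 by default).
#' @return An object of class `cnn_ensemble`.
#' @export
select_ensemble <- function(checkpoints, config, scales, tasks,
                            k_min = 5L, k_max = 7L) {
  if (!length(checkpoints)) stop("no checkpoints to select from")
  mse <- vapply(checkpoints, function(cp) cp$test_mse, numeric(1))
  ep <- vapply(checkpoints, function(cp) cp$epoch, numeric(1))
  ord <- order(mse, ep)
  k <- min(k_max, length(checkpoints))
  if (length(checkpoints) < k_min)
    warning("only ", length(checkpoints), " checkpoints available; ",
            "keeping all (fewer than the intended minimum of ", k_min, ")")
  members <- lapply(checkpoints[ord[seq_len(k)]], function(cp)
    list(epoch = cp$epoch, test_mse = cp$test_mse, params = cp$params))
  structure(list(members = members, config = config, scales = scales,
                 tasks = tasks),
            class = "cnn_ensemble")
}

#' @export
print.cnn_ensemble <- function(x, ...) {
  cat("cnn_ensemble:", length(x$members), "members; test MSE",
      paste(signif(vapply(x$members, `[[`, numeric(1), "test_mse"), 3),
            collapse = ", "), "\n")
  invisible(x)
}

ensemble_forward <- function(ensemble, x, what = c("prediction", "embedding")) {
  what <- match.arg(what)
  cfg <- ensemble$config
  ptr <- cnn_create(cfg$extent, cfg$channels, cfg$layers, cfg$fc_widths,
                    cfg$n_tasks)
  out <- lapply(ensemble$members, function(m) {
    cnn_set_params(ptr, m$params)
    if (what == "prediction") cnn_forward(ptr, x, cfg$batch_size)
    else cnn_embed(ptr, x, cfg$batch_size)
  })
  out
}

#' Predict sub-scores with a checkpoint ensemble
#'
#' The ensemble prediction per subject and task is the arithmetic mean of the
#' member outputs (in scaled units), mapped back to the original sub-score
#' scale.
#'
#' @param object a `cnn_ensemble`.
#' @param volumes list of `brain_volume`s, or an `nvox x n` matrix.
#' @param subject_ids optional ids for the returned table.
#' @param y_true optional `n x n_tasks` matrix of true raw scores to include.
#' @param ... unused.
#' @return data.frame with `subject_id`, `task`, `y_pred` (raw scale) and,
#'   when supplied, `y_true`.
#' @export
predict.cnn_ensemble <- function(object, volumes, subject_ids = NULL,
                                 y_true = NULL, ...) {
  x <- if (is.matrix(volumes)) volumes else volumes_to_matrix(volumes)
  preds <- ensemble_forward(object, x, "prediction")
  p01 <- Reduce(`+`, preds) / length(preds)
  praw <- unscale_targets(p01, object$tasks, object$scales)
  n <- ncol(x)
  if (is.null(subject_ids)) {
    subject_ids <- if (!is.matrix(volumes))
      vapply(volumes, function(v) v$subject_id, character(1))
    else sprintf("S%04d", seq_len(n))
  }
  out <- data.frame(
    subject_id = rep(subject_ids, times = length(object$tasks)),
    task = rep(object$tasks, each = n),
    y_pred = as.vector(praw), stringsAsFactors = FALSE)
  if (!is.null(y_true)) out$y_true <- as.vector(as.matrix(y_true))
  out
}

#' Penultimate-layer (FC2) embeddings
#'
#' Extracts, for every ensemble member, the FC2 activation vector of each
#' volume: the deep-learning features reused by the diagnostic extension.
#'
#' @param ensemble a `cnn_ensemble`.
#' @param volumes list of `brain_volume`s or an `nvox x n` matrix.
#' @return list of `n x fc2_width` matrices, one per ensemble member.
#' @export
extract_embeddings <- function(ensemble, volumes) {
  x <- if (is.matrix(volumes)) volumes else volumes_to_matrix(volumes)
  ensemble_forward(ensemble, x, "embedding")
}
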