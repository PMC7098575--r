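#' Model specification
#'
#' Bundles the architecture and the phase-specific training hyper-parameters
#' of a CNN or MLNN, including the pre-training and fine-tuning learning
#' rates, batch sizes and epoch counts that the transfer-learning procedure
#' optimises jointly.
#'
#' @param kind `"cnn"` or `"mlnn"`.
#' @param conv_filters,kernel_sizes,pool_sizes Integer vectors, one entry per
#'   convolutional block (CNN only). `pool_sizes` of 1 disables pooling for
#'   that block.
#' @param dense_units Integer vector of hidden dense-layer widths.
#' @param dropout Dropout rate in `[0, 1)` applied after each hidden dense
#'   layer.
#' @param batch_norm Use batch normalization before each hidden dense
#'   activation (the MLNN convention).
#' @param lr_pretrain,lr_finetune Learning rates (> 0) for the two phases.
#' @param batch_pretrain,batch_finetune Mini-batch sizes.
#' @param epochs_pretrain,epochs_finetune Epoch counts (0 fine-tuning epochs
#'   returns the pre-trained model unchanged).
#' @param seed Integer seed for weight initialization and mini-batch order.
#' @return An object of class `gx_model_spec`.
#' @export
model_spec <- function(kind = c("cnn", "mlnn"),
                       conv_filters = 8, kernel_sizes = 5, pool_sizes = 2,
                       dense_units = 16, dropout = 0, batch_norm = kind == "mlnn",
                       lr_pretrain = 1e-3, lr_finetune = 5e-4,
                       batch_pretrain = 32, batch_finetune = 16,
                       epochs_pretrain = 10, epochs_finetune = 10,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "cnn") {
    nb <- length(conv_filters)
    if (length(kernel_sizes) != nb || length(pool_sizes) != nb) {
      stop("conv_filters, kernel_sizes and pool_sizes must have equal length",
           call. = FALSE)
    }
  }
  if (any(c(lr_pretrain, lr_finetune) <= 0)) {
    stop("learning rates must be positive", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) {
    stop("dropout must be in [0, 1)", call. = FALSE)
  }
  structure(list(
    kind = kind,
    conv_filters = as.integer(conv_filters),
    kernel_sizes = as.integer(kernel_sizes),
    pool_sizes = as.integer(pool_sizes),
    dense_units = as.integer(dense_units),
    dropout = dropout, batch_norm = isTRUE(batch_norm),
    lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
    batch_pretrain = as.integer(batch_pretrain),
    batch_finetune = as.integer(batch_finetune),
    epochs_pretrain = as.integer(epochs_pretrain),
    epochs_finetune = as.integer(epochs_finetune),
    seed = as.integer(seed)
  ), class = "gx_model_spec")
}

# dense head shared by both architectures
append_dense_head <- function(layers, n_in, spec) {
  for (u in spec$dense_units) {
    layers[[length(layers) + 1]] <- init_dense(n_in, u)
    if (spec$batch_norm) {
      layers[[length(layers) + 1]] <- list(type = "batchnorm",
                                           gamma = rep(1, u), beta = numeric(u),
                                           running_mean = numeric(u),
                                           running_var = rep(1, u))
    }
    layers[[length(layers) + 1]] <- list(type = "relu")
    if (spec$dropout > 0) {
      layers[[length(layers) + 1]] <- list(type = "dropout", rate = spec$dropout)
    }
    n_in <- u
  }
  layers[[length(layers) + 1]] <- init_dense(n_in, 1)
  layers
}

#' Build a convolutional network for gene-expression images
#'
#' Constructs a CNN mapping an `r x c` single-channel image to an event
#' probability: one or more blocks of valid convolution + ReLU + max-pooling,
#' followed by dense layers and a sigmoid output.
#'
#' @param spec A [model_spec()] with `kind = "cnn"`.
#' @param input_shape Integer vector `c(r, c)`.
#' @return An object of class `gx_model` (untrained; weights are initialized
#'   from `spec$seed`).
#' @export
build_cnn <- function(spec, input_shape) {
  stopifnot(inherits(spec, "gx_model_spec"), spec$kind == "cnn",
            length(input_shape) == 2)
  set.seed(spec$seed)
  h <- as.integer(input_shape[1])
  w <- as.integer(input_shape[2])
  ch <- 1L
  layers <- list()
  for (i in seq_along(spec$conv_filters)) {
    cv <- init_conv(spec$kernel_sizes[i], ch, spec$conv_filters[i], h, w)
    layers[[length(layers) + 1]] <- cv
    layers[[length(layers) + 1]] <- list(type = "relu")
    h <- cv$oh; w <- cv$ow; ch <- spec$conv_filters[i]
    s <- spec$pool_sizes[i]
    if (s > 1) {
      if (s > h || s > w) stop("pool size exceeds feature map", call. = FALSE)
      layers[[length(layers) + 1]] <- list(type = "pool", s = s)
      h <- h %/% s; w <- w %/% s
    }
  }
  layers[[length(layers) + 1]] <- list(type = "flatten")
  layers <- append_dense_head(layers, h * w * ch, spec)
  structure(list(spec = spec, layers = layers,
                 states = vector("list", length(layers)),
                 input_shape = c(input_shape, 1L), kind = "cnn",
                 step = 0L, losses = list()),
            class = "gx_model")
}

#' Build a multi-layer dense network for expression vectors
#'
#' Constructs an MLNN mapping a length-`n` expression vector to an event
#' probability: dense layers with batch normalization, ReLU and dropout,
#' ending in a sigmoid output.
#'
#' @param spec A [model_spec()] with `kind = "mlnn"`.
#' @param n_input Input feature count.
#' @return An object of class `gx_model`.
#' @export
build_mlnn <- function(spec, n_input) {
  stopifnot(inherits(spec, "gx_model_spec"), spec$kind == "mlnn", n_input >= 1)
  set.seed(spec$seed)
  layers <- append_dense_head(list(), as.integer(n_input), spec)
  structure(list(spec = spec, layers = layers,
                 states = vector("list", length(layers)),
                 input_shape = as.integer(n_input), kind = "mlnn",
                 step = 0L, losses = list()),
            class = "gx_model")
}

#' @export
print.gx_model <- function(x, ...) {
  cat(sprintf("<gx_model> %s, %d layers, %d parameters\n",
              x$kind, length(x$layers), n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `gx_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "gx_model"))
  nn_n_params(model$layers)
}

# convert user-facing inputs to the engine layout
model_input <- function(model, x) {
  if (model$kind == "cnn") {
    stopifnot(length(dim(x)) == 3) # samples x r x c
    d <- dim(x)
    out <- aperm(x, c(2, 3, 1))
    dim(out) <- c(d[2], d[3], 1L, d[1])
    out
  } else {
    stopifnot(is.matrix(x)) # samples x features
    t(x)
  }
}

#' Train a model for a number of epochs
#'
#' Runs mini-batch Adam on binary cross-entropy. Can be called repeatedly
#' (optimizer state is carried across calls), which is how fine-tuning
#' continues from pre-trained weights.
#'
#' @param model A `gx_model`.
#' @param x Features: `samples x r x c` array (CNN) or `samples x features`
#'   matrix (MLNN).
#' @param y Binary labels (0/1).
#' @param epochs,lr,batch_size Training-phase parameters.
#' @param seed Seed for batch shuffling and dropout.
#' @return The updated `gx_model` (per-epoch losses appended).
#' @export
fit_model <- function(model, x, y, epochs, lr, batch_size, seed = 1L) {
  stopifnot(inherits(model, "gx_model"))
  xe <- model_input(model, x)
  n <- if (model$kind == "cnn") dim(xe)[4] else ncol(xe)
  stopifnot(length(y) == n)
  tr <- nn_train(model$layers, model$states, xe, as.numeric(y),
                 epochs, lr, batch_size, seed, step0 = model$step)
  model$layers <- tr$layers
  model$states <- tr$states
  model$step <- tr$step
  model$losses <- c(model$losses, list(tr$losses))
  model
}

#' Predict event probabilities
#'
#' @param object A trained `gx_model`.
#' @param x Features in the same layout as [fit_model()].
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.gx_model <- function(object, x, ...) {
  nn_predict(object$layers, model_input(object, x))
}

#' Pre-train on the base cohorts, then fine-tune on the target cohort
#'
#' The transfer-learning procedure: the model is first trained to
#' convergence-budget on the (oversampled) base set — all non-target tumor
#' types — initializing its weights; the same model is then further trained
#' on the (oversampled) target training set with the fine-tuning learning
#' rate and batch size. Both phases optimize the same fixed-time PFI
#' objective. With `epochs_finetune = 0` the pre-trained model is returned
#' unchanged.
#'
#' @param spec A [model_spec()].
#' @param base_x,base_y Base-set features and binary labels.
#' @param target_x,target_y Target training-fold features and labels.
#' @param oversample Random-oversample both phases' training data (default
#'   TRUE, the class-imbalance handling used with transfer learning).
#' @return A fitted `gx_model`.
#' @export
pretrain_finetune <- function(spec, base_x, base_y, target_x, target_y,
                              oversample = TRUE) {
  stopifnot(inherits(spec, "gx_model_spec"))
  dim_b <- if (length(dim(base_x)) == 3) dim(base_x)[-1] else ncol(base_x)
  dim_t <- if (length(dim(target_x)) == 3) dim(target_x)[-1] else ncol(target_x)
  if (!identical(dim_b, dim_t)) {
    stop("base and target feature spaces must be identical", call. = FALSE)
  }
  model <- if (spec$kind == "cnn") build_cnn(spec, dim(base_x)[-1])
           else build_mlnn(spec, ncol(base_x))
  if (oversample) {
    os <- random_oversample(base_x, base_y, seed = spec$seed)
    base_x <- os$features; base_y <- os$labels
  }
  model <- fit_model(model, base_x, base_y, spec$epochs_pretrain,
                     spec$lr_pretrain, spec$batch_pretrain, seed = spec$seed)
  if (spec$epochs_finetune > 0) {
    if (oversample) {
      os <- random_oversample(target_x, target_y, seed = spec$seed + 1L)
      target_x <- os$features; target_y <- os$labels
    }
    model <- fit_model(model, target_x, target_y, spec$epochs_finetune,
                       spec$lr_finetune, spec$batch_finetune,
                       seed = spec$seed + 2L)
  }
  model
}
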