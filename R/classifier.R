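#' Training configuration for the window classifier
#'
#' @param epochs Number of full-sweep SGD passes over the training set
#'   (default 100).
#' @param learning_rate Constant SGD step size (default 0.01).
#' @param seed Seed controlling the per-epoch visiting order.
#' @param shuffle_each_epoch Reshuffle the sample order every epoch?
#' @param loss `"cross_entropy"` (canonical pairing with the sigmoid
#'   probabilistic output) or `"squared"` (0.5 (p - y)^2).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.01, seed = 1L,
                         shuffle_each_epoch = TRUE,
                         loss = c("cross_entropy", "squared")) {
  loss <- match.arg(loss)
  if (epochs < 1) abort("`epochs` must be at least 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 loss = loss),
            class = "train_config")
}

loss_code <- function(loss) match(loss, c("cross_entropy", "squared")) - 1L

#' Initialize the feed-forward window classifier
#'
#' A 1285 x 1285 x 1 network by default: the input is the flattened window
#' spectrogram, the hidden layer is logistic, and the output unit is a
#' biased sigmoid (additive output bias `out_bias`, zero by default, so it
#' reduces to the plain logistic) giving the probability that the window is
#' part of a swallow. Weights are drawn uniformly from
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`; biases start at zero.
#'
#' @param input_size,hidden_size Layer widths (defaults 1285 and 1285).
#' @param seed Seed for the weight draw.
#' @param init_scale Optional override of the uniform half-width (0 gives a
#'   zero network whose every prediction is 0.5).
#' @param decision_threshold Probability cut for [mlp_classify()]
#'   (default 0.5).
#' @return A `swallow_mlp` model object.
#' @export
mlp_init <- function(input_size = 1285L, hidden_size = 1285L, seed = 1L,
                     init_scale = NULL, decision_threshold = 0.5) {
  d <- as.integer(input_size)
  h <- as.integer(hidden_size)
  s1 <- init_scale %||% (1 / sqrt(d))
  s2 <- init_scale %||% (1 / sqrt(h))
  withr::with_seed(seed, {
    W1 <- matrix(runif(h * d, -s1, s1), nrow = h, ncol = d)
    w2 <- runif(h, -s2, s2)
  })
  structure(
    list(layer_sizes = c(d, h, 1L),
         W1 = W1, b1 = numeric(h), w2 = w2, b2 = 0,
         out_bias = 0, decision_threshold = decision_threshold,
         seed = as.integer(seed), loss_trace = numeric(0),
         train_config = NULL),
    class = "swallow_mlp"
  )
}

#' @export
print.swallow_mlp <- function(x, ...) {
  cat(sprintf("<swallow_mlp> %s (%s parameters)\n",
              paste(x$layer_sizes, collapse = " x "),
              format(n_parameters(x), big.mark = ",")))
  if (length(x$loss_trace) > 0) {
    cat(sprintf("  trained %d epoch(s); final mean loss %.4g\n",
                length(x$loss_trace), tail(x$loss_trace, 1)))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model A `swallow_mlp`.
#' @return Integer count: `(d + 1) h + (h + 1)`.
#' @export
n_parameters <- function(model) {
  d <- model$layer_sizes[1]; h <- model$layer_sizes[2]
  (d + 1) * h + (h + 1)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.numeric(as.character(labels) == "swallow")
  } else {
    y <- as.numeric(labels)
    if (!all(y %in% c(0, 1))) abort("Labels must be 0/1 or swallow labels.")
    y
  }
}

#' Train the window classifier by full-sweep SGD
#'
#' Each epoch makes one pass over every training sample in (shuffled) order
#' with a per-sample gradient step; there is no dropout. Training aborts
#' with a diagnostic if the loss turns non-finite.
#'
#' @param model A `swallow_mlp` from [mlp_init()].
#' @param features Numeric matrix, one row per sample, `input_size` columns.
#' @param labels Vector of 0/1 or `"swallow"`/`"non_swallow"` labels.
#' @param config A [train_config()].
#' @return The trained model; `tidy()` exposes the per-epoch mean loss
#'   trace.
#' @export
mlp_train <- function(model, features, labels, config = train_config()) {
  stopifnot(inherits(model, "swallow_mlp"), inherits(config, "train_config"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (n == 0) abort("Training data is empty.")
  if (ncol(features) != model$layer_sizes[1]) {
    abort(sprintf("Expected %d feature columns, got %d.",
                  model$layer_sizes[1], ncol(features)))
  }
  y <- as_binary_labels(labels)
  if (length(y) != n) abort("One label per feature row is required.")

  order <- withr::with_seed(config$seed, {
    if (config$shuffle_each_epoch) {
      t(replicate(config$epochs, sample.int(n) - 1L))
    } else {
      matrix(rep(seq_len(n) - 1L, each = config$epochs),
             nrow = config$epochs)
    }
  })
  storage.mode(order) <- "integer"
  fit <- cpp_mlp_sgd(model$W1, model$b1, model$w2, model$b2,
                     model$out_bias, t(features), y, order,
                     config$learning_rate, loss_code(config$loss))
  model$W1 <- fit$W1
  model$b1 <- as.numeric(fit$b1)
  model$w2 <- as.numeric(fit$w2)
  model$b2 <- as.numeric(fit$b2)
  model$loss_trace <- c(model$loss_trace, as.numeric(fit$loss_trace))
  model$train_config <- config
  model
}

#' Predict swallow probabilities or classes for feature rows
#'
#' @param object A `swallow_mlp`.
#' @param features Numeric matrix (rows = windows) or a single feature
#'   vector.
#' @param type `"prob"` for probabilities, `"class"` for thresholded
#'   labels.
#' @param ... Unused.
#' @return Numeric probabilities in (0, 1), or character labels.
#' @export
predict.swallow_mlp <- function(object, features,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != object$layer_sizes[1]) {
    abort(sprintf("Expected %d feature columns, got %d.",
                  object$layer_sizes[1], ncol(features)))
  }
  if (!all(is.finite(features))) abort("Features must be finite.")
  p <- as.numeric(cpp_mlp_forward(object$W1, object$b1, object$w2,
                                  object$b2, object$out_bias, t(features)))
  if (type == "prob") p else mlp_classify(object, p)
}

#' Threshold probabilities into window decisions
#'
#' @param model A `swallow_mlp` (supplies `decision_threshold`).
#' @param p Probabilities in `[0, 1]`.
#' @return `"swallow"` where `p >= decision_threshold` (inclusive), else
#'   `"non_swallow"`.
#' @export
mlp_classify <- function(model, p) {
  if (any(p < 0 | p > 1)) abort("Probabilities must lie in [0, 1].")
  ifelse(p >= model$decision_threshold, "swallow", "non_swallow")
}

#' Analytic gradient of the per-sample loss
#'
#' Backpropagated gradient of the loss at one sample with respect to all
#' parameters; used for gradient checking against finite differences.
#'
#' @param model A `swallow_mlp`.
#' @param x Feature vector.
#' @param y Scalar 0/1 label.
#' @param loss Loss name as in [train_config()].
#' @return List with `gW1`, `gb1`, `gw2`, `gb2`, `loss`, `p`.
#' @export
mlp_gradient <- function(model, x, y, loss = "cross_entropy") {
  cpp_mlp_gradient(model$W1, model$b1, model$w2, model$b2, model$out_bias,
                   as.numeric(x), y, loss_code(loss))
}

#' Save / load a trained model
#'
#' One portable file holding layer sizes, weights, training configuration
#' and seed.
#'
#' @param model A `swallow_mlp`.
#' @param path Destination / source file path.
#' @return `save_mlp` the path invisibly; `load_mlp` the model.
#' @export
save_mlp <- function(model, path) {
  stopifnot(inherits(model, "swallow_mlp"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "swallow_mlp")) abort("Not a saved swallow_mlp.")
  model
}

#' Tidy the training trace of a fitted classifier
#'
#' @param x A `swallow_mlp`.
#' @param ... Unused.
#' @return Tibble with columns `epoch` and `mean_loss`.
#' @export
tidy.swallow_mlp <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), mean_loss = x$loss_trace)
}

#' One-row model summary
#'
#' @param x A `swallow_mlp`.
#' @param ... Unused.
#' @return One-row tibble: layer sizes, parameter count, epochs trained,
#'   final loss.
#' @export
glance.swallow_mlp <- function(x, ...) {
  tibble(
    input_size = x$layer_sizes[1], hidden_size = x$layer_sizes[2],
    n_parameters = n_parameters(x),
    epochs_trained = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) tail(x$loss_trace, 1) else NA_real_,
    learning_rate = x$train_config$learning_rate %||% NA_real_,
    loss = x$train_config$loss %||% NA_character_
  )
}
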