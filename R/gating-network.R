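#' Specify the gating-layer classifier architecture
#'
#' The model is a feature-selection (gating) layer followed by a dense
#' classifier. The gating layer has one weight per gene and no bias; its
#' output is the elementwise (Hadamard) product `y = w * x` with a linear
#' activation, so after training a large `w[i]` flags gene `i` as important.
#' The classifier is a stack of ReLU dense layers with dropout and a softmax
#' output over the classes. Defaults mirror the study configuration: three
#' 500-unit hidden layers with dropout probability 0.5.
#'
#' @param k_features Number of input genes (gating-layer units).
#' @param n_classes Number of classes (>= 2).
#' @param hidden_widths Integer vector of hidden-layer widths.
#' @param dropout_rate Dropout probability in `[0, 1)` applied after each
#'   hidden activation during training.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec(k_features = 100)
#' @export
model_spec <- function(k_features, n_classes = 2L,
                       hidden_widths = c(500L, 500L, 500L),
                       dropout_rate = 0.5) {
  k_features <- as.integer(k_features)
  n_classes <- as.integer(n_classes)
  hidden_widths <- as.integer(hidden_widths)
  if (is.na(k_features) || k_features < 1L) abort("k_features must be >= 1")
  if (is.na(n_classes) || n_classes < 2L) abort("n_classes must be >= 2")
  if (length(hidden_widths) < 1L || any(hidden_widths < 1L))
    abort("hidden_widths must be positive integers")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    abort("dropout_rate must be in [0, 1)")
  structure(list(k_features = k_features,
                 n_classes = n_classes,
                 hidden_widths = hidden_widths,
                 dropout_rate = as.double(dropout_rate),
                 gate_activation = "linear",
                 hidden_activation = "relu"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat("  gating layer:", x$k_features, "units (no bias, linear, w >= 0)\n")
  cat("  hidden layers:", paste(x$hidden_widths, collapse = " - "),
      sprintf("(ReLU, dropout %.2f)\n", x$dropout_rate))
  cat("  output:", x$n_classes, "classes (softmax)\n")
  invisible(x)
}

#' @export
glance.model_spec <- function(x, ...) {
  widths <- c(x$k_features, x$hidden_widths, x$n_classes)
  n_dense <- sum(widths[-length(widths)] * widths[-1]) + sum(widths[-1])
  tibble::tibble(k_features = x$k_features,
                 n_classes = x$n_classes,
                 n_hidden_layers = length(x$hidden_widths),
                 hidden_width = x$hidden_widths[1],
                 dropout_rate = x$dropout_rate,
                 n_gate_weights = x$k_features,
                 n_parameters = x$k_features + n_dense)
}

#' Serialize / deserialize a model specification
#'
#' Writes the full specification, defaults included, to YAML so a training
#' trial is reproducible from the config file plus a seed.
#'
#' @param spec A [model_spec()].
#' @param path YAML file path.
#' @return For `write_model_spec`, `path` invisibly; for `read_model_spec`,
#'   the reconstructed `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  model_spec(k_features = x$k_features, n_classes = x$n_classes,
             hidden_widths = unlist(x$hidden_widths),
             dropout_rate = x$dropout_rate)
}

#' Gating-layer forward pass
#'
#' The operation of the feature-selection layer: the elementwise (Hadamard)
#' product of the input vector with the gate weights, passed through a linear
#' activation, so `y[i] = w[i] * x[i]` exactly.
#'
#' @param x Numeric vector of normalized feature values.
#' @param w Non-negative gate weights, same length as `x`.
#' @return Numeric vector `w * x`.
#' @examples
#' gate_forward(c(0.2, 0.8), c(0, 2))
#' @export
gate_forward <- function(x, w) {
  if (length(x) != length(w))
    abort(sprintf("length mismatch: x has %d elements, w has %d",
                  length(x), length(w)))
  if (any(w < 0)) abort("gate weights must be non-negative")
  w * x
}

#' Project weights onto the non-negative orthant
#'
#' Clips negative entries to zero; applied to the gate weights after every
#' optimizer update so the trained gate satisfies `w >= 0`.
#'
#' @param w Numeric vector.
#' @return `pmax(w, 0)`.
#' @export
project_nonnegative <- function(w) pmax(w, 0)

#' Categorical cross-entropy
#'
#' `-sum(onehot * log(probs))` with a probability floor of `1e-12` before the
#' logarithm so confident predictions do not produce `log(0)`.
#'
#' @param probs Class-probability vector (sums to 1).
#' @param onehot One-hot label vector of the same length.
#' @param floor Probability floor.
#' @return Non-negative scalar loss.
#' @export
categorical_cross_entropy <- function(probs, onehot, floor = 1e-12) {
  if (length(probs) != length(onehot))
    abort("probs and onehot must have the same length")
  -sum(onehot * log(pmax(probs, floor)))
}

#' Build (initialize) a gating-layer classifier
#'
#' Creates the trainable weights for a [model_spec()]: gate weights start at
#' 1 (the identity gate, so the first forward pass equals a gate-free model
#' and training alone decides which genes decay or grow), dense weights use
#' Glorot-uniform initialization drawn from R's RNG stream (seed with
#' `set.seed()` for reproducibility), biases start at zero.
#'
#' @param spec A [model_spec()].
#' @return An object of class `gate_model` holding `gate` (length-k vector),
#'   `W` and `b` (dense weights/biases per layer), and the `spec`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  widths <- c(spec$k_features, spec$hidden_widths, spec$n_classes)
  W <- vector("list", length(widths) - 1L)
  b <- vector("list", length(widths) - 1L)
  for (l in seq_along(W)) {
    fi <- widths[l]; fo <- widths[l + 1L]
    lim <- sqrt(6 / (fi + fo))
    W[[l]] <- matrix(runif(fi * fo, -lim, lim), fi, fo)
    b[[l]] <- numeric(fo)
  }
  structure(list(gate = rep(1, spec$k_features), W = W, b = b, spec = spec),
            class = "gate_model")
}

#' @export
print.gate_model <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  gate weights: min %.4g, max %.4g\n",
              min(x$gate), max(x$gate)))
  invisible(x)
}

#' @export
glance.gate_model <- function(x, ...) glance(x$spec)

#' Class probabilities from a gating-layer classifier
#'
#' Evaluation-mode forward pass (no dropout). With `use_gate = FALSE` the
#' gating layer is skipped, which is how one verifies that an identity gate
#' (all weights 1) leaves the downstream network untouched.
#'
#' @param model A `gate_model`.
#' @param X Samples x genes matrix of normalized values (or a single vector).
#' @param use_gate Apply the gating layer (default `TRUE`).
#' @return Samples x classes matrix of probabilities; rows sum to 1.
#' @export
predict_proba <- function(model, X, use_gate = TRUE) {
  stopifnot(inherits(model, "gate_model"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$spec$k_features)
    abort(sprintf("X has %d features, model expects %d",
                  ncol(X), model$spec$k_features))
  A <- if (use_gate) sweep(X, 2L, model$gate, `*`) else X
  L <- length(model$W)
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A %*% model$W[[l]], 2L, model$b[[l]], `+`)
    A <- pmax(Z, 0)
  }
  Z <- sweep(A %*% model$W[[L]], 2L, model$b[[L]], `+`)
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}
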