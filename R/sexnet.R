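# Densely connected feed-forward sex classifier.
#
# The network maps a standardized expression profile to the probability that
# the sample is male (female = 0, male = 1 throughout the package). "Dense
# connection" means DenseNet-style wiring: every hidden layer receives the
# concatenation of the raw input and all earlier hidden activations, and the
# output unit sees the full concatenation. Forward, backward and
# input-gradient passes are implemented directly so that integrated-gradient
# attribution has exact analytic gradients to work with.

#' Network configuration
#'
#' @param total_layers Number of weighted layers (hidden layers plus the
#'   sigmoid output unit); default 11.
#' @param hidden_width Units per hidden layer (default 64).
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param dense_connectivity If `TRUE` (default) each layer receives the
#'   concatenated outputs of all earlier layers plus the input; if `FALSE` a
#'   plain layer chain is built.
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param metric Validation metric used to pick the best epoch:
#'   `"accuracy"` (default) or `"auc"`.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A validated list of class `net_config`.
#' @export
net_config <- function(total_layers = 11L, hidden_width = 64L,
                       activation = c("relu", "tanh"),
                       dense_connectivity = TRUE,
                       epochs = 200L, learning_rate = 1e-3,
                       batch_size = 32L,
                       metric = c("accuracy", "auc"), seed = 1L) {
  activation <- match.arg(activation)
  metric <- match.arg(metric)
  if (!is_count(total_layers, 2L)) abort("'total_layers' must be >= 2")
  if (!is_count(hidden_width)) abort("'hidden_width' must be >= 1")
  if (!is_count(epochs)) abort("'epochs' must be >= 1")
  if (!is_count(batch_size)) abort("'batch_size' must be >= 1")
  if (!is_number(learning_rate) || learning_rate <= 0)
    abort("'learning_rate' must be > 0")
  if (!is_flag(dense_connectivity)) abort("'dense_connectivity' must be a flag")
  structure(list(total_layers = as.integer(total_layers),
                 hidden_width = as.integer(hidden_width),
                 activation = activation,
                 dense_connectivity = dense_connectivity,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 metric = metric, seed = as.integer(seed)),
            class = "net_config")
}

# Column indices (within the running concatenation [x, A_1, ..., A_k]) that
# feed layer k, and that feed the output unit.
layer_in_cols <- function(d, width, k, dense) {
  if (dense || k == 1L) seq_len(d + (k - 1L) * width)
  else d + (k - 2L) * width + seq_len(width)
}
out_in_cols <- function(d, width, n_hidden, dense) {
  if (dense) seq_len(d + n_hidden * width)
  else d + (n_hidden - 1L) * width + seq_len(width)
}

#' Build an untrained classifier
#'
#' Initializes weights (He-scaled normal draws) for the configured topology.
#' Two builds with the same config and seed are identical.
#'
#' @param n_genes Input dimension (number of genes).
#' @param config A [net_config()].
#' @return A `sexnet_model` holding weights, biases and the config.
#' @export
build_model <- function(n_genes, config = net_config()) {
  if (!is_count(n_genes)) abort("'n_genes' must be >= 1")
  stopifnot(inherits(config, "net_config"))
  d <- as.integer(n_genes)
  width <- config$hidden_width
  n_hidden <- config$total_layers - 1L
  dense <- config$dense_connectivity
  set.seed(config$seed)
  W <- vector("list", n_hidden)
  b <- vector("list", n_hidden)
  for (k in seq_len(n_hidden)) {
    fan_in <- length(layer_in_cols(d, width, k, dense))
    W[[k]] <- matrix(rnorm(fan_in * width, sd = sqrt(2 / fan_in)),
                     fan_in, width)
    b[[k]] <- numeric(width)
  }
  fan_out <- length(out_in_cols(d, width, n_hidden, dense))
  structure(list(W = W, b = b,
                 w_out = matrix(rnorm(fan_out, sd = sqrt(2 / fan_out)),
                                fan_out, 1L),
                 b_out = 0,
                 n_genes = d, config = config),
            class = "sexnet_model")
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

net_act <- function(model, z) {
  if (model$config$activation == "relu") pmax(z, 0) else tanh(z)
}
net_act_grad <- function(model, z, a) {
  if (model$config$activation == "relu") (z > 0) * 1 else 1 - a * a
}

# Forward pass. X: samples x genes. Returns probabilities and, if cache =
# TRUE, the running concatenation H plus per-layer pre-activations.
net_forward <- function(model, X, cache = FALSE) {
  cfg <- model$config
  d <- model$n_genes
  if (ncol(X) != d) abort("input has %d genes, model expects %d", ncol(X), d)
  n_hidden <- cfg$total_layers - 1L
  H <- X
  Z <- if (cache) vector("list", n_hidden) else NULL
  A <- if (cache) vector("list", n_hidden) else NULL
  for (k in seq_len(n_hidden)) {
    cols <- layer_in_cols(d, cfg$hidden_width, k, cfg$dense_connectivity)
    z <- H[, cols, drop = FALSE] %*% model$W[[k]]
    z <- sweep(z, 2L, model$b[[k]], "+")
    a <- net_act(model, z)
    if (cache) { Z[[k]] <- z; A[[k]] <- a }
    H <- cbind(H, a)
  }
  ocols <- out_in_cols(d, cfg$hidden_width, n_hidden, cfg$dense_connectivity)
  logit <- drop(H[, ocols, drop = FALSE] %*% model$w_out) + model$b_out
  p <- sigmoid(logit)
  if (cache) list(p = p, logit = logit, H = H, Z = Z, A = A) else p
}

# Backward pass from a gradient on the pre-sigmoid logit (one value per
# sample). Returns parameter gradients and/or the gradient with respect to
# the input rows. dlogit: numeric vector length n.
net_backward <- function(model, fwd, dlogit, want_params = TRUE,
                         want_input = FALSE) {
  cfg <- model$config
  d <- model$n_genes
  n_hidden <- cfg$total_layers - 1L
  H <- fwd$H
  G <- matrix(0, nrow(H), ncol(H))
  ocols <- out_in_cols(d, cfg$hidden_width, n_hidden, cfg$dense_connectivity)
  G[, ocols] <- dlogit %*% t(model$w_out)
  gW <- gb <- NULL
  if (want_params) {
    gW <- vector("list", n_hidden)
    gb <- vector("list", n_hidden)
    g_w_out <- crossprod(H[, ocols, drop = FALSE], dlogit)
    g_b_out <- sum(dlogit)
  }
  for (k in rev(seq_len(n_hidden))) {
    acols <- d + (k - 1L) * cfg$hidden_width + seq_len(cfg$hidden_width)
    dZ <- G[, acols, drop = FALSE] *
      net_act_grad(model, fwd$Z[[k]], fwd$A[[k]])
    icols <- layer_in_cols(d, cfg$hidden_width, k, cfg$dense_connectivity)
    if (want_params) {
      gW[[k]] <- crossprod(H[, icols, drop = FALSE], dZ)
      gb[[k]] <- colSums(dZ)
    }
    G[, icols] <- G[, icols, drop = FALSE] + dZ %*% t(model$W[[k]])
  }
  out <- list()
  if (want_params) out[c("gW", "gb", "g_w_out", "g_b_out")] <-
      list(gW, gb, g_w_out, g_b_out)
  if (want_input) out$g_input <- G[, seq_len(d), drop = FALSE]
  out
}

#' Gradient of the predicted male probability with respect to the input
#'
#' Analytic input gradient of the network output, the primitive on which
#' integrated-gradient attribution is built. Each sample's gradient is taken
#' with respect to its own input row.
#'
#' @param model A `sexnet_model` or `sexnet_trained`.
#' @param X Numeric matrix, samples in rows, genes in columns.
#' @return List with `p` (probabilities) and `gradient`
#'   (samples x genes matrix).
#' @export
input_gradients <- function(model, X) {
  model <- as_sexnet_model(model)
  fwd <- net_forward(model, X, cache = TRUE)
  dlogit <- fwd$p * (1 - fwd$p)  # d sigmoid / d logit, per sample
  bk <- net_backward(model, fwd, dlogit, want_params = FALSE,
                     want_input = TRUE)
  list(p = fwd$p, gradient = bk$g_input)
}

as_sexnet_model <- function(object) {
  if (inherits(object, "sexnet_trained")) object$model
  else if (inherits(object, "sexnet_model")) object
  else abort("expected a sexnet_model or sexnet_trained object")
}

#' Encode sex labels as 0/1
#'
#' The package-wide convention is female = 0, male = 1; attribution signs
#' depend on it (positive attribution pushes the prediction toward male).
#'
#' @param sex Character/factor vector of `"male"` / `"female"`, or a numeric
#'   0/1 vector (returned unchanged).
#' @return Numeric 0/1 vector.
#' @export
encode_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.numeric(sex))
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    abort("sex labels must be 'male' or 'female'")
  as.numeric(sex == "male")
}

scaled_to_xt <- function(X) {
  if (inherits(X, "scaled_matrix")) t(X$values)
  else if (inherits(X, "expr_matrix")) t(X$values)
  else if (is.matrix(X)) t(X)
  else abort("expected a scaled_matrix/expr_matrix (genes x samples)")
}

rank_auc <- function(p, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(rank(p)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the sex classifier
#'
#' Minibatch Adam on binary cross-entropy for `config$epochs` epochs. After
#' every epoch the model is scored on the validation set; the parameters of
#' the best-scoring epoch (ties broken toward the earliest) are the ones
#' returned, not those of the final epoch.
#'
#' @param model A `sexnet_model` from [build_model()].
#' @param X_train,X_val `scaled_matrix` objects (genes x samples) or plain
#'   gene-by-sample matrices.
#' @param y_train,y_val Sex labels (see [encode_sex()]).
#' @param config Optional [net_config()] overriding the model's config.
#' @return A `sexnet_trained`: list with `model` (best-epoch parameters),
#'   `validation_trace` (length `epochs`), `best_epoch`, `train_loss`,
#'   `input_dimension` and `gene_ids` (if available on the input).
#' @export
train_classifier <- function(model, X_train, y_train, X_val, y_val,
                             config = NULL) {
  stopifnot(inherits(model, "sexnet_model"))
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  Xt <- scaled_to_xt(X_train)
  Xv <- scaled_to_xt(X_val)
  y <- encode_sex(y_train)
  yv <- encode_sex(y_val)
  if (length(y) != nrow(Xt) || length(yv) != nrow(Xv))
    abort("label vectors must align with sample columns")
  if (length(unique(y)) < 2L)
    abort("training labels contain a single class")
  n <- nrow(Xt)
  gene_ids <- if (inherits(X_train, "scaled_matrix")) X_train$gene_ids
              else rownames(as_expr_values(X_train))

  # Adam state mirrors the parameter list
  params <- list(W = model$W, b = model$b, w_out = model$w_out,
                 b_out = model$b_out)
  mom <- rapply(params, function(p) p * 0, how = "replace")
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0L

  set.seed(cfg$seed)
  trace <- numeric(cfg$epochs)
  loss_trace <- numeric(cfg$epochs)
  best_metric <- -Inf
  best_epoch <- NA_integer_
  best_params <- params

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      model$W <- params$W; model$b <- params$b
      model$w_out <- params$w_out; model$b_out <- params$b_out
      fwd <- net_forward(model, Xt[idx, , drop = FALSE], cache = TRUE)
      p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
      yi <- y[idx]
      ep_loss <- ep_loss - sum(yi * log(p) + (1 - yi) * log(1 - p))
      dlogit <- (fwd$p - yi) / length(idx)
      g <- net_backward(model, fwd, dlogit)
      tstep <- tstep + 1L
      corr <- sqrt(1 - beta2^tstep) / (1 - beta1^tstep)
      for (k in seq_along(params$W)) {
        mom$W[[k]] <- beta1 * mom$W[[k]] + (1 - beta1) * g$gW[[k]]
        vel$W[[k]] <- beta2 * vel$W[[k]] + (1 - beta2) * g$gW[[k]]^2
        params$W[[k]] <- params$W[[k]] -
          cfg$learning_rate * corr * mom$W[[k]] / (sqrt(vel$W[[k]]) + eps)
        mom$b[[k]] <- beta1 * mom$b[[k]] + (1 - beta1) * g$gb[[k]]
        vel$b[[k]] <- beta2 * vel$b[[k]] + (1 - beta2) * g$gb[[k]]^2
        params$b[[k]] <- params$b[[k]] -
          cfg$learning_rate * corr * mom$b[[k]] / (sqrt(vel$b[[k]]) + eps)
      }
      mom$w_out <- beta1 * mom$w_out + (1 - beta1) * g$g_w_out
      vel$w_out <- beta2 * vel$w_out + (1 - beta2) * g$g_w_out^2
      params$w_out <- params$w_out -
        cfg$learning_rate * corr * mom$w_out / (sqrt(vel$w_out) + eps)
      mom$b_out <- beta1 * mom$b_out + (1 - beta1) * g$g_b_out
      vel$b_out <- beta2 * vel$b_out + (1 - beta2) * g$g_b_out^2
      params$b_out <- params$b_out -
        cfg$learning_rate * corr * mom$b_out / (sqrt(vel$b_out) + eps)
    }
    loss_trace[epoch] <- ep_loss / n
    model$W <- params$W; model$b <- params$b
    model$w_out <- params$w_out; model$b_out <- params$b_out
    pv <- net_forward(model, Xv)
    trace[epoch] <- if (cfg$metric == "accuracy")
      mean((pv > 0.5) == (yv == 1)) else rank_auc(pv, yv)
    if (trace[epoch] > best_metric) {  # strict: ties keep the earliest epoch
      best_metric <- trace[epoch]
      best_epoch <- epoch
      best_params <- params
    }
  }
  model$W <- best_params$W; model$b <- best_params$b
  model$w_out <- best_params$w_out; model$b_out <- best_params$b_out
  structure(list(model = model,
                 validation_trace = trace,
                 train_loss = loss_trace,
                 best_epoch = best_epoch,
                 input_dimension = model$n_genes,
                 gene_ids = gene_ids,
                 config = cfg),
            class = "sexnet_trained")
}

#' @method print sexnet_trained
#' @export
print.sexnet_trained <- function(x, ...) {
  cat(sprintf(
    "sexnet_trained: %d-layer %s net, %d inputs; best epoch %d (%s %.3f)\n",
    x$config$total_layers,
    if (x$config$dense_connectivity) "densely connected" else "chain",
    x$input_dimension, x$best_epoch, x$config$metric,
    x$validation_trace[x$best_epoch]))
  invisible(x)
}

#' Predict male probabilities
#'
#' @param object A `sexnet_trained`.
#' @param newdata `scaled_matrix` or gene-by-sample matrix over the same
#'   genes the model was trained on.
#' @param ... Unused.
#' @return Named numeric vector of male probabilities in \[0, 1\].
#' @export
predict.sexnet_trained <- function(object, newdata, ...) {
  Xt <- scaled_to_xt(newdata)
  if (ncol(Xt) != object$input_dimension)
    abort("newdata has %d genes, model expects %d",
          ncol(Xt), object$input_dimension)
  p <- net_forward(object$model, Xt)
  names(p) <- rownames(Xt)
  p
}
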