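# Wavelet (Morlet) and sigmoid feed-forward networks for vGRF prediction.
#
# Both are single-hidden-layer fully connected networks mapping the
# flattened 101 x m stance acceleration input to the 101-point stance vGRF
# curve (BW).  Hidden node k computes z_k = phi((sum_ij w_ijk x_ij - b_k) /
# a_k) with phi the Morlet wavelet or the sigmoid (b_k: shifting factor,
# a_k: scaling factor); output i is y_i = sum_k w_ki z_k - b_i.  Training
# minimizes the per-point MSE plus an L2 penalty on ALL parameters
# (including b_k, a_k, b_i) with mini-batch Adam.

#' Morlet wavelet activation
#'
#' `exp(-u^2/2) * cos(5*u)`, the mother wavelet used by the wavelet network's
#' hidden layer.
#'
#' @param u numeric input.
#' @return Activation values, same shape as `u`.
#' @export
morlet <- function(u) exp(-u^2 / 2) * cos(5 * u)

# derivative d/du morlet(u) = -exp(-u^2/2) * (u*cos(5u) + 5*sin(5u))
morlet_deriv <- function(u) -exp(-u^2 / 2) * (u * cos(5 * u) + 5 * sin(5 * u))

#' Sigmoid activation
#'
#' `1 / (1 + exp(-u))`, numerically stable for large |u| (saturates to 0/1
#' without under/overflow exceptions).
#'
#' @param u numeric input.
#' @return Activation values in (0, 1).
#' @export
sigmoid <- function(u) {
  out <- u
  pos <- !is.na(u) & u >= 0
  out[pos] <- 1 / (1 + exp(-u[pos]))
  eu <- exp(u[!pos])
  out[!pos] <- eu / (1 + eu)
  out
}

sigmoid_deriv <- function(u) { s <- sigmoid(u); s * (1 - s) }

activation_funs <- function(activation) {
  switch(activation,
         morlet = list(f = morlet, df = morlet_deriv),
         sigmoid = list(f = sigmoid, df = sigmoid_deriv),
         abort_invalid("unknown activation '%s'", activation))
}

A_MIN <- 1e-3  # |a_k| is clamped away from 0

new_vgrf_model <- function(activation, K, m, W_hidden, b_shift, a_scale,
                           W_out, b_out) {
  stopifnot(nrow(W_hidden) == K, ncol(W_hidden) == 101 * m,
            length(b_shift) == K, length(a_scale) == K,
            nrow(W_out) == 101, ncol(W_out) == K, length(b_out) == 101)
  structure(list(activation = activation, K = as.integer(K),
                 m = as.integer(m), W_hidden = W_hidden,
                 b_shift = as.numeric(b_shift),
                 a_scale = as.numeric(a_scale),
                 W_out = W_out, b_out = as.numeric(b_out)),
            class = "vgrf_model")
}

#' @export
print.vgrf_model <- function(x, ...) {
  cat(sprintf("<vgrf_model> %s activation, K = %d hidden nodes, m = %d input channel(s) (%d inputs -> 101 outputs)\n",
              x$activation, x$K, x$m, 101 * x$m))
  invisible(x)
}

as_input_matrix <- function(model, x) {
  D <- 101L * model$m
  if (is.null(dim(x))) {
    if (length(x) != D)
      abort_invalid("input length %d does not match model (expects %d)",
                    length(x), D)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != D)
    abort_invalid("input has %d columns; model expects %d", ncol(x), D)
  x
}

# Hidden pre-activations and activations for a batch (n x D input).
hidden_forward <- function(model, X) {
  S <- X %*% t(model$W_hidden)                       # n x K
  U <- sweep(sweep(S, 2, model$b_shift, "-"), 2, model$a_scale, "/")
  list(S = S, U = U, Z = activation_funs(model$activation)$f(U))
}

#' Forward pass of a vGRF network
#'
#' @param model a `vgrf_model` (from [train_vgrf()] or [init_vgrf_model()]).
#' @param x a single flattened input (length `101 * m`, channel-major) or an
#'   n x `101*m` matrix of inputs.
#' @return For a single input, a 101-point predicted vGRF curve (BW); for a
#'   matrix, an n x 101 matrix.
#' @export
vgrf_forward <- function(model, x) {
  single <- is.null(dim(x))
  X <- as_input_matrix(model, x)
  Z <- hidden_forward(model, X)$Z
  Yhat <- sweep(Z %*% t(model$W_out), 2, model$b_out, "-")
  if (single) as.numeric(Yhat) else Yhat
}

param_sq_norm <- function(model) {
  sum(model$W_hidden^2) + sum(model$W_out^2) + sum(model$b_shift^2) +
    sum(model$a_scale^2) + sum(model$b_out^2)
}

param_abs_norm <- function(model) {
  sum(abs(model$W_hidden)) + sum(abs(model$W_out)) + sum(abs(model$b_shift)) +
    sum(abs(model$a_scale)) + sum(abs(model$b_out))
}

#' Regularized training loss
#'
#' The data term is the squared error averaged over samples and the 101
#' output points; the penalty is `lambda * ||w||^2` (or the L1 norm when
#' `reg = "l1"`) over every parameter: hidden weights, output weights,
#' shifting factors, scaling factors and output biases.
#'
#' @param model a `vgrf_model`.
#' @param x n x `101*m` input matrix (or single input vector).
#' @param y n x 101 target matrix (or 101-vector), BW.
#' @param lambda regularization strength.
#' @param reg `"l2"` (default) or `"l1"`.
#' @return Scalar loss.
#' @export
vgrf_loss <- function(model, x, y, lambda = 0.01, reg = c("l2", "l1")) {
  reg <- match.arg(reg)
  X <- as_input_matrix(model, x)
  Y <- if (is.null(dim(y))) matrix(y, nrow = 1L) else as.matrix(y)
  if (nrow(X) < 1L) abort_invalid("empty batch")
  R <- vgrf_forward(model, X) - Y
  data_term <- sum(R^2) / (nrow(X) * 101)
  pen <- if (reg == "l2") param_sq_norm(model) else param_abs_norm(model)
  data_term + lambda * pen
}

#' Analytic gradients of the training loss
#'
#' Backpropagation through Eqs. of the network: returns the gradient of
#' [vgrf_loss()] with respect to every parameter group.
#'
#' @inheritParams vgrf_loss
#' @return List with `W_hidden`, `b_shift`, `a_scale`, `W_out`, `b_out`
#'   gradient arrays (same shapes as the parameters) and the scalar `loss`.
#' @export
vgrf_grad <- function(model, x, y, lambda = 0.01, reg = c("l2", "l1")) {
  reg <- match.arg(reg)
  X <- as_input_matrix(model, x)
  Y <- if (is.null(dim(y))) matrix(y, nrow = 1L) else as.matrix(y)
  n <- nrow(X)
  act <- activation_funs(model$activation)
  hf <- hidden_forward(model, X)
  Yhat <- sweep(hf$Z %*% t(model$W_out), 2, model$b_out, "-")
  R <- Yhat - Y
  G <- 2 * R / (n * 101)                       # dL/dYhat, n x 101
  dZ <- G %*% model$W_out                      # n x K
  dU <- dZ * act$df(hf$U)
  dS <- sweep(dU, 2, model$a_scale, "/")
  pen_grad <- function(w) if (reg == "l2") 2 * lambda * w else lambda * sign(w)
  gW_out <- t(G) %*% hf$Z + pen_grad(model$W_out)
  gb_out <- -colSums(G) + pen_grad(model$b_out)
  gW_hidden <- t(dS) %*% X + pen_grad(model$W_hidden)
  gb_shift <- -colSums(dS) + pen_grad(model$b_shift)
  ga_scale <- -colSums(dU * hf$U) / model$a_scale + pen_grad(model$a_scale)
  data_term <- sum(R^2) / (n * 101)
  pen <- if (reg == "l2") param_sq_norm(model) else param_abs_norm(model)
  list(W_hidden = gW_hidden, b_shift = gb_shift, a_scale = ga_scale,
       W_out = gW_out, b_out = gb_out, loss = data_term + lambda * pen)
}

#' Training configuration
#'
#' Defaults are the final hyperparameters of the study design: one hidden
#' layer with `K = 200` nodes, L2 regularization `lambda_l2 = 0.01`, batch
#' size 128, 100 epochs, learning rate 5e-4, Adam with standard moments.
#'
#' @param lambda_l2 regularization strength.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param epochs number of full passes over the training data.
#' @param K hidden-layer width.
#' @param seed integer; fully determines initialization and batch order.
#' @param beta1,beta2,eps Adam moment/stabilizer constants.
#' @param reg `"l2"` or `"l1"`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lambda_l2 = 0.01, learning_rate = 5e-4,
                         batch_size = 128, epochs = 100, K = 200, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         reg = c("l2", "l1")) {
  reg <- match.arg(reg)
  for (nm in c("lambda_l2", "learning_rate", "batch_size", "epochs", "K"))
    check_number(get(nm), nm, lower = 0)
  structure(list(lambda_l2 = lambda_l2, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), K = as.integer(K),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 eps = eps, reg = reg),
            class = "train_config")
}

#' Initialize a vGRF network
#'
#' Weights are drawn uniformly from `(-r, r)` with radius `1/sqrt(101*m)`.
#' The shifting and scaling factors are set per node from the mean and SD of
#' that node's pre-activations over the provided input sample (the standard
#' wavelet-network recipe: translations/dilations are placed to cover the
#' input domain, which matters because the acceleration inputs are not
#' normalized); without data they fall back to `b_k = 0`, `a_k = 1`.  The
#' output bias is set so the initial prediction equals the mean training
#' curve (0 without data).
#'
#' @param activation `"morlet"` or `"sigmoid"`.
#' @param K hidden width.
#' @param m input channels (1 or 3).
#' @param x optional n x `101*m` input matrix used to place `b_k`, `a_k`.
#' @param y optional n x 101 target matrix used to set the output bias.
#' @return A `vgrf_model`.  Uses the current RNG state; seed externally.
#' @export
init_vgrf_model <- function(activation, K, m, x = NULL, y = NULL) {
  D <- 101L * m
  r <- 1 / sqrt(D)
  W_hidden <- matrix(runif(K * D, -r, r), K, D)
  W_out <- matrix(runif(101L * K, -r, r), 101L, K)
  if (!is.null(x) && nrow(as.matrix(x)) >= 2L) {
    S <- as.matrix(x) %*% t(W_hidden)
    b_shift <- colMeans(S)
    a_scale <- pmax(apply(S, 2, sd), 1)
  } else {
    b_shift <- rep(0, K); a_scale <- rep(1, K)
  }
  b_out <- if (!is.null(y)) -colMeans(as.matrix(y)) else rep(0, 101L)
  new_vgrf_model(activation, K, m, W_hidden, b_shift, a_scale, W_out, b_out)
}

#' Train a vGRF network with mini-batch Adam
#'
#' Runs exactly `cfg$epochs` epochs of mini-batch Adam on the regularized
#' loss, with the data reshuffled every epoch (seeded).  After every step
#' the scaling factors are re-clamped to `|a_k| >= 1e-3`.  Identical seeds
#' give identical parameters.
#'
#' @param train a dataset list with `x` (n x `101*m`) and `y` (n x 101), as
#'   produced by [build_datasets()].
#' @param cfg a [train_config()].
#' @param activation `"morlet"` (WNN) or `"sigmoid"` (FFNN).
#' @return List with `model` (the trained `vgrf_model`) and `history`
#'   (per-epoch full-training-set loss, length `cfg$epochs`).
#' @export
train_vgrf <- function(train, cfg = train_config(),
                       activation = c("morlet", "sigmoid")) {
  activation <- match.arg(activation)
  X <- as.matrix(train$x); Y <- as.matrix(train$y)
  n <- nrow(X)
  if (n < 1L) abort_invalid("empty training set")
  m <- ncol(X) / 101L
  if (m != floor(m)) abort_invalid("input width %d is not a multiple of 101", ncol(X))
  set.seed(cfg$seed)
  model <- init_vgrf_model(activation, cfg$K, m, X, Y)
  params <- c("W_hidden", "b_shift", "a_scale", "W_out", "b_out")
  mom1 <- lapply(model[params], function(p) p * 0)
  mom2 <- mom1
  step <- 0L
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    for (b in starts) {
      idx <- perm[b:min(b + cfg$batch_size - 1L, n)]
      g <- vgrf_grad(model, X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                     cfg$lambda_l2, cfg$reg)
      if (!is.finite(g$loss))
        abort_training("non-finite loss at epoch %d", epoch)
      step <- step + 1L
      bc1 <- 1 - cfg$beta1^step; bc2 <- 1 - cfg$beta2^step
      for (p in params) {
        mom1[[p]] <- cfg$beta1 * mom1[[p]] + (1 - cfg$beta1) * g[[p]]
        mom2[[p]] <- cfg$beta2 * mom2[[p]] + (1 - cfg$beta2) * g[[p]]^2
        model[[p]] <- model[[p]] - cfg$learning_rate * (mom1[[p]] / bc1) /
          (sqrt(mom2[[p]] / bc2) + cfg$eps)
      }
      a <- model$a_scale
      model$a_scale <- ifelse(abs(a) < A_MIN, ifelse(a < 0, -A_MIN, A_MIN), a)
    }
    history[epoch] <- vgrf_loss(model, X, Y, cfg$lambda_l2, cfg$reg)
    if (!is.finite(history[epoch]))
      abort_training("non-finite loss at epoch %d", epoch)
  }
  list(model = model, history = history)
}

#' Predict stance vGRF curves for a dataset
#'
#' @param model a `vgrf_model`.
#' @param dataset a dataset list with `x`; rows are samples.
#' @return An n x 101 matrix of predicted curves (BW); 0-row matrix for an
#'   empty dataset.
#' @export
predict_dataset <- function(model, dataset) {
  X <- as.matrix(dataset$x)
  if (nrow(X) == 0L) return(matrix(numeric(0), 0L, 101L))
  vgrf_forward(model, X)
}

#' Save / load a model as JSON
#'
#' Structured text holding the activation, dimensions and all parameter
#' arrays with shape metadata.
#'
#' @param model a `vgrf_model`.
#' @param path file path.
#' @return `read_vgrf_model()` returns the restored `vgrf_model`.
#' @export
write_vgrf_model <- function(model, path) {
  obj <- list(activation = model$activation, K = model$K, m = model$m,
              W_hidden = list(dim = dim(model$W_hidden),
                              data = as.numeric(model$W_hidden)),
              b_shift = model$b_shift, a_scale = model$a_scale,
              W_out = list(dim = dim(model$W_out),
                           data = as.numeric(model$W_out)),
              b_out = model$b_out)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vgrf_model
#' @export
read_vgrf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_vgrf_model(obj$activation, obj$K, obj$m,
                 matrix(obj$W_hidden$data, obj$W_hidden$dim[1],
                        obj$W_hidden$dim[2]),
                 obj$b_shift, obj$a_scale,
                 matrix(obj$W_out$data, obj$W_out$dim[1], obj$W_out$dim[2]),
                 obj$b_out)
}
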