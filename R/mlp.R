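# Minimal dense multilayer perceptron engine.
#
# All learned components (biomarker transition nets, the mu/T heads of the
# outcome estimator, the deep Q-net, the WGAN-GP critic and generator) are
# small fully connected networks; this file provides their shared forward,
# backward and Adam machinery on plain matrices. Hidden layers share one
# activation; the output layer is always linear.

ACTIVATIONS <- list(
  tanh = list(
    f = function(z) tanh(z),
    df = function(z, a) 1 - a * a
  ),
  relu = list(
    f = function(z) pmax(z, 0),
    df = function(z, a) (z > 0) * 1
  )
)

#' Create a dense multilayer perceptron
#'
#' @param sizes Integer vector of layer widths, input first, output last,
#'   e.g. `c(5, 64, 64, 64, 32)`.
#' @param activation Hidden-layer activation, `"tanh"` or `"relu"`. The output
#'   layer is linear.
#' @param seed Optional integer; when given, weight initialization is
#'   deterministic.
#' @return An object of class `mlp`.
#' @keywords internal
mlp_init <- function(sizes, activation = "tanh", seed = NULL) {
  if (length(sizes) < 2L) stop_config("an MLP needs at least input and output sizes")
  if (!activation %in% names(ACTIVATIONS)) {
    stop_config("unknown activation: ", activation)
  }
  if (!is.null(seed)) set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    n_in <- sizes[l]
    n_out <- sizes[l + 1L]
    # He/Glorot-style scaling keeps activations in range at these widths
    sd <- sqrt(2 / (n_in + n_out))
    W[[l]] <- matrix(stats::rnorm(n_out * n_in, sd = sd), nrow = n_out, ncol = n_in)
    b[[l]] <- numeric(n_out)
  }
  structure(
    list(sizes = as.integer(sizes), W = W, b = b, activation = activation),
    class = "mlp"
  )
}

# Forward pass. X: n x d matrix. Returns list(out, zs, as) where as[[1]] is the
# input and as[[l + 1]] the activation after layer l.
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  act <- ACTIVATIONS[[net$activation]]
  L <- length(net$W)
  as <- vector("list", L + 1L)
  zs <- vector("list", L)
  as[[1L]] <- X
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% t(net$W[[l]])
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    zs[[l]] <- Z
    A <- if (l < L) act$f(Z) else Z
    as[[l + 1L]] <- A
  }
  list(out = A, zs = zs, as = as)
}

mlp_predict <- function(net, X) mlp_forward(net, X)$out

# Backward pass from dL/dout (n x k). Returns weight/bias gradients (summed
# over the batch; divide upstream if a mean is wanted) and dL/dinput.
mlp_backward <- function(net, fwd, d_out) {
  act <- ACTIVATIONS[[net$activation]]
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- d_out
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * act$df(fwd$zs[[l]], fwd$as[[l + 1L]])
    gW[[l]] <- t(delta) %*% fwd$as[[l]]
    gb[[l]] <- colSums(delta)
    delta <- delta %*% net$W[[l]]
  }
  list(gW = gW, gb = gb, d_input = delta)
}

# Gradient of the scalar output w.r.t. the inputs, per row. Only valid for
# single-output networks; returns an n x d matrix.
mlp_input_grad <- function(net, X) {
  fwd <- mlp_forward(net, X)
  if (ncol(fwd$out) != 1L) stop_domain("input gradient requires a scalar-output net")
  mlp_backward(net, fwd, matrix(1, nrow = nrow(fwd$out)))$d_input
}

adam_init <- function(net) {
  list(
    m_W = lapply(net$W, function(w) w * 0), v_W = lapply(net$W, function(w) w * 0),
    m_b = lapply(net$b, function(b) b * 0), v_b = lapply(net$b, function(b) b * 0),
    t = 0L
  )
}

adam_step <- function(net, opt, gW, gb, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$m_W[[l]] <- beta1 * opt$m_W[[l]] + (1 - beta1) * gW[[l]]
    opt$v_W[[l]] <- beta2 * opt$v_W[[l]] + (1 - beta2) * gW[[l]]^2
    opt$m_b[[l]] <- beta1 * opt$m_b[[l]] + (1 - beta1) * gb[[l]]
    opt$v_b[[l]] <- beta2 * opt$v_b[[l]] + (1 - beta2) * gb[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$m_W[[l]] / c1) / (sqrt(opt$v_W[[l]] / c2) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (opt$m_b[[l]] / c1) / (sqrt(opt$v_b[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}
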