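# WGAN-GP tabular augmentation. The critic is a one-hidden-layer tanh
# network: for that architecture the gradient of the gradient penalty with
# respect to the critic weights (a second-order quantity) has an exact
# closed form, derived in the methods vignette, so training needs no
# automatic differentiation. The generator is an arbitrary-depth MLP whose
# gradients flow through the critic to first order only. Features are
# min-max scaled to [-1, 1] for training; generated records are mapped back,
# clipped to the training support, and the categorical columns snapped.

#' WGAN-GP configuration
#'
#' @param latent_dim Generator input (noise) dimension.
#' @param critic_hidden Width of the critic's single tanh hidden layer.
#' @param gen_hidden Generator hidden widths.
#' @param lambda Gradient-penalty weight.
#' @param n_critic Critic updates per generator update.
#' @param epochs Generator updates.
#' @param batch Minibatch size.
#' @param lr Adam learning rate (beta1 = 0.5, beta2 = 0.9, the WGAN-GP
#'   convention).
#' @param n_generate Records emitted by [augment_cohort()] (default 4000).
#' @param ema_decay Exponential-moving-average decay applied to the
#'   generator weights; sampling uses the averaged generator, which damps
#'   the oscillation inherent in adversarial training.
#' @param seed RNG seed.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 8L, critic_hidden = 32L,
                       gen_hidden = c(32, 32), lambda = 10, n_critic = 5L,
                       epochs = 400L, batch = 64L, lr = 5e-4,
                       n_generate = 4000L, ema_decay = 0.999, seed = 1L) {
  if (lambda < 0) stop_config("lambda must be >= 0")
  if (n_generate < 0) stop_config("n_generate must be >= 0")
  structure(as.list(environment()), class = "gan_config")
}

#' Gradient penalty of a critic on interpolated samples
#'
#' Interpolates `x_hat = eps * real + (1 - eps) * fake` with per-sample
#' `eps ~ U(0, 1)` and returns
#' `lambda * mean((||grad_x critic(x_hat)|| - 1)^2)`, the soft unit-Lipschitz
#' constraint of WGAN-GP. Zero exactly when the critic's input gradients
#' have unit norm everywhere on the interpolates.
#'
#' @param critic A scalar-output `mlp`.
#' @param real,fake Matrices of equal shape.
#' @param lambda Penalty weight.
#' @return Nonnegative scalar.
#' @export
gradient_penalty <- function(critic, real, fake, lambda = 10) {
  real <- as.matrix(real)
  fake <- as.matrix(fake)
  if (!all(dim(real) == dim(fake))) stop_domain("real and fake batches must match in shape")
  eps <- stats::runif(nrow(real))
  xhat <- eps * real + (1 - eps) * fake
  grads <- mlp_input_grad(critic, xhat)
  norms <- sqrt(rowSums(grads^2))
  lambda * mean((norms - 1)^2)
}

# Closed-form gradient of the mean gradient penalty w.r.t. the weights of a
# critic with zero (linear) or one tanh hidden layer. Returns gW/gb lists
# aligned with the critic's layers.
gp_weight_grads <- function(critic, xhat, lambda) {
  L <- length(critic$W)
  B <- nrow(xhat)
  if (L == 1L) {
    # linear critic: grad_x f = w for every x
    w <- as.numeric(critic$W[[1L]])
    r <- sqrt(sum(w^2))
    gw <- if (r > 0) 2 * lambda * (r - 1) * w / r else -2 * lambda * w * 0
    return(list(gW = list(matrix(gw, nrow = 1L)), gb = list(0)))
  }
  if (L != 2L) stop_domain("gradient-penalty training supports critics with at most one hidden layer")
  W1 <- critic$W[[1L]]                       # H x d
  w2 <- as.numeric(critic$W[[2L]])           # H
  Z <- sweep(xhat %*% t(W1), 2L, critic$b[[1L]], "+")
  Hm <- tanh(Z)                              # B x H
  Dm <- 1 - Hm^2
  W2rep <- matrix(w2, B, length(w2), byrow = TRUE)
  U <- (Dm * W2rep) %*% W1                   # B x d: per-sample input gradient
  r <- sqrt(rowSums(U^2))
  r_safe <- pmax(r, 1e-12)
  V <- (2 * lambda * (r - 1) / r_safe / B) * U          # dP/dU, mean over batch
  VW1t <- V %*% t(W1)                         # B x H: W1 %*% v per sample
  gW2 <- colSums(Dm * VW1t)                   # dP/dw2
  Qm <- VW1t * W2rep                          # dP/dD
  dPdZ <- Qm * (-2 * Hm * Dm)
  gW1 <- t(Dm * W2rep) %*% V + t(dPdZ) %*% xhat
  gb1 <- colSums(dPdZ)
  list(gW = list(gW1, matrix(gW2, nrow = 1L)), gb = list(gb1, 0))
}

minmax_fit <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  span <- pmax(hi - lo, 1e-12)
  list(lo = lo, hi = hi, span = span)
}
minmax_apply <- function(s, X) sweep(sweep(X, 2L, s$lo, "-"), 2L, s$span, "/") * 2 - 1
minmax_invert <- function(s, Xs) sweep(sweep((Xs + 1) / 2, 2L, s$span, "*"), 2L, s$lo, "+")

#' Fit a WGAN-GP on a numeric table
#'
#' Alternates `n_critic` critic updates (Wasserstein estimate plus gradient
#' penalty, with the exact penalty weight-gradient) with one generator
#' update, on min-max scaled data.
#'
#' @param data Numeric matrix or data frame (rows = records).
#' @param config A [gan_config()].
#' @return A list of class `wgan` with the generator, critic, scaler, the
#'   column names, and the per-epoch critic Wasserstein estimate
#'   (`w_estimate`).
#' @export
fit_wgan <- function(data, config = gan_config()) {
  X <- as.matrix(data)
  if (nrow(X) == 0L) stop_domain("cannot fit a WGAN on an empty table")
  d <- ncol(X)
  set.seed(config$seed)
  scaler <- minmax_fit(X)
  Xs <- minmax_apply(scaler, X)
  critic <- mlp_init(c(d, config$critic_hidden, 1L), activation = "tanh")
  gen <- mlp_init(c(config$latent_dim, config$gen_hidden, d), activation = "tanh")
  c_opt <- adam_init(critic)
  g_opt <- adam_init(gen)
  n <- nrow(Xs)
  B <- min(config$batch, n)
  w_estimate <- numeric(config$epochs)

  sample_real <- function() Xs[sample.int(n, B, replace = n < B), , drop = FALSE]
  sample_fake <- function() {
    z <- matrix(stats::rnorm(B * config$latent_dim), B)
    list(z = z, fwd = mlp_forward(gen, z))
  }

  for (ep in seq_len(config$epochs)) {
    for (ci in seq_len(config$n_critic)) {
      real <- sample_real()
      fake <- sample_fake()$fwd$out
      eps <- stats::runif(B)
      xhat <- eps * real + (1 - eps) * fake
      Xcat <- rbind(fake, real)
      fwd <- mlp_forward(critic, Xcat)
      # critic loss: mean f(fake) - mean f(real) (+ GP)
      d_out <- matrix(c(rep(1 / B, B), rep(-1 / B, B)), ncol = 1L)
      gr <- mlp_backward(critic, fwd, d_out)
      gp <- gp_weight_grads(critic, xhat, config$lambda)
      gW <- Map(`+`, gr$gW, gp$gW)
      gb <- Map(`+`, gr$gb, gp$gb)
      st <- adam_step(critic, c_opt, gW, gb, lr = config$lr,
                      beta1 = 0.5, beta2 = 0.9)
      critic <- st$net
      c_opt <- st$opt
      if (ci == config$n_critic) {
        w_estimate[ep] <- mean(fwd$out[(B + 1):(2 * B), 1]) - mean(fwd$out[1:B, 1])
      }
    }
    fake <- sample_fake()
    c_fwd <- mlp_forward(critic, fake$fwd$out)
    d_fake <- mlp_backward(critic, c_fwd, matrix(-1 / B, B, 1L))$d_input
    gr <- mlp_backward(gen, fake$fwd, d_fake)
    st <- adam_step(gen, g_opt, gr$gW, gr$gb, lr = config$lr,
                    beta1 = 0.5, beta2 = 0.9)
    gen <- st$net
    g_opt <- st$opt
    if (ep == 1L) {
      gen_ema <- gen
    } else {
      a <- config$ema_decay
      for (l in seq_along(gen$W)) {
        gen_ema$W[[l]] <- a * gen_ema$W[[l]] + (1 - a) * gen$W[[l]]
        gen_ema$b[[l]] <- a * gen_ema$b[[l]] + (1 - a) * gen$b[[l]]
      }
    }
  }
  structure(
    list(generator = gen_ema, generator_raw = gen, critic = critic, scaler = scaler,
         columns = colnames(X), latent_dim = config$latent_dim,
         support = list(lo = apply(X, 2L, min), hi = apply(X, 2L, max)),
         w_estimate = w_estimate, config = config),
    class = "wgan"
  )
}

#' Sample records from a fitted WGAN
#'
#' Generated values are mapped back to the data scale and clipped to the
#' training support column-wise.
#'
#' @param model A [fit_wgan()] fit.
#' @param n Number of records.
#' @return Numeric matrix with the training columns.
#' @export
wgan_generate <- function(model, n) {
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, length(model$columns))
    colnames(out) <- model$columns
    return(out)
  }
  z <- matrix(stats::rnorm(n * model$latent_dim), n)
  Xs <- mlp_predict(model$generator, z)
  X <- minmax_invert(model$scaler, Xs)
  for (j in seq_len(ncol(X))) {
    X[, j] <- pmin(pmax(X[, j], model$support$lo[j]), model$support$hi[j])
  }
  colnames(X) <- model$columns
  X
}

#' Fit a WGAN-GP on a cohort and emit synthetic records
#'
#' Learns the joint distribution of the numeric cohort fields and generates
#' `config$n_generate` additional records in the cohort schema. Genotype is
#' snapped to the allele counts {0, 1, 2} and the binary outcomes to {0, 1};
#' continuous fields are clipped to the training support. Synthetic rows
#' carry `is_synthetic = TRUE` and fresh ids.
#'
#' @param cohort Cohort data frame ([cohort_columns]).
#' @param config A [gan_config()].
#' @return Data frame of `config$n_generate` synthetic records with an
#'   `is_synthetic` column; the fitted model in attribute `wgan`.
#' @export
augment_cohort <- function(cohort, config = gan_config()) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0L) stop_domain("cannot augment an empty cohort")
  num_cols <- setdiff(cohort_columns, "patient_id")
  model <- fit_wgan(as.matrix(cohort[, num_cols]), config)
  X <- wgan_generate(model, config$n_generate)
  df <- as.data.frame(X)
  if (nrow(df) > 0L) {
    df$genotype <- as.integer(pmin(pmax(round(df$genotype), 0L), 2L))
    df$lc <- as.integer(round(df$lc) != 0)
    df$rp2 <- as.integer(round(df$rp2) != 0)
    df$patient_id <- sprintf("S%04d", seq_len(nrow(df)))
  } else {
    df$patient_id <- character(0)
  }
  df$is_synthetic <- rep(TRUE, nrow(df))
  df <- df[, c(cohort_columns, "is_synthetic")]
  attr(df, "wgan") <- model
  df
}
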