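# Multilayer perceptron with ELU activations, trained by Adam.  This is
# the predictor f_theta behind both selection layers and the downstream
# evaluation models.  Written in vectorised base R: each step is a handful
# of BLAS matmuls, which is plenty for the panel-selection problem sizes.

mlp_init <- function(d_in, d_out, hidden = c(128L, 128L)) {
  if (!length(hidden)) stopf("at least one hidden layer is required")
  dims <- c(d_in, hidden, d_out)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    # He initialisation, appropriate for the ELU nonlinearity.
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b, n_layers = length(W))
}

mlp_forward <- function(net, X) {
  L <- net$n_layers
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- H[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    H[[l + 1L]] <- elu(Z)
  }
  O <- H[[L]] %*% net$W[[L]]
  O <- O + rep(net$b[[L]], each = nrow(O))
  list(O = O, H = H)
}

mlp_backward <- function(net, fw, dO) {
  L <- net$n_layers
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dO
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fw$H[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * elu_grad(fw$H[[l]])
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

mlp_predict <- function(net, X) mlp_forward(net, X)$O

# ---- Adam over a flat named list of arrays --------------------------------

adam_new <- function(params) {
  zeros <- lapply(params, function(p) {p[] <- 0; p})
  list(m = zeros, v = zeros, t = 0L)
}

adam_update <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

params_flatten <- function(net) {
  out <- list()
  for (l in seq_len(net$n_layers)) {
    out[[paste0("W", l)]] <- net$W[[l]]
    out[[paste0("b", l)]] <- net$b[[l]]
  }
  out
}

params_unflatten <- function(flat, net) {
  for (l in seq_len(net$n_layers)) {
    net$W[[l]] <- flat[[paste0("W", l)]]
    net$b[[l]] <- flat[[paste0("b", l)]]
  }
  net
}

grads_flatten <- function(bw, n_layers) {
  out <- list()
  for (l in seq_len(n_layers)) {
    out[[paste0("W", l)]] <- bw$dW[[l]]
    out[[paste0("b", l)]] <- bw$db[[l]]
  }
  out
}

# ---- Plain predictor training --------------------------------------------

# Trains an MLP (no selection layer) with minibatched Adam and early
# stopping on the validation loss.  `loss_kind` picks the objective:
# reconstruction (hurdle), classification (softmax CE), regression (MSE),
# detection (per-gene BCE).  Batches carry y (and `expressed` for the
# hurdle loss).
mlp_fit <- function(Xtr, ytr, Xval, yval, loss_kind, d_out,
                    expressed_tr = NULL, expressed_val = NULL,
                    hidden = c(128L, 128L), max_epochs = 100L,
                    minibatch_size = 128L, learning_rate = 1e-3,
                    patience = 20L, gamma = 10, seed = 1L, verbose = FALSE) {
  set.seed(as.integer(seed))
  lg <- loss_grad_for(loss_kind)
  net <- mlp_init(ncol(Xtr), d_out, hidden)
  flat <- params_flatten(net)
  opt <- adam_new(flat)
  n <- nrow(Xtr)
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  wait <- 0L
  history <- vector("list", max_epochs)
  eval_loss <- function(flat, X, y, expressed) {
    netv <- params_unflatten(flat, net)
    O <- mlp_predict(netv, X)
    lg(O, list(y = y, expressed = expressed), gamma = gamma)$loss
  }
  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = minibatch_size)
    tr_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + minibatch_size - 1L, n)]
      batch <- list(
        y = if (is.matrix(ytr)) ytr[idx, , drop = FALSE] else ytr[idx],
        expressed = if (is.null(expressed_tr)) NULL else
          expressed_tr[idx, , drop = FALSE])
      net <- params_unflatten(flat, net)
      fw <- mlp_forward(net, Xtr[idx, , drop = FALSE])
      l <- lg(fw$O, batch, gamma = gamma)
      if (!is.finite(l$loss))
        stopf("non-finite training loss at epoch %d", epoch)
      bw <- mlp_backward(net, fw, l$dO)
      upd <- adam_update(flat, grads_flatten(bw, net$n_layers), opt,
                         lr = learning_rate)
      flat <- upd$params; opt <- upd$state
      tr_loss <- tr_loss + l$loss * length(idx)
    }
    val <- eval_loss(flat, Xval,
                     if (is.matrix(yval)) yval else yval,
                     expressed_val)
    history[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / n,
                          val_loss = val)
    if (val < best$loss - 1e-9) {
      best <- list(loss = val, flat = flat, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net <- params_unflatten(best$flat, net)
  list(net = net,
       history = tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null, logical(1))])),
       best_val_loss = best$loss, best_epoch = best$epoch)
}
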