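#' Training configuration
#'
#' Optimisation settings shared by the selection trainers: Adam at the
#' standard learning rate 1e-3, minibatches of 128 cells, geometric
#' temperature annealing from 10.0 to 0.01 applied once per optimisation
#' step over the planned step count, early stopping on the validation
#' loss, and the hurdle weighting `gamma = 10`.
#'
#' @param max_epochs Maximum training epochs.
#' @param minibatch_size Cells per minibatch (default 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Integer seed governing initialisation, shuffling and all
#'   relaxation noise.
#' @param gamma Hurdle loss weighting (default 10).
#' @param tau_init,tau_final Temperature schedule endpoints (defaults 10.0
#'   and 0.01).
#' @param hidden Hidden-layer widths of the predictor MLP.
#' @param secant_epoch_frac Fraction of `max_epochs` used for the
#'   gene-counting trainings inside the secant search (only the surviving
#'   gene count matters there; the final stage retrains fully).
#' @param verbose Print per-epoch progress?
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 500L, minibatch_size = 128L,
                         learning_rate = 1e-3, patience = 50L, seed = 1L,
                         gamma = 10, tau_init = 10, tau_final = 0.01,
                         hidden = c(128L, 128L), secant_epoch_frac = 0.5,
                         verbose = FALSE) {
  stopifnot(max_epochs >= 1, minibatch_size >= 1, learning_rate > 0,
            patience >= 1, gamma > 0, tau_init > tau_final, tau_final > 0,
            secant_epoch_frac > 0, secant_epoch_frac <= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 minibatch_size = as.integer(minibatch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 seed = as.integer(seed), gamma = gamma, tau_init = tau_init,
                 tau_final = tau_final, hidden = as.integer(hidden),
                 secant_epoch_frac = secant_epoch_frac, verbose = verbose),
            class = "train_config")
}

# One optimisation step through selection layer + predictor: loss and
# analytic gradients for all trainable parameters.  In training mode the
# relaxation noise is sampled per cell (see mask_forward_percell); a fixed
# `noise` matrix can be supplied so finite differences can verify the
# gradients.  In evaluation mode the deterministic single-sample forwards
# are used and no gradients for the selection layer are needed.  X is the
# candidate-gene input batch; X_pre optional preselected columns appended
# unmasked.
selector_step <- function(sel, net, X, batch, tau, loss_grad, gamma,
                          noise = NULL, X_pre = NULL, training = TRUE) {
  is_mask <- inherits(sel, "concrete_selector")
  layer <- if (training) {
    if (is_mask) mask_forward_percell(sel, X, tau, noise = noise)
    else gates_forward_percell(sel, X, tau, noise = noise)
  } else {
    if (is_mask) binary_mask_forward(sel, X, tau, training = FALSE)
    else binary_gates_forward(sel, X, tau, training = FALSE)
  }
  Z0 <- if (is.null(X_pre)) layer$xm else cbind(layer$xm, X_pre)
  fw <- mlp_forward(net, Z0)
  l <- loss_grad(fw$O, batch, gamma = gamma)
  loss <- l$loss + if (is_mask) 0 else layer$penalty
  bw <- mlp_backward(net, fw, l$dO)
  grads <- grads_flatten(bw, net$n_layers)
  d <- ncol(X)
  dxm <- bw$dX[, seq_len(d), drop = FALSE]
  if (training) {
    if (is_mask) {
      grads$log_alpha <- mask_backward_percell(sel, layer, dxm, X, tau)
    } else {
      grads$log_beta <- gates_backward_percell(sel, layer, dxm, X, tau)
    }
  }
  list(loss = loss, data_loss = l$loss, grads = grads, layer = layer)
}

#' Train a selection model
#'
#' Jointly optimises a selection layer (Concrete binary mask or
#' Binary-Concrete gates) and the predictor network on the training split,
#' annealing the relaxation temperature once per step, with early
#' stopping on the deterministic evaluation-mode validation loss scored at
#' the final temperature (so the tracked loss reflects the effectively
#' discrete selection the model converges to, not a mid-anneal mask). For
#' the gates layer the sparsity penalty `lambda * sum(b)` is part of the
#' optimised and validated objective. Fully reproducible under the
#' config seed.
#'
#' @param data A [prepare_dataset()] result.
#' @param layer `"mask"` (exactly-k Concrete selection) or `"gates"`
#'   (penalised Binary-Concrete pre-filtering).
#' @param k Panel size (mask layer).
#' @param lam Penalty coefficient lambda (gates layer).
#' @param cfg A [train_config()].
#' @param candidates Integer indices (into `data$gene_names`) of
#'   candidate genes; default all genes.
#' @param preselected Integer indices of genes that bypass selection:
#'   their binarized expression is always appended, unmasked, to the
#'   predictor input.
#' @param max_epochs_override Optional reduced epoch budget (used by the
#'   secant search).
#' @return A `selector_fit`: the trained `sel` layer and `net`, the
#'   per-epoch `history` tibble (epoch, train_loss, val_loss, tau),
#'   `best_val_loss`, `best_epoch`, `converged`, plus the candidate /
#'   preselected bookkeeping.
#' @export
train_selector <- function(data, layer = c("mask", "gates"), k = NULL,
                           lam = 0, cfg = train_config(),
                           candidates = NULL, preselected = NULL,
                           max_epochs_override = NULL) {
  stopifnot(inherits(data, "prepared_dataset"))
  layer <- match.arg(layer)
  set.seed(cfg$seed)
  candidates <- candidates %||% seq_along(data$gene_names)
  candidates <- setdiff(as.integer(candidates), as.integer(preselected %||% integer()))
  d <- length(candidates)
  if (layer == "mask" && (is.null(k) || k < 1L || k > d))
    stopf("mask layer needs 1 <= k <= %d candidates", d)
  max_epochs <- as.integer(max_epochs_override %||% cfg$max_epochs)

  sp <- data$splits
  Xtr <- data$x_binary[sp$train, candidates, drop = FALSE]
  Xval <- data$x_binary[sp$val, candidates, drop = FALSE]
  pre <- as.integer(preselected %||% integer())
  Xtr_pre <- if (length(pre)) data$x_binary[sp$train, pre, drop = FALSE] else NULL
  Xval_pre <- if (length(pre)) data$x_binary[sp$val, pre, drop = FALSE] else NULL
  slice_target <- function(idx) {
    if (is.matrix(data$target)) data$target[idx, , drop = FALSE] else data$target[idx]
  }
  ytr <- slice_target(sp$train); yval <- slice_target(sp$val)
  etr <- if (!is.null(data$expressed)) data$expressed[sp$train, , drop = FALSE]
  eval_ <- if (!is.null(data$expressed)) data$expressed[sp$val, , drop = FALSE]

  lg <- loss_grad_for(data$target_kind)
  sel <- if (layer == "mask") new_concrete_selector(d, k) else new_binary_gates(d, lam)
  net <- mlp_init(d + length(pre), output_dim_for(data), cfg$hidden)
  flat <- c(params_flatten(net),
            if (layer == "mask") list(log_alpha = sel$log_alpha)
            else list(log_beta = sel$log_beta))
  opt <- adam_new(flat)

  n <- nrow(Xtr)
  n_batches <- ceiling(n / cfg$minibatch_size)
  total_steps <- max_epochs * n_batches
  step <- 0L
  best <- list(loss = Inf, flat = flat, epoch = 0L, tau = cfg$tau_init)
  wait <- 0L
  history <- vector("list", max_epochs)

  restore <- function(flat) {
    net <- params_unflatten(flat, net)
    if (layer == "mask") sel$log_alpha <- flat$log_alpha else sel$log_beta <- flat$log_beta
    list(sel = sel, net = net)
  }
# Validation is always scored in evaluation mode at the FINAL temperature:
  # that measures the model as it will be used (an effectively discrete
  # selection), so the best-validation snapshot corresponds to a converged
  # mask rather than a mid-anneal diffuse one.
  val_loss_at <- function(flat) {
    st <- restore(flat)
    selector_step(st$sel, st$net, Xval, list(y = yval, expressed = eval_),
                  cfg$tau_final, lg, cfg$gamma, X_pre = Xval_pre,
                  training = FALSE)
  }

  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$minibatch_size)
    tr_loss <- 0
    for (s in starts) {
      step <- step + 1L
      tau <- anneal_tau(step, total_steps, cfg$tau_init, cfg$tau_final)
      idx <- perm[s:min(s + cfg$minibatch_size - 1L, n)]
      st <- restore(flat)
      batch <- list(y = if (is.matrix(ytr)) ytr[idx, , drop = FALSE] else ytr[idx],
                    expressed = if (is.null(etr)) NULL else etr[idx, , drop = FALSE])
      res <- selector_step(st$sel, st$net, Xtr[idx, , drop = FALSE], batch, tau,
                           lg, cfg$gamma,
                           X_pre = if (is.null(Xtr_pre)) NULL else
                             Xtr_pre[idx, , drop = FALSE])
      if (!is.finite(res$loss))
        stopf("non-finite loss at epoch %d, step %d, tau %.4g (data loss %.4g)",
              epoch, step, tau, res$data_loss)
      upd <- adam_update(flat, res$grads, opt, lr = cfg$learning_rate)
      flat <- upd$params; opt <- upd$state
      tr_loss <- tr_loss + res$loss * length(idx)
    }
    vres <- val_loss_at(flat)
    val <- vres$loss
    history[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / n,
                          val_loss = val, tau = tau)
    if (cfg$verbose)
      message(sprintf("epoch %d: train %.4f val %.4f tau %.4g", epoch,
                      tr_loss / n, val, tau))
    if (val < best$loss - 1e-9) {
      best <- list(loss = val, flat = flat, epoch = epoch, tau = tau)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  st <- restore(best$flat)
  converged <- TRUE
  if (layer == "mask") {
    A <- softmax_rows(st$sel$log_alpha / cfg$tau_final)
    converged <- all(apply(A, 1L, max) > 0.99)
    if (!converged)
      warnf("Concrete slots not fully converged: max evaluation-mode probability %.3f < 0.99; consider more epochs",
            min(apply(A, 1L, max)))
  }
  hist_df <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null, logical(1))]))
  structure(list(sel = st$sel, net = st$net, layer = layer,
                 history = hist_df, best_val_loss = best$loss,
                 best_epoch = best$epoch, converged = converged,
                 candidates = candidates, preselected = pre,
                 target_kind = data$target_kind, seed = cfg$seed),
            class = "selector_fit")
}

#' @export
print.selector_fit <- function(x, ...) {
  cat(sprintf("<selector_fit> %s layer, best val loss %.4f (epoch %d)%s\n",
              x$layer, x$best_val_loss, x$best_epoch,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# Reference predictor with no selection layer, used for sanity checks and
# for the downstream evaluation models.
train_predictor <- function(data, genes = NULL, cfg = train_config(),
                            loss_kind = data$target_kind,
                            max_epochs_override = NULL) {
  stopifnot(inherits(data, "prepared_dataset"))
  genes <- genes %||% seq_along(data$gene_names)
  if (is.character(genes)) genes <- match(genes, data$gene_names)
  sp <- data$splits
  X <- data$x_binary[, genes, drop = FALSE]
  slice <- function(m, idx) if (is.matrix(m)) m[idx, , drop = FALSE] else m[idx]
  y <- if (loss_kind == "detection") data$expressed else data$target
  d_out <- if (loss_kind == "detection") ncol(data$expressed) else output_dim_for(data)
  mlp_fit(X[sp$train, , drop = FALSE], slice(y, sp$train),
          X[sp$val, , drop = FALSE], slice(y, sp$val),
          loss_kind = loss_kind, d_out = d_out,
          expressed_tr = if (loss_kind == "reconstruction")
            data$expressed[sp$train, , drop = FALSE],
          expressed_val = if (loss_kind == "reconstruction")
            data$expressed[sp$val, , drop = FALSE],
          hidden = cfg$hidden,
          max_epochs = as.integer(max_epochs_override %||% cfg$max_epochs),
          minibatch_size = cfg$minibatch_size,
          learning_rate = cfg$learning_rate, patience = cfg$patience,
          gamma = cfg$gamma, seed = cfg$seed)
}

# Test-split loss of a fixed gene subset: train the predictor on the
# subset and report the evaluation loss on held-out cells.  Used by the
# exhaustive-oracle checks.
subset_test_loss <- function(data, genes, cfg = train_config(),
                             max_epochs_override = NULL) {
  fit <- train_predictor(data, genes = genes, cfg = cfg,
                         max_epochs_override = max_epochs_override)
  sp <- data$splits
  if (is.character(genes)) genes <- match(genes, data$gene_names)
  O <- mlp_predict(fit$net, data$x_binary[sp$test, genes, drop = FALSE])
  lg <- loss_grad_for(data$target_kind)
  slice <- function(m, idx) if (is.matrix(m)) m[idx, , drop = FALSE] else m[idx]
  lg(O, list(y = slice(data$target, sp$test),
             expressed = if (!is.null(data$expressed))
               data$expressed[sp$test, , drop = FALSE]),
     gamma = cfg$gamma)$loss
}
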