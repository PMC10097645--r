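#' Geometric temperature annealing
#'
#' The relaxation temperature is annealed geometrically from `tau_init`
#' (default 10.0) to `tau_final` (default 0.01) over the planned number of
#' optimisation steps:
#' `tau(step) = tau_init * (tau_final / tau_init)^(step / total_steps)`,
#' so the per-step ratio is constant and selections become effectively
#' discrete by the end of training.
#'
#' @param step Integer step in `[0, total_steps]`.
#' @param total_steps Total planned optimisation steps.
#' @param tau_init,tau_final Positive endpoints with
#'   `tau_final < tau_init`.
#' @return The temperature at `step`.
#' @export
anneal_tau <- function(step, total_steps, tau_init = 10, tau_final = 0.01) {
  if (tau_init <= 0 || tau_final <= 0 || tau_final >= tau_init)
    stopf("need 0 < tau_final < tau_init")
  if (any(step < 0) || any(step > total_steps))
    stopf("step must lie in [0, %d]", total_steps)
  tau_init * (tau_final / tau_init)^(step / total_steps)
}

#' Sample from a Concrete (Gumbel-Softmax) distribution
#'
#' Returns `softmax((log_alpha + noise) / tau)`: a point in the simplex
#' that concentrates on `which.max(log_alpha + noise)` as `tau -> 0`. With
#' `noise = NULL` the deterministic tempered softmax is returned
#' (evaluation mode).
#'
#' @param log_alpha Numeric vector of log unnormalised probabilities.
#' @param tau Positive temperature.
#' @param noise Optional vector of Gumbel(0, 1) draws (e.g.
#'   [rgumbel()]); `NULL` for evaluation mode.
#' @return A probability vector summing to 1.
#' @export
sample_concrete <- function(log_alpha, tau, noise = NULL) {
  if (tau <= 0) stopf("tau must be positive")
  z <- if (is.null(noise)) log_alpha else log_alpha + noise
  as.numeric(softmax_rows(matrix(z / tau, nrow = 1L)))
}

#' Gumbel(0, 1) draws
#' @param n Number of draws.
#' @return Numeric vector `-log(-log(U))`, `U ~ Uniform(0,1)`.
#' @export
rgumbel <- function(n) -log(-log(stats::runif(n)))

#' Concrete binary-mask selection layer
#'
#' Selects exactly `k` genes from `d` candidates. Each of the `k` slots
#' holds a Concrete distribution over genes with log unnormalised
#' probabilities `log_alpha[i, ]`; the mask is the element-wise maximum of
#' the `k` slot samples and multiplies the (binarized) input. As the
#' temperature is annealed the mask converges to a 0/1 vector with a
#' single 1 per slot.
#'
#' @param d Number of candidate genes.
#' @param k Panel size (`k >= 1`).
#' @param init_range Initial `log_alpha` entries are drawn i.i.d.
#'   Uniform(-`init_range`, `init_range`).
#' @return A `concrete_selector` with fields `log_alpha` (k x d) and `k`.
#' @export
new_concrete_selector <- function(d, k, init_range = 0.01) {
  if (k < 1L) stopf("k must be >= 1")
  structure(list(
    log_alpha = matrix(stats::runif(k * d, -init_range, init_range), k, d),
    k = as.integer(k), d = as.integer(d)),
    class = "concrete_selector")
}

#' Binary-Concrete gates selection layer
#'
#' One relaxed Bernoulli gate per gene, used for pre-filtering a large
#' candidate set. Gate `i` has log unnormalised probability `log_beta[i]`
#' (initialised to 0, i.e. inclusion probability 1/2) and converges to a
#' Bernoulli with success probability `beta_i / (1 + beta_i)` as
#' `tau -> 0`. The training loss is augmented with the penalty
#' `lambda * sum(b)` on the sampled gates, which drives uninformative
#' gates to 0.
#'
#' @param d Number of candidate genes.
#' @param lam Non-negative penalty coefficient lambda.
#' @return A `binary_gates` with fields `log_beta` (length d) and `lam`.
#' @export
new_binary_gates <- function(d, lam = 0) {
  if (lam < 0) stopf("lam must be non-negative")
  structure(list(log_beta = rep(0, d), lam = lam, d = as.integer(d)),
            class = "binary_gates")
}

#' Forward pass of the binary-mask layer
#'
#' In training mode each slot draws fresh Gumbel noise; in evaluation mode
#' the deterministic tempered softmax is used so repeated passes agree.
#'
#' @param sel A [new_concrete_selector()].
#' @param x Input batch (cells x d).
#' @param tau Positive temperature.
#' @param training Draw stochastic samples?
#' @param noise Optional k x d matrix of Gumbel draws (overrides
#'   `training`; used for gradient checking).
#' @return List with the masked batch `xm`, the mask vector `a`, the slot
#'   sample matrix `A` (k x d) and per-gene argmax slot `amax`.
#' @export
binary_mask_forward <- function(sel, x, tau, training = TRUE, noise = NULL) {
  stopifnot(inherits(sel, "concrete_selector"))
  if (ncol(x) != sel$d) stopf("input width %d != selector d %d", ncol(x), sel$d)
  if (is.null(noise) && training)
    noise <- matrix(rgumbel(sel$k * sel$d), sel$k, sel$d)
  z <- if (is.null(noise)) sel$log_alpha else sel$log_alpha + noise
  A <- softmax_rows(z / tau)
  amax <- max.col(t(A), ties.method = "first")  # winning slot per gene
  a <- A[cbind(amax, seq_len(sel$d))]
  list(xm = x * rep(a, each = nrow(x)), a = a, A = A, amax = amax)
}

#' Forward pass of the binary-gates layer
#'
#' In training mode the gates are relaxed Bernoulli samples
#' `sigmoid((log_beta + logit(u)) / tau)` with `u ~ Uniform(0, 1)`; in
#' evaluation mode `sigmoid(log_beta / tau)`.
#'
#' @param g A [new_binary_gates()].
#' @param x Input batch (cells x d).
#' @param tau Positive temperature.
#' @param training Draw stochastic samples?
#' @param noise Optional vector of logistic draws `log(u) - log(1 - u)`.
#' @return List with masked batch `xm`, gate vector `b` and
#'   `penalty = lam * sum(b)`.
#' @export
binary_gates_forward <- function(g, x, tau, training = TRUE, noise = NULL) {
  stopifnot(inherits(g, "binary_gates"))
  if (ncol(x) != g$d) stopf("input width %d != gates d %d", ncol(x), g$d)
  if (is.null(noise) && training) {
    u <- stats::runif(g$d)
    noise <- log(u) - log1p(-u)
  }
  z <- if (is.null(noise)) g$log_beta else g$log_beta + noise
  b <- sigmoid(z / tau)
  list(xm = x * rep(b, each = nrow(x)), b = b, penalty = g$lam * sum(b))
}

# ---- per-cell stochastic forwards (training path) -------------------------
#
# The training loop samples fresh relaxation noise for every cell of the
# minibatch (the standard Monte-Carlo estimator of the expected loss),
# which averages the selection-parameter gradient over the batch and makes
# slot convergence far less noisy than a single shared mask would.  The
# exported single-sample forwards above define the layer semantics and are
# what evaluation mode uses.

# noise: (n*k) x d matrix of Gumbel draws, row r = (slot-1)*n + cell.
mask_forward_percell <- function(sel, x, tau, noise = NULL) {
  n <- nrow(x); d <- sel$d; k <- sel$k
  if (is.null(noise)) noise <- matrix(rgumbel(n * k * d), n * k, d)
  Z <- noise
  for (s in seq_len(k))
    Z[(s - 1L) * n + seq_len(n), ] <-
      (Z[(s - 1L) * n + seq_len(n), , drop = FALSE] +
         rep(sel$log_alpha[s, ], each = n)) / tau
  A <- softmax_rows(Z)
  a <- A[seq_len(n), , drop = FALSE]
  amax <- matrix(1L, n, d)
  if (k > 1L) for (s in 2L:k) {
    As <- A[(s - 1L) * n + seq_len(n), , drop = FALSE]
    upd <- As > a
    a[upd] <- As[upd]
    amax[upd] <- s
  }
  list(xm = x * a, a = a, A = A, amax = amax, noise = noise)
}

mask_backward_percell <- function(sel, fwd, dxm, x, tau) {
  n <- nrow(x); d <- sel$d; k <- sel$k
  da <- dxm * x
  dA <- matrix(0, n * k, d)
  for (s in seq_len(k)) {
    w <- fwd$amax == s
    rows <- (s - 1L) * n + seq_len(n)
    tmp <- dA[rows, , drop = FALSE]
    tmp[w] <- da[w]
    dA[rows, ] <- tmp
  }
  inner <- rowSums(dA * fwd$A)
  dZ <- fwd$A * (dA - inner) / tau
  dla <- sel$log_alpha
  for (s in seq_len(k))
    dla[s, ] <- colSums(dZ[(s - 1L) * n + seq_len(n), , drop = FALSE])
  dla
}

# noise: n x d matrix of logistic draws log(u) - log(1-u).
gates_forward_percell <- function(g, x, tau, noise = NULL) {
  n <- nrow(x)
  if (is.null(noise)) {
    u <- matrix(stats::runif(n * g$d), n, g$d)
    noise <- log(u) - log1p(-u)
  }
  b <- sigmoid((rep(g$log_beta, each = n) + noise) / tau)
  # penalty: minibatch estimate of lam * E[1'b]
  list(xm = x * b, b = b, penalty = g$lam * sum(b) / n, noise = noise)
}

gates_backward_percell <- function(g, fwd, dxm, x, tau) {
  n <- nrow(x)
  db <- dxm * x + g$lam / n
  colSums(db * fwd$b * (1 - fwd$b)) / tau
}

#' Extract the selected panel from a trained mask layer
#'
#' The panel is the argmax gene of each slot's unnormalised probabilities.
#' Within-slot argmax ties resolve to the lowest gene index. If two slots
#' collapse onto the same gene the panel is completed to exactly `k`
#' genes with the globally next-largest `log_alpha` scores among
#' unselected genes, and a warning is raised.
#'
#' @param sel A trained [new_concrete_selector()] (or its `log_alpha`).
#' @return Integer vector of `k` distinct gene indices.
#' @export
extract_mask_panel <- function(sel) {
  la <- if (inherits(sel, "concrete_selector")) sel$log_alpha else as.matrix(sel)
  k <- nrow(la)
  picks <- apply(la, 1L, which.max)  # ties -> lowest index
  out <- unique(picks)
  if (length(out) < k) {
    warnf("%d selection slots collapsed onto duplicate genes; completing the panel with next-best scores",
          k - length(out))
    score <- apply(la, 2L, max)
    filler <- order(score, decreasing = TRUE)
    filler <- filler[!(filler %in% out)]
    out <- c(out, filler[seq_len(k - length(out))])
  }
  as.integer(out)
}

#' Extract the surviving gene set from a trained gates layer
#'
#' Retains genes whose limiting inclusion probability
#' `beta_i / (1 + beta_i)` strictly exceeds 1/2, i.e. `beta_i > 1`
#' (`log_beta > 0`). A gate at exactly 1/2 is excluded.
#'
#' @param g A trained [new_binary_gates()] (or its `log_beta`).
#' @return Integer vector of surviving gene indices.
#' @export
extract_gates_panel <- function(g) {
  lb <- if (inherits(g, "binary_gates")) g$log_beta else as.numeric(g)
  which(lb > 0)
}
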