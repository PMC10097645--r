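#' Hurdle reconstruction loss
#'
#' Two-part loss for zero-inflated log-normalised expression. For each cell
#' and target gene the predictor emits a point prediction `y_hat` and a
#' detection probability `p_hat`; the per-gene loss is
#' `(y_hat - y)^2 / gamma - log(p_hat)` when the gene is expressed
#' (`y > 0`) and `-log(1 - p_hat)` when it is not. Gene losses are summed
#' within a cell and averaged over cells. The weighting `gamma` (default
#' 10) puts the squared-error and cross-entropy components on a similar
#' scale.
#'
#' @param y_hat Matrix of point predictions (cells x target genes).
#' @param p_hat Matrix of detection probabilities in (0, 1), same shape.
#' @param y Matrix of observed log-normalised expression, same shape.
#' @param expressed 0/1 matrix, 1 iff the raw count was positive
#'   (equivalently `y > 0`). Computed from `y` when omitted.
#' @param gamma Positive weighting parameter, default 10.
#' @param prob_clamp Probabilities are clamped into
#'   `[prob_clamp, 1 - prob_clamp]` so the log terms stay finite.
#' @return A single non-negative number.
#' @export
hurdle_loss <- function(y_hat, p_hat, y, expressed = NULL, gamma = 10,
                        prob_clamp = 1e-6) {
  y_hat <- as.matrix(y_hat); p_hat <- as.matrix(p_hat); y <- as.matrix(y)
  if (gamma <= 0) stopf("gamma must be positive")
  if (prob_clamp <= 0 || prob_clamp >= 0.5) stopf("prob_clamp must lie in (0, 0.5)")
  if (!all(dim(y_hat) == dim(y)) || !all(dim(p_hat) == dim(y)))
    stopf("shape mismatch: y_hat %s, p_hat %s, y %s",
          paste(dim(y_hat), collapse = "x"), paste(dim(p_hat), collapse = "x"),
          paste(dim(y), collapse = "x"))
  if (anyNA(y_hat) || anyNA(p_hat) || anyNA(y) || any(!is.finite(y)))
    stopf("non-finite values in hurdle loss inputs")
  expressed <- if (is.null(expressed)) (y > 0) * 1 else as.matrix(expressed)
  if (!all(dim(expressed) == dim(y))) stopf("expressed indicator shape mismatch")
  p <- clamp(p_hat, prob_clamp, 1 - prob_clamp)
  per <- expressed * ((y_hat - y)^2 / gamma - log(p)) +
    (1 - expressed) * (-log(1 - p))
  sum(per) / nrow(y)
}

# Loss + gradient wrt the raw network output O = [y_hat | p_logit]
# (cells x 2m). The clamp is treated as the identity in the backward pass.
hurdle_loss_grad <- function(O, y, expressed, gamma = 10, prob_clamp = 1e-6) {
  n <- nrow(O); m <- ncol(y)
  y_hat <- O[, seq_len(m), drop = FALSE]
  logit <- O[, m + seq_len(m), drop = FALSE]
  p <- clamp(sigmoid(logit), prob_clamp, 1 - prob_clamp)
  per <- expressed * ((y_hat - y)^2 / gamma - log(p)) +
    (1 - expressed) * (-log(1 - p))
  dO <- cbind(expressed * 2 * (y_hat - y) / gamma, sigmoid(logit) - expressed) / n
  list(loss = sum(per) / n, dO = dO)
}

#' Supervised training losses
#'
#' Multiclass cross-entropy over class logits (classification) or mean
#' squared error over continuous targets (regression), averaged over
#' cells. These replace the hurdle loss when selecting panels for a
#' specific experimental aim such as cell-type classification or
#' electrophysiological characterisation.
#'
#' @param predictions Classification: a cells x classes matrix of logits.
#'   Regression: a numeric matrix matching `targets`.
#' @param targets Classification: integer labels in `1..C` (or a factor).
#'   Regression: numeric matrix.
#' @param target_kind `"classification"` or `"regression"`.
#' @return A single non-negative number.
#' @export
supervised_loss <- function(predictions, targets,
                            target_kind = c("classification", "regression")) {
  target_kind <- match.arg(target_kind)
  predictions <- as.matrix(predictions)
  if (target_kind == "classification") {
    if (is.factor(targets)) targets <- as.integer(targets)
    targets <- as.integer(targets)
    if (any(targets < 1L | targets > ncol(predictions)))
      stopf("labels outside 1..%d", ncol(predictions))
    ce_loss_grad(predictions, targets)$loss
  } else {
    targets <- as.matrix(targets)
    if (!all(dim(predictions) == dim(targets))) stopf("shape mismatch")
    mse_loss_grad(predictions, targets)$loss
  }
}

ce_loss_grad <- function(O, y_int) {
  n <- nrow(O)
  z <- O - apply(O, 1L, max)
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  loss <- -sum(logp[cbind(seq_len(n), y_int)]) / n
  P <- exp(logp)
  P[cbind(seq_len(n), y_int)] <- P[cbind(seq_len(n), y_int)] - 1
  list(loss = loss, dO = P / n)
}

# Per-cell summed squared error, averaged over cells.
mse_loss_grad <- function(O, y) {
  n <- nrow(O)
  list(loss = sum((O - y)^2) / n, dO = 2 * (O - y) / n)
}

# Multi-label detection: per-gene binary cross-entropy on logits, summed
# over genes, averaged over cells.
bce_loss_grad <- function(O, e, prob_clamp = 1e-6) {
  n <- nrow(O)
  p <- clamp(sigmoid(O), prob_clamp, 1 - prob_clamp)
  loss <- -sum(e * log(p) + (1 - e) * log(1 - p)) / n
  list(loss = loss, dO = (sigmoid(O) - e) / n)
}

loss_grad_for <- function(target_kind) {
  switch(target_kind,
         reconstruction = function(O, batch, gamma, ...)
           hurdle_loss_grad(O, batch$y, batch$expressed, gamma = gamma),
         classification = function(O, batch, ...) ce_loss_grad(O, batch$y),
         regression = function(O, batch, ...) mse_loss_grad(O, batch$y),
         detection = function(O, batch, ...) bce_loss_grad(O, batch$y),
         stopf("unknown target kind '%s'", target_kind))
}

output_dim_for <- function(data) {
  switch(data$target_kind,
         reconstruction = 2L * ncol(data$target),
         classification = data$n_classes,
         regression = ncol(as.matrix(data$target)))
}
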