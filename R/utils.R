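# Internal numeric helpers shared across the model code.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with max-subtraction so large logits never overflow.
softmax_rows <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

elu <- function(x) ifelse(x > 0, x, expm1(x))

elu_grad <- function(activ) ifelse(activ > 0, 1, activ + 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# All stochastic entry points take an integer seed; derived seeds stay
# within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
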