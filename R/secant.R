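#' Tune the gates penalty by the secant method
#'
#' The binary-gates layer keeps the genes whose limiting inclusion
#' probability exceeds 1/2; how many survive depends on the penalty
#' coefficient lambda. Given a desired candidate count `d_prime`, this
#' routine trains a gates model at trial lambda values and applies the
#' secant update on the observed surviving-gene counts,
#' `lambda[t+1] = lambda[t] - (n[t] - d') * (lambda[t] - lambda[t-1]) /
#' (n[t] - n[t-1])`,
#' clamping proposals to stay positive and falling back to a
#' multiplicative update (double when too many genes survive, halve when
#' too few) whenever consecutive counts are equal. Iteration stops as
#' soon as a count lands within `tolerance * d_prime` of the target.
#'
#' Counting trainings use a reduced epoch budget
#' (`cfg$secant_epoch_frac * cfg$max_epochs`) since only the surviving
#' count matters at this stage.
#'
#' @param data A [prepare_dataset()] result.
#' @param d_prime Desired number of surviving candidate genes
#'   (`d_prime < d`).
#' @param cfg A [train_config()].
#' @param tolerance Fractional band around `d_prime` accepted as
#'   converged (default 0.10, matching a "roughly d_prime genes"
#'   pre-filter).
#' @param max_iterations Maximum trainings before giving up.
#' @param candidates,preselected Passed to [train_selector()].
#' @param lambda_init Optional length-2 vector of starting lambdas. By
#'   default `lambda0` is set so the initial penalty (gates at 1/2) is
#'   10% of the data loss of the untrained model, and
#'   `lambda1 = 2 * lambda0`.
#' @param count_fn Gene-counting oracle `function(lambda) -> list(n_genes,
#'   genes, fit)`; defaults to training the gates model. Injectable for
#'   testing the root-finder in isolation.
#' @return A `secant_fit` list: `lambda`, `genes` (surviving candidate
#'   indices), `n_genes`, `trace` (tibble of lambda / n_genes per
#'   iteration), and the final `fit` when trained.
#' @export
fit_lambda_secant <- function(data, d_prime, cfg = train_config(),
                              tolerance = 0.1, max_iterations = 10L,
                              candidates = NULL, preselected = NULL,
                              lambda_init = NULL, count_fn = NULL) {
  candidates_resolved <- if (is.null(count_fn)) {
    setdiff(candidates %||% seq_along(data$gene_names),
            preselected %||% integer())
  } else NULL
  if (!is.null(candidates_resolved) && d_prime >= length(candidates_resolved))
    stopf("d_prime (%d) must be smaller than the candidate count (%d)",
          d_prime, length(candidates_resolved))
  if (is.null(count_fn)) {
    epochs <- max(1L, as.integer(round(cfg$secant_epoch_frac * cfg$max_epochs)))
    count_fn <- function(lambda) {
      fit <- train_selector(data, layer = "gates", lam = lambda, cfg = cfg,
                            candidates = candidates, preselected = preselected,
                            max_epochs_override = epochs)
      idx <- extract_gates_panel(fit$sel)
      list(n_genes = length(idx), genes = fit$candidates[idx], fit = fit)
    }
  }
  if (is.null(lambda_init)) {
    lam0 <- initial_lambda(data, cfg, candidates = candidates,
                           preselected = preselected)
    lambda_init <- c(lam0, 2 * lam0)
  }
  stopifnot(length(lambda_init) == 2L, all(lambda_init > 0))

  lam_hist <- numeric(0); n_hist <- integer(0); results <- list()
  in_tol <- function(n) abs(n - d_prime) <= tolerance * d_prime
  evaluate <- function(lambda) {
    res <- count_fn(lambda)
    lam_hist <<- c(lam_hist, lambda)
    n_hist <<- c(n_hist, res$n_genes)
    results[[length(lam_hist)]] <<- res
    res
  }

  lambda <- lambda_init[1L]
  for (it in seq_len(max_iterations)) {
    res <- evaluate(lambda)
    if (in_tol(res$n_genes)) {
      trace <- tibble::tibble(iteration = seq_along(lam_hist),
                              lambda = lam_hist, n_genes = n_hist)
      return(structure(list(lambda = lambda, genes = res$genes,
                            n_genes = res$n_genes, trace = trace,
                            fit = res$fit),
                       class = "secant_fit"))
    }
    t <- length(lam_hist)
    if (t == 1L) {
      lambda <- lambda_init[2L]
    } else if (n_hist[t] == n_hist[t - 1L]) {
      lambda <- if (n_hist[t] > d_prime) 2 * lam_hist[t] else lam_hist[t] / 2
    } else {
      prop <- lam_hist[t] - (n_hist[t] - d_prime) *
        (lam_hist[t] - lam_hist[t - 1L]) / (n_hist[t] - n_hist[t - 1L])
      lambda <- if (prop > 0) prop else lam_hist[t] / 2
    }
  }
  stopf("secant search did not reach %d +/- %d genes in %d iterations; trace: %s",
        d_prime, round(tolerance * d_prime), max_iterations,
        paste(sprintf("(lambda=%.4g, n=%d)", lam_hist, n_hist), collapse = " "))
}

# lambda0 such that the penalty at initialisation (every gate at 1/2)
# equals 10% of the untrained model's data loss on a training batch.
initial_lambda <- function(data, cfg, candidates = NULL, preselected = NULL) {
  set.seed(cfg$seed)
  candidates <- setdiff(candidates %||% seq_along(data$gene_names),
                        preselected %||% integer())
  pre <- as.integer(preselected %||% integer())
  sp <- data$splits
  idx <- sp$train[seq_len(min(length(sp$train), 4L * cfg$minibatch_size))]
  X <- data$x_binary[idx, candidates, drop = FALSE]
  X_pre <- if (length(pre)) data$x_binary[idx, pre, drop = FALSE] else NULL
  net <- mlp_init(ncol(X) + length(pre), output_dim_for(data), cfg$hidden)
  g <- new_binary_gates(ncol(X), lam = 0)
  lg <- loss_grad_for(data$target_kind)
  slice <- function(m, i) if (is.matrix(m)) m[i, , drop = FALSE] else m[i]
  res <- selector_step(g, net, X,
                       list(y = slice(data$target, idx),
                            expressed = if (!is.null(data$expressed))
                              data$expressed[idx, , drop = FALSE]),
                       tau = cfg$tau_init, lg, cfg$gamma, training = FALSE)
  0.1 * res$data_loss / (0.5 * ncol(X))
}
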