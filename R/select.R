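#' Two-stage gene panel selection
#'
#' The full selection workflow. When the candidate pool is larger than
#' `prefilter_size`, a first stage trains the penalised binary-gates layer
#' with the secant search until roughly `prefilter_size` genes survive;
#' the second stage trains the Concrete binary-mask model on the
#' survivors to pick exactly `k` genes. With `d <= prefilter_size` the
#' first stage is skipped. Expert-preselected genes bypass both stages:
#' they are always visible to the predictor, count towards the panel, and
#' reduce the number of learned genes accordingly.
#'
#' @param data A [prepare_dataset()] result.
#' @param k Total panel size (including preselected genes).
#' @param prefilter_size Stage-1 target candidate count (default 500).
#' @param cfg A [train_config()].
#' @param candidates Optional gene names or indices restricting the
#'   candidate pool (expert knowledge).
#' @param preselected Optional gene names or indices forced into the
#'   panel.
#' @param prefilter_tolerance Fractional tolerance of the stage-1 count.
#' @return A `panel_result`; see [select_panel()].
#' @export
two_stage_select <- function(data, k, prefilter_size = 500L,
                             cfg = train_config(), candidates = NULL,
                             preselected = NULL, prefilter_tolerance = 0.1) {
  stopifnot(inherits(data, "prepared_dataset"))
  to_idx <- function(g) {
    if (is.null(g)) return(integer())
    if (is.character(g)) {
      missing <- setdiff(g, data$gene_names)
      if (length(missing))
        stopf("genes absent from data: %s", paste(missing, collapse = ", "))
      match(g, data$gene_names)
    } else as.integer(g)
  }
  pre <- to_idx(preselected)
  cand <- setdiff(if (is.null(candidates)) seq_along(data$gene_names)
                  else to_idx(candidates), pre)
  k_eff <- k - length(pre)
  if (k_eff < 0L) stopf("more preselected genes (%d) than the panel size (%d)",
                        length(pre), k)
  if (k_eff > length(cand))
    stopf("k = %d exceeds the %d available candidates (+%d preselected)",
          k, length(cand), length(pre))

  secant_trace <- NULL
  if (length(cand) > prefilter_size) {
    stage1 <- fit_lambda_secant(data, d_prime = prefilter_size, cfg = cfg,
                                tolerance = prefilter_tolerance,
                                candidates = cand, preselected = pre)
    cand <- stage1$genes
    secant_trace <- stage1$trace
    if (k_eff > length(cand))
      stopf("prefilter left only %d candidates for k = %d", length(cand), k)
  }

  if (k_eff == 0L) {
    return(new_panel_result(genes = data$gene_names[pre], data = data,
                            trial_val_losses = NA_real_, chosen_trial = 1L,
                            history = tibble::tibble(), preselected = pre,
                            k = k, seed = cfg$seed, secant_trace = secant_trace))
  }
  fit <- train_selector(data, layer = "mask", k = k_eff, cfg = cfg,
                        candidates = cand, preselected = pre)
  idx <- extract_mask_panel(fit$sel)
  genes <- data$gene_names[c(pre, fit$candidates[idx])]
  new_panel_result(genes = genes, data = data,
                   trial_val_losses = fit$best_val_loss, chosen_trial = 1L,
                   history = dplyr::mutate(fit$history, trial = 1L),
                   preselected = pre, k = k, seed = cfg$seed,
                   secant_trace = secant_trace, converged = fit$converged)
}

#' Select a gene panel (multi-trial)
#'
#' Runs [two_stage_select()] `trials` times (default 5) with derived
#' seeds `seed + 0, ..., seed + trials - 1` and returns the panel from
#' the trial with the lowest validation loss, retaining every trial's
#' loss, panel and training history for audit. Selection is stochastic
#' across seeds; the best-of-trials rule makes the reported panel stable.
#'
#' @inheritParams two_stage_select
#' @param trials Number of independent trials (default 5).
#' @return A `panel_result`: list with `genes` (length `k`, rank order),
#'   `trial_val_losses`, `chosen_trial`, `trial_panels`, `history`
#'   (per-trial per-epoch losses and temperatures), `preselected`, `k`,
#'   `mode`, `seed`. `tidy()` gives the ranked gene tibble, `glance()`
#'   the one-row summary, `autoplot()` the training curves.
#' @export
select_panel <- function(data, k, trials = 5L, cfg = train_config(),
                         prefilter_size = 500L, candidates = NULL,
                         preselected = NULL) {
  stopifnot(trials >= 1L)
  runs <- vector("list", trials)
  for (t in seq_len(trials)) {
    cfg_t <- cfg
    cfg_t$seed <- derive_seed(cfg$seed, t - 1L)
    runs[[t]] <- two_stage_select(data, k, prefilter_size = prefilter_size,
                                  cfg = cfg_t, candidates = candidates,
                                  preselected = preselected)
  }
  losses <- vapply(runs, function(r) r$trial_val_losses[r$chosen_trial],
                   numeric(1))
  best <- which.min(losses)
  hist <- dplyr::bind_rows(lapply(seq_len(trials), function(t)
    dplyr::mutate(runs[[t]]$history, trial = t)))
  out <- runs[[best]]
  out$trial_val_losses <- losses
  out$chosen_trial <- best
  out$trial_panels <- lapply(runs, `[[`, "genes")
  out$history <- hist
  out$seed <- cfg$seed
  out$trials <- trials
  out
}

new_panel_result <- function(genes, data, trial_val_losses, chosen_trial,
                             history, preselected, k, seed,
                             secant_trace = NULL, converged = TRUE) {
  stopifnot(!anyDuplicated(genes))
  structure(list(genes = as.character(genes),
                 trial_val_losses = trial_val_losses,
                 chosen_trial = chosen_trial,
                 trial_panels = list(as.character(genes)),
                 history = history,
                 preselected = data$gene_names[preselected],
                 k = as.integer(k), mode = data$target_kind,
                 seed = as.integer(seed), secant_trace = secant_trace,
                 converged = converged),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> %d genes (%s mode), trial %d of %d, val loss %.4f\n",
              length(x$genes), x$mode, x$chosen_trial,
              length(x$trial_val_losses),
              x$trial_val_losses[x$chosen_trial]))
  cat("genes:", paste(utils::head(x$genes, 12L), collapse = ", "),
      if (length(x$genes) > 12L) "..." else "", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a panel result
#'
#' @param x A `panel_result`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `gene_name`, `preselected`.
#' @export
tidy.panel_result <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$genes), gene_name = x$genes,
                 preselected = x$genes %in% x$preselected)
}

#' Summarise a panel result
#'
#' @param x A `panel_result`.
#' @param ... Unused.
#' @return One-row tibble: panel size, mode, trials, chosen trial, best /
#'   median validation loss, seed.
#' @export
glance.panel_result <- function(x, ...) {
  tibble::tibble(k = length(x$genes), mode = x$mode,
                 trials = length(x$trial_val_losses),
                 chosen_trial = x$chosen_trial,
                 best_val_loss = min(x$trial_val_losses),
                 median_val_loss = stats::median(x$trial_val_losses),
                 seed = x$seed)
}

#' Plot panel-selection training curves
#'
#' @param object A `panel_result`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch, one facet per
#'   trial, with the temperature schedule as a secondary curve.
#' @export
autoplot.panel_result <- function(object, ...) {
  h <- object$history
  if (!nrow(h)) stopf("panel result has no training history")
  long <- dplyr::bind_rows(
    dplyr::transmute(h, .data$trial, .data$epoch, loss = .data$train_loss,
                     which = "train"),
    dplyr::transmute(h, .data$trial, .data$epoch, loss = .data$val_loss,
                     which = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trial, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
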