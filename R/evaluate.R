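# Panel-quality evaluation: every metric is a train-on-panel /
# score-on-test procedure over the splits recorded in the prepared
# dataset.

panel_to_idx <- function(data, panel) {
  if (inherits(panel, "panel_result")) panel <- panel$genes
  if (is.character(panel)) {
    missing <- setdiff(panel, data$gene_names)
    if (length(missing))
      stopf("panel genes absent from data: %s", paste(missing, collapse = ", "))
    match(panel, data$gene_names)
  } else as.integer(panel)
}

# Explained variance as a portion of total variance: pooled over genes,
# 1 - sum(MSE_g) / sum(Var_g) on the test split.
ev_score <- function(pred, truth) {
  v <- colSums(sweep(truth, 2L, colMeans(truth))^2) / nrow(truth)
  if (sum(v) <= 0) stopf("test targets are constant; explained variance undefined")
  mse <- colSums((pred - truth)^2) / nrow(truth)
  1 - sum(mse) / sum(v)
}

#' Explained variance of a gene panel
#'
#' Trains a predictor network from the binarized panel input to the full
#' CPM-log expression profile and reports, on the test split, one minus
#' the ratio of summed per-gene mean squared error to summed per-gene
#' variance — the portion of total variance explained by the panel.
#'
#' @param data A [prepare_dataset()] result with reconstruction targets.
#' @param panel Gene names, indices, or a `panel_result`.
#' @param cfg A [train_config()] for the evaluation predictor.
#' @return A single number, at most 1.
#' @export
explained_variance <- function(data, panel, cfg = train_config()) {
  stopifnot(inherits(data, "prepared_dataset"))
  if (data$target_kind != "reconstruction")
    stopf("explained variance needs reconstruction targets")
  idx <- panel_to_idx(data, panel)
  sp <- data$splits
  fit <- mlp_fit(data$x_binary[sp$train, idx, drop = FALSE],
                 data$target[sp$train, , drop = FALSE],
                 data$x_binary[sp$val, idx, drop = FALSE],
                 data$target[sp$val, , drop = FALSE],
                 loss_kind = "regression", d_out = ncol(data$target),
                 hidden = cfg$hidden, max_epochs = cfg$max_epochs,
                 minibatch_size = cfg$minibatch_size,
                 learning_rate = cfg$learning_rate, patience = cfg$patience,
                 seed = cfg$seed)
  pred <- mlp_predict(fit$net, data$x_binary[sp$test, idx, drop = FALSE])
  ev_score(pred, data$target[sp$test, , drop = FALSE])
}

detection_band_genes <- function(data, band) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] >= 1 ||
      band[1L] >= band[2L])
    stopf("expression band must satisfy 0 < lower < upper < 1")
  frac <- colMeans(data$expressed[data$splits$train, , drop = FALSE])
  which(frac >= band[1L] & frac <= band[2L])
}

accuracy_from_prob <- function(prob, truth) {
  colMeans((prob > 0.5) == (truth == 1))
}

#' Expressed-gene prediction accuracy
#'
#' Trains a network to predict, from the binarized panel input, whether
#' each target gene is expressed (per-gene cross-entropy, summed over
#' genes). Target genes are restricted to those detected in a fraction
#' of training cells inside `band` (default 20-80%), excluding rarely
#' and ubiquitously expressed genes. A gene is called expressed when the
#' predicted probability strictly exceeds 0.5; accuracy is averaged over
#' target genes on the test split.
#'
#' @inheritParams explained_variance
#' @param band Detection-fraction band (training split only) defining
#'   the target genes.
#' @return List with `accuracy` (mean over genes) and `per_gene`
#'   (tibble: gene, detection fraction, accuracy).
#' @export
expressed_gene_accuracy <- function(data, panel, band = c(0.2, 0.8),
                                    cfg = train_config()) {
  stopifnot(inherits(data, "prepared_dataset"))
  if (is.null(data$expressed))
    stopf("expressed-gene accuracy needs reconstruction targets")
  idx <- panel_to_idx(data, panel)
  tg <- detection_band_genes(data, band)
  if (!length(tg)) stopf("no genes fall in the detection band (%g, %g)",
                         band[1L], band[2L])
  sp <- data$splits
  fit <- mlp_fit(data$x_binary[sp$train, idx, drop = FALSE],
                 data$expressed[sp$train, tg, drop = FALSE],
                 data$x_binary[sp$val, idx, drop = FALSE],
                 data$expressed[sp$val, tg, drop = FALSE],
                 loss_kind = "detection", d_out = length(tg),
                 hidden = cfg$hidden, max_epochs = cfg$max_epochs,
                 minibatch_size = cfg$minibatch_size,
                 learning_rate = cfg$learning_rate, patience = cfg$patience,
                 seed = cfg$seed)
  prob <- sigmoid(mlp_predict(fit$net, data$x_binary[sp$test, idx, drop = FALSE]))
  acc <- accuracy_from_prob(prob, data$expressed[sp$test, tg, drop = FALSE])
  list(accuracy = mean(acc),
       per_gene = tibble::tibble(
         gene = data$target_genes[tg],
         detection_fraction = colMeans(data$expressed[sp$train, tg, drop = FALSE]),
         accuracy = unname(acc)))
}

#' Cell-type classification accuracy of a panel
#'
#' Trains a gradient-boosted decision-tree classifier (multiclass
#' softmax) on the binarized panel input and reports test-split accuracy;
#' the class with the highest predicted probability is the call. Labels
#' can optionally be merged to coarser subclasses through a named
#' mapping before training.
#'
#' @inheritParams explained_variance
#' @param merge_map Optional named character vector mapping fine labels
#'   to coarser ones.
#' @param nrounds,max_depth,eta GBDT settings (default 100 trees, depth
#'   6, learning rate 0.1).
#' @return Test accuracy in `[0, 1]`.
#' @export
celltype_accuracy <- function(data, panel, merge_map = NULL, nrounds = 100L,
                              max_depth = 6L, eta = 0.1,
                              cfg = train_config()) {
  stopifnot(inherits(data, "prepared_dataset"))
  labels <- data$labels
  if (is.null(labels)) stopf("cell-type accuracy needs labels")
  labels <- as.character(labels)
  if (!is.null(merge_map)) {
    mapped <- merge_map[labels]
    labels <- ifelse(is.na(mapped), labels, mapped)
  }
  idx <- panel_to_idx(data, panel)
  sp <- data$splits
  f <- factor(labels)
  ytr <- as.integer(f[sp$train]) - 1L
  yte <- as.integer(f[sp$test]) - 1L
  unseen <- setdiff(unique(yte), unique(ytr))
  if (length(unseen))
    warnf("classes present in test but absent from training: %s (counted as errors)",
          paste(levels(f)[unseen + 1L], collapse = ", "))
  if (nlevels(f) < 2L) {
    # degenerate single-class data: the constant classifier is exact
    return(mean(yte == unique(ytr)[1L]))
  }
  Xtr <- data$x_binary[sp$train, idx, drop = FALSE]
  Xte <- data$x_binary[sp$test, idx, drop = FALSE]
  booster <- xgboost::xgb.train(
    params = xgboost::xgb.params(objective = "multi:softprob",
                                 num_class = nlevels(f),
                                 max_depth = max_depth, eta = eta,
                                 nthread = 1L),
    data = xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L),
    nrounds = nrounds, verbose = 0)
  prob <- stats::predict(booster, xgboost::xgb.DMatrix(Xte, nthread = 1L))
  if (is.null(dim(prob)))
    prob <- matrix(prob, nrow(Xte), nlevels(f), byrow = TRUE)
  pred <- max.col(prob, ties.method = "first") - 1L
  mean(pred == yte)
}

#' Overlap fraction between two equal-size panels
#'
#' @param panel_a,panel_b Non-empty character vectors of equal length.
#' @return `|A intersect B| / |A|` in `[0, 1]`.
#' @export
panel_overlap_fraction <- function(panel_a, panel_b) {
  if (inherits(panel_a, "panel_result")) panel_a <- panel_a$genes
  if (inherits(panel_b, "panel_result")) panel_b <- panel_b$genes
  if (!length(panel_a) || !length(panel_b)) stopf("panels must be non-empty")
  if (length(panel_a) != length(panel_b))
    stopf("panels must have equal size (got %d and %d)",
          length(panel_a), length(panel_b))
  length(intersect(panel_a, panel_b)) / length(panel_a)
}

#' Probability that two random panels overlap by chance
#'
#' Exact tail probability `P(X >= m)` where `X` is the overlap of two
#' uniformly random size-`k` panels drawn from `N` candidates —
#' hypergeometric with `k` draws from `k` successes in `N`. Computed via
#' log-binomial-coefficient sums for numerical stability at large `N`.
#' For two 32-gene panels from 10,000 candidates, the probability of
#' sharing more than one gene is about 4.6e-3.
#'
#' @param n_candidates Candidate pool size `N`.
#' @param panel_size Panel size `k` (`k <= N`).
#' @param min_overlap Threshold `m` in `0..k`.
#' @return A probability.
#' @export
random_overlap_probability <- function(n_candidates, panel_size, min_overlap) {
  N <- n_candidates; k <- panel_size; m <- min_overlap
  if (k > N || k < 0) stopf("need 0 <= panel_size <= n_candidates")
  if (m < 0 || m > k) stopf("need 0 <= min_overlap <= panel_size")
  if (m == 0) return(1)
  j <- m:k
  terms <- lchoose(k, j) + lchoose(N - k, k - j) - lchoose(N, k)
  terms <- terms[is.finite(terms)]
  if (!length(terms)) return(0)
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

#' Bootstrap confidence interval for a panel metric
#'
#' Retrains the downstream model on `n_boot` training sets resampled
#' with replacement and reports `mean +/- 1.96 sd` of the test metric
#' across the resamples.
#'
#' @param metric_fn Function `data -> numeric(1)` computing the metric
#'   (e.g. a partially applied [explained_variance()]).
#' @param data A [prepare_dataset()] result.
#' @param n_boot Number of bootstrap resamples (default 5).
#' @param seed Integer seed.
#' @return Named vector `c(lower, upper)` with the per-resample values
#'   as attribute `"values"`.
#' @export
bootstrap_ci <- function(metric_fn, data, n_boot = 5L, seed = 1L) {
  stopifnot(n_boot >= 2L)
  vals <- vapply(seq_len(n_boot), function(b) {
    set.seed(derive_seed(seed, b))
    d2 <- data
    d2$splits$train <- sample(data$splits$train, replace = TRUE)
    metric_fn(d2)
  }, numeric(1))
  ci <- c(lower = mean(vals) - 1.96 * stats::sd(vals),
          upper = mean(vals) + 1.96 * stats::sd(vals))
  attr(ci, "values") <- vals
  ci
}

#' Evaluate a gene panel
#'
#' Runs the applicable quality metrics for a panel: explained variance,
#' expressed-gene prediction accuracy in the detection band, and (when
#' labels are present) gradient-boosted-tree cell-type accuracy.
#'
#' @inheritParams explained_variance
#' @param band Detection band for [expressed_gene_accuracy()].
#' @param n_boot If positive, also compute [bootstrap_ci()] intervals
#'   with this many resamples.
#' @return An `eval_report`; `tidy()` gives the per-gene accuracy table,
#'   `glance()` the one-row metric summary.
#' @export
evaluate_panel <- function(data, panel, cfg = train_config(),
                           band = c(0.2, 0.8), n_boot = 0L) {
  genes <- if (inherits(panel, "panel_result")) panel$genes else panel
  ev <- explained_variance(data, panel, cfg = cfg)
  eg <- expressed_gene_accuracy(data, panel, band = band, cfg = cfg)
  ct <- if (!is.null(data$labels)) celltype_accuracy(data, panel, cfg = cfg)
  out <- list(explained_variance = ev,
              expressed_gene_accuracy = eg$accuracy,
              celltype_accuracy = ct,
              per_gene_accuracy = eg$per_gene,
              panel = genes)
  if (n_boot > 0L) {
    out$bootstrap_ci <- list(
      explained_variance = bootstrap_ci(
        function(d) explained_variance(d, panel, cfg = cfg), data,
        n_boot = n_boot, seed = cfg$seed),
      expressed_gene_accuracy = bootstrap_ci(
        function(d) expressed_gene_accuracy(d, panel, band = band,
                                            cfg = cfg)$accuracy, data,
        n_boot = n_boot, seed = cfg$seed))
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  explained variance:       %.4f\n", x$explained_variance))
  cat(sprintf("  expressed-gene accuracy:  %.4f\n", x$expressed_gene_accuracy))
  if (!is.null(x$celltype_accuracy))
    cat(sprintf("  cell-type accuracy:       %.4f\n", x$celltype_accuracy))
  cat(sprintf("  panel: %s\n", paste(utils::head(x$panel, 10L), collapse = ", ")))
  invisible(x)
}

#' @rdname evaluate_panel
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_gene_accuracy

#' @rdname evaluate_panel
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(panel_size = length(x$panel),
                 explained_variance = x$explained_variance,
                 expressed_gene_accuracy = x$expressed_gene_accuracy,
                 celltype_accuracy = x$celltype_accuracy %||% NA_real_)
}

#' Cross-technology transfer accuracy
#'
#' Measures what the quantile threshold matching buys: an expressed-gene
#' predictor is trained on binarized reference (scRNA-seq) panel input
#' and then applied to the paired target-technology (FISH) measurements
#' of the same cells, binarized either with matched thresholds
#' ([match_binarization_threshold()]) or with a raw zero threshold. Test
#' accuracy is scored against the reference expressed indicators.
#'
#' @param reference Reference `expr_mat` (scRNA-seq).
#' @param fish Paired target-technology `expr_mat`, same cells and gene
#'   names.
#' @param panel Panel gene names used as predictor input.
#' @param band Detection band defining target genes.
#' @param cfg A [train_config()].
#' @param fractions,seed Split settings, see [split_dataset()].
#' @return One-row tibble: `matched_accuracy`, `raw_zero_accuracy`,
#'   `reference_accuracy` (scRNA-seq input, the ceiling) and
#'   `n_target_genes`.
#' @export
evaluate_transfer <- function(reference, fish, panel, band = c(0.2, 0.8),
                              cfg = train_config(),
                              fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(reference, "expr_mat"), inherits(fish, "expr_mat"))
  data <- prepare_dataset(reference, fractions = fractions, seed = seed)
  idx <- panel_to_idx(data, panel)
  tg <- detection_band_genes(data, band)
  if (!length(tg)) stopf("no genes in the detection band")
  sp <- data$splits
  fit <- mlp_fit(data$x_binary[sp$train, idx, drop = FALSE],
                 data$expressed[sp$train, tg, drop = FALSE],
                 data$x_binary[sp$val, idx, drop = FALSE],
                 data$expressed[sp$val, tg, drop = FALSE],
                 loss_kind = "detection", d_out = length(tg),
                 hidden = cfg$hidden, max_epochs = cfg$max_epochs,
                 minibatch_size = cfg$minibatch_size,
                 learning_rate = cfg$learning_rate, patience = cfg$patience,
                 seed = cfg$seed)
  panel_genes <- data$gene_names[idx]
  rule <- match_binarization_threshold(reference, fish,
                                       shared_genes = panel_genes)
  fish_panel <- subset_genes(fish, panel_genes)
  x_matched <- binarize_counts(fish_panel, rule$threshold)[sp$test, , drop = FALSE]
  x_raw <- binarize_counts(fish_panel, 0)[sp$test, , drop = FALSE]
  x_ref <- data$x_binary[sp$test, idx, drop = FALSE]
  truth <- data$expressed[sp$test, tg, drop = FALSE]
  score <- function(x) mean(accuracy_from_prob(sigmoid(mlp_predict(fit$net, x)),
                                               truth))
  tibble::tibble(matched_accuracy = score(x_matched),
                 raw_zero_accuracy = score(x_raw),
                 reference_accuracy = score(x_ref),
                 n_target_genes = length(tg))
}
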