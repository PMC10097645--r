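#' CPM + log1p normalisation
#'
#' Scales each cell's counts to counts-per-million and applies `log1p`.
#' Entry (i, j) becomes `log(1 + counts[i, j] * 1e6 / sum(counts[i, ]))`.
#' Zeros map exactly to zeros and the result is invariant to scaling a
#' cell's counts by a positive constant.
#'
#' @param em An [expression_matrix()].
#' @return A numeric matrix (cells x genes) of log-CPM values.
#' @export
cpm_log_normalize <- function(em) {
  stopifnot(inherits(em, "expr_mat"))
  totals <- rowSums(em$counts)
  if (any(totals <= 0)) {
    bad <- em$cell_ids[totals <= 0]
    stopf("cells with zero total count cannot be CPM-normalised: %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  log1p(em$counts / totals * 1e6)
}

#' Binarize expression counts
#'
#' An entry becomes 1 iff its count is strictly greater than the gene's
#' threshold (default 0 for all genes, the scRNA-seq detection rule).
#'
#' @param em An [expression_matrix()] or a plain cells x genes matrix.
#' @param thresholds Scalar or per-gene numeric vector of thresholds.
#' @return A 0/1 numeric matrix of the same shape.
#' @export
binarize_counts <- function(em, thresholds = 0) {
  counts <- if (inherits(em, "expr_mat")) em$counts else as.matrix(em)
  d <- ncol(counts)
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, d)
  if (length(thresholds) != d)
    stopf("thresholds has length %d but matrix has %d genes",
          length(thresholds), d)
  out <- (counts > rep(thresholds, each = nrow(counts))) * 1
  dimnames(out) <- dimnames(counts)
  out
}

#' Match binarization thresholds across technologies
#'
#' Bridges the scRNA-seq to FISH domain shift under the assumption that the
#' per-gene transformation between technologies is monotone. For each shared
#' gene the zero-threshold of the reference technology is converted into a
#' quantile (the gene's zero fraction in the reference), and the matching
#' threshold in the target technology is that empirical quantile of the
#' target counts (lower interpolation, so the threshold is an observed
#' value). Binarizing the target with these thresholds approximately
#' reproduces the reference positive fractions, and exactly reproduces the
#' reference binarization when the target is a strictly increasing per-gene
#' transform of the reference.
#'
#' @param reference `expr_mat` measured with the reference technology
#'   (scRNA-seq).
#' @param target `expr_mat` measured with the target technology (FISH).
#' @param shared_genes Genes to match; defaults to all genes present in
#'   both matrices.
#' @return A `quantization_rule`: tibble with columns `gene`,
#'   `zero_fraction` (reference quantile of the zero threshold) and
#'   `threshold` (matched target-technology threshold).
#' @export
match_binarization_threshold <- function(reference, target,
                                         shared_genes = NULL) {
  stopifnot(inherits(reference, "expr_mat"), inherits(target, "expr_mat"))
  if (is.null(shared_genes))
    shared_genes <- intersect(reference$gene_names, target$gene_names)
  missing_ref <- setdiff(shared_genes, reference$gene_names)
  missing_tgt <- setdiff(shared_genes, target$gene_names)
  if (length(missing_ref) || length(missing_tgt))
    stopf("genes absent from %s: %s",
          if (length(missing_ref)) "reference" else "target",
          paste(utils::head(c(missing_ref, missing_tgt), 10L), collapse = ", "))
  if (!length(shared_genes)) stopf("no shared genes between matrices")
  q <- vapply(shared_genes, function(g)
    mean(reference$counts[, g] <= 0), numeric(1))
  thr <- vapply(seq_along(shared_genes), function(i) {
    as.numeric(stats::quantile(target$counts[, shared_genes[i]],
                               probs = q[i], type = 1L, names = FALSE))
  }, numeric(1))
  structure(tibble::tibble(gene = shared_genes, zero_fraction = unname(q),
                           threshold = thr),
            class = c("quantization_rule", "tbl_df", "tbl", "data.frame"))
}

#' Keep the highest-variance genes
#'
#' Ranks genes by their per-gene variance (by default on the CPM-log scale,
#' so the ranking is not dominated by sequencing depth) and keeps the
#' `n_keep` most variable, preserving the original gene order among the
#' survivors. Zero-variance genes sort last and never survive while
#' higher-variance alternatives exist.
#'
#' @param em An [expression_matrix()].
#' @param n_keep Number of genes to retain.
#' @param scale Scale on which the variance is computed: `"cpm_log"`
#'   (default), `"cpm"` or `"raw"`.
#' @return An `expr_mat` restricted to the surviving genes.
#' @export
filter_high_variance <- function(em, n_keep,
                                 scale = c("cpm_log", "cpm", "raw")) {
  stopifnot(inherits(em, "expr_mat"))
  scale <- match.arg(scale)
  d <- ncol(em$counts)
  if (n_keep > d)
    stopf("n_keep (%d) exceeds the number of genes (%d)", n_keep, d)
  vals <- switch(scale,
                 cpm_log = cpm_log_normalize(em),
                 cpm = {
                   totals <- rowSums(em$counts)
                   if (any(totals <= 0)) stopf("cells with zero total count")
                   em$counts / totals * 1e6
                 },
                 raw = em$counts)
  v <- matrixStats_colVars(vals)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_keep)])
  subset_genes(em, keep)
}

# Column variances without matrixStats; denominator n - 1 as in stats::var.
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Split cells into train / validation / test sets
#'
#' Random disjoint split, reproducible under a fixed seed, optionally
#' stratified by a label vector so each split preserves class proportions
#' within rounding.
#'
#' @param n_cells Number of cells (or an `expr_mat`).
#' @param fractions Length-3 positive numeric vector summing to 1
#'   (train, validation, test). Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed.
#' @param labels Optional vector of cell labels for stratification.
#' @return A list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_cells, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          labels = NULL) {
  if (inherits(n_cells, "expr_mat")) n_cells <- nrow(n_cells$counts)
  if (length(fractions) != 3L || any(fractions <= 0))
    stopf("fractions must be three positive numbers")
  if (abs(sum(fractions) - 1) > 1e-6)
    stopf("fractions must sum to 1 (got %.8f)", sum(fractions))
  if (!is.null(labels) && length(labels) != n_cells)
    stopf("labels length (%d) does not match n_cells (%d)",
          length(labels), n_cells)
  split_sizes <- function(n) {
    n_train <- round(fractions[1L] * n)
    n_val <- round(fractions[2L] * n)
    n_val <- min(n_val, n - n_train)
    c(n_train, n_val, n - n_train - n_val)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  assign_group <- function(idx) {
    sz <- split_sizes(length(idx))
    idx <- sample(idx)
    list(train = idx[seq_len(sz[1L])],
         val = idx[sz[1L] + seq_len(sz[2L])],
         test = idx[sz[1L] + sz[2L] + seq_len(sz[3L])])
  }
  if (is.null(labels)) {
    out <- assign_group(seq_len(n_cells))
  } else {
    parts <- lapply(split(seq_len(n_cells), labels), assign_group)
    out <- list(train = sort(unlist(lapply(parts, `[[`, "train"), use.names = FALSE)),
                val = sort(unlist(lapply(parts, `[[`, "val"), use.names = FALSE)),
                test = sort(unlist(lapply(parts, `[[`, "test"), use.names = FALSE)))
  }
  lapply(out, as.integer)
}

#' Prepare a dataset for panel selection
#'
#' Assembles the model-ready representation: binarized input, the
#' prediction target for the chosen objective, the expressed/not-expressed
#' indicator used by the hurdle loss, and reproducible train/val/test
#' splits.
#'
#' Targets by objective:
#' * `reconstruction` (default, unsupervised): CPM-log expression of
#'   `target_genes` (all genes by default), with `expressed[i, j] = 1` iff
#'   the raw count is positive.
#' * `classification`: integer-coded cell-type labels.
#' * `regression`: a numeric matrix of continuous per-cell properties.
#'
#' @param em An [expression_matrix()].
#' @param target_kind `"reconstruction"`, `"classification"` or
#'   `"regression"`.
#' @param labels Factor/character cell labels (classification; also used to
#'   stratify splits when present).
#' @param targets Numeric matrix of per-cell continuous targets
#'   (regression).
#' @param target_genes Genes to reconstruct (reconstruction only); default
#'   all.
#' @param thresholds Binarization thresholds, see [binarize_counts()].
#' @param fractions,seed Passed to [split_dataset()].
#' @return A `prepared_dataset` list: `x_binary`, `target`, `target_kind`,
#'   `expressed` (reconstruction only), `splits`, `gene_names`,
#'   `target_genes`, `n_classes`/`class_levels` (classification only),
#'   `labels`, `seed`.
#' @export
prepare_dataset <- function(em,
                            target_kind = c("reconstruction", "classification",
                                            "regression"),
                            labels = NULL, targets = NULL, target_genes = NULL,
                            thresholds = 0, fractions = c(0.8, 0.1, 0.1),
                            seed = 1L) {
  stopifnot(inherits(em, "expr_mat"))
  target_kind <- match.arg(target_kind)
  x_binary <- binarize_counts(em, thresholds)
  out <- list(x_binary = x_binary, target_kind = target_kind,
              gene_names = em$gene_names, seed = as.integer(seed))
  if (target_kind == "reconstruction") {
    target_genes <- target_genes %||% em$gene_names
    tg <- subset_genes(em, target_genes)
    out$target <- cpm_log_normalize(em)[, target_genes, drop = FALSE]
    out$expressed <- (tg$counts > 0) * 1
    out$target_genes <- target_genes
  } else if (target_kind == "classification") {
    if (is.null(labels)) stopf("classification requires labels")
    f <- factor(labels)
    out$target <- as.integer(f)
    out$class_levels <- levels(f)
    out$n_classes <- nlevels(f)
  } else {
    if (is.null(targets)) stopf("regression requires a targets matrix")
    targets <- as.matrix(targets)
    if (nrow(targets) != nrow(em$counts))
      stopf("targets rows (%d) do not match cells (%d)",
            nrow(targets), nrow(em$counts))
    out$target <- targets
  }
  if (!is.null(labels)) out$labels <- labels
  out$splits <- split_dataset(nrow(em$counts), fractions, seed, labels = labels)
  structure(out, class = "prepared_dataset")
}

#' @export
print.prepared_dataset <- function(x, ...) {
  cat(sprintf("<prepared_dataset> %d cells x %d genes, target: %s\n",
              nrow(x$x_binary), ncol(x$x_binary), x$target_kind))
  cat(sprintf("splits: train %d / val %d / test %d\n",
              length(x$splits$train), length(x$splits$val),
              length(x$splits$test)))
  invisible(x)
}
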