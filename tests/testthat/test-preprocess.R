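test_that("CPM-log normalisation matches hand-computed values and preserves zeros", {
  em <- expression_matrix(matrix(c(1, 1, 2), 1, 3),
                          c("a", "b", "c"), "cell1")
  # proportions x 1e6 before log1p
  cpm <- em$counts / sum(em$counts) * 1e6
  expect_equal(as.numeric(cpm), c(250000, 250000, 500000))
  out <- cpm_log_normalize(em)
  expect_equal(round(as.numeric(out), 4), c(12.4292, 12.4292, 13.1224))

  em2 <- random_expr_mat(12, 6, seed = 2)
  out2 <- cpm_log_normalize(em2)
  expect_identical(out2 == 0, em2$counts == 0)

  # all-equal counts in a cell map to all-equal values
  em3 <- expression_matrix(matrix(5, 1, 4), paste0("g", 1:4), "c")
  expect_true(all(cpm_log_normalize(em3) == cpm_log_normalize(em3)[1]))
})

test_that("CPM-log is invariant to scaling a cell's counts and rejects empty cells", {
  em <- random_expr_mat(6, 5, seed = 3)
  scaled <- em
  scaled$counts[2, ] <- scaled$counts[2, ] * 7.5
  expect_equal(cpm_log_normalize(scaled)[2, ], cpm_log_normalize(em)[2, ])

  empty <- em
  empty$counts[4, ] <- 0
  expect_error(cpm_log_normalize(empty), "c4")
})

test_that("binarization is a strict threshold per gene", {
  em <- expression_matrix(matrix(c(0, 0.3, 5), 1, 3), c("a", "b", "c"), "x")
  expect_equal(as.numeric(binarize_counts(em)), c(0, 1, 1))
  # equality with the threshold maps to 0
  expect_equal(as.numeric(binarize_counts(em, c(0, 0.3, 5))), c(0, 0, 0))
  zeros <- expression_matrix(matrix(0, 3, 2), c("a", "b"), paste0("c", 1:3))
  expect_true(all(binarize_counts(zeros) == 0))
  expect_error(binarize_counts(em, c(0, 1)), "length")
})

test_that("quantile threshold matching undoes strictly increasing per-gene transforms", {
  set.seed(42)
  ref <- random_expr_mat(60, 8, seed = 6)
  # the exact-inversion property needs each gene's zero threshold to be
  # observed in the reference (the zero-fraction-0 boundary is tested below)
  ref$counts[1, ] <- 0
  transforms <- list(function(x) 2 * x + 1,
                     function(x) x^2 + 0.5,
                     function(x) exp(x / 4) - 0.9,
                     function(x) 10 * x)
  for (i in seq_along(transforms)) {
    f <- transforms[[i]]
    # different transform per gene, applied cellwise to the same cells
    tgt <- ref
    for (j in seq_len(8)) {
      k <- transforms[[(i + j) %% length(transforms) + 1L]]
      tgt$counts[, j] <- k(ref$counts[, j])
    }
    tgt <- expression_matrix(pmax(tgt$counts, 0), tgt$gene_names, tgt$cell_ids)
    rule <- match_binarization_threshold(ref, tgt)
    expect_equal(binarize_counts(tgt, rule$threshold), binarize_counts(ref),
                 ignore_attr = TRUE)
  }
})

test_that("threshold matching handles degenerate zero fractions", {
  counts_ref <- cbind(never = rep(0, 10), always = 1:10)
  ref <- expression_matrix(counts_ref, c("never", "always"), paste0("c", 1:10))
  tgt <- expression_matrix(cbind(never = 5 + 1:10, always = 3 * (1:10)),
                           c("never", "always"), paste0("c", 1:10))
  rule <- match_binarization_threshold(ref, tgt)
  bt <- binarize_counts(tgt, rule$threshold)
  # zero fraction 1 -> threshold is the target maximum -> never detected
  expect_true(all(bt[, "never"] == 0))
  # zero fraction 0 -> threshold is the target minimum; the strict rule
  # leaves cells at the minimum undetected
  expect_equal(rule$threshold[rule$gene == "always"], 3)
  expect_equal(as.numeric(bt[, "always"]), c(0, rep(1, 9)))

  expect_error(match_binarization_threshold(ref, tgt, c("never", "ghost")),
               "ghost")
})

test_that("high-variance filtering matches a brute-force ranking", {
  em <- random_expr_mat(30, 10, seed = 9)
  expect_equal(filter_high_variance(em, 10)$gene_names, em$gene_names)

  # independent oracle: rank CPM-log variances by hand
  v <- apply(cpm_log_normalize(em), 2, var)
  top3 <- sort(em$gene_names[order(v, decreasing = TRUE)[1:3]])
  kept <- filter_high_variance(em, 3)
  expect_setequal(kept$gene_names, top3)
  # original order preserved among survivors
  expect_equal(kept$gene_names,
               em$gene_names[sort(match(kept$gene_names, em$gene_names))])

  # a constant gene never survives while alternatives exist
  em$counts[, 4] <- 3
  expect_false("g4" %in% filter_high_variance(em, 9, scale = "raw")$gene_names)
  expect_error(filter_high_variance(em, 11), "exceeds")
})

test_that("splits are reproducible, disjoint, exhaustive and stratified", {
  s <- split_dataset(100, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(lengths(s), c(train = 80L, val = 10L, test = 10L))
  expect_equal(sort(unlist(s, use.names = FALSE)), 1:100)
  expect_identical(split_dataset(100, c(0.8, 0.1, 0.1), seed = 5), s)
  expect_false(identical(split_dataset(100, c(0.8, 0.1, 0.1), seed = 6), s))

  labels <- rep(c("A", "B"), c(90, 10))
  st <- split_dataset(100, c(0.8, 0.1, 0.1), seed = 3, labels = labels)
  frac_b <- vapply(st, function(idx) mean(labels[idx] == "B"), numeric(1))
  expect_true(all(abs(frac_b - 0.1) < 0.02))

  expect_error(split_dataset(100, c(0.5, 0.2, 0.2), seed = 1), "sum to 1")
  expect_error(split_dataset(100, c(1.2, -0.1, -0.1), seed = 1), "positive")
})

test_that("prepared datasets satisfy their structural invariants", {
  fix <- default_fixture()
  data <- fix$data
  expect_true(all(data$x_binary %in% c(0, 1)))
  expect_identical(data$expressed == 1, fix$sim$em$counts > 0)
  expect_equal(sort(unlist(data$splits, use.names = FALSE)), seq_len(nrow(fix$sim$em$counts)))
  expect_equal(data$target, cpm_log_normalize(fix$sim$em))

  labs <- paste0("T", fix$sim$truth$cell_types)
  dcls <- prepare_dataset(fix$sim$em, target_kind = "classification",
                          labels = labs, seed = 1)
  expect_equal(dcls$n_classes, 3L)
  expect_error(prepare_dataset(fix$sim$em, target_kind = "classification"),
               "labels")
  expect_error(prepare_dataset(fix$sim$em, target_kind = "regression"),
               "targets")
})
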