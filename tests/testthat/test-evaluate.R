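test_that("explained variance scoring has the right fixed points", {
  set.seed(1)
  truth <- matrix(rnorm(60), 20, 3)
  expect_equal(ps$ev_score(truth, truth), 1)
  means <- matrix(colMeans(truth), 20, 3, byrow = TRUE)
  expect_equal(ps$ev_score(means, truth), 0)
  expect_error(ps$ev_score(truth, matrix(2, 20, 3)), "constant")
})

test_that("explained variance approaches the analytic ceiling on linear data", {
  # targets are a linear map of 4 binary planted genes plus N(0, sigma^2)
  # noise, so no predictor can beat EV = 1 - m * sigma^2 / total variance
  set.seed(5)
  n <- 1500; sigma <- 0.6; m <- 12
  S <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  X <- cbind(S, matrix(rbinom(n * 6, 1, 0.4), n, 6))
  W <- matrix(rnorm(4 * m), 4, m)
  Y <- S %*% W + matrix(rnorm(n * m, 0, sigma), n, m)
  data <- structure(list(x_binary = X, target = Y,
                         target_kind = "reconstruction",
                         gene_names = paste0("g", 1:10),
                         target_genes = paste0("t", seq_len(m)),
                         splits = split_dataset(n, seed = 1)),
                    class = "prepared_dataset")
  te <- data$splits$test
  vtot <- sum(apply(Y[te, ], 2, function(col) mean((col - mean(col))^2)))
  ceiling_ev <- 1 - m * sigma^2 / vtot
  ev <- explained_variance(data, 1:4,
                           cfg = quick_cfg(max_epochs = 200, seed = 2))
  expect_lt(abs(ev - ceiling_ev), 0.05)
  expect_lte(ev, 1)
})

test_that("expressed-gene accuracy respects the detection band and 0.5 rule", {
  fix <- default_fixture()
  data <- fix$data
  # constant predictor probabilities: accuracy equals the detection fraction
  truth <- matrix(c(1, 1, 1, 0, 1, 0, 1, 1, 1, 0), 10, 1)
  expect_equal(as.numeric(ps$accuracy_from_prob(matrix(1, 10, 1), truth)), 0.7)
  expect_equal(as.numeric(ps$accuracy_from_prob(truth, truth)), 1)
  # a probability of exactly 0.5 is called not-expressed (strict >)
  expect_equal(as.numeric(ps$accuracy_from_prob(matrix(0.5, 10, 1), truth)), 0.3)

  # band membership is decided on the training split only
  frac <- colMeans(data$expressed[data$splits$train, ])
  band_genes <- ps$detection_band_genes(data, c(0.2, 0.8))
  expect_true(all(frac[band_genes] >= 0.2 & frac[band_genes] <= 0.8))
  expect_true(all(frac[-band_genes] < 0.2 | frac[-band_genes] > 0.8))
  expect_error(ps$detection_band_genes(data, c(0.8, 0.2)), "band")

  res <- expressed_gene_accuracy(data, 1:4,
                                 cfg = quick_cfg(max_epochs = 60,
                                                 hidden = c(16, 16)))
  expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  expect_equal(nrow(res$per_gene), length(band_genes))
})

test_that("a gene expressed in 10% of cells is excluded from the band targets", {
  set.seed(3)
  counts <- matrix(rpois(200 * 3, 5), 200, 3)
  counts[, 2] <- rbinom(200, 1, 0.10) * 3   # ~10% detection
  counts[, 3] <- rbinom(200, 1, 0.50) * 3   # ~50% detection
  em <- expression_matrix(counts, c("high", "rare", "mid"),
                          paste0("c", 1:200))
  data <- prepare_dataset(em, seed = 1)
  band <- ps$detection_band_genes(data, c(0.2, 0.8))
  expect_false(which(em$gene_names == "rare") %in% band)
  expect_true(which(em$gene_names == "mid") %in% band)
})

test_that("GBDT cell-type accuracy behaves across signal regimes", {
  cfgm <- synthetic_config(n_cells = 800, n_genes = 20, n_types = 4,
                           planted_genes = 1:4, dropout_rate = 0.02, seed = 3)
  sim <- generate_scrnaseq(cfgm)
  labs <- paste0("T", sim$truth$cell_types)
  data <- prepare_dataset(sim$em, labels = labs, seed = 4)
  # markers determine the type up to rare dropout: near-Bayes accuracy
  acc <- celltype_accuracy(data, 1:4)
  expect_gte(acc, 0.95)
  # permuting the panel's gene order changes nothing for the GBDT
  expect_equal(celltype_accuracy(data, c(3, 1, 4, 2)), acc)

  # shuffled labels cannot beat the majority class (binomial 3 SE bound)
  set.seed(8)
  shuffled <- sample(labs)
  dsh <- prepare_dataset(sim$em, labels = shuffled, seed = 4)
  acc_sh <- celltype_accuracy(dsh, 1:4)
  p_maj <- max(table(shuffled)) / length(shuffled)
  n_test <- length(dsh$splits$test)
  expect_lt(abs(acc_sh - p_maj), 3 * sqrt(p_maj * (1 - p_maj) / n_test))

  # single-class data is classified perfectly by the constant rule
  done <- prepare_dataset(sim$em, labels = rep("only", 800), seed = 4)
  expect_equal(celltype_accuracy(done, 1:4), 1)

  # a class present only in the test split is flagged and scored as errors
  labs2 <- labs
  test_cells <- data$splits$test[1:5]
  labs2[test_cells] <- "phantom"
  d2 <- prepare_dataset(sim$em, labels = labs, seed = 4)
  d2$labels <- labs2
  expect_warning(celltype_accuracy(d2, 1:4), "phantom")
})

test_that("panel overlap statistics match enumeration and exact tail formulas", {
  expect_equal(panel_overlap_fraction(letters[1:5], letters[1:5]), 1)
  expect_equal(panel_overlap_fraction(letters[1:5], letters[6:10]), 0)
  a <- paste0("g", 1:32); b <- c(paste0("g", 1:17), paste0("h", 1:15))
  expect_equal(panel_overlap_fraction(a, b), 17 / 32)
  expect_error(panel_overlap_fraction(letters[1:3], letters[1:4]), "equal size")
  expect_error(panel_overlap_fraction(character(0), character(0)), "non-empty")

  expect_equal(random_overlap_probability(100, 10, 0), 1)
  # enumeration oracle: N=4, k=2 -> P(overlap >= 1) = 1 - C(2,2)/C(4,2) = 5/6
  expect_equal(random_overlap_probability(4, 2, 1), 5 / 6)
  # monotone non-increasing in the overlap threshold
  p <- vapply(0:6, function(m) random_overlap_probability(300, 6, m),
              numeric(1))
  expect_true(all(diff(p) <= 1e-15))
  # independent cross-checks: exact hypergeometric tail and Monte-Carlo
  for (m in 1:3)
    expect_equal(random_overlap_probability(100, 10, m),
                 phyper(m - 1, 10, 90, 10, lower.tail = FALSE),
                 tolerance = 1e-12)
  set.seed(4)
  draws <- vapply(1:100000, function(i)
    length(intersect(sample.int(100, 10), sample.int(100, 10))), numeric(1))
  p_mc <- mean(draws >= 2)
  p_exact <- random_overlap_probability(100, 10, 2)
  expect_lt(abs(p_exact - p_mc),
            3 * sqrt(p_exact * (1 - p_exact) / 100000))
})

test_that("bootstrap intervals follow the mean +/- 1.96 sd construction", {
  fix <- default_fixture()
  # a deterministic metric yields a zero-width interval
  ci <- bootstrap_ci(function(d) 0.42, fix$data, n_boot = 5, seed = 1)
  expect_equal(unname(ci["lower"]), 0.42)
  expect_equal(unname(ci["upper"]), 0.42)

  # a metric driven by the resampled training set: interval brackets the
  # mean of the recorded values by construction
  metric <- function(d) mean(d$splits$train)
  ci2 <- bootstrap_ci(metric, fix$data, n_boot = 6, seed = 2)
  vals <- attr(ci2, "values")
  expect_length(vals, 6)
  expect_equal(unname(ci2["lower"]), mean(vals) - 1.96 * sd(vals))
  expect_equal(unname(ci2["upper"]), mean(vals) + 1.96 * sd(vals))
  expect_true(mean(vals) >= ci2["lower"] && mean(vals) <= ci2["upper"])
  # resampling is seed-reproducible
  expect_identical(bootstrap_ci(metric, fix$data, n_boot = 6, seed = 2), ci2)
})

test_that("evaluate_panel assembles a coherent report", {
  fix <- default_fixture()
  labs <- paste0("T", fix$sim$truth$cell_types)
  data <- prepare_dataset(fix$sim$em, labels = labs, seed = 7)
  rep <- evaluate_panel(data, fix$sim$em$gene_names[1:4],
                        cfg = quick_cfg(max_epochs = 60, hidden = c(16, 16)))
  expect_s3_class(rep, "eval_report")
  expect_lte(rep$explained_variance, 1)
  expect_true(rep$expressed_gene_accuracy >= 0 &&
                rep$expressed_gene_accuracy <= 1)
  expect_true(rep$celltype_accuracy >= 0 && rep$celltype_accuracy <= 1)
  gl <- generics::glance(rep)
  expect_equal(gl$panel_size, 4L)
  td <- generics::tidy(rep)
  expect_true(all(c("gene", "detection_fraction", "accuracy") %in% names(td)))
})
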