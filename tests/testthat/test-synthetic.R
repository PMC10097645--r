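test_that("generator output satisfies the expression-matrix contract", {
  sim <- generate_scrnaseq(synthetic_config())
  expect_s3_class(sim$em, "expr_mat")
  expect_equal(dim(sim$em), c(600L, 30L))
  expect_true(all(sim$em$counts >= 0))
  expect_true(all(sim$truth$cell_types %in% 1:3))
  expect_equal(sim$truth$planted_genes, 1:4)
  # distinct type codes over planted genes, no constant planted gene
  S <- sim$truth$type_states
  expect_equal(nrow(unique(S)), 3L)
  expect_true(all(apply(S, 2, function(x) length(unique(x)) > 1)))

  expect_identical(generate_scrnaseq(synthetic_config())$em$counts,
                   sim$em$counts)
  expect_false(identical(
    generate_scrnaseq(synthetic_config(seed = 2))$em$counts, sim$em$counts))

  expect_error(synthetic_config(dropout_rate = 1), "dropout")
  expect_error(synthetic_config(planted_genes = c(1, 1)), "distinct")
  expect_error(synthetic_config(n_types = 40, planted_genes = 1:2), "coded")
})

test_that("zero fractions match the closed-form negative-binomial mass", {
  # fixed depth and no link noise make the per-gene zero probability exact:
  # planted genes are structural (1 - state), others are NB zero mass
  cfg <- synthetic_config(n_cells = 3000, n_genes = 12, n_types = 3,
                          planted_genes = 1:3, dropout_rate = 0,
                          depth_range = c(1, 1), link_noise_sd = 0,
                          seed = 21)
  sim <- generate_scrnaseq(cfg)
  mu <- sim$truth$type_means[sim$truth$cell_types, ]  # per-cell means
  size <- cfg$nb_dispersion
  p0 <- (size / (size + mu))^size
  p0[, 1:3] <- (mu[, 1:3] == 0) * 1   # structural on/off planted genes
  expected <- colMeans(p0)
  observed <- colMeans(sim$em$counts == 0)
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / nrow(mu))
  expect_true(all(abs(observed - expected) <= 3 * se + 1e-9))
})

test_that("planted binarized states identify the cell type exactly at zero dropout", {
  cfg <- synthetic_config(dropout_rate = 0, seed = 5)
  sim <- generate_scrnaseq(cfg)
  xb <- binarize_counts(sim$em)[, sim$truth$planted_genes]
  expect_equal(unname(xb),
               sim$truth$type_states[sim$truth$cell_types, , drop = FALSE],
               ignore_attr = TRUE)
  # with dropout the states are corrupted only towards zero
  simd <- generate_scrnaseq(synthetic_config(dropout_rate = 0.2, seed = 5))
  xbd <- binarize_counts(simd$em)[, simd$truth$planted_genes]
  expect_true(all(xbd <= simd$truth$type_states[simd$truth$cell_types, ]))
})

test_that("the pseudo-FISH transform is monotone and quantile-matchable", {
  base_cfg <- synthetic_config(seed = 9)
  sim <- generate_scrnaseq(base_cfg)

  # identity transform, no noise: FISH equals the scRNA matrix
  ident <- synthetic_config(seed = 9, fish_scale_range = c(1, 1),
                            fish_intercept_range = c(0, 0),
                            fish_noise_sd = 0)
  expect_identical(generate_paired_fish(sim$em, ident)$counts, sim$em$counts)

  # 2x + 1, no noise: matched binarization reproduces the scRNA one
  aff <- synthetic_config(seed = 9, fish_scale_range = c(2, 2),
                          fish_intercept_range = c(1, 1), fish_noise_sd = 0)
  fish <- generate_paired_fish(sim$em, aff)
  expect_identical(fish$counts, 2 * sim$em$counts + 1)
  rule <- match_binarization_threshold(sim$em, fish)
  expect_equal(binarize_counts(fish, rule$threshold), binarize_counts(sim$em),
               ignore_attr = TRUE)

  # binarization agreement decays as transform noise grows
  agree <- vapply(c(0, 0.5, 2), function(sd) {
    cfg <- synthetic_config(seed = 9, fish_noise_sd = sd)
    f <- generate_paired_fish(sim$em, cfg)
    r <- match_binarization_threshold(sim$em, f)
    mean(binarize_counts(f, r$threshold) == binarize_counts(sim$em))
  }, numeric(1))
  expect_gte(agree[1], agree[2] - 0.005)
  expect_gte(agree[2], agree[3] - 0.005)
  expect_gt(agree[1], agree[3])
})

test_that("planted genes dominate random panels in explained variance", {
  fix <- default_fixture()
  cfg <- quick_cfg(max_epochs = 60, hidden = c(16, 16), seed = 7)
  ev_planted <- explained_variance(fix$data, fix$sim$truth$planted_genes,
                                   cfg = cfg)
  set.seed(10)
  wins <- 0L
  for (i in 1:20) {
    rp <- sample(setdiff(1:30, fix$sim$truth$planted_genes), 4)
    if (ev_planted > explained_variance(fix$data, rp, cfg = cfg))
      wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
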