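test_that("temperature annealing is geometric with the documented endpoints", {
  expect_equal(anneal_tau(0, 100), 10)
  expect_equal(anneal_tau(100, 100), 0.01)
  expect_equal(anneal_tau(50, 100), sqrt(10 * 0.01))
  ratios <- anneal_tau(1:100, 100) / anneal_tau(0:99, 100)
  expect_lt(diff(range(ratios)), 1e-12)
  expect_error(anneal_tau(101, 100), "\\[0, 100\\]")
  expect_error(anneal_tau(10, 100, tau_init = 0.01, tau_final = 10),
               "tau_final < tau_init")
})

test_that("Concrete samples are valid simplex points with the right limits", {
  # symmetry: equal log-scores give the uniform vector at any temperature
  for (tau in c(10, 1, 0.01))
    expect_equal(sample_concrete(rep(0.3, 7), tau), rep(1 / 7, 7))

  set.seed(2)
  for (i in 1:20) {
    s <- sample_concrete(rnorm(9, sd = 3), runif(1, 0.01, 5), rgumbel(9))
    expect_equal(sum(s), 1, tolerance = 1e-6)
    expect_true(all(s > 0 & s < 1))
  }

  # tau -> 0 concentrates on the largest score: Monte-Carlo argmax frequency
  set.seed(7)
  la <- c(10, 0, 0)
  hits <- sum(vapply(1:10000, function(i)
    which.max(la + rgumbel(3)) == 1L, logical(1)))
  expect_gte(hits / 10000, 0.99)
})

test_that("the binary-mask forward obeys max/absorption properties", {
  set.seed(5)
  sel <- new_concrete_selector(d = 6, k = 3)
  x0 <- matrix(0, 4, 6)
  out <- binary_mask_forward(sel, x0, tau = 1)
  expect_true(all(out$xm == 0))

  x <- matrix(rbinom(24, 1, 0.5), 4, 6)
  out <- binary_mask_forward(sel, x, tau = 0.5)
  expect_true(all(out$a > 0 & out$a <= 1))
  for (s in 1:3) expect_true(all(out$a >= out$A[s, ] - 1e-12))

  # k = 1, scores peaked at gene 4, evaluation mode: output ~ x[, 4] only
  sel1 <- new_concrete_selector(d = 6, k = 1)
  sel1$log_alpha <- matrix(c(0, 0, 0, 10, 0, 0), 1, 6)
  ev <- binary_mask_forward(sel1, x, tau = 0.01, training = FALSE)
  expect_equal(ev$xm[, 4], x[, 4], tolerance = 1e-6)
  expect_true(all(abs(ev$xm[, -4]) < 1e-3))
})

test_that("binary gates match the Bernoulli limit and penalty arithmetic", {
  g <- new_binary_gates(d = 2, lam = 0.5)
  g$log_beta <- c(50, 50)  # gates saturate at 1
  out <- binary_gates_forward(g, matrix(1, 1, 2), tau = 1, training = FALSE)
  expect_equal(out$penalty, 1)
  g0 <- new_binary_gates(d = 3, lam = 0)
  out0 <- binary_gates_forward(g0, matrix(1, 1, 3), tau = 1)
  expect_equal(out0$penalty, 0)

  # tau -> 0: mean of the relaxed gate approaches beta / (1 + beta)
  set.seed(9)
  beta <- 2
  gb <- new_binary_gates(d = 1, lam = 0)
  gb$log_beta <- log(beta)
  n <- 10000
  b <- vapply(1:n, function(i)
    binary_gates_forward(gb, matrix(1, 1, 1), tau = 0.01)$b, numeric(1))
  p <- beta / (1 + beta)
  expect_lt(abs(mean(b) - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(all(b >= 0 & b <= 1))
  # the strict interior is representable at moderate temperatures
  set.seed(10)
  bmod <- vapply(1:200, function(i)
    binary_gates_forward(gb, matrix(1, 1, 1), tau = 0.5)$b, numeric(1))
  expect_true(all(bmod > 0 & bmod < 1))
})

test_that("panel extraction applies argmax, tie and duplicate rules", {
  la <- matrix(-1, 2, 8)
  la[1, 3] <- 2; la[2, 7] <- 2
  expect_equal(extract_mask_panel(la), c(3L, 7L))

  # ties resolve to the lowest index
  la_tie <- matrix(0, 1, 4)
  expect_equal(extract_mask_panel(la_tie), 1L)

  # duplicate slots are completed with the next-best scores, with a warning
  la_dup <- rbind(c(0, 5, 1, 0), c(0, 5, 0, 2))
  expect_warning(panel <- extract_mask_panel(la_dup), "duplicate")
  expect_equal(panel, c(2L, 4L))

  # gates: retain beta > 1 strictly (beta = 1 excluded)
  expect_equal(extract_gates_panel(log(c(2, 0.5, 3))), c(1L, 3L))
  expect_equal(extract_gates_panel(log(c(0.9, 1, 0.3))), integer(0))
})

test_that("selection-layer gradients match finite differences end to end", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 5L; d <- 4L; m <- 3L; k <- 2L
    X <- matrix(rbinom(n * d, 1, 0.5), n, d)
    y <- matrix(abs(rnorm(n * m)), n, m); y[sample(n * m, 4)] <- 0
    batch <- list(y = y, expressed = (y > 0) * 1)
    net <- ps$mlp_init(d, 2 * m, hidden = c(5L, 4L))
    lg <- ps$loss_grad_for("reconstruction")
    tau <- runif(1, 0.3, 2)

    sel <- new_concrete_selector(d, k)
    noise <- matrix(rgumbel(n * k * d), n * k, d)
    res <- ps$selector_step(sel, net, X, batch, tau, lg, gamma = 10,
                            noise = noise)
    gn <- num_grad(function(la) {
      s2 <- sel; s2$log_alpha <- la
      ps$selector_step(s2, net, X, batch, tau, lg, gamma = 10,
                       noise = noise)$loss
    }, sel$log_alpha)
    expect_lt(rel_err(gn, res$grads$log_alpha), 1e-4)
    gw <- num_grad(function(w) {
      n2 <- net; n2$W[[1]] <- matrix(w, d, 5)
      ps$selector_step(sel, n2, X, batch, tau, lg, gamma = 10,
                       noise = noise)$loss
    }, as.numeric(net$W[[1]]))
    expect_lt(rel_err(matrix(gw, d, 5), res$grads$W1), 1e-4)

    g <- new_binary_gates(d, lam = 0.3)
    u <- matrix(runif(n * d), n, d)
    lnoise <- log(u) - log1p(-u)
    resg <- ps$selector_step(g, net, X, batch, tau, lg, gamma = 10,
                             noise = lnoise)
    gnb <- num_grad(function(lb) {
      g2 <- g; g2$log_beta <- lb
      ps$selector_step(g2, net, X, batch, tau, lg, gamma = 10,
                       noise = lnoise)$loss
    }, g$log_beta)
    expect_lt(rel_err(gnb, resg$grads$log_beta), 1e-4)
  }
})
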