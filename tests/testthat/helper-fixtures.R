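# Shared fixtures and oracles, generated in code at test time.

ps <- asNamespace("panelselect")

# compact training configs: small hidden layers and epoch budgets keep each
# fit in the seconds range while leaving the optimisation dynamics intact
quick_cfg <- function(max_epochs = 120L, seed = 1L, hidden = c(32L, 32L),
                      patience = max_epochs, ...) {
  train_config(max_epochs = max_epochs, patience = patience, seed = seed,
               hidden = hidden, ...)
}

# default benchmark instance: 600 cells x 30 genes, 3 types, 4 planted genes
fixture_env <- new.env()
default_fixture <- function() {
  if (is.null(fixture_env$fix)) {
    sim <- generate_scrnaseq(synthetic_config())
    fixture_env$fix <- list(sim = sim,
                            data = prepare_dataset(sim$em, seed = 7))
  }
  fixture_env$fix
}

# small dense instance where exhaustive panel search is feasible:
# 500 cells x 6 genes, 4 types coded by 2 planted genes
toy6_fixture <- function() {
  if (is.null(fixture_env$toy6)) {
    sim <- generate_scrnaseq(synthetic_config(
      n_cells = 500L, n_genes = 6L, n_types = 4L, planted_genes = 1:2,
      seed = 11L))
    fixture_env$toy6 <- list(sim = sim,
                             data = prepare_dataset(sim$em, seed = 2))
  }
  fixture_env$toy6
}

# central-difference numeric gradient
num_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-12)

local_test_dir <- function() {
  d <- tempfile("panelselect_test_")
  dir.create(d)
  d
}

local_test_file <- function(name) file.path(local_test_dir(), name)

random_expr_mat <- function(n = 8, d = 5, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rpois(n * d, 3), n, d),
                    gene_names = paste0("g", seq_len(d)),
                    cell_ids = paste0("c", seq_len(n)))
}
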