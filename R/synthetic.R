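#' Synthetic scRNA-seq configuration
#'
#' Configures the ground-truth-bearing generator used throughout the test
#' suite and examples. Cells belong to one of `n_types` types drawn
#' uniformly. A small set of planted genes is on/off per type (distinct
#' binary codes, no constant gene): an "off" planted gene is a structural
#' zero and an "on" one is guaranteed detected (count of at least 1, with
#' a negative-binomial magnitude), so at zero dropout the binarized
#' planted states identify the cell type exactly. Every non-planted
#' gene's mean is a bounded monotone (sigmoid) link of a noisy linear
#' function of the planted states, sampled from a negative binomial with
#' per-cell library-size scaling — so the planted genes determine all
#' others up to noise. Dropout then zeroes each entry independently.
#'
#' Defaults give the compact benchmark instance used by the package's
#' own checks: 600 cells, 30 genes, 3 types, 4 planted genes, 10%
#' dropout, NB dispersion 2, depth range (0.7, 1.3).
#'
#' @param n_cells,n_genes,n_types Dataset dimensions.
#' @param planted_genes Indices of the planted determinant genes.
#' @param dropout_rate Probability in `[0, 1)` that an expressed count is
#'   zeroed (post-hoc, independently per entry).
#' @param nb_dispersion Negative-binomial size parameter.
#' @param depth_range Per-cell library-size factor, Uniform(min, max).
#' @param mu_high,mu_low Mean scale of high/low expression.
#' @param link_noise_sd Per-cell noise sd on the linear predictor of
#'   non-planted genes.
#' @param fish_scale_range,fish_intercept_range Per-gene monotone map
#'   `count -> scale * count + intercept` of the paired pseudo-FISH
#'   matrix; parameters drawn uniformly per gene. The positive intercept
#'   emulates FISH background signal (a non-trivial domain shift).
#' @param fish_noise_sd Gaussian noise sd added before rounding.
#' @param fish_extra_zero Extra zero-inflation probability of the FISH
#'   matrix (different detection efficiency).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 600L, n_genes = 30L, n_types = 3L,
                             planted_genes = 1:4, dropout_rate = 0.1,
                             nb_dispersion = 2, depth_range = c(0.7, 1.3),
                             mu_high = 8, mu_low = 0.1, link_noise_sd = 0.5,
                             fish_scale_range = c(1, 3),
                             fish_intercept_range = c(0.5, 2),
                             fish_noise_sd = 0.5, fish_extra_zero = 0,
                             seed = 1L) {
  planted_genes <- as.integer(planted_genes)
  if (anyDuplicated(planted_genes) || any(planted_genes < 1L) ||
      any(planted_genes > n_genes))
    stopf("planted_genes must be distinct indices in 1..%d", n_genes)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (length(depth_range) != 2L || any(depth_range <= 0) ||
      depth_range[1L] > depth_range[2L])
    stopf("depth_range must be a positive interval")
  if (n_types > 2^length(planted_genes))
    stopf("%d types cannot be coded by %d binary planted genes",
          n_types, length(planted_genes))
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types), planted_genes = planted_genes,
                 dropout_rate = dropout_rate, nb_dispersion = nb_dispersion,
                 depth_range = depth_range, mu_high = mu_high, mu_low = mu_low,
                 link_noise_sd = link_noise_sd,
                 fish_scale_range = fish_scale_range,
                 fish_intercept_range = fish_intercept_range,
                 fish_noise_sd = fish_noise_sd,
                 fish_extra_zero = fish_extra_zero,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Distinct type codes over the planted genes, no constant column.
planted_states <- function(n_types, n_planted) {
  repeat {
    S <- matrix(stats::rbinom(n_types * n_planted, 1L, 0.5), n_types, n_planted)
    if (!anyDuplicated(S) && all(apply(S, 2L, function(x) length(unique(x)) > 1L)))
      return(S)
  }
}

#' Generate a synthetic scRNA-seq dataset
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `em` (the [expression_matrix()]) and `truth`
#'   (`cell_types`, `planted_genes`, `type_states`, `type_means`,
#'   `dropout_mask`).
#' @export
generate_scrnaseq <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells; d <- cfg$n_genes
  planted <- cfg$planted_genes
  types <- sample.int(cfg$n_types, n, replace = TRUE)
  S <- planted_states(cfg$n_types, length(planted))
  depth <- stats::runif(n, cfg$depth_range[1L], cfg$depth_range[2L])

  counts <- matrix(0, n, d)
  type_means <- matrix(cfg$mu_low, cfg$n_types, d)

  # planted genes: structural zero when off, guaranteed detection when on
  for (j in seq_along(planted)) {
    on <- S[types, j] == 1L
    mu <- pmax(cfg$mu_high * depth[on] - 1, 0.1)
    counts[on, planted[j]] <-
      1 + stats::rnbinom(sum(on), size = cfg$nb_dispersion, mu = mu)
    type_means[, planted[j]] <- ifelse(S[, j] == 1L, cfg$mu_high, 0)
  }

  # non-planted genes: NB around a sigmoid link of a noisy linear
  # function of the planted states
  others <- setdiff(seq_len(d), planted)
  rng <- cfg$mu_high - cfg$mu_low
  for (j in others) {
    w <- sample(c(-2, -1, 1, 2), length(planted), replace = TRUE)
    b0 <- stats::rnorm(1, 0, 1)
    eta_type <- b0 + as.numeric(S %*% w)
    eta <- eta_type[types] + stats::rnorm(n, 0, cfg$link_noise_sd)
    mu <- cfg$mu_low + rng * sigmoid(eta)
    counts[, j] <- stats::rnbinom(n, size = cfg$nb_dispersion, mu = mu * depth)
    type_means[, j] <- cfg$mu_low + rng * sigmoid(eta_type)
  }

  dropout_mask <- matrix(stats::runif(n * d) < cfg$dropout_rate, n, d)
  counts[dropout_mask] <- 0

  em <- expression_matrix(counts,
                          gene_names = sprintf("gene%03d", seq_len(d)),
                          cell_ids = sprintf("cell%04d", seq_len(n)))
  list(em = em,
       truth = list(cell_types = types, planted_genes = planted,
                    type_states = S, type_means = type_means,
                    dropout_mask = dropout_mask))
}

#' Generate a paired pseudo-FISH matrix
#'
#' Applies an independent strictly increasing per-gene transform
#' `count -> round(scale * count + intercept + noise)` (floored at 0) to
#' a scRNA-seq matrix, emulating the cross-technology domain shift under
#' which quantile threshold matching is exact in the noise-free limit.
#' Optional extra zero inflation mimics a different detection efficiency.
#'
#' @param scrna The reference [expression_matrix()] (same cells).
#' @param cfg A [synthetic_config()]; the `fish_*` fields parameterise
#'   the transform.
#' @return An `expr_mat` with the same gene names and cell ids.
#' @export
generate_paired_fish <- function(scrna, cfg = synthetic_config()) {
  stopifnot(inherits(scrna, "expr_mat"), inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 99991L))
  n <- nrow(scrna$counts); d <- ncol(scrna$counts)
  scale_g <- stats::runif(d, cfg$fish_scale_range[1L], cfg$fish_scale_range[2L])
  shift_g <- stats::runif(d, cfg$fish_intercept_range[1L],
                          cfg$fish_intercept_range[2L])
  fish <- scrna$counts * rep(scale_g, each = n) + rep(shift_g, each = n)
  if (cfg$fish_noise_sd > 0)
    fish <- fish + stats::rnorm(n * d, 0, cfg$fish_noise_sd)
  fish <- pmax(round(fish), 0)
  if (cfg$fish_extra_zero > 0)
    fish[stats::runif(n * d) < cfg$fish_extra_zero] <- 0
  expression_matrix(fish, scrna$gene_names, scrna$cell_ids)
}
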