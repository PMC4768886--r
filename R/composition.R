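#' Monte Carlo integration of composition proportions
#'
#' Under the multinomial probit model the proportion of taxon p at a cell
#' is the probability that its latent utility attains the maximum,
#' theta_p(s) = Prob(W_p = max_q W_q) with W ~ N(alpha(s), I). This has
#' no closed form for P > 2, so it is estimated by drawing `n_mc`
#' hypothetical trees per cell and tabulating how often each taxon wins.
#' Floating-point argmax ties resolve to the lowest taxon index.
#'
#' @param alpha Field matrix (cells x taxa).
#' @param n_mc Number of Monte Carlo trees per cell (default 10000).
#' @return Matrix (cells x taxa) of empirical frequencies; each row sums
#'   to exactly 1.
#' @export
mc_theta <- function(alpha, n_mc = 10000) {
  alpha <- as.matrix(alpha)
  if (!all(is.finite(alpha))) stop("non-finite field values")
  if (n_mc < 1) stop("'n_mc' must be at least 1")
  theta <- cpp_mc_theta(alpha, as.integer(n_mc))
  dimnames(theta) <- dimnames(alpha)
  theta
}

#' Exact two-taxon probit proportion
#'
#' Closed-form probability that a N(a1, 1) utility exceeds an independent
#' N(a2, 1) utility: Phi((a1 - a2) / sqrt(2)). Serves as the analytic
#' check of the Monte Carlo integration when P = 2.
#'
#' @param a1,a2 Field values of the two taxa.
#' @return The proportion of taxon 1.
#' @export
probit_two_taxon_oracle <- function(a1, a2) {
  pnorm((a1 - a2) / sqrt(2))
}

#' Composition proportion draws for a fitted model
#'
#' Converts each retained field draw into a per-cell composition simplex
#' by Monte Carlo integration. Draw k uses an RNG substream seeded
#' deterministically from `seed` and k, so results are reproducible and
#' draws could be computed independently.
#'
#' @param fit A `comp_fit`.
#' @param n_mc Monte Carlo trees per cell and draw (defaults to the
#'   fitted config's `n_mc`).
#' @param seed Master seed for the integration streams.
#' @param cells Optional subset of cell indices (default: all cells,
#'   including buffer; use `fit$grid$core_mask` downstream to restrict).
#' @return A `theta_samples` object: array K x cells x taxa with
#'   attributes `cells`, `n_mc`, `seed`, `taxa`, `grid`.
#' @export
posterior_theta <- function(fit, n_mc = fit$config$n_mc, seed = 1,
                            cells = NULL) {
  stopifnot(inherits(fit, "comp_fit"))
  K <- dim(fit$alpha)[1]
  cells <- cells %||% seq_len(dim(fit$alpha)[2])
  P <- dim(fit$alpha)[3]
  theta <- array(NA_real_, c(K, length(cells), P),
                 dimnames = list(NULL, NULL, fit$taxa))
  for (k in seq_len(K)) {
    set.seed(seed + k - 1L)
    a_k <- matrix(fit$alpha[k, cells, ], nrow = length(cells))
    theta[k, , ] <- mc_theta(a_k, n_mc)
  }
  structure(theta, class = "theta_samples", cells = cells, n_mc = n_mc,
            seed = seed, taxa = fit$taxa, grid = fit$grid)
}

#' Posterior mean and standard deviation of composition
#'
#' Elementwise mean and sample standard deviation across the K retained
#' composition draws; the mean is the point prediction and the standard
#' deviation its Bayesian standard error. Means per cell sum to 1.
#'
#' @param theta A `theta_samples` array (K x cells x taxa), K >= 2.
#' @return List with matrices `mean` and `sd` (cells x taxa).
#' @export
summarize_theta <- function(theta) {
  K <- dim(theta)[1]
  if (is.null(K) || K < 2) {
    stop("at least 2 posterior draws are needed to summarize")
  }
  mn <- apply(theta, c(2, 3), mean)
  vr <- apply(theta, c(2, 3), function(x) sum((x - mean(x))^2)) / (K - 1)
  list(mean = mn, sd = sqrt(vr))
}
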