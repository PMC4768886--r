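#' Intrinsic CAR precision template
#'
#' Builds the intrinsic conditional autoregressive (ICAR) precision
#' Q = D - C, where C is the cardinal-neighbor adjacency and D the
#' diagonal matrix of neighbor counts. Q is symmetric with zero row sums
#' and rank m - (number of connected components); the resulting field
#' prior is improper with an unconstrained overall level.
#'
#' @param adj A `cell_adjacency`.
#' @return A `precision_template` (list with sparse symmetric `Q`,
#'   `kind = "car"`, `m`, `rank` of Q).
#' @export
build_car_precision <- function(adj) {
  stopifnot(inherits(adj, "cell_adjacency"))
  Q <- Matrix::Diagonal(x = adj$degree) - adj$C
  Q <- as(Matrix::forceSymmetric(Q), "CsparseMatrix")
  structure(list(Q = Q, kind = "car", rho = NULL, m = length(adj$degree),
                 rank = length(adj$degree) - n_components(adj)),
            class = "precision_template")
}

#' GMRF precision template approximating a Matern (nu = 1) field
#'
#' Builds the lattice Gaussian Markov random field approximation to a
#' Gaussian process with Matern covariance of smoothness nu = 1 and range
#' `rho` (in grid-cell units). With a = 4 + 1/rho^2 the precision is the
#' matrix square (a I - C)^2, giving the interior stencil: diagonal
#' 4 + a^2, cardinal neighbors -2a, diagonal neighbors 2, second-order
#' cardinal neighbors 1. The construction uses the finite buffered lattice
#' with no extra boundary correction; a buffer pushes the resulting edge
#' artifacts away from the core cells.
#'
#' @param adj A `cell_adjacency`.
#' @param rho Spatial range, in grid-cell units; must be positive.
#' @return A `precision_template` (sparse positive-definite `Q`,
#'   `kind = "spde"`, the `rho` used).
#' @export
build_spde_precision <- function(adj, rho) {
  stopifnot(inherits(adj, "cell_adjacency"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("'rho' must be a positive number")
  }
  m <- length(adj$degree)
  a <- 4 + 1 / rho^2
  B <- Matrix::Diagonal(m, x = a) - adj$C
  Q <- as(Matrix::forceSymmetric(Matrix::crossprod(B)), "CsparseMatrix")
  structure(list(Q = Q, kind = "spde", rho = rho, m = m, rank = m),
            class = "precision_template")
}

#' @export
print.precision_template <- function(x, ...) {
  cat(sprintf("precision_template: kind '%s', %d cells%s\n", x$kind, x$m,
              if (x$kind == "spde") sprintf(", rho = %g", x$rho) else ""))
  invisible(x)
}

#' Scale a precision template into a per-taxon precision
#'
#' CAR: Q_p = Q / sigma^2. SPDE: Q_p = Q(rho) / (sigma^2 * 4 * pi * rho^2);
#' the 4 pi rho^2 factor makes sigma^2 the marginal variance scale,
#' mathematically comparable between the two models.
#'
#' @param template A `precision_template`.
#' @param sigma Field scale for the taxon; must be positive.
#' @return A sparse symmetric precision matrix.
#' @export
scale_precision <- function(template, sigma) {
  stopifnot(inherits(template, "precision_template"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a positive number")
  }
  if (template$kind == "car") {
    template$Q / sigma^2
  } else {
    template$Q / (sigma^2 * 4 * pi * template$rho^2)
  }
}

#' Matern correlation function
#'
#' R(d) = 1 / (Gamma(nu) 2^(nu - 1)) * (sqrt(2 nu) d / rho)^nu *
#' K_nu(sqrt(2 nu) d / rho), with K_nu the modified Bessel function of the
#' second kind. nu = 0.5 reduces to the exponential correlation
#' exp(-d / rho); R(0) = 1.
#'
#' @param d Nonnegative distances (vectorized).
#' @param rho Range parameter, positive.
#' @param nu Smoothness parameter, positive; default 1 (the smoothness
#'   the lattice GMRF approximation targets).
#' @return Correlations in `[0, 1]`.
#' @export
matern_correlation <- function(d, rho, nu = 1) {
  if (!is.numeric(rho) || rho <= 0) stop("'rho' must be positive")
  if (!is.numeric(nu) || nu <= 0) stop("'nu' must be positive")
  if (any(d < 0)) stop("'d' must be nonnegative")
  u <- sqrt(2 * nu) * d / rho
  out <- rep(1, length(u))
  pos <- u > 0
  out[pos] <- u[pos]^nu * besselK(u[pos], nu) / (gamma(nu) * 2^(nu - 1))
  pmin(pmax(out, 0), 1)
}

#' Hyperprior support bounds
#'
#' The hyperpriors are flat within bounds: sigma uniform on
#' (0, sigma_max], mu (SPDE only) uniform on [-mu_bound, mu_bound], rho
#' (SPDE only) uniform on (rho_min, rho_max). Defaults follow the model's
#' reference priors: sigma_max = 1000, mu_bound = 10, rho on
#' (0.1, exp(5)).
#'
#' @param sigma_max Upper bound for the field scale sigma.
#' @param mu_bound Half-width of the flat prior on the SPDE field mean.
#' @param rho_min,rho_max Support of the flat prior on the SPDE range.
#' @return A `hyperprior_bounds` list.
#' @export
hyperprior_bounds <- function(sigma_max = 1000, mu_bound = 10,
                              rho_min = 0.1, rho_max = exp(5)) {
  stopifnot(sigma_max > 0, mu_bound >= 0, rho_min > 0, rho_max > rho_min)
  structure(list(sigma_max = sigma_max, mu_bound = mu_bound,
                 rho_min = rho_min, rho_max = rho_max),
            class = "hyperprior_bounds")
}

#' Log density of the hyperprior (up to a constant)
#'
#' Returns 0 inside the support and -Inf outside. For the CAR model only
#' sigma is checked; for the SPDE model sigma, mu and rho are all checked.
#'
#' @param sigma Field scale.
#' @param mu Field mean (SPDE; ignored for CAR).
#' @param rho Field range (SPDE; ignored for CAR).
#' @param kind `"car"` or `"spde"`.
#' @param bounds A `hyperprior_bounds`.
#' @return 0 or -Inf.
#' @export
hyperprior_logdensity <- function(sigma, mu = 0, rho = 1,
                                  kind = c("car", "spde"),
                                  bounds = hyperprior_bounds()) {
  kind <- match.arg(kind)
  ok <- is.finite(sigma) && sigma > 0 && sigma <= bounds$sigma_max
  if (kind == "spde") {
    ok <- ok && is.finite(mu) && abs(mu) <= bounds$mu_bound &&
      is.finite(rho) && rho > bounds$rho_min && rho < bounds$rho_max
  }
  if (ok) 0 else -Inf
}
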