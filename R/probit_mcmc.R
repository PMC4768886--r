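#' Draw from truncated normal distributions (vectorized)
#'
#' Inverse-CDF sampler working in whichever tail is numerically safer,
#' using log-scale normal CDF/quantile evaluations so that truncation
#' points beyond +-8 remain exact instead of collapsing to the bound.
#'
#' @param n Number of draws (recycling `mean`, `sd`, `lower`, `upper`).
#' @param mean,sd Location and scale.
#' @param lower,upper Truncation bounds (may be -Inf / Inf).
#' @param u Optional uniforms in (0, 1); supply to make the inverse-CDF
#'   map deterministic (e.g. `u = 0.5` returns the truncated median).
#' @return Numeric vector of draws.
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf, u = NULL) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  a <- (rep_len(lower, n) - mean) / sd
  b <- (rep_len(upper, n) - mean) / sd
  if (any(a >= b)) stop("'lower' must be strictly below 'upper'")
  if (is.null(u)) u <- runif(n) else u <- rep_len(u, n)
  z <- numeric(n)
  hi <- a > 0            # both bounds in the upper tail: work with survival
  lo <- !hi & b < 0      # both bounds in the lower tail: work with the CDF
  mid <- !hi & !lo
  if (any(hi)) {
    la <- pnorm(a[hi], lower.tail = FALSE, log.p = TRUE)
    lb <- pnorm(b[hi], lower.tail = FALSE, log.p = TRUE)
    # log S(x) uniform between lb and la: la + log(1 - u (1 - e^{lb-la}))
    tgt <- la + log1p(-u[hi] * (1 - exp(lb - la)))
    z[hi] <- qnorm(tgt, lower.tail = FALSE, log.p = TRUE)
  }
  if (any(lo)) {
    la <- pnorm(a[lo], log.p = TRUE)
    lb <- pnorm(b[lo], log.p = TRUE)
    tgt <- lb + log1p(-(1 - u[lo]) * (1 - exp(la - lb)))
    z[lo] <- qnorm(tgt, log.p = TRUE)
  }
  if (any(mid)) {
    pa <- pnorm(a[mid]); pb <- pnorm(b[mid])
    z[mid] <- qnorm(pa + u[mid] * (pb - pa))
  }
  mean + sd * z
}

#' One Gibbs sweep of the latent probit utilities
#'
#' For every tree the utility of the observed taxon is redrawn from a
#' normal truncated below at the largest competing utility, then each
#' competing utility is redrawn truncated above at the new value, so the
#' observed taxon remains the strict argmax.
#'
#' @param W Numeric matrix, trees x taxa, of current latent utilities.
#' @param tree_cell Integer vector: current grid-cell index per tree.
#' @param tree_taxon Integer vector: observed taxon per tree.
#' @param alpha Numeric matrix, cells x taxa, of latent field values.
#' @return Updated utility matrix.
#' @export
gibbs_update_W <- function(W, tree_cell, tree_taxon, alpha) {
  if (!all(is.finite(alpha))) {
    stop("non-finite latent field values passed to the W update")
  }
  stopifnot(nrow(W) == length(tree_cell), nrow(W) == length(tree_taxon),
            ncol(W) == ncol(alpha))
  cpp_update_W(W, as.integer(tree_cell), as.integer(tree_taxon), alpha)
}

#' Per-cell sufficient statistics of the latent utilities
#'
#' @param W Numeric matrix, trees x taxa.
#' @param tree_cell Integer vector of cell indices per tree.
#' @param m Total number of cells.
#' @return List with `A` (per-cell tree counts, length m) and `wbar`
#'   (m x P matrix of per-cell utility means; 0 where `A` is 0).
#' @export
compute_suff_stats <- function(W, tree_cell, m) {
  A <- tabulate(tree_cell, nbins = m)
  wbar <- matrix(0, m, ncol(W))
  if (nrow(W) > 0L) {
    S <- rowsum(W, group = tree_cell)
    pres <- as.integer(rownames(S))
    wbar[pres, ] <- S / A[pres]
  }
  list(A = A, wbar = wbar)
}

# Sparse Cholesky with a logged ridge fallback for (numerically) singular
# systems, e.g. an intrinsic CAR component with no trees.
chol_pd <- function(V) {
  ch <- tryCatch(Matrix::Cholesky(V, LDL = FALSE, perm = TRUE, super = FALSE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-8 * max(Matrix::diag(V))
    message("singular precision: adding ridge ", signif(ridge, 3))
    ch <- Matrix::Cholesky(V + Matrix::Diagonal(nrow(V), ridge),
                           LDL = FALSE, perm = TRUE, super = FALSE)
  }
  list(ch = ch,
       logdet = as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                               sqrt = FALSE)$modulus))
}

# Rebuild a symmetric sparse matrix from a fixed pattern template and a
# new x slot; all per-taxon precisions share one pattern per model kind,
# so hot-loop construction is pure vector arithmetic.
make_dsC <- function(pat, x) {
  out <- pat
  out@x <- x
  out
}

# Align the entries of symmetric sparse M onto the x slot of the
# (super-pattern) template `pat`; positions absent from M get 0.
align_pattern <- function(pat, M) {
  m <- nrow(pat)
  colT <- rep.int(seq_len(m), diff(pat@p))
  M <- as(Matrix::forceSymmetric(Matrix::drop0(M), "U"), "CsparseMatrix")
  colM <- rep.int(seq_len(m), diff(M@p))
  x <- numeric(length(pat@x))
  x[match(M@i + m * (colM - 1), pat@i + m * (colT - 1))] <- M@x
  x
}

# Numeric Cholesky factorization reusing a cached symbolic analysis (the
# sparsity pattern of A + Q_p never changes within a run); falls back to
# a logged ridge when the matrix is numerically singular.
cached_chol <- function(minfo, V) {
  cache <- minfo$cache
  ch <- tryCatch({
    if (is.null(cache$ch)) {
      cache$ch <- Matrix::Cholesky(V, LDL = FALSE, perm = TRUE, super = FALSE)
    } else {
      Matrix::update(cache$ch, V)
    }
  }, error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-8 * max(Matrix::diag(V), 1)
    message("singular precision: adding ridge ", signif(ridge, 3))
    Vr <- V + Matrix::Diagonal(nrow(V), ridge)
    ch <- if (is.null(cache$ch)) {
      cache$ch <- Matrix::Cholesky(Vr, LDL = FALSE, perm = TRUE,
                                   super = FALSE)
    } else Matrix::update(cache$ch, Vr)
  }
  ch
}

# Per-taxon precision bundle in pattern-aligned form: x slot of the
# scaled precision, its (generalized) log-determinant comparable across
# hyperparameter values within a model kind, and Q_p %*% 1 terms used
# when the prior mean is nonzero. For the SPDE kind the log-determinant
# uses the closed-form lattice eigenvalues of the cardinal adjacency:
# log|Q(rho)| = 2 sum log(a - lambda_ij).
taxon_precision <- function(minfo, sigma, rho = NULL) {
  if (minfo$kind == "car") {
    list(Qx = minfo$xQ / sigma^2,
         logdet = -2 * minfo$template$rank * log(sigma),
         Q1s = 0, oneQ1 = 0)
  } else {
    a <- 4 + 1 / rho^2
    s <- 1 / (sigma^2 * 4 * pi * rho^2)
    Q1s <- s * (a^2 - 2 * a * minfo$deg + minfo$rsC2)
    list(Qx = s * (a^2 * minfo$xI - 2 * a * minfo$xC + minfo$xC2),
         logdet = minfo$m * log(s) + 2 * sum(log(a - minfo$lat_eigs)),
         Q1s = Q1s, oneQ1 = sum(Q1s))
  }
}

# Marginal (field-integrated) log likelihood of the latent utilities as a
# function of one taxon's hyperparameters, up to terms free of them:
# 0.5 log|Q_p| - 0.5 log|A + Q_p| + 0.5 b' (A + Q_p)^{-1} b
#   - 0.5 mu^2 1'Q_p 1,  with b = A wbar + mu Q_p 1.
# Also returns the Cholesky factor of (A + Q_p) and b, from which the
# field full conditional N((A+Q_p)^{-1} b, (A+Q_p)^{-1}) is sampled.
# `Vch` allows reuse of the factor when only mu changes.
taxon_marginal <- function(minfo, A, wbar_p, Qpinfo, mu = 0, Vch = NULL) {
  if (is.null(Vch)) {
    Vx <- Qpinfo$Qx
    Vx[minfo$diag_idx] <- Vx[minfo$diag_idx] + A
    ch <- cached_chol(minfo, make_dsC(minfo$pat, Vx))
    logdetV <- as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                              sqrt = FALSE)$modulus)
  } else {
    ch <- Vch$ch
    logdetV <- Vch$logdetV
  }
  b <- A * wbar_p + mu * Qpinfo$Q1s
  quad <- sum(b * as.numeric(Matrix::solve(ch, b, system = "A")))
  ll <- 0.5 * Qpinfo$logdet - 0.5 * logdetV + 0.5 * quad -
    0.5 * mu^2 * Qpinfo$oneQ1
  list(ll = ll, ch = ch, logdetV = logdetV, b = b)
}

# Draw the latent field from its full conditional given the Cholesky
# factor of the conditional precision V = P'LL'P and b: mean = V^{-1} b,
# draw = mean + P' L^{-T} z.
draw_alpha_from <- function(marg) {
  m <- length(marg$b)
  mean <- as.numeric(Matrix::solve(marg$ch, marg$b, system = "A"))
  z <- rnorm(m)
  mean + as.numeric(Matrix::solve(marg$ch,
                                  Matrix::solve(marg$ch, z, system = "Lt"),
                                  system = "Pt"))
}

#' Draw one taxon's latent field from its Gaussian full conditional
#'
#' The full conditional given the per-cell utility means is
#' N((A + Q_p)^{-1} (A wbar_p + Q_p mu 1), (A + Q_p)^{-1}), sampled
#' exactly via a sparse Cholesky factorization. For the intrinsic CAR
#' model `mu` is 0 by construction.
#'
#' @param A Per-cell tree counts (diagonal of the data precision).
#' @param wbar_p Per-cell mean utilities for the taxon.
#' @param Qp Sparse per-taxon prior precision (already scaled).
#' @param mu Prior mean of the field (SPDE); default 0.
#' @return List with `draw`, `mean`, and `chol` (the factor of A + Q_p).
#' @export
gibbs_update_alpha <- function(A, wbar_p, Qp, mu = 0) {
  V <- Matrix::forceSymmetric(Qp + Matrix::Diagonal(x = A), "U")
  chV <- chol_pd(as(V, "CsparseMatrix"))
  b <- A * wbar_p +
    if (mu != 0) mu * as.numeric(Qp %*% rep(1, length(A))) else 0
  marg <- list(ch = chV$ch, b = b)
  mean <- as.numeric(Matrix::solve(marg$ch, marg$b, system = "A"))
  list(draw = draw_alpha_from(marg), mean = mean, chol = marg$ch)
}

# Log Metropolis-Hastings ratio of the cross-level joint update, which
# equals the field-marginalized posterior ratio of the hyperparameter
# block given the utilities: marginal likelihood ratio x flat prior
# support x log-scale Jacobians (blocks random-walk on log sigma /
# log rho; mu on its natural scale).
crosslevel_log_ratio <- function(minfo, A, wbar_p, cur, prop,
                                 bounds = hyperprior_bounds()) {
  lp_prop <- hyperprior_logdensity(prop$sigma, prop$mu %||% 0, prop$rho %||% 1,
                                   kind = minfo$kind, bounds = bounds)
  if (!is.finite(lp_prop)) return(-Inf)
  jac <- function(s) {
    if (minfo$kind == "car") log(s$sigma) else log(s$sigma) + log(s$rho)
  }
  mg <- function(s) {
    taxon_marginal(minfo, A, wbar_p, taxon_precision(minfo, s$sigma, s$rho),
                   mu = s$mu %||% 0)$ll
  }
  (mg(prop) + jac(prop)) - (mg(cur) + jac(cur))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Model-structure bundle shared across the run: adjacency, the shared
# sparsity pattern with coefficient vectors for fast precision assembly,
# closed-form lattice adjacency eigenvalues (SPDE log-determinants), and
# a cache for the symbolic Cholesky analysis.
build_model_info <- function(grid, kind) {
  adj <- cardinal_adjacency(grid)
  m <- grid$m
  info <- list(kind = kind, adj = adj, m = m, grid = grid,
               cache = new.env(parent = emptyenv()))
  C <- as(Matrix::forceSymmetric(adj$C, "U"), "CsparseMatrix")
  if (kind == "car") {
    info$template <- build_car_precision(adj)
    # pattern includes the full diagonal so per-cell counts always land
    pat <- as(Matrix::forceSymmetric(
      Matrix::drop0(info$template$Q) + Matrix::Diagonal(m), "U"),
      "CsparseMatrix")
    info$pat <- pat
    info$xQ <- align_pattern(pat, info$template$Q)
  } else {
    C2 <- Matrix::forceSymmetric(C %*% C, "U")
    pat <- as(Matrix::forceSymmetric(
      Matrix::Diagonal(m) + C + C2, "U"), "CsparseMatrix")
    info$pat <- pat
    info$xI <- align_pattern(pat, Matrix::Diagonal(m))
    info$xC <- align_pattern(pat, C)
    info$xC2 <- align_pattern(pat, C2)
    info$deg <- adj$degree
    info$rsC2 <- as.numeric(Matrix::rowSums(C2))
    cx <- 2 * cos(pi * seq_len(grid$nxb) / (grid$nxb + 1))
    cy <- 2 * cos(pi * seq_len(grid$nyb) / (grid$nyb + 1))
    info$lat_eigs <- as.numeric(outer(cx, cy, "+"))
  }
  colT <- rep.int(seq_len(m), diff(info$pat@p))
  info$diag_idx <- which(info$pat@i + 1L == colT)
  info
}

new_adapt <- function(kind, init_scale = 0.1) {
  if (kind == "car") {
    list(sigma = list(ls = log(init_scale), n = 0L, acc = 0))
  } else {
    list(mu = list(ls = log(init_scale), n = 0L, acc = 0),
         sigrho = list(ls = 0, n = 0L, acc = 0,
                       mean = c(0, 0), M2 = diag(init_scale^2, 2)))
  }
}

adapt_scalar <- function(ad, apr, target, adapting) {
  ad$n <- ad$n + 1L
  ad$acc <- ad$acc + apr
  if (adapting) ad$ls <- ad$ls + ad$n^-0.7 * (apr - target)
  ad
}

# Haario-style running covariance of the (log sigma, log rho) chain plus
# Robbins-Monro global scaling toward the 2-d target acceptance rate.
adapt_vector <- function(ad, x, apr, target, adapting) {
  ad$n <- ad$n + 1L
  ad$acc <- ad$acc + apr
  if (adapting) {
    ad$ls <- ad$ls + ad$n^-0.7 * (apr - target)
    d <- x - ad$mean
    ad$mean <- ad$mean + d / ad$n
    ad$M2 <- ad$M2 + (tcrossprod(d, x - ad$mean) - ad$M2) / ad$n
  }
  ad
}

prop_cov <- function(ad) {
  exp(2 * ad$ls) * (2.38^2 / 2) * (ad$M2 + diag(1e-8, 2))
}

# One taxon's full update: cross-level Metropolis block(s) on the
# hyperparameters (each block jointly refreshing the field on accept),
# followed by a Gibbs draw of the field at the current hyperparameters.
update_taxon <- function(p, A, wbar_p, hp, adapt_p, minfo, bounds, cfg,
                         adapting) {
  sigma <- hp$sigma; mu <- hp$mu; rho <- hp$rho
  Qpinfo <- taxon_precision(minfo, sigma, rho)
  marg <- taxon_marginal(minfo, A, wbar_p, Qpinfo, mu = mu)
  if (minfo$kind == "car") {
    ls_star <- log(sigma) + exp(adapt_p$sigma$ls) * rnorm(1)
    s_star <- exp(ls_star)
    apr <- 0
    if (s_star <= bounds$sigma_max) {
      marg_star <- taxon_marginal(minfo, A, wbar_p,
                                  taxon_precision(minfo, s_star), mu = 0)
      d <- (marg_star$ll + ls_star) - (marg$ll + log(sigma))
      apr <- exp(min(0, d))
      if (runif(1) < apr) {
        sigma <- s_star
        marg <- marg_star
      }
    }
    adapt_p$sigma <- adapt_scalar(adapt_p$sigma, apr, cfg$target_scalar,
                                  adapting)
  } else {
    for (block in cfg$spde_block_order) {
      if (block == "mu") {
        mu_star <- mu + exp(adapt_p$mu$ls) * rnorm(1)
        apr <- 0
        if (abs(mu_star) <= bounds$mu_bound) {
          # (A + Q_p) does not involve mu: reuse the current factor
          marg_star <- taxon_marginal(minfo, A, wbar_p, Qpinfo,
                                      mu = mu_star, Vch = marg)
          apr <- exp(min(0, marg_star$ll - marg$ll))
          if (runif(1) < apr) {
            mu <- mu_star
            marg <- marg_star
          }
        }
        adapt_p$mu <- adapt_scalar(adapt_p$mu, apr, cfg$target_scalar,
                                   adapting)
      } else {
        x <- c(log(sigma), log(rho))
        L <- chol(prop_cov(adapt_p$sigrho))
        x_star <- x + as.numeric(crossprod(L, rnorm(2)))
        s_star <- exp(x_star[1]); r_star <- exp(x_star[2])
        apr <- 0
        if (is.finite(hyperprior_logdensity(s_star, mu, r_star, "spde",
                                            bounds))) {
          Qpinfo_star <- taxon_precision(minfo, s_star, r_star)
          marg_star <- taxon_marginal(minfo, A, wbar_p, Qpinfo_star,
                                      mu = mu)
          d <- (marg_star$ll + sum(x_star)) - (marg$ll + sum(x))
          apr <- exp(min(0, d))
          if (runif(1) < apr) {
            sigma <- s_star; rho <- r_star
            Qpinfo <- Qpinfo_star
            marg <- marg_star
          }
        }
        adapt_p$sigrho <- adapt_vector(adapt_p$sigrho,
                                       c(log(sigma), log(rho)),
                                       apr, cfg$target_vector, adapting)
      }
    }
  }
  list(alpha = draw_alpha_from(marg),
       hp = list(sigma = sigma, mu = mu, rho = rho),
       adapt = adapt_p)
}

# Unnormalized log posterior weights for one township tree block: for each
# candidate cell, log psi plus the log likelihood of that tree's utilities
# under the cell's field values (constant-in-cell terms dropped).
membership_logweights <- function(W, cells, psi, alpha) {
  asup <- alpha[cells, , drop = FALSE]
  sweep(W %*% t(asup), 2, 0.5 * rowSums(asup^2) - log(psi), "-")
}

#' Gibbs update of township tree memberships
#'
#' Draws, for each tree of one township, the grid cell it belongs to from
#' the discrete distribution with mass proportional to the areal-overlap
#' prior weight times the normal likelihood of the tree's current latent
#' utilities under each candidate cell's field values. Sampling uses the
#' Gumbel-max trick in log space, so weights never underflow and draws
#' never leave the township's support.
#'
#' @param W Utility matrix for the township's trees (n_t x P).
#' @param cells Candidate cell indices (the township's support).
#' @param psi Overlap weights for `cells` (positive, summing to 1).
#' @param alpha Field matrix (cells x taxa, full lattice).
#' @return Integer vector of sampled cell indices, one per tree.
#' @export
gibbs_update_membership <- function(W, cells, psi, alpha) {
  if (length(cells) == 1L) return(rep(cells, nrow(W)))
  lw <- membership_logweights(W, cells, psi, alpha)
  g <- -log(-log(matrix(runif(length(lw)), nrow(lw))))
  cells[max.col(lw + g, ties.method = "first")]
}

#' MCMC configuration
#'
#' @param n_iter Total iterations.
#' @param n_burn Burn-in iterations to discard (adaptation also stops
#'   here); must be less than `n_iter`.
#' @param n_keep Number of retained field draws, evenly spaced over the
#'   post-burn-in iterations (default 250).
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param n_mc Monte Carlo sample count used later when integrating
#'   composition proportions (default 10000).
#' @param target_scalar,target_vector Adaptive Metropolis target
#'   acceptance rates for scalar and two-dimensional blocks.
#' @param spde_block_order Order of the SPDE hyperparameter blocks.
#' @param init_scale Initial random-walk proposal scale.
#' @param progress_every Log progress and acceptance rates every so many
#'   iterations (0 = silent).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 2000, n_burn = 500,
                        n_keep = min(250, n_iter - n_burn), seed = 1,
                        n_mc = 10000, target_scalar = 0.44,
                        target_vector = 0.23,
                        spde_block_order = c("mu", "sigrho"),
                        init_scale = 0.1, progress_every = 0) {
  if (n_burn >= n_iter) stop("'n_burn' must be less than 'n_iter'")
  if (n_keep > n_iter - n_burn) {
    stop("'n_keep' cannot exceed the number of post-burn-in iterations")
  }
  if (n_keep < 1) stop("'n_keep' must be at least 1")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep), seed = as.integer(seed),
                 n_mc = as.integer(n_mc), target_scalar = target_scalar,
                 target_vector = target_vector,
                 spde_block_order = spde_block_order,
                 init_scale = init_scale,
                 progress_every = as.integer(progress_every)),
            class = "mcmc_config")
}

# Expand a cells-x-taxa (or townships-x-taxa) count matrix into one row
# per tree.
expand_trees <- function(counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  list(loc = rep(idx[, 1], counts[idx]), taxon = rep(idx[, 2], counts[idx]))
}

#' Fit the spatial multinomial probit composition model by MCMC
#'
#' Runs the latent-variable sampler: a Gibbs sweep over per-tree latent
#' utilities, a Gibbs sweep over township tree memberships (change of
#' support), then per taxon the cross-level Metropolis update(s) of the
#' hyperparameters jointly with the field, and a Gibbs draw of the field.
#'
#' @param gridded Integer matrix of per-cell counts (m x P over the full
#'   buffered lattice; use [core_counts_matrix()] to place a core-grid
#'   table) or NULL.
#' @param township Integer matrix of per-township counts (T x P, rows in
#'   the order of `overlap$townships`) or NULL.
#' @param overlap A `township_overlap`; required with township data.
#' @param grid A `grid_spec`.
#' @param model `"car"` or `"spde"`.
#' @param config An `mcmc_config`.
#' @param bounds A `hyperprior_bounds`.
#' @param min_count Taxa with fewer total trees than this are dropped
#'   with a warning (default 1, i.e. drop empty taxa only).
#' @return A `comp_fit` object: `alpha` (K x m x P array of retained
#'   field draws), `hyper` (full traces of sigma, and mu/rho for SPDE),
#'   `kept` (retained iteration numbers), `accept` (mean acceptance rate
#'   per taxon and block), plus the taxa, grid, model, config and bounds.
#' @export
run_sampler <- function(gridded = NULL, township = NULL, overlap = NULL,
                        grid, model = c("car", "spde"),
                        config = mcmc_config(),
                        bounds = hyperprior_bounds(), min_count = 1) {
  model <- match.arg(model)
  if (is.null(gridded) && is.null(township)) {
    stop("at least one of 'gridded' or 'township' data is required")
  }
  if (!is.null(township) && is.null(overlap)) {
    stop("township data requires an overlap table")
  }
  taxa <- colnames(gridded) %||% colnames(township) %||%
    paste0("taxon", seq_len(ncol(gridded %||% township)))
  if (!is.null(gridded) && !is.null(township) &&
      !identical(ncol(gridded), ncol(township))) {
    stop("gridded and township tables must share the same taxa")
  }
  if (!is.null(gridded) && nrow(gridded) != grid$m) {
    stop("'gridded' must have one row per buffered-lattice cell")
  }

  totals <- (if (is.null(gridded)) 0 else colSums(gridded)) +
    (if (is.null(township)) 0 else colSums(township))
  drop <- totals < min_count
  if (any(drop)) {
    warning("dropping taxa with fewer than ", min_count, " trees: ",
            paste(taxa[drop], collapse = ", "))
    gridded <- gridded[, !drop, drop = FALSE]
    township <- township[, !drop, drop = FALSE]
  }
  dropped <- taxa[drop]
  taxa <- taxa[!drop]
  P <- length(taxa)
  if (P < 2) stop("fewer than 2 taxa with data; nothing to model")

  set.seed(config$seed)
  m <- grid$m
  minfo <- build_model_info(grid, model)

  # trees: gridded trees have fixed cells; township trees carry a
  # township id and a latent cell membership
  gtr <- if (!is.null(gridded) && sum(gridded) > 0) expand_trees(gridded)
  ttr <- if (!is.null(township) && sum(township) > 0) expand_trees(township)
  n_grid <- length(gtr$loc %||% integer(0))
  n_town <- length(ttr$loc %||% integer(0))
  n <- n_grid + n_town
  if (n == 0L) stop("no trees in the data")
  tree_taxon <- c(gtr$taxon %||% integer(0), ttr$taxon %||% integer(0))

  # township support lookup, and tree row indices per township
  if (n_town > 0) {
    tab <- overlap$table
    tid <- match(tab$township_id, overlap$townships)
    supp <- split(seq_len(nrow(tab)), tid)
    town_rows <- split(n_grid + seq_len(n_town), ttr$loc)
    town_keys <- names(town_rows)
    init_c <- vapply(ttr$loc, function(t) {
      s <- supp[[as.character(t)]]
      if (is.null(s)) stop("township ", t, " has no overlap entry")
      tab$cell[s[sample.int(length(s), 1L, prob = tab$psi[s])]]
    }, integer(1))
  }
  tree_cell <- c(gtr$loc %||% integer(0),
                 if (n_town > 0) init_c else integer(0))

  # neutral overdispersed start: fields at 0, sigma = rho = 1, mu = 0;
  # utilities from the field prior predictive, rank-adjusted so the
  # observed taxon is the strict maximum
  alpha <- matrix(0, m, P)
  hp <- lapply(seq_len(P), function(p) list(sigma = 1, mu = 0, rho = 1))
  W <- matrix(rnorm(n * P), n, P)
  obs <- cbind(seq_len(n), tree_taxon)
  Wobs <- W[obs]
  W[obs] <- -Inf
  other_max <- do.call(pmax, as.data.frame(W))
  W[obs] <- ifelse(Wobs > other_max, Wobs, other_max + abs(rnorm(n)))

  adapt <- lapply(seq_len(P), function(p) new_adapt(model, config$init_scale))
  kept <- unique(round(seq(config$n_burn + 1, config$n_iter,
                           length.out = config$n_keep)))
  K <- length(kept)
  alpha_keep <- array(NA_real_, c(K, m, P),
                      dimnames = list(NULL, NULL, taxa))
  sig_tr <- matrix(NA_real_, config$n_iter, P, dimnames = list(NULL, taxa))
  mu_tr <- if (model == "spde") sig_tr else NULL
  rho_tr <- if (model == "spde") sig_tr else NULL

  k_out <- 0L
  for (it in seq_len(config$n_iter)) {
    adapting <- it <= config$n_burn
    W <- cpp_update_W(W, tree_cell, tree_taxon, alpha)
    if (n_town > 0) {
      for (ti in seq_along(town_rows)) {
        s <- supp[[town_keys[ti]]]
        rows <- town_rows[[ti]]
        tree_cell[rows] <- gibbs_update_membership(
          W[rows, , drop = FALSE], tab$cell[s], tab$psi[s], alpha)
      }
    }
    ss <- compute_suff_stats(W, tree_cell, m)
    for (p in seq_len(P)) {
      up <- update_taxon(p, ss$A, ss$wbar[, p], hp[[p]], adapt[[p]],
                         minfo, bounds, config, adapting)
      alpha[, p] <- up$alpha
      hp[[p]] <- up$hp
      adapt[[p]] <- up$adapt
    }
    sig_tr[it, ] <- vapply(hp, `[[`, 0, "sigma")
    if (model == "spde") {
      mu_tr[it, ] <- vapply(hp, `[[`, 0, "mu")
      rho_tr[it, ] <- vapply(hp, `[[`, 0, "rho")
    }
    if (k_out < K && it == kept[k_out + 1L]) {
      k_out <- k_out + 1L
      alpha_keep[k_out, , ] <- alpha
    }
    if (config$progress_every > 0 && it %% config$progress_every == 0) {
      acc <- vapply(adapt, function(a) a[[length(a)]]$acc / a[[length(a)]]$n, 0)
      message(sprintf("iter %d/%d; mean block acceptance %.2f",
                      it, config$n_iter, mean(acc)))
    }
  }

  accept <- lapply(adapt, function(a) {
    vapply(a, function(b) b$acc / max(1L, b$n), 0)
  })
  names(accept) <- taxa
  structure(list(alpha = alpha_keep, kept = kept,
                 hyper = list(sigma = sig_tr, mu = mu_tr, rho = rho_tr),
                 accept = accept, taxa = taxa, dropped_taxa = dropped,
                 model = model, grid = grid, config = config,
                 bounds = bounds),
            class = "comp_fit")
}

#' @export
print.comp_fit <- function(x, ...) {
  cat(sprintf(
    "comp_fit: %s model, %d taxa, %d cells, %d retained draws (of %d iter)\n",
    x$model, length(x$taxa), x$grid$m, length(x$kept), x$config$n_iter))
  if (length(x$dropped_taxa)) {
    cat("dropped taxa:", paste(x$dropped_taxa, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Place a core-grid count table onto the buffered lattice
#'
#' @param grid A `grid_spec`.
#' @param cell_x,cell_y Core coordinates (1..nx, 1..ny) per row of `counts`.
#' @param counts Count matrix with one row per (cell_x, cell_y) pair.
#' @return An m x P integer matrix over the buffered lattice, zero
#'   elsewhere (buffer cells carry no observations).
#' @export
core_counts_matrix <- function(grid, cell_x, cell_y, counts) {
  counts <- as.matrix(counts)
  out <- matrix(0L, grid$m, ncol(counts), dimnames = list(NULL, colnames(counts)))
  out[core_index(grid, cell_x, cell_y), ] <- as.integer(counts)
  out
}
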