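#' Define a synthetic-data scenario
#'
#' A scenario fixes everything needed to generate a dataset with the
#' statistical structure the model assumes: smooth latent fields per
#' taxon, multinomial counts with on the order of a hundred trees per
#' cell, optional sparse coverage, and optional areal (township)
#' aggregation. All randomness derives from `seed`.
#'
#' @param nx,ny Core grid dimensions.
#' @param buffer_width Buffer cells per side.
#' @param P Number of taxa.
#' @param kind Field prior: `"spde"` or `"car"`.
#' @param sigma,mu,rho True hyperparameters (scalars, or length-P
#'   vectors). `mu` and `rho` apply to the SPDE kind only.
#' @param trees_mean Mean of the per-cell tree-count distribution,
#'   Poisson truncated at zero; default 124, the typical survey density.
#' @param missing_fraction Fraction of core cells masked as unobserved.
#' @param block_dims Township tiling block size `c(bx, by)` in cells.
#' @param jitter Whether township block boundaries are randomly jittered
#'   to make units irregular.
#' @param theta_n_mc Monte Carlo trees per cell used to evaluate the true
#'   composition for P > 2 (P = 2 uses the closed form).
#' @param seed Master seed.
#' @return A `scenario` list.
#' @export
scenario <- function(nx = 25, ny = 25, buffer_width = 6, P = 3,
                     kind = c("spde", "car"), sigma = 1, mu = 0, rho = 3,
                     trees_mean = 124, missing_fraction = 0,
                     block_dims = c(4, 4), jitter = TRUE,
                     theta_n_mc = 10000, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(P >= 2, trees_mean > 0, missing_fraction >= 0,
            missing_fraction < 1, all(block_dims >= 1))
  if (kind == "spde" && any(rho <= 0)) stop("'rho' must be positive")
  if (any(sigma <= 0)) stop("'sigma' must be positive")
  structure(list(nx = nx, ny = ny, buffer_width = buffer_width, P = P,
                 kind = kind, sigma = rep_len(sigma, P),
                 mu = rep_len(mu, P), rho = rep_len(rho, P),
                 trees_mean = trees_mean,
                 missing_fraction = missing_fraction,
                 block_dims = block_dims, jitter = jitter,
                 theta_n_mc = theta_n_mc, seed = seed),
            class = "scenario")
}

#' Draw the true latent fields of a scenario
#'
#' Exact Gaussian draws with the scenario's precision via sparse
#' Cholesky factorization. For the CAR kind the draw is from the proper
#' part of the intrinsic prior with the (improper) overall level pinned
#' at zero, via eigendecomposition of the unscaled precision.
#'
#' @param sc A `scenario`.
#' @return List with `grid`, `alpha` (m x P matrix) and the true
#'   hyperparameters.
#' @export
draw_alpha_fields <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  grid <- build_grid(sc$nx, sc$ny, sc$buffer_width)
  adj <- cardinal_adjacency(grid)
  m <- grid$m
  alpha <- matrix(NA_real_, m, sc$P)
  if (sc$kind == "spde") {
    for (p in seq_len(sc$P)) {
      Qp <- scale_precision(build_spde_precision(adj, sc$rho[p]), sc$sigma[p])
      ch <- chol_pd(Qp)$ch
      z <- rnorm(m)
      alpha[, p] <- sc$mu[p] +
        as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                                 system = "Pt"))
    }
  } else {
    Q <- as.matrix(build_car_precision(adj)$Q)
    eg <- eigen(Q, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-9
    U <- eg$vectors[, pos, drop = FALSE]
    lam <- eg$values[pos]
    for (p in seq_len(sc$P)) {
      z <- rnorm(sum(pos))
      alpha[, p] <- sc$sigma[p] * as.numeric(U %*% (z / sqrt(lam)))
    }
  }
  list(grid = grid, alpha = alpha, sigma = sc$sigma, mu = sc$mu,
       rho = if (sc$kind == "spde") sc$rho else NULL)
}

#' Draw multinomial counts given latent fields
#'
#' Computes the true composition per cell (closed form for P = 2, Monte
#' Carlo integration otherwise), draws zero-truncated Poisson tree counts
#' for core cells, multinomial taxon counts, and applies the
#' missing-cell mask. Buffer cells never carry observations.
#'
#' @param fields Output of [draw_alpha_fields()].
#' @param sc The same `scenario`.
#' @return List with `counts` (m x P), `n` (per-cell totals),
#'   `theta_true` (m x P), `missing_mask` (logical; masked core cells),
#'   and `grid`.
#' @export
draw_counts <- function(fields, sc) {
  grid <- fields$grid
  m <- grid$m
  set.seed(sc$seed + 1L)
  if (sc$P == 2) {
    t1 <- probit_two_taxon_oracle(fields$alpha[, 1], fields$alpha[, 2])
    theta <- cbind(t1, 1 - t1)
  } else {
    theta <- mc_theta(fields$alpha, sc$theta_n_mc)
  }
  n <- integer(m)
  core <- which(grid$core_mask)
  n[core] <- rpois(length(core), sc$trees_mean)
  while (any(z <- n[core] == 0)) {           # zero-truncated Poisson
    n[core][z] <- rpois(sum(z), sc$trees_mean)
  }
  missing_mask <- rep(FALSE, m)
  if (sc$missing_fraction > 0) {
    drop <- sample(core, round(sc$missing_fraction * length(core)))
    missing_mask[drop] <- TRUE
    n[drop] <- 0L
  }
  counts <- matrix(0L, m, sc$P,
                   dimnames = list(NULL, paste0("taxon", seq_len(sc$P))))
  pos <- which(n > 0)
  for (i in pos) counts[i, ] <- rmultinom(1, n[i], theta[i, ])
  list(counts = counts, n = n, theta_true = theta,
       missing_mask = missing_mask, grid = grid)
}

#' Aggregate gridded counts into townships
#'
#' Tiles the core grid into rectangular blocks (with optional random
#' boundary jitter so units are irregular), sums counts within blocks,
#' and emits uniform-by-area overlap weights (cells have equal area, so
#' psi is uniform over a township's member cells). Cell identities of
#' individual trees are discarded -- only township totals survive -- but
#' the original per-cell table is returned as hidden truth.
#'
#' @param counts m x P count matrix on the buffered lattice.
#' @param grid The `grid_spec`.
#' @param block_dims Block size `c(bx, by)` in cells.
#' @param seed RNG seed for the boundary jitter.
#' @param jitter Jitter interior block boundaries by -1/0/+1 cells.
#' @return List with `township` (T x P counts), `overlap`
#'   (`township_overlap`), and `cell_truth` (the input per-cell counts).
#' @export
make_townships <- function(counts, grid, block_dims = c(4, 4), seed = 1,
                           jitter = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == grid$m, all(block_dims >= 1))
  set.seed(seed)
  cuts <- function(nn, bb) {
    br <- seq(0L, nn, by = bb)
    if (br[length(br)] < nn) br <- c(br, nn)
    if (jitter && length(br) > 2) {
      interior <- 2:(length(br) - 1)
      br[interior] <- br[interior] + sample(-1:1, length(interior),
                                            replace = TRUE)
      br <- sort(unique(pmin(pmax(br, 0L), nn)))
    }
    br
  }
  bx <- cuts(grid$nx, block_dims[1])
  by <- cuts(grid$ny, block_dims[2])
  blk_x <- findInterval(seq_len(grid$nx), bx, left.open = TRUE)
  blk_y <- findInterval(seq_len(grid$ny), by, left.open = TRUE)
  cx <- rep(seq_len(grid$nx), times = grid$ny)
  cy <- rep(seq_len(grid$ny), each = grid$nx)
  town <- paste0("t", blk_x[cx], "_", blk_y[cy])
  cell <- core_index(grid, cx, cy)
  ids <- unique(town)
  tidx <- match(town, ids)
  township <- rowsum(counts[cell, , drop = FALSE], tidx)
  rownames(township) <- ids[as.integer(rownames(township))]
  township <- township[ids, , drop = FALSE]
  raw <- data.frame(township_id = town, cell = cell, area = 1)
  overlap <- normalize_overlap(raw, grid)
  list(township = township, overlap = overlap, cell_truth = counts)
}

#' Generate a full synthetic dataset from a named preset
#'
#' Presets mirror the data regimes the model targets:
#' \describe{
#'   \item{dense_grid}{every core cell observed (gridded data only).}
#'   \item{sparse_95}{95\% of core cells masked (no data), emulating a
#'     sparsely digitized region.}
#'   \item{sparse_80}{80\% of core cells masked.}
#'   \item{township_east}{counts aggregated into irregular townships
#'     with no gridded observations.}
#'   \item{mixed_domain}{the western half of the core grid observed per
#'     cell, the eastern half aggregated into townships.}
#' }
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param ... Overrides passed to [scenario()].
#' @return List with `grid`, `gridded` (m x P counts or NULL),
#'   `township` / `overlap` (or NULL), and `truth` (fields, true theta,
#'   per-cell counts, hyperparameters, missing mask).
#' @export
make_scenario <- function(name = c("dense_grid", "sparse_95", "sparse_80",
                                   "township_east", "mixed_domain"),
                          seed = 1, ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    dense_grid = list(),
    sparse_95 = list(missing_fraction = 0.95),
    sparse_80 = list(missing_fraction = 0.80),
    township_east = list(nx = 20, ny = 20),
    mixed_domain = list())
  sc <- do.call(scenario, c(base, over, list(seed = seed)))
  fields <- draw_alpha_fields(sc)
  dat <- draw_counts(fields, sc)
  grid <- dat$grid
  truth <- list(alpha = fields$alpha, theta = dat$theta_true,
                cell_counts = dat$counts, n = dat$n,
                sigma = sc$sigma, mu = sc$mu,
                rho = if (sc$kind == "spde") sc$rho else NULL,
                missing_mask = dat$missing_mask)
  out <- list(grid = grid, gridded = dat$counts, township = NULL,
              overlap = NULL, truth = truth, scenario = sc, name = name)
  if (name == "township_east") {
    tw <- make_townships(dat$counts, grid, sc$block_dims, seed = seed + 2L,
                         jitter = sc$jitter)
    out$gridded <- NULL
    out$township <- tw$township
    out$overlap <- tw$overlap
  } else if (name == "mixed_domain") {
    co <- cell_coords(grid, seq_len(grid$m))
    west <- co[, "ix"] - grid$buffer <= grid$nx / 2
    east_counts <- dat$counts
    east_counts[west | !grid$core_mask, ] <- 0L
    west_counts <- dat$counts
    west_counts[!west | !grid$core_mask, ] <- 0L
    tw <- make_townships(east_counts, grid, sc$block_dims, seed = seed + 2L,
                         jitter = sc$jitter)
    keep <- rowSums(tw$township) > 0
    out$gridded <- west_counts
    out$township <- tw$township[keep, , drop = FALSE]
    ok <- tw$overlap$table$township_id %in% rownames(out$township)
    out$overlap <- structure(
      list(table = tw$overlap$table[ok, ],
           townships = tw$overlap$townships[tw$overlap$townships %in%
                                              rownames(out$township)]),
      class = "township_overlap")
    out$township <- out$township[out$overlap$townships, , drop = FALSE]
  }
  out
}
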