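test_that("rtnorm inverse-CDF map is exact and tail-stable", {
  # median of N(0,1) truncated below at 0.3, via the closed-form map
  med <- rtnorm(1, lower = 0.3, u = 0.5)
  expect_equal(med, qnorm((pnorm(0.3) + 1) / 2), tolerance = 1e-10)
  expect_equal(med, 0.8740545, tolerance = 1e-6)
  # far-tail truncations stay finite and respect the bounds
  x <- rtnorm(100, lower = 10)
  expect_true(all(is.finite(x)) && all(x > 10))
  x <- rtnorm(100, upper = -12)
  expect_true(all(is.finite(x)) && all(x < -12))
  x <- rtnorm(100, mean = 2, sd = 3, lower = -1, upper = 4)
  expect_true(all(x > -1 & x < 4))
  expect_error(rtnorm(1, lower = 2, upper = 1), "strictly below")
})

test_that("W update enforces the argmax invariant and correct truncation", {
  set.seed(4)
  n <- 20000
  # all trees observed as taxon 1, alpha = 0, initial losing utility 0.3
  W <- cbind(rep(0.4, n), rep(0.3, n))
  alpha <- matrix(0, 1, 2)
  Wn <- gibbs_update_W(W, rep(1L, n), rep(1L, n), alpha)
  expect_true(all(max.col(Wn) == 1))
  # W1 | W2 = 0.3 ~ TN(0.3, Inf, 0, 1): check the median against the
  # inverse-CDF value (Monte Carlo tolerance)
  expect_equal(median(Wn[, 1]), qnorm((pnorm(0.3) + 1) / 2),
               tolerance = 0.02)
  expect_true(all(Wn[, 2] < Wn[, 1]))

  # random multi-taxon case keeps the invariant
  set.seed(5)
  m <- 12; P <- 4; n <- 500
  cell <- sample.int(m, n, replace = TRUE)
  tax <- sample.int(P, n, replace = TRUE)
  alpha <- matrix(rnorm(m * P), m, P)
  W <- matrix(rnorm(n * P), n, P)
  W[cbind(seq_len(n), tax)] <- apply(W, 1, max) + 1
  for (rep in 1:3) {
    W <- gibbs_update_W(W, cell, tax, alpha)
    expect_equal(max.col(W, ties.method = "first"), tax)
  }
  expect_error(gibbs_update_W(W, cell, tax, alpha * NA), "non-finite")
})

test_that("sufficient statistics count and average per cell", {
  m <- 5
  ss <- compute_suff_stats(matrix(numeric(0), 0, 2), integer(0), m)
  expect_equal(ss$A, rep(0, m))
  expect_equal(ss$wbar, matrix(0, m, 2))

  W <- matrix(c(1, 3, -1, 2), 2, 2)
  ss <- compute_suff_stats(W, c(2L, 2L), m)
  expect_equal(ss$A, c(0, 2, 0, 0, 0))
  expect_equal(ss$wbar[2, ], c(2, 0.5))
  expect_equal(ss$wbar[1, ], c(0, 0))

  # conservation under reassignment of a tree
  cells <- c(1L, 1L)
  ss1 <- compute_suff_stats(W, cells, m)
  cells2 <- c(1L, 4L)
  ss2 <- compute_suff_stats(W, cells2, m)
  expect_equal(sum(ss1$A), sum(ss2$A))
  expect_equal(ss2$A[1], ss1$A[1] - 1)
  expect_equal(ss2$A[4], 1)
})

test_that("alpha full conditional matches the dense-matrix oracle", {
  # 1x1 grid, CAR: Q = 0, conditional is N(wbar, 1/n)
  up <- gibbs_update_alpha(A = 5, wbar_p = 1.2,
                           Qp = Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                     symmetric = TRUE))
  expect_equal(up$mean, 1.2, tolerance = 1e-12)

  # no data, SPDE: conditional is the prior N(mu 1, Qp^-1)
  adj <- cardinal_adjacency(build_grid(3, 3, 0))
  Qp <- scale_precision(build_spde_precision(adj, 1.5), 0.8)
  up <- gibbs_update_alpha(A = rep(0, 9), wbar_p = rep(0, 9), Qp, mu = 0.7)
  expect_equal(up$mean, rep(0.7, 9), tolerance = 1e-10)

  # 3x3 and 4x4 grids with arbitrary data: mean and covariance vs dense
  set.seed(11)
  for (dims in list(c(3, 3), c(4, 4))) {
    adj <- cardinal_adjacency(build_grid(dims[1], dims[2], 0))
    m <- prod(dims)
    A <- rpois(m, 3)
    wbar <- rnorm(m) * (A > 0)
    for (mod in c("car", "spde")) {
      Qp <- if (mod == "car") {
        scale_precision(build_car_precision(adj), 1.3)
      } else {
        scale_precision(build_spde_precision(adj, 2), 1.3)
      }
      mu <- if (mod == "spde") 0.4 else 0
      up <- gibbs_update_alpha(A, wbar, Qp, mu = mu)
      Vd <- as.matrix(Qp) + diag(A)
      md <- solve(Vd, A * wbar + mu * as.numeric(as.matrix(Qp) %*% rep(1, m)))
      expect_equal(up$mean, md, tolerance = 1e-8)
      # covariance implied by the factor equals the dense inverse
      I_m <- diag(m)
      Sig <- as.matrix(Matrix::solve(up$chol, I_m, system = "A"))
      expect_equal(Sig, solve(Vd), tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("cross-level acceptance ratio matches 2-D quadrature oracle", {
  g <- build_grid(2, 1, 0)
  minfo <- spcomp:::build_model_info(g, "car")
  A <- c(3, 2); wbar <- c(0.5, -0.2)
  cur <- list(sigma = 0.8, mu = 0, rho = 1)
  prop <- list(sigma = 1.3, mu = 0, rho = 1)
  lr <- spcomp:::crosslevel_log_ratio(minfo, A, wbar, cur, prop)

  # brute force: I(sigma) = sigma^(-1) * integral of
  #   exp(-0.5 sum A_i (wbar_i - a_i)^2) exp(-0.5 (a1 - a2)^2 / sigma^2)
  # over R^2 (Simpson product rule); MH ratio adds the log-scale Jacobian
  quad <- function(sigma, h = 0.01, lim = 8) {
    a <- seq(-lim, lim, by = h)
    n <- length(a)
    w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1) * h / 3
    f1 <- exp(-0.5 * A[1] * (wbar[1] - a)^2)
    f2 <- exp(-0.5 * A[2] * (wbar[2] - a)^2)
    G <- exp(-0.5 * outer(a, a, "-")^2 / sigma^2)
    as.numeric((w * f1) %*% G %*% (w * f2)) / sigma
  }
  oracle <- log(quad(prop$sigma) / quad(cur$sigma)) +
    log(prop$sigma) - log(cur$sigma)
  expect_equal(lr, oracle, tolerance = 1e-8)

  # identical proposal: ratio exactly 0; out-of-support: -Inf
  expect_equal(spcomp:::crosslevel_log_ratio(minfo, A, wbar, cur, cur), 0)
  expect_equal(spcomp:::crosslevel_log_ratio(minfo, A, wbar, cur,
                                             list(sigma = 1001)), -Inf)
})

test_that("SPDE closed-form log-determinant matches dense computation", {
  g <- build_grid(4, 3, 1)
  minfo <- spcomp:::build_model_info(g, "spde")
  for (par in list(c(0.7, 1.4), c(1.2, 3))) {
    Qp <- spcomp:::taxon_precision(minfo, par[1], par[2])
    Qm <- spcomp:::make_dsC(minfo$pat, Qp$Qx)
    expect_equal(Qp$logdet,
                 as.numeric(determinant(as.matrix(Qm))$modulus),
                 tolerance = 1e-9)
    expect_equal(as.numeric(Qm %*% rep(1, g$m)), Qp$Q1s, tolerance = 1e-10)
  }
})

test_that("membership weights and sampling follow psi times likelihood", {
  # single-cell township is deterministic
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(gibbs_update_membership(W, 4L, 1, matrix(0, 9, 2)),
               rep(4L, 3))

  # P = 1, W = 0, alpha = (0, 1): probabilities dnorm(0)/dnorm(1) ratio
  lw <- spcomp:::membership_logweights(matrix(0, 1, 1), c(1L, 2L),
                                       c(0.5, 0.5), matrix(c(0, 1), 2, 1))
  pr <- exp(lw[1, ]) / sum(exp(lw[1, ]))
  expect_equal(pr, c(0.6224593, 0.3775407), tolerance = 1e-6)

  # equal psi, identical alpha columns: empirical frequency near 1/2
  set.seed(8)
  alpha <- matrix(rnorm(4), 2, 2)
  alpha[2, ] <- alpha[1, ]
  draws <- replicate(4000, gibbs_update_membership(
    matrix(rnorm(2), 1, 2), c(1L, 2L), c(0.5, 0.5), alpha))
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.03)

  # frequencies match the exact weights for an asymmetric case
  alpha <- matrix(c(0, 1, 0.5, -0.5), 2, 2)
  W1 <- matrix(c(0.3, 0.2), 1, 2)
  lw <- spcomp:::membership_logweights(W1, c(1L, 2L), c(0.7, 0.3), alpha)
  pr <- exp(lw[1, ] - max(lw[1, ])); pr <- pr / sum(pr)
  draws <- replicate(4000, gibbs_update_membership(W1, c(1L, 2L),
                                                   c(0.7, 0.3), alpha))
  expect_equal(mean(draws == 1), pr[1], tolerance = 0.03)
})

test_that("sampler is reproducible, validates inputs, drops empty taxa", {
  g <- build_grid(3, 3, 0)
  set.seed(2)
  counts <- matrix(rpois(27, 5), 9, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  cfg <- mcmc_config(n_iter = 40, n_burn = 10, n_keep = 10, seed = 33)
  f1 <- run_sampler(gridded = counts, grid = g, model = "car", config = cfg)
  f2 <- run_sampler(gridded = counts, grid = g, model = "car", config = cfg)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$hyper$sigma, f2$hyper$sigma)
  expect_equal(dim(f1$alpha), c(10, 9, 3))

  counts0 <- counts; counts0[, 3] <- 0L
  expect_warning(f3 <- run_sampler(gridded = counts0, grid = g,
                                   model = "car", config = cfg), "dropping")
  expect_equal(f3$taxa, c("a", "b"))
  expect_equal(f3$dropped_taxa, "c")

  counts1 <- counts; counts1[, 2:3] <- 0L
  expect_error(suppressWarnings(
    run_sampler(gridded = counts1, grid = g, model = "car", config = cfg)),
    "fewer than 2")
  expect_error(run_sampler(grid = g, model = "car", config = cfg),
               "at least one")
  expect_error(mcmc_config(n_iter = 10, n_burn = 10), "less than")
})

test_that("posterior composition matches empirical proportions with rich data", {
  # single cell, P = 2, 700/300 split
  g <- build_grid(1, 1, 0)
  counts <- matrix(c(700L, 300L), 1, 2, dimnames = list(NULL, c("a", "b")))
  fit <- run_sampler(gridded = counts, grid = g, model = "car",
                     config = mcmc_config(n_iter = 800, n_burn = 200,
                                          n_keep = 150, seed = 12))
  th <- summarize_theta(posterior_theta(fit, n_mc = 4000, seed = 5))
  expect_equal(unname(th$mean[1, 1]), 0.7, tolerance = 0.03)

  # data-rich limit on a small grid: >= 500 trees per cell pins theta
  g <- build_grid(3, 3, 1)
  set.seed(21)
  core <- which(g$core_mask)
  counts <- matrix(0L, g$m, 3, dimnames = list(NULL, c("a", "b", "c")))
  thetas <- random_simplex(length(core), 3) * 0.8 + 0.2 / 3
  for (j in seq_along(core)) {
    counts[core[j], ] <- as.integer(rmultinom(1, 600, thetas[j, ]))
  }
  fit <- run_sampler(gridded = counts, grid = g, model = "car",
                     config = mcmc_config(n_iter = 1200, n_burn = 400,
                                          n_keep = 200, seed = 13))
  th <- summarize_theta(posterior_theta(fit, n_mc = 4000, seed = 5))
  emp <- counts[core, ] / rowSums(counts[core, ])
  expect_lt(max(abs(th$mean[core, ] - emp)), 0.02)
})

test_that("argmax invariant and tree-count conservation hold along a run", {
  set.seed(14)
  g <- build_grid(4, 4, 0)
  minfo <- spcomp:::build_model_info(g, "car")
  m <- g$m; P <- 3
  counts <- matrix(rpois(m * P, 4), m, P)
  tr <- spcomp:::expand_trees(counts)
  n <- length(tr$loc)
  # one township overlapping four cells, plus the gridded trees
  ov <- normalize_overlap(data.frame(township_id = "t1", cell = c(1, 2, 5, 6),
                                     area = c(1, 1, 1, 1)))
  town_tax <- sample.int(P, 30, replace = TRUE)
  cells <- c(tr$loc, sample(c(1L, 2L, 5L, 6L), 30, replace = TRUE))
  taxa <- c(tr$taxon, town_tax)
  ntot <- length(cells)
  alpha <- matrix(0, m, P)
  W <- matrix(rnorm(ntot * P), ntot, P)
  W[cbind(seq_len(ntot), taxa)] <- apply(W, 1, max) + 1
  for (it in 1:10) {
    W <- gibbs_update_W(W, cells, taxa, alpha)
    rows <- n + seq_len(30)
    cells[rows] <- gibbs_update_membership(W[rows, , drop = FALSE],
                                           ov$table$cell, ov$table$psi,
                                           alpha)
    ss <- compute_suff_stats(W, cells, m)
    expect_equal(sum(ss$A), ntot)
    expect_equal(max.col(W, ties.method = "first"), taxa)
    for (p in seq_len(P)) {
      Qp <- scale_precision(build_car_precision(cardinal_adjacency(g)), 1)
      alpha[, p] <- gibbs_update_alpha(ss$A, ss$wbar[, p], Qp)$draw
    }
    expect_true(all(cells[rows] %in% c(1L, 2L, 5L, 6L)))
  }
})

test_that("the transition kernel leaves the joint prior invariant", {
  # Geweke-style successive-conditional check on a 3x3 SPDE model with
  # narrowed (proper) hyperprior support: alternating data redraws with
  # sampler transitions must preserve the prior of (sigma, mu, rho, alpha)
  set.seed(99)
  g <- build_grid(3, 3, 0)
  m <- g$m; P <- 2
  minfo <- spcomp:::build_model_info(g, "spde")
  bounds <- hyperprior_bounds(sigma_max = 1.5, mu_bound = 1,
                              rho_min = 1, rho_max = 3)
  cfg <- mcmc_config(n_iter = 10, n_burn = 5, seed = 1)
  tree_cell <- rep(seq_len(m), each = 4)
  n <- length(tree_cell)
  draw_hp <- function() list(sigma = runif(1, 0, 1.5),
                             mu = runif(1, -1, 1), rho = runif(1, 1, 3))
  draw_field <- function(hp) {
    Qx <- spcomp:::taxon_precision(minfo, hp$sigma, hp$rho)$Qx
    ch <- Matrix::Cholesky(spcomp:::make_dsC(minfo$pat, Qx), LDL = FALSE,
                           perm = TRUE, super = FALSE)
    hp$mu + as.numeric(Matrix::solve(ch, Matrix::solve(ch, rnorm(m),
                                                       system = "Lt"),
                                     system = "Pt"))
  }
  warm <- 800; keep <- 3500
  rec <- matrix(NA_real_, keep, 4)
  hp <- list(draw_hp(), draw_hp())
  alpha <- cbind(draw_field(hp[[1]]), draw_field(hp[[2]]))
  adapt <- lapply(1:2, function(p) spcomp:::new_adapt("spde", 0.1))
  for (s in seq_len(warm + keep)) {
    W <- alpha[tree_cell, ] + matrix(rnorm(n * P), n, P)
    tree_taxon <- max.col(W, ties.method = "first")
    W <- gibbs_update_W(W, tree_cell, tree_taxon, alpha)
    ss <- compute_suff_stats(W, tree_cell, m)
    for (p in 1:2) {
      up <- spcomp:::update_taxon(p, ss$A, ss$wbar[, p], hp[[p]],
                                  adapt[[p]], minfo, bounds, cfg,
                                  adapting = s <= warm)
      alpha[, p] <- up$alpha; hp[[p]] <- up$hp; adapt[[p]] <- up$adapt
    }
    if (s > warm) {
      rec[s - warm, ] <- c(hp[[1]]$sigma, hp[[1]]$mu, hp[[1]]$rho,
                           alpha[5, 1])
    }
  }
  ref <- t(replicate(4000, {
    h <- draw_hp(); c(h$sigma, h$mu, h$rho, draw_field(h)[5])
  }))
  # batch-means standard error for the autocorrelated chain
  bm_se <- function(x, b = 70) {
    nb <- floor(length(x) / b)
    mb <- colMeans(matrix(x[seq_len(nb * b)], b))
    sd(mb) / sqrt(nb)
  }
  for (j in 1:4) {
    se <- sqrt(bm_se(rec[, j])^2 + var(ref[, j]) / nrow(ref))
    expect_lt(abs(mean(rec[, j]) - mean(ref[, j])), 5 * se)
    expect_lt(abs(sd(rec[, j]) / sd(ref[, j]) - 1), 0.25)
  }
})
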