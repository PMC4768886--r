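#' Construct a holdout partition of gridded count data
#'
#' Two designs: `"cells"` removes all trees from a random fraction of
#' cells (interpolation skill under sparse coverage); `"trees"` removes
#' individual trees uniformly at random (within-cell estimation skill).
#'
#' @param counts m x P count matrix on the buffered lattice.
#' @param kind `"cells"` or `"trees"`.
#' @param fraction Fraction held out, in `[0, 1)`.
#' @param region_mask Optional logical vector (length m). For `"cells"`,
#'   cells are sampled within the mask (default: all cells with data);
#'   for `"trees"`, only trees in masked-in cells are eligible (default:
#'   all).
#' @param seed RNG seed; partitions are exactly reproducible.
#' @return A `holdout` object: list with `train` and `test` count
#'   matrices (train + test = counts), `kind`, `fraction`, `held_cells`
#'   (cells-kind), `seed`.
#' @export
make_holdout <- function(counts, kind = c("cells", "trees"), fraction,
                         region_mask = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("'fraction' must be in [0, 1)")
  }
  counts <- as.matrix(counts)
  m <- nrow(counts)
  set.seed(seed)
  train <- counts
  test <- matrix(0L, m, ncol(counts), dimnames = dimnames(counts))
  held_cells <- integer(0)
  if (fraction > 0) {
    if (kind == "cells") {
      cand <- which(region_mask %||% (rowSums(counts) > 0))
      held_cells <- sort(sample(cand, round(fraction * length(cand))))
      test[held_cells, ] <- counts[held_cells, ]
      train[held_cells, ] <- 0L
    } else {
      elig <- region_mask %||% rep(TRUE, m)
      tr <- expand_trees(counts * elig)
      n_el <- length(tr$loc)
      pick <- sample.int(n_el, round(fraction * n_el))
      for (j in pick) {
        test[tr$loc[j], tr$taxon[j]] <- test[tr$loc[j], tr$taxon[j]] + 1L
        train[tr$loc[j], tr$taxon[j]] <- train[tr$loc[j], tr$taxon[j]] - 1L
      }
    }
  }
  structure(list(train = train, test = test, kind = kind,
                 fraction = fraction, held_cells = held_cells, seed = seed),
            class = "holdout")
}

#' Multi-category Brier score of held-out trees
#'
#' Mean over held-out trees of the squared distance between the one-hot
#' observed taxon vector and the predicted composition at the tree's
#' cell: (1/n) sum_i sum_j sum_p (y_ijp - theta_p(s_i))^2.
#'
#' @param test_counts Held-out count matrix (cells x taxa).
#' @param theta_hat Predicted composition (cells x taxa), aligned to
#'   the same rows.
#' @return Nonnegative scalar.
#' @export
brier <- function(test_counts, theta_hat) {
  test_counts <- as.matrix(test_counts); theta_hat <- as.matrix(theta_hat)
  stopifnot(identical(dim(test_counts), dim(theta_hat)))
  ni <- rowSums(test_counts)
  used <- ni > 0
  if (any(used & !is.finite(rowSums(theta_hat)))) {
    stop("held-out trees in cells without predictions")
  }
  n <- sum(ni)
  if (n == 0) return(0)
  s2 <- rowSums(theta_hat^2)
  # a tree of taxon p contributes (1 - theta_p)^2 + sum_{q != p} theta_q^2
  #   = s2 + 1 - 2 theta_p
  sum(test_counts * (s2 + 1 - 2 * theta_hat)) / n
}

#' Log predictive density of held-out counts
#'
#' Sum over held-out cells of the log multinomial mass of the held-out
#' count vector under the predicted composition. Predicted proportions
#' that are exactly 0 where the count is positive (an artifact of
#' finite Monte Carlo integration) are replaced by `floor` before
#' evaluating, without renormalization.
#'
#' @param test_counts Held-out count matrix (cells x taxa).
#' @param theta_hat Predicted composition (cells x taxa).
#' @param floor Replacement for zero predicted proportions with positive
#'   counts (default 1/100000).
#' @return Scalar log predictive density (<= 0).
#' @export
log_pred_density <- function(test_counts, theta_hat, floor = 1e-5) {
  test_counts <- as.matrix(test_counts); theta_hat <- as.matrix(theta_hat)
  stopifnot(identical(dim(test_counts), dim(theta_hat)))
  th <- ifelse(theta_hat == 0 & test_counts > 0, floor, theta_hat)
  ni <- rowSums(test_counts)
  used <- which(ni > 0)
  tot <- 0
  for (i in used) {
    y <- test_counts[i, ]
    pos <- y > 0
    tot <- tot + lgamma(ni[i] + 1) - sum(lgamma(y[pos] + 1)) +
      sum(y[pos] * log(th[i, pos]))
  }
  tot
}

#' Weighted RMSPE and MAE of predicted proportions
#'
#' Compares predicted composition to the empirical proportions of the
#' held-out trees, weighting each cell by its held-out tree count:
#' RMSPE = sqrt((1/(P n)) sum_i sum_p n_i (thetahat_ip - theta_p(s_i))^2)
#' and MAE = (1/(P n)) sum_i sum_p n_i |thetahat_ip - theta_p(s_i)|,
#' where thetahat_ip are held-out empirical proportions. Cells with no
#' held-out trees contribute nothing.
#'
#' @param test_counts Held-out count matrix (cells x taxa).
#' @param theta_hat Predicted composition (cells x taxa).
#' @return Named numeric vector `c(rmspe, mae)`.
#' @export
rmspe_mae <- function(test_counts, theta_hat) {
  test_counts <- as.matrix(test_counts); theta_hat <- as.matrix(theta_hat)
  stopifnot(identical(dim(test_counts), dim(theta_hat)))
  ni <- rowSums(test_counts)
  used <- ni > 0
  n <- sum(ni)
  P <- ncol(test_counts)
  if (n == 0) return(c(rmspe = 0, mae = 0))
  emp <- test_counts[used, , drop = FALSE] / ni[used]
  diff <- emp - theta_hat[used, , drop = FALSE]
  w <- ni[used]
  c(rmspe = sqrt(sum(w * diff^2) / (P * n)),
    mae = sum(w * abs(diff)) / (P * n))
}

#' Coverage and length of predictive intervals for held-out proportions
#'
#' For each eligible cell (held-out tree count >= `min_trees`) and taxon,
#' builds the central predictive interval for the held-out proportion:
#' per posterior composition draw, a multinomial count of size n_i is
#' simulated and its proportions collected; the interval is the
#' (1 +- level)/2 quantile band on the proportion scale. Coverage is the
#' fraction of (cell, taxon) pairs whose empirical held-out proportion
#' lies inside (pooled over taxa by default).
#'
#' @param theta Composition draws for the relevant cells, K x cells x P.
#' @param test_counts Held-out count matrix aligned to the same cells.
#' @param level Interval level (default 0.95).
#' @param min_trees Minimum held-out trees for a cell to be eligible
#'   (default 50).
#' @param seed RNG seed for the multinomial simulation.
#' @return List with `coverage`, `mean_length`, `median_length`,
#'   `n_pairs`, and the per-pair `inside`/`length` vectors.
#' @export
interval_metrics <- function(theta, test_counts, level = 0.95,
                             min_trees = 50, seed = 1) {
  test_counts <- as.matrix(test_counts)
  K <- dim(theta)[1]; P <- dim(theta)[3]
  stopifnot(dim(theta)[2] == nrow(test_counts), P == ncol(test_counts))
  ni <- rowSums(test_counts)
  elig <- which(ni >= min_trees)
  if (!length(elig)) {
    warning("no cells with at least ", min_trees, " held-out trees")
    return(list(coverage = NA_real_, mean_length = NA_real_,
                median_length = NA_real_, n_pairs = 0L,
                inside = logical(0), length = numeric(0)))
  }
  set.seed(seed)
  qlo <- (1 - level) / 2; qhi <- (1 + level) / 2
  inside <- logical(0); len <- numeric(0)
  for (i in elig) {
    props <- matrix(NA_real_, K, P)
    for (k in seq_len(K)) {
      props[k, ] <- rmultinom(1, ni[i], theta[k, i, ]) / ni[i]
    }
    lo <- apply(props, 2, quantile, probs = qlo)
    hi <- apply(props, 2, quantile, probs = qhi)
    emp <- test_counts[i, ] / ni[i]
    inside <- c(inside, emp >= lo & emp <= hi)
    len <- c(len, hi - lo)
  }
  list(coverage = mean(inside), mean_length = mean(len),
       median_length = median(len), n_pairs = length(inside),
       inside = inside, length = len)
}

#' Score a holdout with all predictive metrics
#'
#' Computes the Brier score, negative log predictive density, and (for
#' cell holdouts) weighted RMSPE and MAE, both at the posterior mean
#' composition and per retained posterior draw. All reported metrics are
#' lower-is-better.
#'
#' @param holdout A `holdout`.
#' @param theta A `theta_samples` array over all lattice cells (or the
#'   cells recorded in its `cells` attribute).
#' @param floor Zero-proportion floor for the log density.
#' @return A `metric_report`: list with `point` (named vector of metric
#'   values at the posterior mean) and `per_sample` (K x metrics matrix).
#' @export
evaluate_holdout <- function(holdout, theta, floor = 1e-5) {
  stopifnot(inherits(holdout, "holdout"))
  cells <- attr(theta, "cells") %||% seq_len(dim(theta)[2])
  test <- holdout$test[cells, , drop = FALSE]
  K <- dim(theta)[1]
  mean_theta <- apply(theta, c(2, 3), mean)
  one <- function(th) {
    v <- c(brier = brier(test, th),
           neg_log_density = -log_pred_density(test, th, floor = floor))
    if (holdout$kind == "cells") v <- c(v, rmspe_mae(test, th))
    v
  }
  point <- one(mean_theta)
  per_sample <- t(vapply(seq_len(K),
                         function(k) one(matrix(theta[k, , ],
                                                nrow = dim(theta)[2])),
                         point))
  structure(list(point = point, per_sample = per_sample,
                 posterior_mean_of_metric = colMeans(per_sample),
                 kind = holdout$kind, K = K),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (", x$kind, " holdout, K = ", x$K, ")\n", sep = "")
  tab <- rbind(`posterior mean prediction` = x$point,
               `posterior mean of metric` = x$posterior_mean_of_metric)
  print(signif(tab, 4))
  invisible(x)
}

#' Posterior probability that one model scores lower than another
#'
#' For each metric, the fraction of posterior sample indices at which
#' model A's metric value is below model B's; exact ties count 1/2.
#'
#' @param report_a,report_b `metric_report`s computed on the identical
#'   holdout with equal numbers of retained draws.
#' @return Named vector of probabilities in `[0, 1]`.
#' @export
compare_models <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "metric_report"),
            inherits(report_b, "metric_report"))
  if (report_a$K != report_b$K ||
      !identical(colnames(report_a$per_sample),
                 colnames(report_b$per_sample)) ||
      report_a$kind != report_b$kind) {
    stop("reports must come from identical holdouts with equal K")
  }
  a <- report_a$per_sample; b <- report_b$per_sample
  colMeans((a < b) + 0.5 * (a == b))
}
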