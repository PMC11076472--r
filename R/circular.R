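HOURS_TO_RAD <- 2 * pi / 24

#' Wrapped circular prediction error
#'
#' The raw difference `d = pred - true` is first reduced into (-24, 24),
#' then wrapped onto `[-12, 12]`: `D = d - 24` if `d > 12`, `D = d + 24`
#' if `d < -12`, else `D = d`. At exactly `|d| = 12` the middle branch
#' applies, so the sign of `d` is kept.
#'
#' @param pred,true Hours (vectors recycle).
#' @return Wrapped differences in `[-12, 12]`.
#' @export
circular_error <- function(pred, true) {
  d <- pred - true
  d <- d - 24 * trunc(d / 24)            # sign-preserving reduction to (-24, 24)
  ifelse(d > 12, d - 24, ifelse(d < -12, d + 24, d))
}

#' Score predictions on the 24-h circle
#'
#' @param preds,truths Hours, equal length.
#' @param window Correctness window in hours (default 2): a prediction is
#'   correct when `|D| <= window`.
#' @return List with `accuracy`, `rmse` (root mean squared wrapped error)
#'   and the per-sample errors `D`.
#' @export
score_predictions <- function(preds, truths, window = 2) {
  if (length(preds) == 0) stop("empty input")
  if (length(preds) != length(truths)) stop("length mismatch")
  D <- circular_error(preds, truths)
  list(accuracy = mean(abs(D) <= window), rmse = sqrt(mean(D^2)), D = D)
}

#' Circular mean and standard deviation of hours
#'
#' Hours are embedded on the circle at `2*pi/24` rad per hour. The mean is
#' the direction of the resultant vector mapped back to `[0, 24)`; the SD
#' is `sqrt(-2 log(Rbar)) * 24 / (2*pi)` with `Rbar` the mean resultant
#' length. A zero resultant leaves the mean undefined (`NA`, flagged) and
#' the SD infinite.
#'
#' @param hours Numeric vector of hours (reduced mod 24).
#' @return List with `mean`, `sd`, `rbar`, `n`, `mean_defined`.
#' @export
circular_mean_sd <- function(hours) {
  if (length(hours) < 1) stop("need at least one observation")
  th <- (hours %% 24) * HOURS_TO_RAD
  C <- mean(cos(th)); S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  if (rbar < 1e-12) {
    return(list(mean = NA_real_, sd = Inf, rbar = 0, n = length(hours),
                mean_defined = FALSE))
  }
  m <- (atan2(S, C) / HOURS_TO_RAD) %% 24
  if (24 - m < 1e-9) m <- 0
  list(mean = m, sd = sqrt(-2 * log(rbar)) / HOURS_TO_RAD, rbar = rbar,
       n = length(hours), mean_defined = TRUE)
}

# Per-group first/second moments of the circle embedding (cos, sin).
rao_group_stats <- function(groups) {
  lapply(groups, function(h) {
    th <- (h %% 24) * HOURS_TO_RAD
    n <- length(th)
    x <- cos(th); y <- sin(th)
    S <- stats::cov(cbind(x, y))
    list(n = n, m = c(mean(x), mean(y)), S = S)
  })
}

#' Rao's tests of homogeneity for circular samples
#'
#' Large-sample chi-square tests in the spirit of Rao (1967) for k groups
#' of angles. The polar-vector (mean) component compares each group's
#' resultant vector `(mean cos, mean sin)` across groups, weighting by the
#' inverse of its estimated covariance; under homogeneity the statistic is
#' chi-square with `2(k-1)` degrees of freedom. The dispersion component
#' compares the mean resultant lengths with delta-method variances,
#' chi-square with `k-1` degrees of freedom. Both statistics are invariant
#' to a common rotation of all groups.
#'
#' @param groups List of >= 2 numeric vectors of hours (each n >= 2).
#' @return List with `statistic_mean`, `p_mean` (polar vectors,
#'   df `2(k-1)`), `statistic_dispersion`, `p_dispersion` (df `k-1`), and
#'   `degenerate` (TRUE when a group has (near-)zero resultant length or a
#'   singular embedding covariance, in which case p-values are `NA`).
#' @export
rao_homogeneity_test <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  gs <- rao_group_stats(groups)
  rbars <- vapply(gs, function(g) sqrt(sum(g$m^2)), 1)
  degenerate_out <- list(statistic_mean = NA_real_, p_mean = NA_real_,
                         statistic_dispersion = NA_real_,
                         p_dispersion = NA_real_, degenerate = TRUE)
  if (any(rbars < 1e-10)) return(degenerate_out)
  # polar vectors: weighted 2-d homogeneity, W_i = n_i * solve(cov_i)
  Ws <- lapply(gs, function(g)
    tryCatch(g$n * solve(g$S), error = function(e) NULL))
  if (any(vapply(Ws, is.null, TRUE))) return(degenerate_out)
  Wsum <- Reduce(`+`, Ws)
  Wm <- Map(function(W, g) W %*% g$m, Ws, gs)
  H1 <- sum(vapply(seq_len(k), function(i)
    drop(crossprod(gs[[i]]$m, Wm[[i]])), 1)) -
    drop(crossprod(Reduce(`+`, Wm), solve(Wsum, Reduce(`+`, Wm))))
  # dispersions: mean resultant lengths, delta-method variances
  var_r <- vapply(seq_len(k), function(i) {
    g <- gs[[i]]
    drop(crossprod(g$m, g$S %*% g$m)) / (g$n * rbars[i]^2)
  }, 1)
  if (any(var_r <= 0)) return(degenerate_out)
  w <- 1 / var_r
  H2 <- sum(w * rbars^2) - sum(w * rbars)^2 / sum(w)
  list(statistic_mean = H1,
       p_mean = stats::pchisq(H1, 2 * (k - 1), lower.tail = FALSE),
       statistic_dispersion = H2,
       p_dispersion = stats::pchisq(H2, k - 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Wallraff test of angular distances
#'
#' Nonparametric test for a difference in dispersion: each observation is
#' replaced by its absolute angular distance (hours, on the circle) to its
#' own group's circular mean, and the distances are compared across groups
#' by a Wilcoxon rank-sum test (2 groups) or Kruskal-Wallis test
#' (> 2 groups).
#'
#' When the observations live on a discrete grid (e.g. whole-hour class
#' predictions), set `grid` to the grid step: each group's circular mean
#' is then snapped to the nearest grid point before distances are taken.
#' Without snapping, the continuous mean gives heavily tied discrete data
#' a group-specific fractional offset that the rank test mistakes for a
#' dispersion difference.
#'
#' @param groups List of >= 2 numeric vectors of hours.
#' @param grid Optional grid step in hours for discrete observations
#'   (e.g. 1 for whole-hour predictions); `NULL` for continuous data.
#' @return List with `p`, `statistic`, `distances`.
#' @export
wallraff_test <- function(groups, grid = NULL) {
  if (length(groups) < 2) stop("need at least 2 groups")
  dists <- lapply(groups, function(h) {
    m <- circular_mean_sd(h)$mean
    if (is.na(m)) m <- 0
    if (!is.null(grid)) m <- (round(m / grid) * grid) %% 24
    d <- abs(circular_error(h, m))
    d[d < 1e-9] <- 0                     # constant groups hit fp residue
    d
  })
  if (length(unique(unlist(dists))) == 1)
    return(list(p = 1, statistic = 0, distances = dists))
  if (length(groups) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(dists[[1]], dists[[2]],
                                              exact = FALSE))
    list(p = wt$p.value, statistic = unname(wt$statistic), distances = dists)
  } else {
    g <- factor(rep(seq_along(dists), lengths(dists)))
    kt <- stats::kruskal.test(unlist(dists), g)
    list(p = kt$p.value, statistic = unname(kt$statistic), distances = dists)
  }
}

#' Hypergeometric enrichment of a gene set
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between `hits` and `target` inside `background`, plus the
#' observed/expected overlap ratio. A zero overlap gives p = 1 by the
#' upper-tail convention.
#'
#' @param hits,target,background Character vectors of gene ids;
#'   `hits` and `target` must be subsets of `background`.
#' @return List with `p`, `ratio`, `overlap`, `expected`.
#' @export
hypergeometric_enrichment <- function(hits, target, background) {
  background <- unique(background)
  hits <- unique(hits); target <- unique(target)
  if (length(background) == 0) stop("empty background")
  if (length(setdiff(hits, background)) || length(setdiff(target, background)))
    stop("hits and target must be subsets of background")
  ov <- length(intersect(hits, target))
  expected <- length(hits) * length(target) / length(background)
  p <- stats::phyper(ov - 1, length(target),
                     length(background) - length(target), length(hits),
                     lower.tail = FALSE)
  list(p = p, ratio = if (expected > 0) ov / expected else NA_real_,
       overlap = ov, expected = expected)
}

#' Draw from a von Mises distribution (hours on the 24-h circle)
#'
#' Best-Fisher rejection sampler; used by calibration checks and the
#' simulators.
#'
#' @param n Number of draws.
#' @param mu_hours Mean direction in hours.
#' @param kappa Concentration (0 = uniform).
#' @return Hours in `[0, 24)`.
#' @export
rvonmises_hours <- function(n, mu_hours, kappa) {
  mu <- mu_hours * HOURS_TO_RAD
  if (kappa < 1e-10) return(stats::runif(n, 0, 24))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  th <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        th[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (th / HOURS_TO_RAD) %% 24
}
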