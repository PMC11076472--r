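#' Fourier basis evaluation
#'
#' Basis order: `1, sin(wt), cos(wt), sin(2wt), cos(2wt), ...` truncated to
#' `K` functions. With `omega = 2*pi/24` every basis function is 24-h
#' periodic, hence so is any fitted curve.
#'
#' @param t Time(s) in hours.
#' @param K Number of basis functions; must be odd and >= 3.
#' @param omega Angular frequency in rad/hour (default `2*pi/24`).
#' @return For scalar `t` a length-`K` vector; otherwise a
#'   `length(t) x K` matrix.
#' @export
fourier_basis <- function(t, K = 5, omega = 2 * pi / 24) {
  if (K %% 2 == 0 || K < 3) stop("K must be odd and >= 3")
  n_harm <- (K - 1) / 2
  out <- matrix(0, length(t), K)
  out[, 1] <- 1
  for (r in seq_len(n_harm)) {
    out[, 2 * r] <- sin(r * omega * t)
    out[, 2 * r + 1] <- cos(r * omega * t)
  }
  if (length(t) == 1) drop(out) else out
}

fourier_basis_matrix <- function(t, K, omega) {
  b <- fourier_basis(t, K, omega)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b
}

# Closed-form roughness penalty matrix: Omega[j,k] = int_a^b phi_j'' phi_k'' dt
# on the Fourier basis. The constant has zero curvature; trig products reduce
# to integrals of cos/sin of multiples of omega via product-to-sum.
fourier_penalty_matrix <- function(K, omega, span) {
  a <- span[1]; b <- span[2]
  int_cos <- function(al) if (al == 0) b - a else (sin(al * b) - sin(al * a)) / al
  int_sin <- function(al) if (al == 0) 0 else (cos(al * a) - cos(al * b)) / al
  n_harm <- (K - 1) / 2
  Omega <- matrix(0, K, K)
  for (r in seq_len(n_harm)) {
    for (s in seq_len(n_harm)) {
      cr <- (r * omega)^2 * (s * omega)^2
      ss <- 0.5 * (int_cos((r - s) * omega) - int_cos((r + s) * omega))
      cc <- 0.5 * (int_cos((r - s) * omega) + int_cos((r + s) * omega))
      sc <- 0.5 * (int_sin((r + s) * omega) + int_sin((r - s) * omega))
      Omega[2 * r, 2 * s] <- cr * ss
      Omega[2 * r + 1, 2 * s + 1] <- cr * cc
      Omega[2 * r, 2 * s + 1] <- cr * sc
      Omega[2 * s + 1, 2 * r] <- cr * sc
    }
  }
  (Omega + t(Omega)) / 2
}

#' Fit a positive penalized Fourier smooth to one gene's time course
#'
#' Represents a log-expression time course as the exponential of an
#' unconstrained Fourier expansion, `Y(t) = exp(Z(t))` with
#' `Z(t) = sum_k c_k phi_k(t)`, so the smoothed curve is strictly positive.
#' Coefficients minimize the penalized least squares criterion
#' `sum_j (y_j - exp(Z(t_j)))^2 + lambda * int (Z'')^2`, solved by
#' Levenberg-Marquardt nonlinear least squares with the roughness penalty
#' embedded as extra residuals (matrix square root of `lambda * Omega`).
#' The start value is the linear fit of `Z` to `log(y + 1e-6)`.
#'
#' @param log_values Non-negative values (already `log2(x + 1)` scaled).
#' @param times Hours, same length.
#' @param K Odd basis size (default 5).
#' @param omega Angular frequency (default `2*pi/24`).
#' @param lambda Roughness penalty weight (default 1e-2).
#' @return Object of class `fourier_fit`: `coefficients`, `K`, `omega`,
#'   `lambda`, `span`, `rss`.
#' @export
fit_positive_smooth <- function(log_values, times, K = 5,
                                omega = 2 * pi / 24, lambda = 1e-2) {
  if (any(log_values < 0)) stop("log_values must be non-negative")
  if (length(log_values) < K)
    stop("need at least K = ", K, " time points")
  B <- fourier_basis_matrix(times, K, omega)
  span <- range(times)
  Omega <- fourier_penalty_matrix(K, omega, span)
  eig <- eigen(lambda * Omega, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  L <- diag(sqrt(pos), K) %*% t(eig$vectors)
  y <- log_values
  c0 <- tryCatch(
    solve(crossprod(B) + lambda * Omega + diag(1e-10, K),
          crossprod(B, log(y + 1e-6))),
    error = function(e) rep(0, K))
  resid_fun <- function(cc) c(y - exp(drop(B %*% cc)), drop(L %*% cc))
  jac_fun <- function(cc) rbind(-exp(drop(B %*% cc)) * B, L)
  fit <- minpack.lm::nls.lm(
    par = drop(c0), fn = resid_fun, jac = jac_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-8,
                                         ftol = 1e-12))
  if (fit$info == 0 || fit$info == 5)
    stop("positive smooth did not converge; last residual norm ",
         signif(sqrt(fit$deviance), 6))
  structure(list(coefficients = unname(fit$par), K = K, omega = omega,
                 lambda = lambda, span = span, rss = fit$deviance),
            class = "fourier_fit")
}

#' Evaluate a fitted positive smooth
#'
#' @param object A `fourier_fit`.
#' @param t Hours at which to evaluate.
#' @param ... Unused.
#' @return `Y(t) = exp(Z(t))`, strictly positive.
#' @export
predict.fourier_fit <- function(object, t, ...) {
  B <- fourier_basis_matrix(t, object$K, object$omega)
  exp(drop(B %*% object$coefficients))
}

# Curvature functional int (Z'')^2 of a fit (used by monotonicity checks).
curvature_energy <- function(fit) {
  Omega <- fourier_penalty_matrix(fit$K, fit$omega, fit$span)
  drop(crossprod(fit$coefficients, Omega %*% fit$coefficients))
}

#' Evaluate per-gene smooths on the prediction time grid
#'
#' Grid rule: if the training time course spans less than 24 h, curves are
#' evaluated on `{0, ..., 23}` (T = 24) so all hours of the cycle are
#' represented; otherwise on `{min(times), ..., max(times)}` in
#' `interval`-hour steps (T = span + 1 at the default 1-h interval).
#'
#' @param fits Named list of `fourier_fit` objects (one per gene), sharing
#'   a common span.
#' @param interval Grid step in hours (default 1).
#' @return Object of class `smoothed_matrix`: `values` (genes x grid),
#'   `grid_times`, `source_genes`.
#' @export
evaluate_on_grid <- function(fits, interval = 1) {
  span <- fits[[1]]$span
  grid <- if (diff(span) < 24) seq(0, 23, by = interval)
          else seq(span[1], span[2], by = interval)
  vals <- t(vapply(fits, function(f) predict(f, grid), numeric(length(grid))))
  rownames(vals) <- names(fits)
  structure(list(values = vals, grid_times = grid,
                 source_genes = names(fits)),
            class = "smoothed_matrix")
}
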