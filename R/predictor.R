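#' Log2(x + 1) transform
#'
#' @param x Non-negative numeric vector/matrix, or a
#'   [time_series_matrix()] (transformed in place).
#' @return Same shape, element-wise `log2(x + 1)`.
#' @export
log2_transform <- function(x) {
  if (inherits(x, "time_series_matrix")) {
    x$values <- log2_transform(x$values)
    return(x)
  }
  if (any(x < 0)) stop("log2_transform requires non-negative values")
  log2(x + 1)
}

# Ordered gene-pair index for M genes: (A,B) for every A != B, both orders,
# A-major. Shared by training and prediction so feature columns align.
pair_index <- function(M) {
  A <- rep(seq_len(M), each = M)
  B <- rep(seq_len(M), times = M)
  keep <- A != B
  cbind(A = A[keep], B = B[keep])
}

#' All ordered pairwise differences of one expression vector
#'
#' For genes A != B both `A - B` and `B - A` are retained, in a fixed
#' A-major order, giving `M * (M - 1)` features.
#'
#' @param sample_vector Numeric, length M >= 2.
#' @return Numeric vector of length `M * (M - 1)`.
#' @export
pairwise_differences <- function(sample_vector) {
  M <- length(sample_vector)
  if (M < 2) stop("need at least 2 genes")
  idx <- pair_index(M)
  out <- sample_vector[idx[, "A"]] - sample_vector[idx[, "B"]]
  nm <- names(sample_vector)
  if (!is.null(nm)) names(out) <- paste0(nm[idx[, "A"]], "-", nm[idx[, "B"]])
  out
}

#' Min-max rescale a feature vector within one sample
#'
#' `(value - min) / (max - min)`, mapping the minimum to 0 and the maximum
#' to 1. Degenerate input (max == min) maps everything to 0.5. Because the
#' pairwise-difference multiset is symmetric about zero, rescaled values
#' satisfy `scaled(A-B) + scaled(B-A) = 1` for every pair.
#'
#' @param diffs Numeric vector.
#' @return Values in `[0, 1]`.
#' @export
rescale_within_sample <- function(diffs) {
  rng <- range(diffs)
  if (rng[2] == rng[1]) return(rep(0.5, length(diffs)))
  (diffs - rng[1]) / (rng[2] - rng[1])
}

# samples x M*(M-1) feature matrix: pairwise differences + per-sample rescale.
# X is genes x samples.
difference_features <- function(X) {
  M <- nrow(X)
  idx <- pair_index(M)
  d <- t(X[idx[, "A"], , drop = FALSE] - X[idx[, "B"], , drop = FALSE])
  t(apply(d, 1, rescale_within_sample))
}

# PCA + multinomial classifier over the hourly class grid, built from the
# smoothed genes x grid matrix. Reused at predict time when the test sample
# misses predictor genes (rebuild on the gene intersection).
build_classifier <- function(Y, grid_times, ridge = 1e-4, maxit = 500) {
  if (ncol(Y) < 3) stop("PCA needs at least 3 grid samples")
  feats <- difference_features(Y)
  center <- colMeans(feats)
  Xc <- sweep(feats, 2, center)
  sv <- svd(Xc, nu = 0, nv = 2)
  rot <- sv$v
  for (k in 1:2) if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  scores <- Xc %*% rot
  classes <- as.integer(round(grid_times)) %% 24L
  levs <- sort(unique(classes))
  df <- data.frame(hour = factor(classes, levels = levs),
                   x1 = scores[, 1], x2 = scores[, 2])
  fit <- nnet::multinom(hour ~ x1 + x2, data = df, decay = ridge,
                        maxit = maxit, trace = FALSE, reltol = 1e-8)
  if (fit$convergence != 0)
    stop("multinomial regression did not converge (value ",
         signif(fit$value, 6), ")")
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(df$hour)[2], NULL))
  list(center = center, rotation = rot, beta = unname(cf),
       beta_classes = as.integer(rownames(coef(fit))), classes = levs)
}

# Softmax class probabilities from a classifier for a samples x features
# matrix of rescaled difference features.
classifier_probs <- function(clf, feats) {
  scores <- sweep(feats, 2, clf$center) %*% clf$rotation
  eta <- cbind(0, scores %*% t(clf$beta[, -1, drop = FALSE]) +
                 rep(1, nrow(scores)) %o% clf$beta[, 1])
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  colnames(p) <- c(clf$classes[1], clf$beta_classes)
  p[, order(as.integer(colnames(p))), drop = FALSE]
}

#' Train a circadian-time predictor
#'
#' Full training pipeline: predictor-gene selection (rhythmicity test,
#' top genes + core clock union), `log2(x+1)` transform, positive Fourier
#' smoothing per gene, evaluation on the hourly grid, ordered pairwise
#' gene differences min-max rescaled within each grid time, PCA to two
#' components, and multinomial regression of hour class (grid hour mod 24,
#' reference class 0) on the two components.
#'
#' @param matrix A [time_series_matrix()] of training expression.
#' @param method Rhythmicity test, `"jtk"` (default) or `"ls"`.
#' @param alpha,n_top,adjust Passed to [select_predictor_genes()].
#' @param K,lambda,omega Passed to [fit_positive_smooth()].
#' @param interval Prediction grid step in hours (default 1).
#' @param ridge Ridge penalty on the multinomial coefficients
#'   (default 1e-4).
#' @param genes Optional explicit predictor gene ids, bypassing selection.
#' @return Object of class `taufisher_model`.
#' @export
train_taufisher <- function(matrix, method = c("jtk", "ls"), alpha = 0.05,
                            n_top = 10, adjust = c("none", "BH"), K = 5,
                            lambda = 1e-2, omega = 2 * pi / 24, interval = 1,
                            ridge = 1e-4, genes = NULL) {
  stopifnot(inherits(matrix, "time_series_matrix"))
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (is.null(genes)) {
    sel <- select_predictor_genes(matrix, method, alpha, n_top, adjust)
    genes <- sel$genes
  } else {
    sel <- NULL
    genes <- intersect(genes, matrix$gene_ids)
  }
  if (length(genes) < 2) stop("fewer than 2 predictor genes available")
  Xp <- log2_transform(matrix$values[match(genes, matrix$gene_ids), ,
                                     drop = FALSE])
  fits <- lapply(seq_along(genes), function(i)
    fit_positive_smooth(Xp[i, ], matrix$times, K, omega, lambda))
  names(fits) <- genes
  sm <- evaluate_on_grid(fits, interval)
  clf <- build_classifier(sm$values, sm$grid_times, ridge)
  structure(
    list(version = 1L, genes = genes, gene_set = sel, fits = fits,
         smoothed = sm, classifier = clf,
         config = list(method = method, alpha = alpha, n_top = n_top,
                       adjust = adjust, K = K, lambda = lambda,
                       omega = omega, interval = interval, ridge = ridge)),
    class = "taufisher_model")
}

#' @export
print.taufisher_model <- function(x, ...) {
  cat(sprintf(
    "taufisher_model: %d predictor genes, %d grid points, %d hour classes\n",
    length(x$genes), length(x$smoothed$grid_times),
    length(x$classifier$classes)))
  invisible(x)
}

#' Predict circadian time for one or more samples
#'
#' The test sample is trimmed to the model's predictor genes; if some are
#' absent, the downstream feature space (pairs, PCA, multinomial
#' regression) is rebuilt from the stored smoothed curves restricted to
#' the gene intersection before predicting. Values are `log2(x + 1)`
#' transformed (set `log2 = FALSE` for already-logged input), turned into
#' rescaled pairwise-difference features, projected onto the stored
#' principal components and classified by softmax; ties break toward the
#' smaller hour.
#'
#' @param object A `taufisher_model`.
#' @param newdata Named numeric vector (gene -> value), or a genes x
#'   samples matrix with gene ids as rownames, or a
#'   [time_series_matrix()].
#' @param log2 Apply `log2(x + 1)` to the test values (default TRUE; raw
#'   counts or intensities may be fed directly).
#' @param ... Unused.
#' @return List with `hour` (integer vector, one per sample),
#'   `probabilities` (samples x classes matrix) and `genes_used`.
#' @export
predict.taufisher_model <- function(object, newdata, log2 = TRUE, ...) {
  if (inherits(newdata, "time_series_matrix")) {
    mat <- newdata$values
  } else if (is.null(dim(newdata))) {
    if (is.null(names(newdata))) stop("newdata vector must be named by gene")
    mat <- matrix(newdata, ncol = 1, dimnames = list(names(newdata), NULL))
  } else {
    mat <- as.matrix(newdata)
  }
  shared <- intersect(object$genes, rownames(mat))
  if (length(shared) < 2)
    stop("test sample shares fewer than 2 genes with the model")
  if (length(shared) < length(object$genes)) {
    keep <- match(shared, object$smoothed$source_genes)
    clf <- build_classifier(object$smoothed$values[keep, , drop = FALSE],
                            object$smoothed$grid_times,
                            object$config$ridge)
  } else {
    clf <- object$classifier
  }
  V <- mat[match(shared, rownames(mat)), , drop = FALSE]
  if (log2) V <- log2_transform(V)
  feats <- difference_features(V)
  probs <- classifier_probs(clf, feats)
  hours <- as.integer(colnames(probs))[apply(probs, 1, which.max)]
  nm <- colnames(mat)
  if (!is.null(nm)) names(hours) <- nm
  list(hour = hours, probabilities = probs, genes_used = shared)
}

# Subset samples of a time_series_matrix by index.
subset_samples <- function(x, idx) {
  time_series_matrix(x$values[, idx, drop = FALSE], x$gene_ids, x$times[idx])
}

#' Random train/test partition benchmark
#'
#' Repeatedly splits the samples into train and test sets (without
#' replacement), trains the full pipeline on the training split and scores
#' predictions on the test split with the wrapped circular error. A
#' prediction within `window` hours of the true time counts as correct.
#'
#' @param matrix A [time_series_matrix()].
#' @param n_iter Number of random partitions (default 100).
#' @param train_frac Fraction of samples used for training (default 0.8;
#'   train size is `round(train_frac * P)`).
#' @param window Correctness window in hours (default 2).
#' @param seed Master seed; per-iteration streams are derived from it.
#' @param ... Passed to [train_taufisher()].
#' @return Data frame with one row per iteration: `iteration`, `accuracy`,
#'   `rmse`, `n_test`. Iterations where training fails (e.g. the split
#'   loses all rhythmic genes) are recorded as `NA`, not dropped.
#' @export
benchmark_partitions <- function(matrix, n_iter = 100, train_frac = 0.8,
                                 window = 2, seed = 1, ...) {
  P <- ncol(matrix$values)
  if (P < 5) stop("at least 5 samples are required")
  n_train <- round(train_frac * P)
  res <- lapply(seq_len(n_iter), function(it) {
    set.seed(derive_seed(seed, "benchmark", it))
    tr <- sort(sample.int(P, n_train))
    te <- setdiff(seq_len(P), tr)
    out <- tryCatch({
      model <- train_taufisher(subset_samples(matrix, tr), ...)
      pred <- predict(model, matrix$values[, te, drop = FALSE], log2 = TRUE)
      sc <- score_predictions(pred$hour, matrix$times[te] %% 24, window)
      c(sc$accuracy, sc$rmse)
    }, error = function(e) c(NA_real_, NA_real_))
    data.frame(iteration = it, accuracy = out[1], rmse = out[2],
               n_test = length(te))
  })
  do.call(rbind, res)
}
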