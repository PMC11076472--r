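#' Core clock gene symbols
#'
#' The transcription-translation feedback-loop genes considered for the
#' predictor set. `Arntl` is an alias of `Bmal1`; matching is
#' case-insensitive and alias-aware.
#'
#' @return Character vector of canonical symbols.
#' @export
core_clock_genes <- function() {
  c("Bmal1", "Dbp", "Nr1d1", "Nr1d2", "Per1", "Per2", "Per3", "Cry1", "Cry2")
}

# Canonicalize gene symbols for core-clock matching (alias map + case fold).
canonical_symbol <- function(x) {
  lx <- tolower(x)
  lx[lx == "arntl"] <- "bmal1"
  lx
}

# Reference cosine ordering for a candidate (period, phase): peaks at
# t == phase. Rounded so that symmetric sampling points produce exact ties
# (the tie-aware null and the S statistic must agree on the tie pattern).
jtk_reference <- function(times, period, phase) {
  round(cos(2 * pi * (times - phase) / period), 9)
}

# Signs of all ordered pair differences (i < j) of a vector.
pair_signs <- function(x) {
  n <- length(x)
  i <- sequence(seq_len(n - 1))                 # 1,1,2,1,2,3,...
  j <- rep(2:n, seq_len(n - 1))
  sign(x[j] - x[i])
}

# Coefficients of the Gaussian binomial [a choose b]_q (Pascal recurrence).
gaussian_binomial <- function(a, b) {
  b <- min(b, a - b)
  if (b == 0) return(1)
  if (b == 1) return(rep(1, a))               # 1 + q + ... + q^{a-1}
  Q <- vector("list", b + 1)
  Q[[1]] <- 1
  for (j in 1:b) Q[[j + 1]] <- 0
  for (i in 1:a) {
    for (j in min(i, b):1) {
      left <- Q[[j]]
      right <- c(rep(0, j), Q[[j + 1]])
      n <- max(length(left), length(right))
      Q[[j + 1]] <- c(left, rep(0, n - length(left))) +
        c(right, rep(0, n - length(right)))
    }
  }
  Q[[b + 1]]
}

# Exact null distribution of the Kendall concordance count K between a fixed
# reference (ties allowed) and a uniformly random permutation of distinct
# data. Returns the number of untied pairs U and P(K = 0..U). S = 2K - U.
jtk_null_distribution <- function(reference) {
  sizes <- as.integer(tabulate(match(reference, sort(unique(reference)))))
  n <- sum(sizes)
  dist <- 1
  m <- 0
  for (t in sizes) {
    if (m > 0 && t > 0) {
      g <- gaussian_binomial(m + t, t)
      # polynomial product (distribution convolution, exact small integers)
      new <- rep(0, length(dist) + length(g) - 1)
      for (k in seq_along(g)) {
        if (g[k] != 0)
          new[k:(k + length(dist) - 1)] <- new[k:(k + length(dist) - 1)] +
            g[k] * dist
      }
      dist <- new
    }
    m <- m + t
  }
  U <- sum(utils::head(cumsum(sizes), -1) * sizes[-1])
  probs <- dist / sum(dist)
  list(U = U, probs = probs)
}

# Upper-tail lookup table: tail[s + 1] = P(|S_null| >= s) for s = 0..U.
jtk_tail_probs <- function(null) {
  U <- null$U
  s_vals <- abs(2 * (0:U) - U)
  tail <- numeric(U + 1)
  for (s in 0:U) tail[s + 1] <- sum(null$probs[s_vals >= s])
  tail
}

# Build the candidate grid and per-candidate machinery for a fixed time
# vector: reference pair signs, exact nulls, |S| -> p lookup. Cached by the
# caller across genes since it is data-independent.
jtk_candidates <- function(times, period_grid, phase_step) {
  cand <- do.call(rbind, lapply(period_grid, function(per) {
    phases <- seq(0, per - min(phase_step, per), by = phase_step)
    if (!length(phases)) phases <- 0
    data.frame(period = per, phase = phases)
  }))
  refs <- vapply(seq_len(nrow(cand)),
                 function(k) jtk_reference(times, cand$period[k], cand$phase[k]),
                 numeric(length(times)))
  ref_signs <- apply(refs, 2, pair_signs)
  if (is.null(dim(ref_signs)))
    ref_signs <- matrix(ref_signs, ncol = nrow(cand))
  null_cache <- new.env(parent = emptyenv())
  tails <- lapply(seq_len(nrow(cand)), function(k) {
    key <- paste(ref_signs[, k], collapse = "")
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- jtk_tail_probs(jtk_null_distribution(refs[, k]))
    null_cache[[key]]
  })
  list(cand = cand, ref_signs = ref_signs, tails = tails)
}

# JTK-style amplitude: half the difference between the mean of observations
# near the reference peak and near the trough (windows of +/- half a
# sampling interval on the circle; nearest points if a window is empty).
jtk_amplitude <- function(series, times, period, phase, interval) {
  window_mean <- function(center) {
    d <- abs(((times - center + period / 2) %% period) - period / 2)
    sel <- d <= interval / 2 + 1e-9
    if (!any(sel)) sel <- d <= min(d) + 1e-9
    mean(series[sel])
  }
  max(0, (window_mean(phase) - window_mean(phase + period / 2)) / 2)
}

#' JTK_Cycle-style rhythmicity test
#'
#' Compares the rank order of a series with reference cosine orderings over
#' a grid of candidate periods and peak phases using the Kendall S
#' statistic. For each candidate the p-value is exact: the null
#' distribution of S under permutation of the data, with reference ties
#' handled by the tie-aware null (computed by convolution of Gaussian
#' binomial coefficients). The reported p-value is the Bonferroni-adjusted
#' minimum over candidates.
#'
#' @param series Numeric vector of expression values (P >= 4).
#' @param times Sampling times in hours, ascending.
#' @param period_grid Candidate periods (hours); default 20 to 28 h in
#'   steps of the sampling interval.
#' @param phase_step Phase grid step (hours); default the sampling interval.
#' @param candidates Precomputed [jtk_candidates()] machinery (internal
#'   fast path when testing many genes on the same time vector).
#' @return A one-row data frame: `p_value`, `best_period`, `peak_phase`,
#'   `amplitude`, `method`. Constant series get `p_value = 1`,
#'   `amplitude = 0`, `peak_phase = 0` and `best_period = NA`.
#' @export
jtk_test <- function(series, times, period_grid = NULL, phase_step = NULL,
                     candidates = NULL) {
  if (length(series) != length(times)) stop("series/times length mismatch")
  if (length(series) < 4) stop("at least 4 time points are required")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  interval <- stats::median(diff(times))
  if (is.null(phase_step)) phase_step <- interval
  if (is.null(period_grid)) period_grid <- seq(20, 28, by = interval)
  if (stats::var(series) == 0 || all(!is.finite(series)))
    return(data.frame(p_value = 1, best_period = NA_real_, peak_phase = 0,
                      amplitude = 0, method = "JTK",
                      stringsAsFactors = FALSE))
  if (is.null(candidates))
    candidates <- jtk_candidates(times, period_grid, phase_step)
  y_signs <- pair_signs(series)
  S <- as.vector(crossprod(candidates$ref_signs, y_signs))
  p_each <- vapply(seq_along(S),
                   function(k) candidates$tails[[k]][abs(S[k]) + 1],
                   numeric(1))
  # ties in the two-sided p (e.g. a candidate and its anti-phase partner)
  # resolve toward the concordant candidate: larger S, then grid order
  best <- order(p_each, -S)[1]
  p_adj <- min(1, length(p_each) * p_each[best])
  per <- candidates$cand$period[best]
  ph <- candidates$cand$phase[best] %% 24
  data.frame(p_value = p_adj, best_period = per, peak_phase = ph,
             amplitude = jtk_amplitude(series, times, per,
                                       candidates$cand$phase[best], interval),
             method = "JTK", stringsAsFactors = FALSE)
}

#' Exact per-candidate JTK p-value
#'
#' The unadjusted exact permutation p-value of the Kendall S statistic for
#' one (period, phase) candidate: `P(|S_null| >= |S_obs|)` under random
#' permutation of the data, with reference ties handled exactly.
#'
#' @inheritParams jtk_test
#' @param period,phase One candidate (hours).
#' @return List with `S`, `p` and the number of untied reference pairs `U`.
#' @export
jtk_exact_p <- function(series, times, period, phase) {
  reference <- jtk_reference(times, period, phase)
  null <- jtk_null_distribution(reference)
  S <- sum(pair_signs(series) * pair_signs(reference))
  tail <- jtk_tail_probs(null)
  list(S = S, p = tail[abs(S) + 1], U = null$U)
}

#' Lomb-Scargle rhythmicity test
#'
#' Classic normalized Lomb-Scargle periodogram (variance-normalized, with
#' the time-offset term). The single-frequency false-alarm probability uses
#' the exact beta-tail null for variance-normalized power,
#' `(1 - 2 P / (n - 1))^{(n-3)/2}`, combined over the frequency grid as
#' independent trials.
#'
#' @param series Numeric vector (P >= 4).
#' @param times Hours.
#' @param freq_grid Candidate frequencies in 1/hours; default the
#'   reciprocals of periods 20 to 28 h in sampling-interval steps.
#' @return A one-row data frame as in [jtk_test()], `method = "LS"`.
#' @export
lomb_scargle_test <- function(series, times, freq_grid = NULL) {
  n <- length(series)
  if (n != length(times)) stop("series/times length mismatch")
  if (n < 4) stop("at least 4 time points are required")
  if (is.null(freq_grid)) {
    interval <- stats::median(diff(times))
    freq_grid <- 1 / seq(20, 28, by = interval)
  }
  s2 <- stats::var(series)
  if (s2 == 0)
    return(data.frame(p_value = 1, best_period = NA_real_, peak_phase = 0,
                      amplitude = 0, method = "LS", stringsAsFactors = FALSE))
  yc <- series - mean(series)
  power <- vapply(freq_grid, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  best <- which.max(power)
  # exact single-frequency tail for variance-normalized power
  z <- power[best]
  fap1 <- if (2 * z >= n - 1) 0 else (1 - 2 * z / (n - 1))^((n - 3) / 2)
  p <- 1 - (1 - fap1)^length(freq_grid)
  w <- 2 * pi * freq_grid[best]
  fit <- stats::lm(series ~ cos(w * times) + sin(w * times))
  a <- stats::coef(fit)[2]; b <- stats::coef(fit)[3]
  period <- 1 / freq_grid[best]
  phase <- (atan2(b, a) / w) %% period
  data.frame(p_value = max(p, .Machine$double.xmin),
             best_period = period, peak_phase = phase %% 24,
             amplitude = sqrt(a^2 + b^2), method = "LS",
             stringsAsFactors = FALSE)
}

#' Per-gene rhythmicity statistics for a whole matrix
#'
#' @param matrix A [time_series_matrix()].
#' @param method `"jtk"` or `"ls"`.
#' @param period_grid,phase_step Passed to the chosen test.
#' @return Data frame with one row per gene: `gene_id`, `p_value`,
#'   `q_value` (Benjamini-Hochberg), `best_period`, `peak_phase`,
#'   `amplitude`, `method`.
#' @export
rhythm_statistics <- function(matrix, method = c("jtk", "ls"),
                              period_grid = NULL, phase_step = NULL) {
  stopifnot(inherits(matrix, "time_series_matrix"))
  method <- match.arg(method)
  times <- matrix$times
  ord <- order(times)
  vals <- matrix$values[, ord, drop = FALSE]
  times <- times[ord]
  if (method == "jtk") {
    interval <- stats::median(diff(times))
    if (is.null(phase_step)) phase_step <- interval
    if (is.null(period_grid)) period_grid <- seq(20, 28, by = interval)
    cands <- jtk_candidates(times, period_grid, phase_step)
    rows <- lapply(seq_len(nrow(vals)), function(i)
      jtk_test(vals[i, ], times, period_grid, phase_step, candidates = cands))
  } else {
    freq_grid <- if (is.null(period_grid)) NULL else 1 / period_grid
    rows <- lapply(seq_len(nrow(vals)), function(i)
      lomb_scargle_test(vals[i, ], times, freq_grid))
  }
  out <- do.call(rbind, rows)
  out <- cbind(gene_id = matrix$gene_ids, out, stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("gene_id", "p_value", "q_value", "best_period", "peak_phase",
          "amplitude", "method")]
}

#' Select the predictor gene set
#'
#' Runs the chosen rhythmicity test on every gene, keeps significant genes
#' whose best period is exactly 24 h, takes the top `n_top` by ascending
#' p-value, and unions them with the core clock genes that independently
#' pass the same 24-h filter. Ties are broken by descending amplitude then
#' lexicographic gene id, so selection is fully deterministic.
#'
#' @param matrix A [time_series_matrix()].
#' @param method `"jtk"` or `"ls"`.
#' @param alpha Significance level on the per-gene p-value (default 0.05).
#' @param n_top Number of top rhythmic genes (default 10).
#' @param adjust `"none"` (raw p, default) or `"BH"`.
#' @param period_grid,phase_step Passed to the test.
#' @return Object of class `predictor_gene_set`: `genes` (ordered ids),
#'   `core_included`, and `statistics` (the full rhythm table).
#' @export
select_predictor_genes <- function(matrix, method = c("jtk", "ls"),
                                   alpha = 0.05, n_top = 10,
                                   adjust = c("none", "BH"),
                                   period_grid = NULL, phase_step = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stats_tab <- rhythm_statistics(matrix, method, period_grid, phase_step)
  p_use <- if (adjust == "BH") stats_tab$q_value else stats_tab$p_value
  pass <- !is.na(stats_tab$best_period) &
    abs(stats_tab$best_period - 24) < 1e-6 & p_use < alpha
  hits <- stats_tab[pass, , drop = FALSE]
  ord <- order(hits$p_value, -hits$amplitude, hits$gene_id)
  hits <- hits[ord, , drop = FALSE]
  top <- utils::head(hits$gene_id, n_top)
  is_core <- canonical_symbol(hits$gene_id) %in% canonical_symbol(core_clock_genes())
  core_pass <- hits$gene_id[is_core]
  genes <- c(top, setdiff(core_pass, top))
  if (length(genes) < 2)
    stop("insufficient rhythmic genes: only ", length(genes),
         " passed the significance and 24-h period filters")
  structure(list(genes = genes, core_included = core_pass,
                 statistics = stats_tab),
            class = "predictor_gene_set")
}

#' @export
print.predictor_gene_set <- function(x, ...) {
  cat(sprintf("predictor_gene_set: %d genes (%d core clock)\n",
              length(x$genes), length(x$core_included)))
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Bin rhythmic genes by peak phase
#'
#' Quarter-day bins on Zeitgeber time: day ZT[3,9), evening ZT[9,15),
#' night ZT[15,21), morning ZT[21,24) and [0,3).
#'
#' @param peak_phase Numeric hours in [0, 24), or a data frame with a
#'   `peak_phase` column (e.g. from [rhythm_statistics()]).
#' @return Factor with levels day, evening, night, morning.
#' @export
bin_by_peak_phase <- function(peak_phase) {
  if (is.data.frame(peak_phase)) peak_phase <- peak_phase$peak_phase
  ph <- peak_phase %% 24
  out <- character(length(ph))
  out[ph >= 3 & ph < 9] <- "day"
  out[ph >= 9 & ph < 15] <- "evening"
  out[ph >= 15 & ph < 21] <- "night"
  out[ph >= 21 | ph < 3] <- "morning"
  factor(out, levels = c("day", "evening", "night", "morning"))
}
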