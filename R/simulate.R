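#' Sinusoidal circadian expression
#'
#' `y = A * sin(2*pi/B * (x + C)) + D_shift`, the base waveform of the
#' single-cell simulators: amplitude `A`, period `B` hours, phase shift
#' `C` hours, vertical shift `D_shift` keeping expression positive.
#'
#' @param A Amplitude (expression units).
#' @param B Period in hours (default 24).
#' @param C Phase shift in hours.
#' @param D_shift Vertical shift (default 25).
#' @param x_grid Hours at which to evaluate (default integers 0..23).
#' @return Numeric vector, one value per element of `x_grid`.
#' @export
sine_expression <- function(A, B = 24, C = 0, D_shift = 25,
                            x_grid = 0:23) {
  if (B <= 0) stop("period B must be positive")
  A * sin(2 * pi / B * (x_grid + C)) + D_shift
}

#' Default base parameters for the simulated clock genes
#'
#' Synthetic amplitudes and phase shifts for the nine core clock genes
#' used by [simulate_group()]. These are plausible stand-in values
#' (amplitudes between 1 and 5, phases spread over the cycle), not
#' estimates from any real dataset, and can be overridden.
#'
#' @return Data frame with columns `gene`, `amplitude`, `phase`.
#' @export
default_clock_params <- function() {
  data.frame(
    gene = core_clock_genes(),
    amplitude = c(4.0, 5.0, 4.5, 3.0, 2.5, 3.5, 2.0, 1.5, 1.0),
    phase = c(0, 14, 16, 15, 10, 12, 11, 22, 20),
    stringsAsFactors = FALSE)
}

#' Simulate single-cell circadian expression under three noise scenarios
#'
#' Each cell expresses the base genes over hours 0..23 with one random
#' draw per gene per cell entering the waveform according to the group:
#' Group 1 (synchronized, dampened) multiplies the amplitude by a
#' Beta(1, 2) draw; Group 2 (robust, asynchronous) adds a Normal(0, 6)
#' draw to the phase; Group 3 (level-shifted) adds a Normal(0, 1) draw to
#' the vertical level. Period is 24 h and the vertical shift is 25
#' throughout; positivity of the simulated values is asserted after
#' generation.
#'
#' @param group 1, 2 or 3.
#' @param base_params Data frame with `gene`, `amplitude`, `phase`
#'   (default [default_clock_params()]).
#' @param n_cells Number of simulated cells (default 100).
#' @param seed Seed making the experiment reproducible.
#' @param D_shift Vertical shift (default 25).
#' @param x_grid Hours (default 0:23).
#' @return Object of class `simulated_sc_experiment`: `cells` (list of
#'   gene x hour matrices), `group`, `base_params`, `x_grid`, `seed`.
#' @export
simulate_group <- function(group, base_params = default_clock_params(),
                           n_cells = 100, seed = 1, D_shift = 25,
                           x_grid = 0:23) {
  if (!group %in% 1:3) stop("unknown group: ", group)
  set.seed(derive_seed(seed, "simulate_group", group))
  n_genes <- nrow(base_params)
  cells <- lapply(seq_len(n_cells), function(cell) {
    R <- switch(group,
                stats::rbeta(n_genes, 1, 2),
                stats::rnorm(n_genes, 0, 6),
                stats::rnorm(n_genes, 0, 1))
    m <- t(vapply(seq_len(n_genes), function(i) {
      A <- base_params$amplitude[i]
      C <- base_params$phase[i]
      switch(group,
             sine_expression(A * R[i], 24, C, D_shift, x_grid),
             sine_expression(A, 24, C + R[i], D_shift, x_grid),
             sine_expression(A, 24, C, D_shift + R[i], x_grid))
    }, numeric(length(x_grid))))
    rownames(m) <- base_params$gene
    colnames(m) <- as.character(x_grid)
    m
  })
  if (min(vapply(cells, min, 1)) < 0)
    stop("simulated expression went negative; increase D_shift")
  structure(list(cells = cells, group = group, base_params = base_params,
                 x_grid = x_grid, seed = seed),
            class = "simulated_sc_experiment")
}

#' Pseudobulk replicate sets from simulated single cells
#'
#' Draws `n_timepoints` distinct hours without replacement, then for each
#' experiment and hour builds `n_reps` pseudobulk replicates, each the
#' per-gene sum of `floor(frac * n_cells)` distinct cells (cells replaced
#' between replicates).
#'
#' @param experiments List of `simulated_sc_experiment` objects.
#' @param n_timepoints Number of distinct hours (default 6).
#' @param frac Fraction of cells per replicate (default 0.2).
#' @param n_reps Replicates per experiment per hour (default 500).
#' @param seed Master seed.
#' @return List with `timepoints` (hours) and `replicates`: per
#'   experiment, per hour, a genes x n_reps matrix of pseudobulk sums.
#' @export
heterogeneity_fixture <- function(experiments, n_timepoints = 6,
                                  frac = 0.2, n_reps = 500, seed = 1) {
  if (inherits(experiments, "simulated_sc_experiment"))
    experiments <- list(experiments)
  x_grid <- experiments[[1]]$x_grid
  set.seed(derive_seed(seed, "het_fixture", "timepoints"))
  tps <- sort(sample(x_grid, n_timepoints))
  replicates <- lapply(seq_along(experiments), function(e) {
    exp <- experiments[[e]]
    n_cells <- length(exp$cells)
    n_draw <- floor(frac * n_cells)
    genes <- rownames(exp$cells[[1]])
    # genes x cells expression at each chosen hour
    per_tp <- lapply(tps, function(tp) {
      col <- match(tp, exp$x_grid)
      cell_expr <- vapply(exp$cells, function(m) m[, col],
                          numeric(length(genes)))
      set.seed(derive_seed(seed, "het_fixture", e, tp))
      reps <- vapply(seq_len(n_reps), function(r) {
        sel <- sample.int(n_cells, n_draw)
        rowSums(cell_expr[, sel, drop = FALSE])
      }, numeric(length(genes)))
      rownames(reps) <- genes
      reps
    })
    names(per_tp) <- as.character(tps)
    per_tp
  })
  names(replicates) <- paste0("experiment", seq_along(experiments))
  list(timepoints = tps, replicates = replicates)
}

#' Simulate a bulk circadian time series
#'
#' Generic fixture generator for end-to-end tests: `n_rhythmic` genes
#' follow the sinusoid `A * sin(2*pi/24 * (t + C)) + D_shift` with random
#' amplitudes and phases plus Gaussian noise of standard deviation
#' `noise_sd * A`; the remaining genes are noisy constants. The nine core
#' clock gene names are included among the rhythmic genes so that
#' selection exercises the top-n + core-clock union rule.
#'
#' @param n_genes Total genes (default 100).
#' @param n_rhythmic Rhythmic genes, >= 9 and <= `n_genes` (default 20).
#' @param span Time span in hours (default 48).
#' @param interval Sampling interval in hours (default 2).
#' @param noise_sd Noise level as a fraction of each gene's amplitude
#'   (default 0.2).
#' @param seed Seed.
#' @param D_shift Vertical shift (default 25).
#' @return A [time_series_matrix()] with attribute `rhythmic_genes`.
#' @export
simulate_bulk_timeseries <- function(n_genes = 100, n_rhythmic = 20,
                                     span = 48, interval = 2,
                                     noise_sd = 0.2, seed = 1,
                                     D_shift = 25) {
  if (n_rhythmic > n_genes) stop("n_rhythmic must be <= n_genes")
  set.seed(derive_seed(seed, "simulate_bulk"))
  times <- seq(0, span, by = interval)
  core <- core_clock_genes()
  n_extra <- max(0, n_rhythmic - length(core))
  rhythmic <- c(utils::head(core, n_rhythmic),
                if (n_extra > 0) sprintf("Rhy%02d", seq_len(n_extra)))
  flat <- sprintf("Flat%03d", seq_len(n_genes - n_rhythmic))
  genes <- c(rhythmic, flat)
  vals <- matrix(0, n_genes, length(times))
  for (i in seq_along(rhythmic)) {
    A <- stats::runif(1, 1, 5)
    C <- stats::runif(1, 0, 24)
    vals[i, ] <- sine_expression(A, 24, C, D_shift, times) +
      stats::rnorm(length(times), 0, noise_sd * A)
  }
  for (i in seq_along(flat)) {
    level <- stats::runif(1, D_shift - 5, D_shift + 5)
    vals[length(rhythmic) + i, ] <-
      level + stats::rnorm(length(times), 0, noise_sd * mean(c(1, 5)))
  }
  vals[vals < 0] <- 0
  out <- time_series_matrix(vals, genes, times)
  attr(out, "rhythmic_genes") <- rhythmic
  out
}
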