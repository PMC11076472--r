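# Shared fixtures and independent oracles, built in code at test time.

# All permutations of 1..n (n <= 7), for brute-force JTK nulls.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = pos)
  }
  out
}

# Brute-force exhaustive-permutation p-value for the Kendall S statistic
# against one reference candidate; the independent oracle for jtk_exact_p.
brute_force_jtk_p <- function(series, times, period, phase,
                              perms = all_permutations(length(series))) {
  ref <- taufisher:::jtk_reference(times, period, phase)
  rs <- taufisher:::pair_signs(ref)
  s_obs <- sum(taufisher:::pair_signs(series) * rs)
  s_all <- vapply(perms,
                  function(p) sum(taufisher:::pair_signs(p) * rs), numeric(1))
  mean(abs(s_all) >= abs(s_obs))
}

# Noise-free bulk series of the nine simulated clock genes, hourly over a
# day: the reference training data for heterogeneity tests.
clock_reference_matrix <- function() {
  bp <- default_clock_params()
  vals <- t(vapply(seq_len(nrow(bp)), function(i)
    sine_expression(bp$amplitude[i], 24, bp$phase[i], 25, 0:23),
    numeric(24)))
  time_series_matrix(vals, bp$gene, 0:23)
}

# Cached reference predictor shared across heterogeneity/bootstrap tests.
clock_reference_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      bp <- default_clock_params()
      model <<- train_taufisher(clock_reference_matrix(), genes = bp$gene)
    }
    model
  }
})

# Tiny deterministic cell_matrix: `n_per` cells per (type, sample), counts
# drawn from the simulators' sinusoids rounded to integers.
toy_cell_matrix <- function(n_per = 12, types = c("fibroblast", "immune"),
                            samples = c(ZT0 = 0, ZT6 = 6), seed = 1) {
  set.seed(seed)
  bp <- default_clock_params()
  cols <- list(); cell_labels <- character(); sample_labels <- character()
  for (sm in names(samples)) {
    for (ty in types) {
      for (i in seq_len(n_per)) {
        mu <- sine_expression(bp$amplitude, 24, bp$phase, 25, samples[[sm]])
        cols[[length(cols) + 1]] <- rpois(length(mu), mu)
        cell_labels <- c(cell_labels, ty)
        sample_labels <- c(sample_labels, sm)
      }
    }
  }
  cell_matrix(do.call(cbind, cols), bp$gene, cell_labels, sample_labels,
              samples)
}
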