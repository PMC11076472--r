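test_that("a noiseless 24-h cosine is detected at its period and phase", {
  tt <- seq(0, 46, 2)
  r <- jtk_test(cos(2 * pi * (tt - 8) / 24), tt)
  expect_equal(r$best_period, 24)
  expect_equal(r$peak_phase, 8)
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$method, "JTK")
})

test_that("constant series are never rhythmic", {
  r <- jtk_test(rep(3, 24), seq(0, 46, 2))
  expect_equal(r$p_value, 1)
  expect_equal(r$amplitude, 0)
  expect_equal(r$peak_phase, 0)
  r2 <- lomb_scargle_test(rep(3, 24), seq(0, 46, 2))
  expect_equal(r2$p_value, 1)
})

test_that("the exact JTK p-value matches exhaustive permutation enumeration", {
  # the fixed n = 6 case against a tied reference (period 6, phase 0)
  ex <- jtk_exact_p(c(3, 1, 2, 6, 5, 4), 0:5, 6, 0)
  expect_equal(ex$p, brute_force_jtk_p(c(3, 1, 2, 6, 5, 4), 0:5, 6, 0))
  # random series and candidates, n = 4..6
  set.seed(101)
  perms <- lapply(4:6, all_permutations)
  for (i in 1:25) {
    n <- sample(4:6, 1)
    tt <- sort(runif(n, 0, 24))
    y <- rnorm(n)
    per <- sample(c(6, 12, 24), 1)
    ph <- runif(1, 0, per)
    expect_equal(jtk_exact_p(y, tt, per, ph)$p,
                 brute_force_jtk_p(y, tt, per, ph, perms[[n - 3]]),
                 tolerance = 1e-12)
  }
})

test_that("JTK is exactly invariant to monotone affine transforms", {
  set.seed(7)
  tt <- seq(0, 44, 4)
  y <- sin(2 * pi * tt / 24) + rnorm(length(tt), 0, 0.3)
  a <- jtk_test(y, tt)
  b <- jtk_test(3 * y + 10, tt)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$best_period, b$best_period)
  expect_identical(a$peak_phase, b$peak_phase)
})

test_that("Lomb-Scargle finds the dominant period and keeps type-I error", {
  tt <- seq(0, 46, 2)
  r <- lomb_scargle_test(sin(2 * pi * tt / 24), tt)
  expect_equal(r$best_period, 24)
  expect_lt(r$p_value, 1e-4)
  # 24-h dominant over a 12-h harmonic (3 full cycles avoid leakage)
  tt3 <- seq(0, 70, 2)
  r2 <- lomb_scargle_test(sin(2 * pi * tt3 / 24) + 0.5 * sin(2 * pi * tt3 / 12),
                          tt3)
  expect_equal(r2$best_period, 24)
  # positive scaling leaves the result unchanged (variance-normalized)
  y <- sin(2 * pi * tt / 24) + c(0.2, -0.1)
  expect_equal(lomb_scargle_test(5 * y + 2, tt)$p_value,
               lomb_scargle_test(y, tt)$p_value, tolerance = 1e-9)
})

test_that("white-noise false-positive rate is near the nominal level", {
  set.seed(11)
  tt <- seq(0, 46, 2)
  freqs <- (1:11) / 48  # natural (independent) frequencies of the window
  rej <- mean(replicate(1000,
    lomb_scargle_test(rnorm(length(tt)), tt, freqs)$p_value < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("selection keeps significant 24-h genes and unions core clock", {
  # 10 planted rhythmic + 90 flat, no core-clock names
  set.seed(3)
  tt <- seq(0, 46, 2)
  vals <- rbind(
    t(vapply(1:10, function(i)
      sine_expression(3, 24, runif(1, 0, 24), 25, tt) +
        rnorm(length(tt), 0, 0.2), numeric(length(tt)))),
    matrix(25 + rnorm(90 * length(tt), 0, 0.5), 90))
  genes <- c(sprintf("R%02d", 1:10), sprintf("F%02d", 1:90))
  sel <- select_predictor_genes(time_series_matrix(vals, genes, tt))
  expect_setequal(sel$genes, sprintf("R%02d", 1:10))
  # 9 rhythmic core-clock + 10 stronger non-core rhythmic genes -> 19
  # selected: the noiseless non-core genes are perfectly concordant and
  # occupy the top-10, the noisier core genes join through the union rule
  vals2 <- rbind(
    t(vapply(1:9, function(i)
      sine_expression(2, 24, (i * 24) / 9, 25, tt) +
        rnorm(length(tt), 0, 0.3), numeric(length(tt)))),
    t(vapply(1:10, function(i)
      sine_expression(4, 24, (i * 24) / 10, 25, tt),
      numeric(length(tt)))),
    matrix(25 + rnorm(40 * length(tt), 0, 0.5), 40))
  genes2 <- c(core_clock_genes(), sprintf("R%02d", 1:10), sprintf("F%02d", 1:40))
  sel2 <- select_predictor_genes(time_series_matrix(vals2, genes2, tt))
  expect_length(sel2$genes, 19)
  expect_true(all(core_clock_genes() %in% sel2$genes))
  # core-clock matching is alias- and case-aware (Arntl == Bmal1)
  genes3 <- sub("Bmal1", "ARNTL", genes2)
  sel3 <- select_predictor_genes(time_series_matrix(vals2, genes3, tt))
  expect_true("ARNTL" %in% sel3$core_included)
})

test_that("selection is deterministic and errors without rhythmic genes", {
  mat <- simulate_bulk_timeseries(50, 15, 48, 2, 0.2, seed = 21)
  s1 <- select_predictor_genes(mat)
  s2 <- select_predictor_genes(mat)
  expect_identical(s1$genes, s2$genes)
  flat <- time_series_matrix(matrix(25 + rnorm(100, 0, 0.1), 5),
                             paste0("F", 1:5), seq(0, 38, 2))
  expect_error(select_predictor_genes(flat), "insufficient rhythmic genes")
})

test_that("peak phases map to quarter-day bins that partition the cycle", {
  expect_equal(as.character(bin_by_peak_phase(4)), "day")
  expect_equal(as.character(bin_by_peak_phase(9)), "evening")
  expect_equal(as.character(bin_by_peak_phase(23.5)), "morning")
  ph <- seq(0, 23.9, by = 0.1)
  bins <- bin_by_peak_phase(ph)
  expect_false(anyNA(bins))
  expect_setequal(levels(bins), c("day", "evening", "night", "morning"))
})
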