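test_that("wrapped differences follow the three branches", {
  expect_equal(circular_error(23, 1), -2)
  expect_equal(circular_error(1, 23), 2)
  expect_equal(circular_error(6, 18), -12)
  expect_equal(circular_error(18, 6), 12)
  expect_equal(circular_error(5, 5), 0)
})

test_that("all integer hour pairs wrap into [-12, 12] antisymmetrically", {
  grid <- expand.grid(pred = 0:23, true = 0:23)
  D <- circular_error(grid$pred, grid$true)
  expect_true(all(D >= -12 & D <= 12))
  d <- grid$pred - grid$true
  expect_equal(abs(D), pmin(abs(d) %% 24, 24 - abs(d) %% 24))
  rev_D <- circular_error(grid$true, grid$pred)
  off_boundary <- abs(D) != 12
  expect_equal(D[off_boundary], -rev_D[off_boundary])
  expect_equal(abs(D[!off_boundary]), abs(rev_D[!off_boundary]))
})

test_that("scoring computes accuracy within the window and circular RMSE", {
  sc <- score_predictions(c(0, 2), c(23, 1))
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$rmse, 1)
  sc2 <- score_predictions(0:23, (0:23 + 12) %% 24)
  expect_equal(sc2$accuracy, 0)
  expect_equal(sc2$rmse, 12)
  expect_equal(score_predictions(0:5, 0:5, window = 0)$accuracy, 1)
  # rmse invariant to relabeling pred <-> true
  set.seed(1)
  p <- runif(50, 0, 24); t <- runif(50, 0, 24)
  expect_equal(score_predictions(p, t)$rmse, score_predictions(t, p)$rmse)
  expect_error(score_predictions(numeric(0), numeric(0)), "empty")
})

test_that("circular mean and SD behave at the landmarks", {
  m <- circular_mean_sd(c(23, 1))
  expect_equal(m$mean, 0)
  m2 <- circular_mean_sd(rep(7.5, 10))
  expect_equal(m2$mean, 7.5)
  expect_equal(m2$sd, 0)
  m3 <- circular_mean_sd(c(0, 6, 12, 18))
  expect_false(m3$mean_defined)
  expect_equal(m3$sd, Inf)
})

test_that("the circular mean minimizes mean angular dissimilarity", {
  # the resultant direction minimizes mean(1 - cos(angular distance));
  # a brute-force grid search must land on the same hour. On concentrated
  # samples it also tracks the squared-distance minimizer closely.
  set.seed(5)
  for (i in 1:10) {
    h <- rvonmises_hours(40, runif(1, 0, 24), runif(1, 0.5, 4))
    grid <- seq(0, 23.995, by = 0.005)
    obj <- vapply(grid, function(g)
      mean(1 - cos((h - g) * pi / 12)), numeric(1))
    expect_lt(abs(circular_error(circular_mean_sd(h)$mean,
                                 grid[which.min(obj)])), 0.01)
  }
  for (i in 1:5) {
    h <- rvonmises_hours(60, runif(1, 0, 24), 6)
    grid <- seq(0, 23.995, by = 0.005)
    obj2 <- vapply(grid, function(g)
      mean(circular_error(h, g)^2), numeric(1))
    expect_lt(abs(circular_error(circular_mean_sd(h)$mean,
                                 grid[which.min(obj2)])), 0.2)
  }
})

test_that("Rao homogeneity separates shifted means and accepts the null", {
  set.seed(6)
  g <- rvonmises_hours(200, 8, 2)
  same <- rao_homogeneity_test(list(g, g))
  expect_gt(same$p_mean, 0.99)
  expect_gt(same$p_dispersion, 0.99)
  # opposite means, tight dispersion
  shifted <- rao_homogeneity_test(list(rvonmises_hours(100, 0, 4),
                                       rvonmises_hours(100, 12, 4)))
  expect_lt(shifted$p_mean, 0.01)
  # rotation invariance
  g1 <- rvonmises_hours(50, 3, 2); g2 <- rvonmises_hours(50, 9, 3)
  a <- rao_homogeneity_test(list(g1, g2))
  b <- rao_homogeneity_test(list((g1 + 5.5) %% 24, (g2 + 5.5) %% 24))
  expect_equal(a$statistic_mean, b$statistic_mean, tolerance = 1e-9)
  expect_equal(a$statistic_dispersion, b$statistic_dispersion,
               tolerance = 1e-9)
  # degenerate group flagged
  deg <- rao_homogeneity_test(list(rep(3, 5), g1))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_mean))
})

test_that("Wallraff test detects dispersion differences only", {
  set.seed(8)
  conc <- rvonmises_hours(100, 6, 8)
  disp <- rvonmises_hours(100, 6, 0.3)
  expect_lt(wallraff_test(list(conc, disp))$p, 0.01)
  # two constant groups at different hours: no dispersion difference
  expect_equal(wallraff_test(list(rep(3, 20), rep(15, 20)))$p, 1)
  # rotation invariance
  a <- wallraff_test(list(conc, disp))$p
  b <- wallraff_test(list((conc + 4) %% 24, (disp + 4) %% 24))$p
  expect_equal(a, b, tolerance = 1e-9)
  # three groups route through Kruskal-Wallis
  expect_true(is.numeric(
    wallraff_test(list(conc, disp, rvonmises_hours(50, 2, 1)))$p))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  background <- paste0("g", 1:20)
  target <- background[1:4]
  hits <- c(background[1:3], background[10:11])
  got <- hypergeometric_enrichment(hits, target, background)
  # oracle: enumerate all 5-subsets of the background
  subsets <- combn(20, 5)
  overlaps <- colSums(subsets <= 4)
  expect_equal(got$p, mean(overlaps >= 3))
  expect_equal(got$ratio, 3 / (5 * 4 / 20))
  # degenerate identities
  all_eq <- hypergeometric_enrichment(background, background, background)
  expect_equal(all_eq$p, 1)
  expect_equal(all_eq$ratio, 1)
  none <- hypergeometric_enrichment(background[1:5], background[6:10],
                                    background)
  expect_equal(none$p, 1)
  expect_error(hypergeometric_enrichment("x", "y", character(0)), "background")
})
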