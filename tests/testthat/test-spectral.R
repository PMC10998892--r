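test_that("total power matches a brute-force discrete-transform oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(32:200, 1)
    tr <- sample(c(2.1, 2.4), 1)
    x <- rnorm(n)
    sp <- compute_power_spectrum(bold_series(x, tr), exclude_dc = FALSE)
    oracle <- naive_dft_power(x, tr)
    expect_equal(sp$total_power, sum(oracle$squared),
                 tolerance = 1e-9)
    expect_equal(sp$frequencies, oracle$frequencies, tolerance = 1e-12)
    expect_equal(sp$squared_amplitudes, oracle$squared, tolerance = 1e-6)
  }
})

test_that("constant series is degenerate and rejected downstream", {
  sp <- compute_power_spectrum(bold_series(rep(3, 50), 2.1))
  expect_true(sp$degenerate)
  expect_equal(sp$total_power, 0, tolerance = 1e-20)
  expect_error(binned_power_distribution(sp), class = "dasnet_data_error")
  expect_error(cumulative_power(sp), class = "dasnet_data_error")
})

test_that("a single on-grid sinusoid concentrates power at its frequency", {
  n <- 128; tr <- 2.1; k <- 10
  x <- sin(2 * pi * k * (0:(n - 1)) / n)
  sp <- compute_power_spectrum(bold_series(x, tr))
  peak <- which.max(sp$squared_amplitudes)
  expect_equal(sp$frequencies[peak], k / (n * tr), tolerance = 1e-12)
  expect_lt(sum(sp$squared_amplitudes[-peak]) / sp$total_power, 1e-20)
})

test_that("binned power distributes two equal components as expected", {
  n <- 200; tr <- 2
  x <- sin(2 * pi * 10 * (0:(n - 1)) / n) + sin(2 * pi * 12 * (0:(n - 1)) / n)
  sp <- compute_power_spectrum(bold_series(x, tr))
  wide <- binned_power_distribution(sp, delta_omega = sp$nyquist)
  expect_equal(sum(wide$percentages), 100, tolerance = 1e-6)
  expect_equal(max(wide$percentages), 100, tolerance = 1e-6)
  # narrow bins that split the two components: 50 / 50
  narrow <- binned_power_distribution(sp, delta_omega = 1.5 / (n * tr))
  occupied <- narrow$percentages[narrow$percentages > 1e-9]
  expect_equal(unname(occupied), c(50, 50), tolerance = 1e-6)
})

test_that("binned power equals a direct per-bin summation oracle", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(150)
    sp <- compute_power_spectrum(bold_series(x, 2.1))
    dw <- runif(1, 0.01, 0.1)
    bp <- binned_power_distribution(sp, delta_omega = dw)
    oracle <- vapply(seq_along(bp$percentages), function(b) {
      inb <- sp$frequencies > (b - 1) * dw + 1e-12 & sp$frequencies <= b * dw + 1e-12
      sum(sp$squared_amplitudes[inb]) / sp$total_power * 100
    }, numeric(1))
    expect_equal(bp$percentages, oracle, tolerance = 1e-9)
    expect_equal(sum(bp$percentages), 100, tolerance = 1e-6)
  }
})

test_that("bin width selection puts roughly the target power in the first bin", {
  set.seed(11)
  x <- rnorm(183)
  sp <- compute_power_spectrum(bold_series(x, 2.1))
  bp <- binned_power_distribution(sp, target_first_bin_pct = 10)
  first_occ <- bp$percentages[bp$percentages > 0][1]
  expect_gt(first_occ, 4); expect_lt(first_occ, 25)
  ep <- binned_power_distribution(sp, method = "equal_power")
  expect_equal(sum(ep$percentages), 100, tolerance = 1e-6)
  expect_true(all(abs(ep$percentages[-length(ep$percentages)] - 10) < 10))
})

test_that("cumulative power equals a prefix-sum oracle and ends at 100", {
  set.seed(5)
  x <- rnorm(120)
  sp <- compute_power_spectrum(bold_series(x, 2.4))
  cp <- cumulative_power(sp, "full")
  oracle <- vapply(cp$thresholds, function(th) {
    100 * sum(sp$squared_amplitudes[sp$frequencies <= th + 1e-12]) / sp$total_power
  }, numeric(1))
  expect_equal(cp$cumulative_pct, oracle, tolerance = 1e-9)
  expect_true(all(diff(cp$cumulative_pct) >= -1e-12))
  expect_equal(cp$cumulative_pct[length(cp$cumulative_pct)], 100,
               tolerance = 1e-6)
  dec <- cumulative_power(sp, "deciles")
  expect_length(dec$thresholds, 10)
  expect_equal(dec$cumulative_pct[10], 100, tolerance = 1e-6)
  expect_error(cumulative_power(sp, c(0.2, 0.1)), class = "dasnet_config_error")
})

test_that("a sinusoid's cumulative power is a step at its frequency", {
  n <- 100; tr <- 2.1; k <- 25
  x <- sin(2 * pi * k * (0:(n - 1)) / n)
  cp <- cumulative_power(compute_power_spectrum(bold_series(x, tr)), "full")
  f0 <- k / (n * tr)
  expect_true(all(cp$cumulative_pct[cp$thresholds < f0 - 1e-9] < 1e-9))
  expect_true(all(abs(cp$cumulative_pct[cp$thresholds >= f0] - 100) < 1e-9))
})

test_that("harmonization pads, truncates and matches durations", {
  a <- bold_series(rnorm(100), 2.1)
  b <- bold_series(rnorm(120), 2.1)
  h <- harmonize_pair(a, b)
  expect_length(h$a$values, 120)
  expect_equal(h$a$values[101:120], rep(0, 20))
  expect_true(h$common_grid)

  same <- harmonize_pair(a, a)
  expect_equal(same$a$values, a$values)
  expect_equal(same$b$values, a$values)

  p <- bold_series(rnorm(183), 2.1)
  q <- bold_series(rnorm(160), 2.4)
  h2 <- harmonize_pair(p, q)
  da <- length(h2$a$values) * 2.1
  db <- length(h2$b$values) * 2.4
  expect_lt(abs(da - db), 2.4)
  expect_false(h2$common_grid)
})

test_that("DAS is zero on identical curves and antisymmetric", {
  grid <- seq(0, 0.25, length.out = 90)
  for (i in 1:25) {
    ci <- random_cp(grid, seed = i)
    cj <- random_cp(grid, seed = 1000 + i)
    expect_equal(das(ci, ci)$value, 0, tolerance = 1e-12)
    expect_equal(das(ci, cj)$value, -das(cj, ci)$value, tolerance = 1e-10)
  }
})

test_that("DAS between two pure sinusoids matches the closed form", {
  n <- 200; tr <- 2; k1 <- 5; k2 <- 20
  mk <- function(k) bold_series(sin(2 * pi * k * (0:(n - 1)) / n), tr)
  cp1 <- cumulative_power(compute_power_spectrum(mk(k1)), "full")
  cp2 <- cumulative_power(compute_power_spectrum(mk(k2)), "full")
  f1 <- k1 / (n * tr); f2 <- k2 / (n * tr); fn <- 1 / (2 * tr)
  expect_equal(das(cp1, cp2)$value, 100 * (f2 - f1) / fn, tolerance = 1e-9)
})

test_that("DAS is additive along a chain on a common grid", {
  grid <- seq(0, 0.2, length.out = 60)
  a <- random_cp(grid, 1); b <- random_cp(grid, 2); c <- random_cp(grid, 3)
  expect_equal(das(a, c)$raw_area,
               das(a, b)$raw_area + das(b, c)$raw_area, tolerance = 1e-9)
})

test_that("DAS rejects non-overlapping grids and interpolates differing ones", {
  a <- random_cp(seq(0, 0.1, length.out = 30), 1)
  b <- random_cp(seq(0.2, 0.3, length.out = 30), 2)
  expect_error(das(a, b), class = "dasnet_data_error")
  c1 <- random_cp(seq(0, 0.2, length.out = 41), 3)
  c2 <- random_cp(seq(0, 0.2, length.out = 61), 4)
  expect_s3_class(das(c1, c2), "das_score")
})

test_that("signed and absolute DAS aggregation are not interchangeable", {
  expect_equal(aggregate_das(c(1, -1))$mean, 0)
  expect_equal(aggregate_das(c(1, -1), absolute = TRUE)$mean, 1)
  agg <- aggregate_das(c(2, -4, 6), absolute = TRUE)
  expect_equal(agg$mean, 4)
  expect_equal(agg$sem, sd(c(2, 4, 6)) / sqrt(3))
  expect_error(aggregate_das(numeric(0)), class = "dasnet_config_error")
})

test_that("autocorrelation is unit at lag zero and bounded for white noise", {
  set.seed(9)
  s <- bold_series(rnorm(1e4), 2.1)
  acf_vals <- autocorrelation(s, 10)
  expect_equal(acf_vals[1], 1)
  expect_true(all(abs(acf_vals[-1]) < 4 / sqrt(1e4)))
})

test_that("autocorrelation returns to one at an on-grid sinusoid's period", {
  P <- 20; n <- 1000
  s <- bold_series(sin(2 * pi * (0:(n - 1)) / P), 2.1)
  acf_vals <- autocorrelation(s, P)
  expect_equal(acf_vals[P + 1], 1, tolerance = 1e-6)
  expect_error(autocorrelation(bold_series(rep(1, 50), 2.1), 5),
               class = "dasnet_data_error")
})
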