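test_that("histograms match naive per-sample binning and the edge convention", {
  set.seed(41)
  w <- tibble::tibble(index = 0:1, center = c(-0.2, 0.2), force_constant = 10,
                      n_equil_samples = 0L, n_prod_samples = 100L,
                      sample_interval = 5)
  series <- tibble::tibble(
    window_index = rep(0:1, each = 500),
    xi = c(rnorm(500, -0.2, 0.3), rnorm(500, 0.2, 0.3))
  )
  h <- histogram_windows(series, w, bin_width = 0.1, range = c(-1, 1))
  # naive oracle
  breaks <- seq(-1, 1, by = 0.1)
  for (i in 1:2) {
    v <- series$xi[series$window_index == i - 1]
    naive <- vapply(seq_len(length(breaks) - 1), function(b) {
      sum(v >= breaks[b] & v < breaks[b + 1])
    }, numeric(1))
    expect_equal(unname(h$counts[i, ]), naive)
  }
  expect_equal(rowSums(h$counts), h$n_total)
  expect_equal(h$n_outside,
               vapply(0:1, function(i) sum(series$xi[series$window_index == i] < -1 |
                                             series$xi[series$window_index == i] >= 1),
                      numeric(1)), ignore_attr = TRUE)

  # a value exactly on an edge belongs to the bin on its right
  s1 <- tibble::tibble(window_index = 0L, xi = rep(0.1, 10))
  h1 <- histogram_windows(s1, w[1, ], bin_width = 0.1, range = c(0, 0.3))
  expect_equal(unname(h1$counts[1, ]), c(0, 10, 0))

  # identical values land in one bin
  s2 <- tibble::tibble(window_index = 0L, xi = rep(0.05, 10))
  h2 <- histogram_windows(s2, w[1, ], bin_width = 0.1, range = c(0, 0.3))
  expect_equal(max(h2$counts), 10)
  expect_equal(sum(h2$counts), 10)
})

test_that("a window with no in-range samples is reported by name", {
  w <- tibble::tibble(index = 0:1, center = c(0, 5), force_constant = 10,
                      n_equil_samples = 0L, n_prod_samples = 10L,
                      sample_interval = 5)
  series <- tibble::tibble(window_index = rep(0:1, each = 10),
                           xi = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)))
  err <- expect_error(
    histogram_windows(series, w, bin_width = 0.1, range = c(-1, 1)),
    class = "chiralpmf_value_error")
  expect_match(conditionMessage(err), "window index 1")
})

test_that("an unbiased Gaussian sample recovers its quadratic free energy", {
  # independent of the Langevin path: samples drawn directly from the
  # stationary law of G(x) = c/2 x^2
  set.seed(47)
  curv <- 2
  kT <- thermal_energy(300)
  sigma <- sqrt(kT / curv)
  n <- 50000
  w <- tibble::tibble(index = 0L, center = 0, force_constant = 0,
                      n_equil_samples = 0L, n_prod_samples = n,
                      sample_interval = 5)
  series <- tibble::tibble(window_index = 0L, xi = rnorm(n, 0, sigma))
  fit <- solve_wham(series, w, bin_width = 0.02, anchor_below = Inf)
  prof <- tidy(fit)
  prof <- prof[is.finite(prof$pmf) & prof$counts > 30, ]
  qfit <- stats::lm(pmf ~ I(bin_center^2), data = prof, weights = prof$counts)
  expect_equal(2 * unname(coef(qfit)[2]), curv, tolerance = 0.10)
  expect_true(fit$converged)
})

test_that("feeding the same campaign twice leaves the profile unchanged", {
  # duplicating every window's data duplicates both numerator and
  # denominator of the WHAM equations, so the estimate must not move
  sc <- small_campaign(n_samples = 400, seed = 51)
  fit1 <- solve_wham(sc$campaign, sc$windows, bin_width = 0.05)
  w2 <- dplyr::bind_rows(sc$windows,
                         dplyr::mutate(sc$windows, index = index + 100L))
  camp2 <- dplyr::bind_rows(
    sc$campaign,
    dplyr::mutate(sc$campaign, window_index = window_index + 100L)
  )
  fit2 <- solve_wham(camp2, w2, bin_width = 0.05, range = fit1$config$range)
  expect_equal(fit2$profile$pmf, fit1$profile$pmf, tolerance = 1e-10)
})

test_that("the anchored profile is gauge invariant under constant bias shifts", {
  sc <- small_campaign(n_samples = 400, seed = 52)
  fit1 <- solve_wham(sc$campaign, sc$windows, bin_width = 0.05)
  w_shift <- dplyr::mutate(sc$windows, bias_offset = 7.3)
  fit2 <- solve_wham(sc$campaign, w_shift, bin_width = 0.05,
                     range = fit1$config$range)
  expect_equal(fit2$profile$pmf, fit1$profile$pmf, tolerance = 1e-9)
})

test_that("the converged estimate is a fixpoint of both WHAM equations", {
  sc <- small_campaign(n_samples = 400, seed = 53)
  fit <- solve_wham(sc$campaign, sc$windows, bin_width = 0.05)
  h <- fit$histogram
  kT <- thermal_energy(300)
  bias <- chiralpmf:::.window_bias_matrix(sc$windows, h$bin_centers, "half_k")
  f <- fit$window_free_energies$f
  denom <- colSums(h$n_total * exp(f / kT) * exp(-bias / kT))
  p <- colSums(h$counts) / denom
  f_back <- -kT * log(exp(-bias / kT) %*% ifelse(is.finite(p) & colSums(h$counts) > 0, p, 0))
  f_back <- as.numeric(f_back - f_back[1])
  expect_equal(f_back, f, tolerance = 1e-6)
  # and the anchored PMF is -kT log of the direct P equation, up to scale
  occ <- colSums(h$counts) > 0
  ratio <- p[occ] / exp(-fit$profile$pmf[occ] / kT)
  expect_lt(diff(range(log(ratio))), 1e-8)
})

test_that("scaling temperature and energies together leaves PMF/kBT unchanged", {
  sc <- small_campaign(n_samples = 300, seed = 54)
  fit1 <- solve_wham(sc$campaign, sc$windows, bin_width = 0.05)
  w2 <- dplyr::mutate(sc$windows, force_constant = force_constant * 2)
  # the f-increment tolerance is an energy, so it scales with the energies
  fit2 <- solve_wham(sc$campaign, w2, bin_width = 0.05, temperature = 600,
                     range = fit1$config$range, tolerance = 2e-7)
  expect_equal(fit2$profile$pmf / thermal_energy(600),
               fit1$profile$pmf / thermal_energy(300), tolerance = 1e-9)
})

test_that("the histogram estimate agrees with a binless MBAR-style oracle", {
  sc <- small_campaign(n_samples = 800, seed = 55)
  fit <- solve_wham(sc$campaign, sc$windows, bin_width = 0.05,
                    anchor_below = Inf)
  vals <- split(sc$campaign$xi, sc$campaign$window_index)
  h <- fit$histogram
  orc <- mbar_oracle_pmf(vals, sc$windows, thermal_energy(300), h$breaks)
  keep <- fit$profile$counts > 100 & is.finite(fit$profile$pmf)
  est <- fit$profile$pmf[keep]
  ref <- orc$pmf[keep]
  ref <- ref - (mean(ref) - mean(est))  # common gauge
  expect_lt(max(abs(est - ref)), 0.1)
})

test_that("degenerate inputs raise errors and warnings honestly", {
  w <- tibble::tibble(index = 0L, center = 0, force_constant = 10,
                      n_equil_samples = 0L, n_prod_samples = 10L,
                      sample_interval = 5)
  series <- tibble::tibble(window_index = 0L, xi = rnorm(10))
  expect_error(solve_wham(series[0, ], w), class = "chiralpmf_value_error")
  w_two <- tibble::tibble(index = 0:1, center = c(-0.2, 0.2),
                          force_constant = 10, n_equil_samples = 0L,
                          n_prod_samples = 200L, sample_interval = 5)
  s_two <- tibble::tibble(window_index = rep(0:1, each = 200),
                          xi = c(rnorm(200, -0.2, 0.2), rnorm(200, 0.2, 0.2)))
  expect_warning(
    solve_wham(s_two, w_two, max_iterations = 1, bin_width = 0.05),
    "did not converge")
  # disconnected windows warn about missing overlap
  w2 <- tibble::tibble(index = 0:1, center = c(-3, 3), force_constant = 500,
                       n_equil_samples = 0L, n_prod_samples = 50L,
                       sample_interval = 5)
  s2 <- tibble::tibble(window_index = rep(0:1, each = 50),
                       xi = c(rnorm(50, -3, 0.03), rnorm(50, 3, 0.03)))
  expect_warning(solve_wham(s2, w2, bin_width = 0.05), "no occupied bins")
})
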