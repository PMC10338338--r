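test_that("clock distributions are fitted on the log scale", {
  d <- fit_clock_distribution(rep(10, 6))
  expect_equal(d$median, 10)
  expect_equal(d$log_sd, 0)
  # geometric spacing: log-times are an arithmetic progression of step ln 2
  g <- fit_clock_distribution(c(5, 10, 20, 40, 80))
  expect_equal(g$median, 20)
  expect_equal(g$log_sd, log(2) * sd(0:4))
  expect_error(fit_clock_distribution(numeric(0)), "5 uncensored")
  expect_error(fit_clock_distribution(c(5, 10, 20)), "5 uncensored")
  e <- fit_clock_distribution(c(5, 6, 7, 8, 9), family = "EMPIRICAL")
  expect_equal(sort(e$sample), 5:9)
})

test_that("deterministic clock orderings resolve as specified (ties to mitosis)", {
  pm <- function(m) clock_distribution("LOGNORMAL", median = m, log_sd = 0)
  expect_equal(simulate_competition(pm(15), pm(11), n = 100, seed = 1)$exit_fraction, 0)
  expect_equal(simulate_competition(pm(11), pm(11), n = 100, seed = 1)$exit_fraction, 0)
  expect_equal(simulate_competition(pm(9), pm(11), n = 100, seed = 1)$exit_fraction, 1)
  out <- simulate_competition(pm(9), pm(11), n = 50, seed = 1)
  expect_equal(length(out$winner_times_exit) + length(out$winner_times_mitosis),
               out$n)
})

test_that("competition draws are reproducible and tidy/glance summarise them", {
  ex <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
  mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
  a <- simulate_competition(ex, mi, n = 500, seed = 42, keep_pairs = TRUE)
  b <- simulate_competition(ex, mi, n = 500, seed = 42, keep_pairs = TRUE)
  expect_identical(a$sampled_pairs, b$sampled_pairs)
  td <- tidy(a)
  expect_equal(nrow(td), 500)
  expect_setequal(unique(td$winner), c("EXIT", "MITOSIS"))
  gl <- glance(a)
  expect_equal(gl$exit_fraction, a$exit_fraction)
})

test_that("the analytic oracle matches known values and symmetry", {
  ex <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
  mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
  expect_equal(analytic_exit_probability(ex, mi), 0.1376, tolerance = 5e-4)
  same <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.3)
  expect_equal(analytic_exit_probability(same, mi_same <- same), 0.5)
  # degenerate dispersions: strict ordering decides, ties go to mitosis
  pm <- function(m) clock_distribution("LOGNORMAL", median = m, log_sd = 0)
  expect_equal(analytic_exit_probability(pm(15), pm(11)), 0)
  expect_equal(analytic_exit_probability(pm(11), pm(11)), 0)
  emp <- clock_distribution("EMPIRICAL", sample = c(5, 6, 7, 8, 9))
  expect_error(analytic_exit_probability(emp, mi), "LOGNORMAL")
})

test_that("Monte Carlo exit fractions agree with the analytic oracle within 3 binomial SEs", {
  grid <- list(c(15, 0.22, 11, 0.18), c(13, 0.3, 11, 0.3), c(11, 0.1, 12, 0.2))
  n <- 2e4
  for (g in grid) {
    ex <- clock_distribution("LOGNORMAL", median = g[1], log_sd = g[2])
    mi <- clock_distribution("LOGNORMAL", median = g[3], log_sd = g[4])
    p <- analytic_exit_probability(ex, mi)
    sim <- simulate_competition(ex, mi, n = n, seed = 7)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sim$exit_fraction - p), 3 * se)
  }
})

test_that("disabling one clock hands the win to the other fate", {
  fin <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
  inf <- clock_distribution("LOGNORMAL", median = Inf, log_sd = 0)
  expect_equal(simulate_competition(inf, fin, n = 500, seed = 1)$exit_fraction, 0)
  expect_equal(simulate_competition(fin, inf, n = 500, seed = 1)$exit_fraction, 1)
  expect_equal(analytic_exit_probability(inf, fin), 0)
  expect_equal(analytic_exit_probability(fin, inf), 1)
})

test_that("winner-side exit times show the competition selection effect", {
  ex <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
  mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
  sim <- simulate_competition(ex, mi, n = 5e4, seed = 3)
  # stochastically smaller than the pre-competition exit distribution:
  # its empirical CDF dominates the log-normal CDF
  qs <- c(8, 10, 12, 14)
  ecdf_w <- stats::ecdf(sim$winner_times_exit)
  for (q in qs) {
    expect_gte(ecdf_w(q), stats::plnorm(q, log(15), 0.22) - 0.02)
  }
  expect_lt(median(sim$winner_times_exit), 15)
})

test_that("post-competition KS comparison behaves at the extremes", {
  ex <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
  mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
  sim <- simulate_competition(ex, mi, n = 2000, seed = 5)
  self <- compare_post_competition(sim, sim$winner_times_exit, "EXIT")
  expect_equal(self$ks_statistic, 0)
  far <- compare_post_competition(sim, sim$winner_times_exit + 1000, "EXIT")
  expect_equal(far$ks_statistic, 1)
  expect_lt(far$p_value, 1e-6)
  expect_error(compare_post_competition(sim, numeric(0), "EXIT"), "non-empty")
})

test_that("null KS calibration: identical generating distributions give flat p-values", {
  ex <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
  mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
  ps <- vapply(1:20, function(s) {
    a <- simulate_competition(ex, mi, n = 3000, seed = s)
    b <- simulate_competition(ex, mi, n = 3000, seed = s + 1000)
    compare_post_competition(a, b$winner_times_exit, "EXIT")$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8) # expected ~0.95
})
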