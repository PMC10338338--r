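grid <- round(seq(0, 20, by = 0.2), 10)

test_that("S-entry detection needs a sustained APC/C drop", {
  # never inactivated
  tr <- make_trace(grid, apc = rep(1, length(grid)))
  expect_true(is.na(detect_s_entry(tr)))
  # clean step at t = 5
  tr <- make_trace(grid, apc = ifelse(grid < 5, 1, 0))
  expect_equal(detect_s_entry(tr), 5)
  # a one-frame blip at t = 3 is rejected; the real switch at t = 6 is kept
  apc <- ifelse(grid < 6, 1, 0)
  apc[grid == 3] <- 0.4
  tr <- make_trace(grid, apc = apc)
  expect_equal(detect_s_entry(tr), 6)
  expect_error(detect_s_entry(make_trace(grid)[, c("cell_id", "time_h", "cdk2")]),
               "apc")
})

test_that("mitosis detection prefers division events and falls back to CDK2 collapse", {
  # event channel: first division after treatment
  div <- integer(length(grid))
  div[grid == 18.2] <- 1L
  tr <- make_trace(grid, divided = div, treatment_time = 10)
  expect_equal(detect_mitosis(tr), 18.2)
  # collapse detector: climb to 1.3, one-frame fall to 0.3 at t = 20
  cdk2 <- 0.1 + 0.06 * grid
  cdk2[length(grid)] <- 0.3
  tr <- make_trace(grid, cdk2 = cdk2)
  expect_equal(detect_mitosis(tr), 20)
  # monotone rise, no division: nothing to report
  tr <- make_trace(grid, cdk2 = 0.1 + 0.06 * grid)
  expect_true(is.na(detect_mitosis(tr)))
})

test_that("exit detection interpolates the threshold crossing and respects divisions", {
  # constant high activity: no exit
  tr <- make_trace(grid, cdk2 = rep(0.9, length(grid)))
  expect_true(is.na(detect_exit(tr)))
  # linear ramp 1.0 at t = 10 to 0.2 at t = 14: crossing of 0.6 at t = 12
  cdk2 <- ifelse(grid < 10, 1, pmax(1 - 0.2 * (grid - 10), 0.2))
  tr <- make_trace(grid, cdk2 = cdk2, treatment_time = 8)
  expect_equal(detect_exit(tr), 12)
  # same ramp but the cell divided at t = 11: the low CDK2 is a daughter, not exit
  div <- integer(length(grid))
  div[grid == 11] <- 1L
  tr_div <- make_trace(grid, cdk2 = cdk2, divided = div, treatment_time = 8)
  expect_true(is.na(detect_exit(tr_div)))
  # crossing too close to the end of the recording is right-censored
  cdk2_late <- ifelse(grid < 19, 1, 0.2)
  tr_late <- make_trace(grid, cdk2 = cdk2_late, treatment_time = 8)
  expect_true(is.na(detect_exit(tr_late)))
})

test_that("landmarks recovered from noiseless traces match the generator truth", {
  p <- make_preset("MCF10A")
  for (lab in c("CDK46I", "DMSO", "CDK46I_CDK1I")) {
    tr <- generate_population(p, treatment_program(lab), n_cells = 40,
                              seed = 21, keep_truth = TRUE, noise = FALSE)
    truth <- attr(tr, "truth")
    fe <- classify_fates(tr)
    j <- dplyr::inner_join(fe, truth, by = "cell_id")
    j <- j[j$post_r_at_treatment, ]
    expect_true(all(abs(j$s_entry_time - j$s_entry) <= 0.2 + 1e-9))
    div <- !is.na(j$mitosis_time) & is.finite(j$mitosis_clock)
    expect_true(all(abs(j$mitosis_time[div] -
                          (12 + j$mitosis_clock[div])) <= 0.2 + 1e-9))
    ex <- !is.na(j$exit_time)
    expect_true(all(abs(j$exit_time[ex] -
                          (12 + j$exit_clock[ex])) <= 0.2 + 1e-9))
    expect_true(all(j$fate.x[ex] == "EXIT"))
  }
})

test_that("fates partition the post-R population and stay mutually exclusive", {
  tr <- generate_population(make_preset("MCF10A"), treatment_program("CDK46I"),
                            n_cells = 300, seed = 13)
  fe <- classify_fates(tr)
  pr <- fe[fe$post_r_at_treatment, ]
  expect_equal(sum(pr$fate %in% c("MITOSIS", "EXIT", "COMMITTED")), nrow(pr))
  # exclusivity encoded in the feature table
  expect_true(all(is.na(pr$exit_time[pr$fate == "MITOSIS"])))
  expect_true(all(is.na(pr$mitosis_time[pr$fate == "EXIT"])))
  # endpoints: exit without division is the G0-like 4N state; dividers under
  # mitogen blockade leave arrested daughters
  expect_true(all(pr$endpoint[pr$fate == "EXIT"] == "G0LIKE_4N"))
  expect_gt(mean(pr$endpoint[pr$fate == "MITOSIS"] == "G0_2N"), 0.9)
})

test_that("exit fraction declines with treatment offset from S entry", {
  tr <- generate_population(make_preset("MCF10A"), treatment_program("CDK46I"),
                            n_cells = 600, seed = 17)
  fe <- classify_fates(tr)
  bins <- exit_fraction_by_offset(fe, bin_width = 2)
  filled <- bins[bins$n > 0, ]
  expect_gte(nrow(filled), 3)
  expect_true(all(filled$fraction >= 0 & filled$fraction <= 1))
  # early bins exit more than late bins
  expect_gt(filled$fraction[1], filled$fraction[nrow(filled)])
})

test_that("offset binning handles edge cases", {
  all_exit <- make_features(offset = runif(30, 0, 6), fate = rep("EXIT", 30))
  b <- exit_fraction_by_offset(all_exit)
  expect_true(all(b$fraction[b$n > 0] == 1))
  empty <- exit_fraction_by_offset(make_features(numeric(0), character(0)))
  expect_equal(nrow(empty), 0)
  expect_error(exit_fraction_by_offset(all_exit, bin_width = -1), "positive")
})

test_that("the exit logistic fit flags degenerate data instead of fitting it", {
  # single-outcome population (vehicle-like: nothing exits)
  f <- make_features(offset = runif(50, 0, 6), fate = rep("MITOSIS", 50))
  fit <- fit_exit_logistic(f)
  expect_true(fit$degenerate)
  expect_equal(fit$reason, "single outcome class")
  expect_equal(nrow(tidy(fit)), 0)
  # perfectly separated outcomes
  off <- c(runif(30, 0, 2), runif(30, 4, 6))
  f2 <- make_features(offset = off, fate = rep(c("EXIT", "MITOSIS"), each = 30))
  fit2 <- fit_exit_logistic(f2)
  expect_true(fit2$degenerate)
  expect_true(is.infinite(fit2$slope))
})

test_that("the exit logistic fit has calibrated type-I error under the null", {
  set.seed(99)
  ps <- vapply(1:40, function(i) {
    f <- make_features(offset = runif(300, 0, 6),
                       fate = sample(c("EXIT", "MITOSIS"), 300, replace = TRUE))
    fit_exit_logistic(f)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.85) # expected ~0.95
})

test_that("the exit logistic fit recovers the generator's negative trend", {
  tr <- generate_population(make_preset("MCF10A"), treatment_program("CDK46I"),
                            n_cells = 600, seed = 23)
  fit <- fit_exit_logistic(classify_fates(tr))
  expect_false(fit$degenerate)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.05)
  gl <- glance(fit)
  expect_equal(gl$slope, fit$slope)
  expect_equal(unname(tidy(fit)$estimate[2]), fit$slope)
})

test_that("heat-map ordering puts dividers first and preserves ties", {
  f <- tibble::tibble(
    cell_id = c("a", "b", "c", "d", "e"),
    mitosis_time = c(12, 8, NA, 12, NA),
    exit_time = c(NA, NA, 20, NA, 15)
  )
  expect_equal(order_for_heatmap(f), c("b", "a", "d", "e", "c"))
  # all non-dividers: ascending exit time
  f2 <- tibble::tibble(cell_id = c("x", "y"), mitosis_time = c(NA, NA),
                       exit_time = c(9, 3))
  expect_equal(order_for_heatmap(f2), c("y", "x"))
})
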