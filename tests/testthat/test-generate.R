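test_that("trace generation is bit-identical under a fixed seed", {
  p <- make_preset("MCF10A")
  tp <- treatment_program("CDK46I")
  a <- generate_population(p, tp, n_cells = 5, seed = 7)
  b <- generate_population(p, tp, n_cells = 5, seed = 7)
  expect_identical(a, b)
  c <- generate_population(p, tp, n_cells = 5, seed = 8)
  expect_false(identical(a$cdk2, c$cdk2))
})

test_that("traces respect the structural invariants", {
  tr <- generate_population(make_preset("RPE1"), treatment_program("DMSO"),
                            n_cells = 20, seed = 3)
  expect_true(all(is.finite(tr$cdk2)))
  expect_true(all(tr$cdk2 >= 0))
  expect_true(all(tr$apc >= 0 & tr$apc <= 1.5))
  expect_true(all(tr$ccna2 > 0))
  per_cell <- split(tr$time_h, tr$cell_id)
  expect_true(all(vapply(per_cell, function(t) {
    !is.unsorted(t, strictly = TRUE) && all(abs(diff(t) - 0.2) < 1e-9)
  }, logical(1))))
  # division flags lie inside the recording
  expect_true(all(tr$time_h[tr$divided == 1] >= 0 &
                    tr$time_h[tr$divided == 1] <= 48))
})

test_that("vehicle-treated cells never exit and divide repeatedly", {
  tr <- generate_population(make_preset("MCF10A"), treatment_program("DMSO"),
                            n_cells = 60, seed = 1, keep_truth = TRUE)
  truth <- attr(tr, "truth")
  expect_true(all(is.infinite(truth$exit_clock)))
  expect_false(any(truth$fate == "EXIT"))
  divs <- tapply(tr$divided, tr$cell_id, sum)
  expect_gt(mean(divs >= 2), 0.3) # many cells divide more than once in 48 h
})

test_that("blocking both arms drives every post-R cell to exit without division", {
  tr <- generate_population(make_preset("MCF10A"),
                            treatment_program("CDK46I_CDK1I"),
                            n_cells = 80, seed = 2, keep_truth = TRUE)
  truth <- attr(tr, "truth")
  expect_true(all(is.infinite(truth$mitosis_clock)))
  expect_equal(sum(tr$divided), 0)
  # almost all exits land inside the 48 h recording and cross below 0.6
  expect_gt(mean(truth$fate == "EXIT"), 0.95)
  last_cdk2 <- tapply(tr$cdk2, tr$cell_id, function(x) tail(x, 1))
  expect_gt(mean(last_cdk2 < 0.6), 0.9)
})

test_that("unregulated-promoter cyclin A2 abolishes exit under CDK4/6 inhibition", {
  tr <- generate_population(
    make_preset("MCF10A"),
    treatment_program("CDK46I", constitutive_ccna2 = TRUE),
    n_cells = 60, seed = 4, keep_truth = TRUE
  )
  expect_false(any(attr(tr, "truth")$fate == "EXIT"))
})

test_that("generated clock medians match the preset calibration", {
  tr <- generate_population(make_preset("MCF10A"), treatment_program("CDK46I"),
                            n_cells = 3000, seed = 11, keep_truth = TRUE)
  truth <- attr(tr, "truth")
  # remaining-mitosis-time median about 11 h, exit clock about the kinetic
  # prediction for a 12 h protein half-life
  expect_equal(median(truth$mitosis_clock), 11, tolerance = 0.05)
  expect_equal(median(truth$exit_clock),
               predict_exit_time(kinetic_params(12)), tolerance = 0.05)
  # population exit frequency in the outlier range seen in dividing cultures
  expect_gt(mean(truth$fate == "EXIT"), 0.09)
  expect_lt(mean(truth$fate == "EXIT"), 0.16)
})

test_that("imposed S-phase delays lengthen the mitosis clock additively", {
  p <- make_preset("MCF10A")
  t0 <- attr(generate_population(p, treatment_program("CDK46I", delay_hours = 0),
                                 n_cells = 200, seed = 9, keep_truth = TRUE),
             "truth")
  t4 <- attr(generate_population(p, treatment_program("CDK46I", delay_hours = 4),
                                 n_cells = 200, seed = 9, keep_truth = TRUE),
             "truth")
  # common random numbers: identical draws, shifted mitosis clock
  expect_equal(t4$mitosis_clock, t0$mitosis_clock + 4)
  expect_gt(mean(t4$fate == "EXIT"), mean(t0$fate == "EXIT"))
})

test_that("decay assays follow the half-life definition exactly without noise", {
  a5 <- generate_decay_assay(make_preset("RPE1_CCNA2dd"), n_cells = 1,
                             noise_cv = 0, seed = 1)
  at <- function(assay, t) assay$ccna2[assay$time_h == t]
  expect_equal(at(a5, 5) / at(a5, 0), 0.5)
  a10 <- generate_decay_assay(make_preset("RPE1"), n_cells = 1,
                              noise_cv = 0, seed = 1)
  expect_equal(at(a10, 20) / at(a10, 0), 0.25)
})

test_that("per-cell log-linear fits centre on the true half-life under noise", {
  assay <- generate_decay_assay(make_preset("MCF10A"), n_cells = 150,
                                noise_cv = 0.04, seed = 6)
  hl <- estimate_half_lives(assay)
  expect_equal(median(hl$half_life), 12, tolerance = 0.05)
})

test_that("generator preconditions are enforced", {
  p <- make_preset("MCF10A")
  tp <- treatment_program("CDK46I")
  expect_error(generate_population(p, tp, n_cells = 0, seed = 1), "at least 1")
  expect_error(generate_population(p, tp, n_cells = 5), "seed")
  expect_error(generate_decay_assay(p, n_cells = 5, noise_cv = -0.1, seed = 1),
               ">= 0")
})
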