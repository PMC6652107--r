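test_that("objective standardizes residuals by the cell SD", {
  # frozen dynamics: all coefficients zero keep volume at exactly 30%
  # of control, and the homeostatic reference maps to exactly 100%
  p0 <- model_parameters()
  cells <- data.frame(group = c("phx", "untreated"), day = c(4, 0),
                      observable = "volume", mean = c(25, 90),
                      sd = c(5, 10))
  expect_equal(objective(p0, observable_mapping(), cells),
               ((30 - 25) / 5)^2 + ((100 - 90) / 10)^2, tolerance = 1e-12)
})

test_that("objective is zero at the generating parameters on noise-free data", {
  p <- params_mild()
  m <- observable_mapping()
  ds <- generate_cohort(p, m, noise = noise_model(0), seed = 1)
  expect_lt(objective(p, m, ds), 1e-20)

  perturbed <- model_parameters(0.05, 0.25, 0.1, 0.15, 0.1, 0.2)
  expect_gt(objective(perturbed, m, ds), 1e-6)
})

test_that("objective rejects empty data and off-range days", {
  expect_error(objective(params_mild(), observable_mapping(),
                         data.frame()), "non-empty")
  only_controls <- data.frame(group = "sham", day = 4,
                              observable = "volume", mean = 100, sd = 5)
  expect_error(objective(params_mild(), observable_mapping(),
                         only_controls), "phx")
})

test_that("fitting from the optimum converges immediately to it", {
  p <- params_mild()
  m <- observable_mapping()
  ds <- generate_cohort(p, m, noise = noise_model(0), seed = 2)
  fit <- fit_model(ds, init = p, mapping = m, n_starts = 1,
                   max_eval = 500, n_restarts = 0)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-12)
  expect_equal(unclass(fit$params), unclass(p), tolerance = 1e-4)
})

test_that("fit results are reproducible for a fixed seed", {
  p <- params_mild()
  ds <- generate_cohort(p, noise = noise_model(0.1), seed = 3)
  f1 <- fit_model(ds, seed = 9, n_starts = 2, max_eval = 200,
                  n_restarts = 0)
  f2 <- fit_model(ds, seed = 9, n_starts = 2, max_eval = 200,
                  n_restarts = 0)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
})

test_that("noise-free coefficients are recovered from a wrong start", {
  rec <- recover_parameters(calibrated_parameters(),
                            design = dense_design(), cv = 0,
                            n_replicates = 1, seed = 5, max_eval = 3000)
  expect_lt(max(rec$per_replicate$rel_error), 0.05)
})

test_that("recovery error grows with measurement noise", {
  p <- calibrated_parameters()
  meds <- sapply(c(0, 0.05, 0.15), function(cv) {
    recover_parameters(p, cv = cv, n_replicates = 6, seed = 31,
                       max_eval = 500)$median_rel_error
  })
  expect_true(all(is.finite(meds)))
  expect_true(all(diff(meds) > 0))
})

test_that("generating parameters sit at the global objective minimum", {
  p <- params_mild()
  m <- observable_mapping()
  ds <- generate_cohort(p, m, design = dense_design(),
                        noise = noise_model(0), seed = 8)
  cells <- summarize_dataset(ds)
  at_truth <- objective(p, m, cells)
  set.seed(99)
  draws <- replicate(1000, {
    cand <- random_nonneg_params()
    tryCatch(objective(cand, m, cells), error = function(e) Inf)
  })
  expect_true(all(draws > at_truth))
})

test_that("the shipped calibrated model satisfies every published constraint", {
  report <- check_constraints(calibrated_parameters())
  expect_true(all(report$pass))
  expect_equal(nrow(report), 10L)
})

test_that("degenerate parameterizations fail the expected constraints", {
  # frozen dynamics: the liver never regrows
  rep0 <- check_constraints(model_parameters())
  expect_false(rep0$pass[rep0$id == "volume_d4"])

  # without macrophage attraction, strong relaxation gives a monotone
  # macrophage curve with no day-8 peak
  p <- model_parameters(k_homeostasis = 1)
  repm <- check_constraints(p)
  expect_false(repm$pass[repm$id == "macrophage_peak_d8"])
})

test_that("recalibrating against the default targets keeps all constraints", {
  fit <- fit_model(default_calibration_targets(),
                   init = calibrated_parameters(), seed = 42,
                   fit_mapping = TRUE, n_starts = 2, max_eval = 1500,
                   constraint_weight = 50)
  expect_true(all(fit$constraint_report$pass))
})

test_that("fit result JSON serialization is complete", {
  p <- params_mild()
  ds <- generate_cohort(p, noise = noise_model(0), seed = 4)
  fit <- fit_model(ds, init = p, n_starts = 1, max_eval = 100,
                   n_restarts = 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_result_json(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(back$parameters), unclass(fit$params),
               tolerance = 1e-12)
  expect_equal(back$objective, fit$objective, tolerance = 1e-12)
  expect_true(all(c("converged", "constraint_report") %in% names(back)))
})
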