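test_that("a noiseless trace is recovered to machine precision", {
  tr <- gen_decay_trace(kinetic_spec(A = 1, k = 2, c = 0.1, dt = 0.01,
                                     n_points = 200))
  fit <- fit_monoexp(tr)
  expect_equal(unname(coef(fit)), c(1, 2, 0.1), tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("the fit beats a coarse grid search on its own objective", {
  tr <- gen_decay_trace(kinetic_spec(A = 0.9, k = 1.7, c = 0.08, dt = 0.02,
                                     n_points = 150, noise_sigma = 0.01,
                                     seed = 21))
  fit <- fit_monoexp(tr)
  grid <- grid_monoexp(tr$time_s, tr$intensity,
                       A_grid = seq(0.5, 1.3, by = 0.02),
                       k_grid = seq(0.8, 2.6, by = 0.02),
                       c_grid = seq(0, 0.2, by = 0.01))
  expect_lte(sum(residuals(fit)^2), grid$sse + 1e-12)
  # parameters agree within one grid step
  expect_lt(abs(coef(fit)[["A"]] - grid$A), 0.02 + 1e-9)
  expect_lt(abs(coef(fit)[["k"]] - grid$k), 0.02 + 1e-9)
  expect_lt(abs(coef(fit)[["c"]] - grid$c), 0.01 + 1e-9)
})

test_that("unusable traces are rejected", {
  up <- decay_trace(0:9, seq(0.1, 1, length.out = 10))
  expect_error(fit_monoexp(up), "increasing")
  short <- decay_trace(0:3, c(1, 0.8, 0.6, 0.5))
  expect_error(fit_monoexp(short), "5 points")
  expect_error(decay_trace(c(0, 1, 1), c(1, 0.5, 0.4)), "increasing")
})

test_that("switching contrast covers the limiting cases", {
  full <- fit_monoexp(gen_decay_trace(kinetic_spec(A = 1, k = 2, c = 0,
                                                   dt = 0.01,
                                                   n_points = 100)))
  expect_equal(switching_contrast(full), 100, tolerance = 1e-6)
  expect_equal(switching_contrast(list(A = 0, c = 0.5)), 0)
  expect_error(switching_contrast(list(A = 0, c = 0)), "positive")
})

test_that("rate fold changes propagate and round as documented", {
  tr <- gen_decay_trace(kinetic_spec(A = 1, k = 2, c = 0.05, dt = 0.01,
                                     n_points = 120, noise_sigma = 0.005,
                                     seed = 3))
  fit <- fit_monoexp(tr)
  same <- rate_fold_change(fit, fit)
  expect_equal(same$ratio, 1)
  # planted 4x ratio recovered well within 7 %
  fa <- fit_monoexp(gen_decay_trace(kinetic_spec(A = 1, k = 4, c = 0.05,
                                                 dt = 0.005, n_points = 200,
                                                 noise_sigma = 0.005,
                                                 seed = 4)))
  fb <- fit_monoexp(gen_decay_trace(kinetic_spec(A = 1, k = 1, c = 0.05,
                                                 dt = 0.02, n_points = 200,
                                                 noise_sigma = 0.005,
                                                 seed = 5)))
  fc <- rate_fold_change(fa, fb)
  expect_equal(fc$ratio, 4, tolerance = 0.07)
  expect_equal(fc$rounded, 4)
})

test_that("cycle photostability recovers the planted bleach factor", {
  cyc <- gen_switch_cycles(kinetic_spec(A = 1, k = 2, c = 0.05, dt = 0.01,
                                        n_points = 150, noise_sigma = 0.005,
                                        n_cycles = 5, bleach_factor = 0.8,
                                        seed = 6))
  ps <- cycle_photostability(cyc)
  expect_equal(ps$loss_factor, 0.8, tolerance = 0.03 * 0.8)
  stable <- gen_switch_cycles(kinetic_spec(A = 1, k = 2, c = 0.05, dt = 0.01,
                                           n_points = 150,
                                           noise_sigma = 0.003,
                                           n_cycles = 4, bleach_factor = 1,
                                           seed = 7))
  ps1 <- cycle_photostability(stable)
  expect_equal(ps1$loss_factor, 1, tolerance = 0.02)
  expect_error(cycle_photostability(cyc[1]), "2 cycles")
})

test_that("the rate estimator is calibrated over seeded replicates", {
  k_true <- 1.45
  fits <- lapply(1:50, function(s) {
    fit_monoexp(gen_decay_trace(kinetic_spec(
      A = 0.95, k = k_true, c = 0.05, dt = 5 / (k_true * 200),
      n_points = 200, noise_sigma = 0.005, seed = 900 + s)))
  })
  ks <- vapply(fits, function(f) coef(f)[["k"]], numeric(1))
  ses <- vapply(fits, function(f) f$se[["k"]], numeric(1))
  expect_equal(mean(ks), k_true, tolerance = 0.02 * k_true)
  # reported standard errors agree with the replicate scatter within 2x
  expect_gt(mean(ses) / sd(ks), 0.5)
  expect_lt(mean(ses) / sd(ks), 2)
})

test_that("traces round-trip through CSV, including cycles", {
  tr <- gen_decay_trace(kinetic_spec(A = 1, k = 1, c = 0.1, n_points = 30,
                                     noise_sigma = 0.01, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$intensity, tr$intensity, tolerance = 1e-12)
  cyc <- gen_switch_cycles(kinetic_spec(A = 1, k = 2, n_points = 20,
                                        n_cycles = 3, bleach_factor = 0.9))
  files <- withr::local_tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(cyc, function(x) {
    cbind(as.data.frame(x), cycle = attr(x, "cycle"))
  }))
  write.csv(df, files, row.names = FALSE)
  back2 <- read_trace_csv(files)
  expect_length(back2, 3)
  expect_equal(back2[[2]]$intensity, cyc[[2]]$intensity, tolerance = 1e-12)
})

test_that("simulate() regenerates traces the fitter can refit", {
  fit <- fit_monoexp(gen_decay_trace(kinetic_spec(A = 1, k = 2, c = 0.1,
                                                  dt = 0.01, n_points = 200,
                                                  noise_sigma = 0.01,
                                                  seed = 10)))
  sims <- simulate(fit, nsim = 2, seed = 11)
  refit <- fit_monoexp(sims[[1]])
  expect_equal(unname(coef(refit)["k"]), unname(coef(fit)["k"]),
               tolerance = 0.1)
})
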