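test_that("discrepancy is the mean squared transverse residual", {
  p <- default_params()
  tq <- reference_torque(p)
  sh <- rod_shape(tq$M, p)
  tr <- make_model_trace(tq$M, p)
  expect_equal(discrepancy(sh, tr), 0, tolerance = 1e-20)
  off <- tr; off$y_um <- off$y_um + 0.1
  expect_equal(discrepancy(sh, off), 0.01, tolerance = 1e-12)
  out <- tr; out$x_um[1] <- -0.2
  expect_warning(discrepancy(sh, out), "clamped")
})

test_that("discrepancy is invariant under a joint rotation of shape and trace", {
  p <- default_params()
  tq <- reference_torque(p)
  sh <- rod_shape(tq$M, p)
  tr <- make_model_trace(tq$M, p, noise_sd = 0.1, seed = 5)
  d0 <- discrepancy(sh, tr)
  a <- 1.1
  rot <- tr
  rot$y_um <- tr$y_um * cos(a) - tr$z_um * sin(a)
  rot$z_um <- tr$y_um * sin(a) + tr$z_um * cos(a)
  # rotate the trace back into the shape frame: same residuals
  back <- rot
  back$y_um <- rot$y_um * cos(a) + rot$z_um * sin(a)
  back$z_um <- -rot$y_um * sin(a) + rot$z_um * cos(a)
  expect_equal(discrepancy(sh, back), d0, tolerance = 1e-12)
})

test_that("noise-free fits round-trip the generating parameters", {
  p <- default_params()
  set.seed(77)
  for (i in 1:8) {
    tq <- random_feasible_torque(p, mx_range = c(2, 20))
    phi <- stats::runif(1, 0, 2 * pi)
    tr <- make_model_trace(tq$M, p, phi = phi)
    fit <- fit_bundle(tr, p$L)
    expect_lt(fit$discrepancy, 1e-10)
    expect_equal(fit$Mx, tq$M[1], tolerance = 1e-3)
    expect_equal(abs(fit$My), abs(tq$M[2]), tolerance = 1e-3)
    expect_equal(fit$bend_moment, sqrt(tq$M[2]^2 + tq$M[3]^2),
                 tolerance = 1e-3)
  }
})

test_that("planar C-shaped traces need no twisting moment", {
  p <- default_params()
  tr <- make_model_trace(c(0, 0, 140), p, phi = 0.9)
  fit <- fit_bundle(tr, p$L)
  expect_lte(abs(fit$Mx), 0.1)
  expect_equal(fit$Mz, 140, tolerance = 1e-6)
  expect_lt(fit$discrepancy, 1e-12)
})

test_that("noisy fits recover the twisting moment within a piconewton-micron", {
  p <- default_params()
  set.seed(88)
  for (i in 1:5) {
    tq <- torque_from_attachment(stats::rnorm(1, -8.4, 5),
                                 stats::runif(1, 0.3, 0.9), sample(c(-1, 1), 1),
                                 p)
    tr <- make_model_trace(tq$M, p, phi = stats::runif(1, 0, 2 * pi),
                           noise_sd = 0.05)
    fit <- fit_bundle(tr, p$L)
    expect_true(fit$pass)
    expect_lt(abs(fit$Mx - tq$M[1]), 1)
  }
})

test_that("fitting a mirrored trace flips the twist and nothing else", {
  p <- default_params()
  set.seed(99)
  tq <- torque_from_attachment(-12, 0.7, 1, p)
  tr <- make_model_trace(tq$M, p, phi = 0.4, noise_sd = 0.05)
  mir <- tr; mir$y_um <- -mir$y_um
  f1 <- fit_bundle(tr, p$L); f2 <- fit_bundle(mir, p$L)
  expect_equal(f2$Mx, -f1$Mx, tolerance = 1e-6)
  expect_equal(f2$bend_moment, f1$bend_moment, tolerance = 1e-6)
  expect_equal(f2$discrepancy, f1$discrepancy, tolerance = 1e-9)
})

test_that("median discrepancy increases with localization noise", {
  p <- default_params()
  meds <- sapply(c(0.02, 0.06, 0.12), function(sg) {
    set.seed(123)
    stats::median(sapply(1:6, function(i) {
      tq <- random_feasible_torque(p, mx_range = c(3, 15))
      tr <- make_model_trace(tq$M, p, phi = stats::runif(1, 0, 2 * pi),
                             noise_sd = sg)
      fit_bundle(tr, p$L)$discrepancy
    }))
  })
  expect_true(all(diff(meds) > 0))
})

test_that("bundle_fit methods are coherent", {
  p <- default_params()
  tq <- reference_torque(p)
  tr <- make_model_trace(tq$M, p, phi = 0.3, noise_sd = 0.03, seed = 42)
  fit <- fit_bundle(tr, p$L)
  cf <- coef(fit)
  expect_named(cf, c("Mx", "My", "Mz", "orientation_deg"))
  pred <- predict(fit)
  expect_equal(nrow(pred), nrow(tr))
  res <- residuals(fit)
  expect_equal(mean(res[, "y_um"]^2 + res[, "z_um"]^2), fit$discrepancy,
               tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1, sigma = 0.05)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), c(nrow(tr), 3))
  expect_output(print(summary(fit)), "bending moment")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("cohort moments summarize passing fits only", {
  tab <- data.frame(Mx = c(-8, -9, -10, -50),
                    bend_moment = c(sqrt(3^2 + 4^2) * 28, 140, 150, 500),
                    pass = c(TRUE, TRUE, TRUE, FALSE))
  ms <- cohort_moments(tab)
  expect_equal(ms$n_pass, 3)
  expect_equal(ms$n_total, 4)
  expect_equal(ms$twist_mean, -9)
  expect_equal(ms$bend_mean, mean(c(140, 140, 150)))
  expect_error(cohort_moments(data.frame(Mx = 1, bend_moment = 1,
                                         pass = FALSE)), "no fits pass")
  # Pythagorean identity for the bending moment of a single fit
  p <- default_params()
  tr <- make_model_trace(c(0, 0, 140), p)
  expect_equal(fit_bundle(tr, p$L)$bend_moment, 140, tolerance = 1e-6)
})

test_that("a cohort generated at the observed twisting-moment scale is recovered", {
  p <- default_params()
  cfg <- sim_config(n_cells = 2, bundles_per_cell = 30, mx_mean = -8.4,
                    mx_sd = 5, noise_sd = 0.05, tilt = FALSE, seed = 314)
  sim <- generate_spindle_traces(cfg)
  al <- align_spindle_frame(sim$traces)
  res <- suppressWarnings(fit_spindle_traces(filter_traces(al, "fitting")))
  ms <- cohort_moments(res)
  expect_gte(ms$n_pass, 40)
  expect_lt(abs(ms$twist_mean - (-8.4)), 2 * ms$twist_sem)
})
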