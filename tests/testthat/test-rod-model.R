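test_that("attachment follows from the torque balance relations", {
  p <- default_params()
  att <- attachment_from_torque(c(-10, -70, 116.487), p)
  expect_equal(att$d_y, 6 / 7, tolerance = 1e-12)
  expect_equal(abs(att$d_z), sqrt(1 - (6 / 7)^2), tolerance = 1e-12)
  expect_equal(att$d_y^2 + att$d_z^2, p$d^2, tolerance = 1e-9)
  # consistent |Mz| from the sphere constraint
  expect_equal(abs(-att$d_y * -70 / att$d_z), 116.487, tolerance = 1e-3)

  att2 <- attachment_from_torque(c(-1, -60, 0.1 * 60 / sqrt(0.99)), p)
  expect_equal(att2$d_y, 0.1, tolerance = 1e-12)
  expect_equal(abs(att2$d_z), sqrt(0.99), tolerance = 1e-12)

  # |d_y| = d exactly: the attachment sits on the equator, d_z = 0
  expect_error(attachment_from_torque(c(-10, -60, 100), p), "degenerate")
  # |d_y| > d: no attachment on the sphere can balance the torque
  expect_error(attachment_from_torque(c(-10, -50, 100), p), "infeasible")
  expect_error(attachment_from_torque(c(0, -70, 100), p), "degenerate")
})

test_that("reaction force balances the twisting moment about the axis", {
  p <- default_params()
  tq <- reference_torque(p)
  F <- reaction_force(tq$M, tq$attachment)
  expect_equal(F, c(0, 0, 70 / 6), tolerance = 1e-12)
  expect_equal(reaction_force(c(0, 10, 10), tq$attachment), c(0, 0, 0))
  # antisymmetry in Mx
  Fm <- reaction_force(c(10, tq$M[2], tq$M[3]), tq$attachment)
  expect_equal(Fm, -F)
  expect_error(reaction_force(c(-10, -70, 116.5), list(d_y = 0)), "degenerate")
})

test_that("right-pole torque follows the left/right exchange symmetry", {
  expect_equal(mirror_pole_torque(c(-10, -70, 116.5)), c(10, -70, -116.5))
  expect_equal(mirror_pole_torque(c(0, 0, 0)), c(0, 0, 0))
  set.seed(1)
  for (i in 1:10) {
    M <- stats::rnorm(3, 0, 50)
    expect_equal(sqrt(sum(mirror_pole_torque(M)^2)), sqrt(sum(M^2)))
  }
})

test_that("twist-free special cases reproduce the printed planar shapes", {
  p <- default_params()
  shC <- rod_shape(c(0, 0, 180), p)
  expect_identical(shC$regime, "Mx0_bendZ")
  yz <- shC$f(c(0, 6, 12))
  expect_equal(yz[, "z"], rep(0, 3))
  expect_equal(unname(yz[2, "y"]), 4.6, tolerance = 1e-12)
  expect_equal(unname(yz[c(1, 3), "y"]), c(1, 1), tolerance = 1e-12)

  shS <- rod_shape(c(0, -150, 0), p)
  expect_identical(shS$regime, "Mx0_bendY")
  yz <- shS$f(c(0, 3, 12))
  expect_equal(yz[, "y"], rep(0, 3))
  expect_equal(unname(yz[1, "z"]), 1, tolerance = 1e-12)
  expect_equal(unname(yz[2, "z"]), 0.875, tolerance = 1e-12)
  expect_equal(unname(yz[3, "z"]), -1, tolerance = 1e-12)

  # both bending components non-negligible at Mx ~ 0 has no closed form
  expect_error(rod_shape(c(0, -100, 100), p), "unsupported")
})

test_that("boundary conditions and y/z symmetry hold for random feasible torques", {
  p <- default_params()
  set.seed(101)
  xs <- seq(0, p$L, length.out = 97)
  for (i in 1:25) {
    tq <- random_feasible_torque(p)
    sh <- rod_shape(tq$M, p)
    yz0 <- sh$f(c(0, p$L))
    expect_lt(max(abs(yz0[, "y"] - tq$attachment$d_y)), 1e-9)
    expect_lt(abs(yz0[1, "z"] - tq$attachment$d_z), 1e-9)
    expect_lt(abs(yz0[2, "z"] + tq$attachment$d_z), 1e-9)
    a <- sh$f(xs); b <- sh$f(p$L - xs)
    expect_lt(max(abs(b[, "y"] - a[, "y"])), 1e-9)
    expect_lt(max(abs(b[, "z"] + a[, "z"])), 1e-9)
  }
})

test_that("closed-form shapes agree with the independent linear BVP solve", {
  p <- default_params()
  set.seed(202)
  for (i in 1:50) {
    tq <- random_feasible_torque(p)
    bend <- sqrt(tq$M[2]^2 + tq$M[3]^2)
    if (bend < 20 || bend > 250) next
    sol <- linear_bvp_oracle(tq$M, p, n_grid = 33)
    yz <- rod_shape(tq$M, p)$f(sol$x)
    expect_lt(max(abs(yz[, "y"] - sol$y), abs(yz[, "z"] - sol$z)), 1e-6)
  }
  # planar special cases against the same oracle
  for (M in list(c(0, 0, 180), c(0, -150, 0))) {
    sol <- linear_bvp_oracle(M, p, n_grid = 33)
    yz <- rod_shape(M, p)$f(sol$x)
    expect_lt(max(abs(yz[, "y"] - sol$y), abs(yz[, "z"] - sol$z)), 1e-6)
  }
  # zero torque, zero force: a straight segment between the attachments
  sol0 <- linear_bvp_oracle(c(0, 0, 0), p, n_grid = 33,
                            F = c(0, 0, 0), attachment = list(d_y = 1, d_z = 0))
  expect_equal(sol0$y, rep(1, 33), tolerance = 1e-9)
  expect_equal(sol0$z, rep(0, 33), tolerance = 1e-9)
})

test_that("shapes are continuous in Mx across the special-case switch", {
  p <- default_params()
  # near-planar C: tiny twisting moment, Mz-dominated bending
  Mx <- 1e-3; Mz <- 180
  dz <- -Mx * p$L / (2 * Mz)
  tq <- torque_from_attachment(Mx, sqrt(p$d^2 - dz^2), sign(dz), p)
  general <- rod_shape(tq$M, p)
  expect_identical(general$regime, "general")
  planar <- rod_shape(c(0, 0, Mz), p)
  xs <- seq(0, p$L, length.out = 121)
  expect_lt(max(abs(general$f(xs) - planar$f(xs))), 1e-4)
})

test_that("two-bundle force/torque balance closes exactly", {
  p <- default_params()
  set.seed(303)
  for (i in 1:10) {
    tq <- random_feasible_torque(p)
    res <- verify_balance(tq$M, p)
    expect_lt(max(abs(unlist(res))), 1e-9)
  }
  # perturbing F1z by +1 pN breaks the pole force balance by exactly 1 pN
  tq <- reference_torque(p)
  F1 <- reaction_force(tq$M, tq$attachment) + c(0, 0, 1)
  res <- verify_balance(tq$M, p, F1 = F1)
  expect_equal(res$pole_force$left, c(0, 0, 1))
  expect_gt(max(abs(res$bundle_torque$bundle1)), 0)
  # per-bundle force balance is identically zero when F' = -F
  expect_equal(res$bundle_force$bundle1, c(0, 0, 0))
})

test_that("twist rate is chiral and vanishes exactly for planar shapes", {
  p <- default_params()
  expect_identical(twist_per_length(c(0, 0, 180), p), 0)
  expect_identical(twist_per_length(c(0, -150, 0), p), 0)
  set.seed(404)
  for (i in 1:10) {
    Mx <- stats::runif(1, 2, 25); dy <- stats::runif(1, 0.5, 0.9)
    t1 <- twist_per_length(torque_from_attachment(Mx, dy, 1, p)$M, p)
    # the z-mirrored configuration (Mx, dz signs flipped) has opposite twist
    t2 <- twist_per_length(torque_from_attachment(-Mx, dy, -1, p)$M, p)
    expect_equal(t2, -t1, tolerance = 1e-12)
    expect_gt(abs(t1), 0)
  }
})

test_that("model twist matches the trace helicity estimator", {
  p <- default_params()
  tq <- reference_torque(p)
  tw <- twist_per_length(tq$M, p)
  # sample the same curve at 0.1 um inside the central window, vertical frame
  xs <- seq(0.3 * p$L, 0.7 * p$L, by = 0.1)
  yz <- rod_shape(tq$M, p)$f(xs)
  trace <- data.frame(x_um = yz[, 1], y_um = yz[, 2], z_um = xs)
  rec <- bundle_helicity(trace, axial = "z")
  expect_equal(rec$helicity, tw, tolerance = 1e-3)
})

test_that("cross-section orientation has slope -Mx/tau and no effect on the contour", {
  p <- rod_params(kappa = 900, L = 12, d = 1, tau = 500)
  tq <- reference_torque(p)
  sh <- rod_shape(tq$M, p)
  expect_equal(sh$phi(2) - sh$phi(0), -tq$M[1] / 500 * 2, tolerance = 1e-12)
  p0 <- default_params()
  expect_equal(sh$f(c(1, 5, 9)), rod_shape(tq$M, p0)$f(c(1, 5, 9)))
})

test_that("small-angle bias grows with curvature and vanishes for flat shapes", {
  p <- default_params()
  expect_lt(small_angle_error_estimate(0.1, p), 1e-4)
  e1 <- small_angle_error_estimate(50, p)
  e2 <- small_angle_error_estimate(111, p)
  e3 <- small_angle_error_estimate(180, p)
  expect_true(e1 < e2 && e2 < e3)
  # fitted circle too tight to span the pole separation
  expect_error(small_angle_error_estimate(240, p), "geometric")
})

test_that("constraint residual flags rounded torque triplets", {
  p <- default_params()
  tq <- reference_torque(p)
  expect_lt(torque_constraint_residual(tq$M, p), 1e-12)
  # a rounded triplet violates the sphere constraint measurably
  expect_gt(torque_constraint_residual(c(-5, -30, 111), p), 1e-3)
  expect_true(is.na(torque_constraint_residual(c(0, 0, 180), p)))
})
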