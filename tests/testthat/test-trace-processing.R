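test_that("stack verticalization is the stated cyclic permutation", {
  arr <- array(0, c(8, 10, 12))
  arr[3, 6, 8] <- 1  # 0-based (2, 5, 7)
  out <- verticalize_stack(arr)
  expect_equal(dim(out), c(10, 12, 8))
  expect_equal(which(out == 1, arr.ind = TRUE)[1, ], c(6, 8, 3),
               ignore_attr = TRUE)  # 0-based (5, 7, 2)
  # order-3 cyclic permutation: applying it three times is the identity
  expect_equal(unclass(verticalize_stack(verticalize_stack(out))), arr,
               ignore_attr = TRUE)
  expect_error(verticalize_stack(matrix(0, 2, 2)), "3D")
})

test_that("physical coordinates apply the axial correction to the z-step", {
  cal <- cal_settings(pixel_size = 0.083, z_step = 0.5)
  expect_equal(to_physical_coordinates(c(0, 0, 0), cal)[1, ],
               c(x_um = 0, y_um = 0, z_um = 0))
  expect_equal(to_physical_coordinates(c(0, 0, 10), cal)[1, "z_um"],
               c(z_um = 4.05))
  cal1 <- cal_settings(0.1, 0.5, axial_correction = 1)
  expect_equal(to_physical_coordinates(c(2, 3, 4), cal1)[1, ],
               c(x_um = 0.2, y_um = 0.3, z_um = 2),
               ignore_attr = TRUE)
  # pitch metadata follows the stack through reorientation
  st <- voxel_stack(array(0, c(4, 4, 4)), cal)
  expect_equal(attr(verticalize_stack(st), "pitch"),
               c(0.083, 0.405, 0.083))
})

test_that("pole alignment is a proper rigid motion", {
  sim <- generate_spindle_traces(sim_config(n_cells = 2, bundles_per_cell = 4,
                                            seed = 9, tilt = TRUE))
  al <- align_spindle_frame(sim$traces, axial = "z")
  frames <- attr(al, "spindle_frames")
  for (f in frames) {
    expect_equal(det(f$rotation), 1, tolerance = 1e-12)
  }
  for (cell in unique(al$cell_id)) {
    P <- pole_positions(al, cell)
    expect_equal(P["POLE1", ], c(x_um = 0, y_um = 0, z_um = 0),
                 tolerance = 1e-9)
    expect_equal(unname(P["POLE2", c("x_um", "y_um")]), c(0, 0),
                 tolerance = 1e-9)
    expect_gt(P["POLE2", "z_um"], 0)
    # pairwise distances are preserved
    raw <- as.matrix(sim$traces[sim$traces$cell_id == cell, 5:7])
    new <- as.matrix(al[al$cell_id == cell, 5:7])
    i <- seq(1, nrow(raw), length.out = min(12, nrow(raw)))
    expect_equal(as.numeric(dist(new[i, ])), as.numeric(dist(raw[i, ])),
                 tolerance = 1e-9)
  }
  # poles already on the axis: alignment reduces to a translation
  tab <- make_trace_table(list(b1 = data.frame(x_um = 1:3, y_um = 0,
                                               z_um = c(2, 5, 8))), L = 12)
  tab[, c("x_um", "y_um", "z_um")] <-
    sweep(tab[, c("x_um", "y_um", "z_um")], 2L, c(1, 2, 3), `+`)
  al2 <- align_spindle_frame(tab, axial = "z")
  expect_equal(al2$x_um[1:3], 1:3, tolerance = 1e-9)
  expect_equal(al2$z_um[1:3], c(2, 5, 8), tolerance = 1e-9)
  expect_error(align_spindle_frame(
    make_trace_table(list(b1 = data.frame(x_um = 1, y_um = 1, z_um = 1)),
                     L = 0)), "coincident")
})

test_that("alignment preserves handedness of mirrored traces", {
  sim <- generate_spindle_traces(sim_config(n_cells = 1, bundles_per_cell = 6,
                                            torque_mode = "twist", seed = 31))
  hel1 <- helicity_table(filter_traces(align_spindle_frame(sim$traces),
                                       "helicity"))
  hel2 <- helicity_table(filter_traces(align_spindle_frame(
    mirror_traces(sim$traces)), "helicity"))
  m <- merge(hel1, hel2, by = c("cell_id", "bundle_id"))
  expect_equal(m$helicity.y, -m$helicity.x, tolerance = 1e-9)
})

test_that("selection filters implement the stated rules and are idempotent", {
  L <- 12
  zc <- seq(2, 10, 0.5)  # spans the equator with > 12 points
  ring <- function(r) data.frame(x_um = r * cos(zc), y_um = r * sin(zc),
                                 z_um = zc)
  full <- function(r, n = 20) {
    z <- seq(0.5, 11.5, length.out = n)
    data.frame(x_um = r * cos(z / 2), y_um = r * sin(z / 2), z_um = z)
  }
  tab <- make_trace_table(list(
    near_axis = ring(1.2),        # mean radius 1.2 < 1.35: helicity-excluded
    good = full(2, 20),           # passes everything
    few_points = full(2, 11),     # 11 < 12 points: fitting-excluded
    onesided = {p <- full(2, 20); p$z_um <- seq(6.2, 11.5, length.out = 20); p}
  ), L = L)
  al <- align_spindle_frame(tab)
  hel <- filter_traces(al, "helicity")
  kept_h <- unique(hel$bundle_id[!hel$bundle_id %in% c("POLE1", "POLE2")])
  expect_false("near_axis" %in% kept_h)
  expect_true("good" %in% kept_h)
  # helicity mode retains only central points
  s <- hel$z_um[hel$bundle_id == "good"] / L
  expect_true(all(s >= 0.3 & s <= 0.7))

  fit <- filter_traces(al, "fitting")
  kept_f <- unique(fit$bundle_id[!fit$bundle_id %in% c("POLE1", "POLE2")])
  expect_false("few_points" %in% kept_f)
  expect_false("onesided" %in% kept_f)   # < 3 points below the equator
  expect_true("good" %in% kept_f)
  expect_true("near_axis" %in% kept_f)   # max radius 1.2 > 1 um

  # idempotence
  expect_identical(filter_traces(hel, "helicity")[, 1:7], hel[, 1:7])
  expect_identical(filter_traces(fit, "fitting")[, 1:7], fit[, 1:7])
  expect_error(filter_traces(tab, "helicity"), "align")
})
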