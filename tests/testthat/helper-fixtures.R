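# Shared fixtures: all built in code at test time.

default_params <- function() rod_params(kappa = 900, L = 12, d = 1)

# the worked reference torque: Mx = -10 pN um at d_y = 6/7 um, d_z > 0
reference_torque <- function(params = default_params()) {
  torque_from_attachment(-10, params$L * -10 / (2 * -70), 1, params)
}

# draw a random feasible torque via the attachment parameterization
random_feasible_torque <- function(params = default_params(),
                                   mx_range = c(1, 30)) {
  Mx <- sample(c(-1, 1), 1) * stats::runif(1, mx_range[1], mx_range[2])
  dy <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 0.95) * params$d
  s <- sample(c(-1, 1), 1)
  torque_from_attachment(Mx, dy, s, params)
}

# ideal helix trace in the vertical frame (axial z), slope deg/um
make_helix_trace <- function(slope_deg_per_um, radius = 2, z = seq(0, 10, 0.5),
                             phase = 0) {
  th <- (phase + slope_deg_per_um * z) * pi / 180
  data.frame(cell_id = "c1", condition = "test", bundle_id = "b1",
             point_index = seq_along(z),
             x_um = radius * cos(th), y_um = radius * sin(th), z_um = z)
}

# sampled model-frame trace of a torque, optional rotation about the axis
# and Gaussian noise
make_model_trace <- function(M, params = default_params(), step = 0.5,
                             phi = 0, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(0, params$L, by = step)
  yz <- rod_shape(M, params)$f(xs)
  y <- yz[, 1] * cos(phi) - yz[, 2] * sin(phi)
  z <- yz[, 1] * sin(phi) + yz[, 2] * cos(phi)
  if (noise_sd > 0) {
    y <- y + stats::rnorm(length(y), 0, noise_sd)
    z <- z + stats::rnorm(length(z), 0, noise_sd)
  }
  data.frame(x_um = xs, y_um = y, z_um = z)
}

# minimal aligned-frame trace table wrapper around a set of point frames
make_trace_table <- function(bundles, L = 12, cell = "c1", cond = "test") {
  rows <- lapply(names(bundles), function(b) {
    p <- bundles[[b]]
    data.frame(cell_id = cell, condition = cond, bundle_id = b,
               point_index = seq_len(nrow(p)),
               x_um = p$x_um, y_um = p$y_um, z_um = p$z_um)
  })
  poles <- data.frame(cell_id = cell, condition = cond,
                      bundle_id = c("POLE1", "POLE2"), point_index = 1L,
                      x_um = 0, y_um = 0, z_um = c(0, L))
  rbind(do.call(rbind, rows), poles)
}
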