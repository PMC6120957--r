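# Fitting the small-angle rod shapes to 3D bundle traces. The fit frame is
# the model frame: x along the pole-pole axis, origin at the left pole
# centre. Free parameters are the twisting moment Mx and the attachment
# coordinate d_y (the bending components follow from the balance relations,
# so the sphere constraint holds by construction), the sign of d_z as a
# discrete choice, and the orientation of the coordinate system about the
# spindle axis. For any candidate shape the optimal orientation angle has a
# closed form, so the optimizer works on the two continuous parameters with
# the orientation profiled out.

#' Configuration of the bundle-shape fit
#'
#' @param kappa Flexural rigidity, pN um^2.
#' @param d Pole sphere radius, um.
#' @param threshold Discrepancy (mean squared transverse residual, um^2)
#'   below which a fit is accepted.
#' @param mx_grid Twisting-moment start values, pN um (zero is dropped; the
#'   planar branches cover it).
#' @param dy_frac Attachment start values as fractions of \code{d}.
#' @param n_orient Orientation grid size for the planar branches.
#' @param n_refine Number of best grid starts refined by local search.
#' @param mx_switch Minimal \code{|Mx|} of the general (twisted) branch.
#' @param maxit Iteration cap per local search.
#' @return An object of class \code{"fit_config"}.
#' @export
fit_config <- function(kappa = 900, d = 1, threshold = 0.1,
                       mx_grid = setdiff(seq(-20, 20, by = 5), 0),
                       dy_frac = c(-0.8, -0.5, -0.2, 0.2, 0.5, 0.8),
                       n_orient = 24, n_refine = 6,
                       mx_switch = 1e-3, maxit = 500) {
  stopifnot(kappa > 0, d > 0, threshold > 0, length(mx_grid) > 0,
            all(mx_grid != 0), all(abs(dy_frac) > 0 & abs(dy_frac) < 1),
            n_orient >= 4, n_refine >= 1, mx_switch > 0)
  structure(list(kappa = kappa, d = d, threshold = threshold,
                 mx_grid = mx_grid, dy_frac = dy_frac, n_orient = n_orient,
                 n_refine = n_refine, mx_switch = mx_switch, maxit = maxit),
            class = "fit_config")
}

#' Discrepancy between a model shape and a traced bundle
#'
#' The mean squared transverse residual
#' \code{[sum_j (y(X_j) - Y_j)^2 + sum_j (z(X_j) - Z_j)^2] / N}, evaluated at
#' the measured axial coordinates only. Axial coordinates outside [0, L]
#' (tracking jitter beyond the poles) are clamped to the boundary with a
#' warning.
#'
#' @param shape A \code{\link{rod_shape}}.
#' @param trace Data.frame with columns \code{x_um}, \code{y_um}, \code{z_um}
#'   in the model frame (x axial).
#' @return Discrepancy, um^2.
#' @export
discrepancy <- function(shape, trace) {
  stopifnot(inherits(shape, "rod_shape"), nrow(trace) >= 1L)
  L <- shape$params$L
  X <- trace$x_um
  if (any(X < 0 | X > L)) {
    warning("axial coordinates outside [0, L] clamped to the boundary",
            call. = FALSE)
    X <- pmin(pmax(X, 0), L)
  }
  yz <- shape$f(X)
  (sum((yz[, 1] - trace$y_um)^2) + sum((yz[, 2] - trace$z_um)^2)) / nrow(trace)
}

# ---- internal fast objectives ----------------------------------------------

# General-branch shape values at fixed axial positions; returns list(y, z) or
# NULL when the parameters leave the feasible region.
.gen_shape_vals <- function(Mx, dy, s, X, L, kap, d, mx_switch) {
  if (!is.finite(Mx) || !is.finite(dy)) return(NULL)
  if (abs(Mx) < mx_switch || abs(dy) >= 0.999999 * d || dy == 0) return(NULL)
  dz <- s * sqrt(d^2 - dy^2)
  My <- Mx * L / (2 * dy)
  Mz <- -dy * My / dz
  om <- Mx / kap
  s_half <- sin(om * L / 2)
  if (s_half == 0) return(NULL)
  A <- (-2 * kap * My * Mz - L * Mx * (Mx^2 - Mz^2)) / (2 * Mx^2 * Mz)
  sx2 <- sin(om * X / 2)
  y <- A * (2 * sin(om * (L - X) / 2) * sx2 / s_half) -
    My / (L * Mx) * X^2 + My / Mx * X + L * Mx / (2 * My)
  z <- A * (-2 * cos(om * (L - X) / 2) * sx2 / s_half) +
    (Mz / Mx - 2 * kap * My / (L * Mx^2)) * X - L * Mx / (2 * Mz)
  list(y = y, z = z, My = My, Mz = Mz, dz = dz)
}

# Profile discrepancy over the orientation angle: for model values (ym, zm)
# and data (Y, Z), disc(phi) = a - (2/N)*(b*cos(phi) + c*sin(phi)) with the
# minimizer phi* = atan2(c, b).
.profile_orientation <- function(ym, zm, Y, Z) {
  N <- length(Y)
  b <- sum(ym * Y + zm * Z)
  c_ <- sum(ym * Z - zm * Y)
  a <- (sum(ym^2 + zm^2) + sum(Y^2 + Z^2)) / N
  list(disc = max(0, a - 2 * sqrt(b^2 + c_^2) / N), phi = atan2(c_, b))
}

# rotate data into the fit frame by angle phi
.rotate_data <- function(Y, Z, phi) {
  list(u = Y * cos(phi) + Z * sin(phi),
       v = -Y * sin(phi) + Z * cos(phi))
}

# planar C branch: u(x) = d + Mz*(L-x)*x/(2*kappa), v = 0; LS over Mz at
# fixed phi, 1D search over phi.
.fit_planar_C <- function(X, Y, Z, L, kap, d, n_orient) {
  g <- (L - X) * X / (2 * kap)
  gg <- sum(g^2)
  obj <- function(phi) {
    rot <- .rotate_data(Y, Z, phi)
    Mz <- sum(g * (rot$u - d)) / gg
    disc <- (sum((d + Mz * g - rot$u)^2) + sum(rot$v^2)) / length(X)
    list(disc = disc, Mz = Mz)
  }
  phis <- seq(0, 2 * pi, length.out = 4 * n_orient + 1)[-(4 * n_orient + 1)]
  dvals <- vapply(phis, function(p) obj(p)$disc, 0)
  p0 <- phis[which.min(dvals)]
  opt <- stats::optimize(function(p) obj(p)$disc, c(p0 - 0.2, p0 + 0.2),
                         tol = 1e-12)
  best <- obj(opt$minimum)
  list(disc = best$disc, phi = opt$minimum, M = c(0, 0, best$Mz),
       d_y = d, d_z = 0, regime = "Mx0_bendZ")
}

# planar S branch: u = 0, v(x) = (L-2x)*d/L + My*(L-2x)*x*(x-L)/(6*kappa*L)
.fit_planar_S <- function(X, Y, Z, L, kap, d, n_orient) {
  base <- (L - 2 * X) * d / L
  g <- (L - 2 * X) * X * (X - L) / (6 * kap * L)
  gg <- sum(g^2)
  obj <- function(phi) {
    rot <- .rotate_data(Y, Z, phi)
    My <- sum(g * (rot$v - base)) / gg
    disc <- (sum(rot$u^2) + sum((base + My * g - rot$v)^2)) / length(X)
    list(disc = disc, My = My)
  }
  phis <- seq(0, 2 * pi, length.out = 4 * n_orient + 1)[-(4 * n_orient + 1)]
  dvals <- vapply(phis, function(p) obj(p)$disc, 0)
  p0 <- phis[which.min(dvals)]
  opt <- stats::optimize(function(p) obj(p)$disc, c(p0 - 0.2, p0 + 0.2),
                         tol = 1e-12)
  best <- obj(opt$minimum)
  list(disc = best$disc, phi = opt$minimum, M = c(0, best$My, 0),
       d_y = 0, d_z = d, regime = "Mx0_bendY")
}

#' Convert aligned vertical-frame points to the model frame
#'
#' The fixed right-handed relabelling between the vertical-spindle frame
#' (axial z) and the rod-model frame (axial x):
#' \code{(x, y, z)_model = (z, x, y)_vertical}.
#'
#' @param points Data.frame with \code{x_um}, \code{y_um}, \code{z_um}.
#' @return The relabelled data.frame.
#' @export
to_model_frame <- function(points) {
  data.frame(points[setdiff(names(points), c("x_um", "y_um", "z_um"))],
             x_um = points$z_um, y_um = points$x_um, z_um = points$y_um)
}

#' Fit the rod model to one traced bundle
#'
#' Minimizes the \code{\link{discrepancy}} over the twisting moment
#' \code{Mx}, the attachment coordinate \code{d_y}, the sign of \code{d_z}
#' and the orientation of the coordinate system about the spindle axis
#' (profiled out in closed form), with the bending components implied by the
#' balance constraint. The twist-free planar C and S branches are fitted by
#' linear least squares and compete with the twisted branch; ties are broken
#' towards the smaller \code{|Mx|}. Deterministic given the configuration
#' (grid-seeded Nelder-Mead refinement with fixed tie-breaking).
#'
#' @param trace Data.frame of traced points. With \code{frame = "model"}
#'   columns \code{x_um} (axial), \code{y_um}, \code{z_um}; with
#'   \code{frame = "vertical"} the aligned vertical-spindle convention
#'   (axial \code{z_um}).
#' @param L Spindle length (pole separation), um.
#' @param config A \code{\link{fit_config}}.
#' @param frame Frame of the input points.
#' @return An object of class \code{"bundle_fit"} with components \code{M}
#'   (fitted torque, pN um), \code{bend_moment} (\code{sqrt(My^2 + Mz^2)}),
#'   \code{d_y}, \code{d_z}, \code{orientation_deg}, \code{discrepancy},
#'   \code{pass}, \code{regime}, \code{n_points}, \code{twist_deg_per_um},
#'   \code{bias_estimate}, plus the data and configuration. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{fitted}, \code{plot}, \code{simulate}.
#' @export
fit_bundle <- function(trace, L, config = fit_config(),
                       frame = c("model", "vertical")) {
  stopifnot(inherits(config, "fit_config"), is.numeric(L), L > 0)
  frame <- match.arg(frame)
  if (frame == "vertical") trace <- to_model_frame(trace)
  if (nrow(trace) < 4L)
    stop("too few points to fit a bundle shape", call. = FALSE)
  X <- trace$x_um
  if (any(X < 0 | X > L)) {
    warning("axial coordinates outside [0, L] clamped to the boundary",
            call. = FALSE)
    X <- pmin(pmax(X, 0), L)
  }
  Y <- trace$y_um; Z <- trace$z_um
  kap <- config$kappa; d <- config$d; msw <- config$mx_switch

  # objective for the twisted branch, orientation profiled out
  gen_obj <- function(par, s) {
    sv <- .gen_shape_vals(par[1], par[2], s, X, L, kap, d, msw)
    if (is.null(sv)) return(1e8 + sum(par^2))
    .profile_orientation(sv$y, sv$z, Y, Z)$disc
  }

  # grid screening over (Mx, d_y, sign)
  grid <- expand.grid(Mx = config$mx_grid, dy = config$dy_frac * d,
                      s = c(-1, 1))
  grid$disc <- mapply(function(Mx, dy, s) gen_obj(c(Mx, dy), s),
                      grid$Mx, grid$dy, grid$s)
  grid <- grid[order(grid$disc), ]
  starts <- utils::head(grid[is.finite(grid$disc) & grid$disc < 1e8, ],
                        config$n_refine)

  best_gen <- NULL
  for (i in seq_len(nrow(starts))) {
    s <- starts$s[i]
    par <- c(starts$Mx[i], starts$dy[i])
    for (rep in 1:3) {  # Nelder-Mead with restarts for tight convergence
      opt <- stats::optim(par, gen_obj, s = s, method = "Nelder-Mead",
                          control = list(maxit = config$maxit,
                                         reltol = 1e-14))
      par <- opt$par
      if (rep > 1 && opt$convergence == 0) break
    }
    if (is.null(best_gen) || opt$value < best_gen$value)
      best_gen <- list(value = opt$value, par = par, s = s)
  }

  candidates <- list()
  if (!is.null(best_gen)) {
    sv <- .gen_shape_vals(best_gen$par[1], best_gen$par[2], best_gen$s,
                          X, L, kap, d, msw)
    prof <- .profile_orientation(sv$y, sv$z, Y, Z)
    candidates$general <- list(
      disc = prof$disc, phi = prof$phi,
      M = c(best_gen$par[1], sv$My, sv$Mz),
      d_y = best_gen$par[2], d_z = sv$dz, regime = "general")
  }
  candidates$planarC <- .fit_planar_C(X, Y, Z, L, kap, d, config$n_orient)
  candidates$planarS <- .fit_planar_S(X, Y, Z, L, kap, d, config$n_orient)

  discs <- vapply(candidates, `[[`, 0, "disc")
  # ties (within 1e-10 um^2) go to the smaller |Mx|, i.e. the planar branch
  best_disc <- min(discs)
  tied <- which(discs <= best_disc + 1e-10)
  mxs <- vapply(candidates, function(cc) abs(cc$M[1]), 0)
  chosen <- candidates[[tied[which.min(mxs[tied])]]]

  # canonical representation: attachment with d_y > 0 for the twisted branch
  if (chosen$regime == "general" && chosen$d_y < 0) {
    chosen$d_y <- -chosen$d_y; chosen$d_z <- -chosen$d_z
    chosen$M[2:3] <- -chosen$M[2:3]
    chosen$phi <- chosen$phi + pi
  }
  chosen$phi <- chosen$phi %% (2 * pi)

  params <- rod_params(kappa = kap, L = L, d = d)
  shape <- rod_shape(chosen$M, params, mx_switch = msw)
  bias <- tryCatch(small_angle_error_estimate(abs(chosen$M[3]), params),
                   error = function(e) NA_real_)
  twist <- tryCatch(twist_per_length(shape), error = function(e) NA_real_)

  structure(list(
    M = chosen$M, Mx = chosen$M[1], My = chosen$M[2], Mz = chosen$M[3],
    bend_moment = sqrt(chosen$M[2]^2 + chosen$M[3]^2),
    d_y = chosen$d_y, d_z = chosen$d_z,
    orientation_deg = chosen$phi * 180 / pi,
    discrepancy = chosen$disc, pass = chosen$disc < config$threshold,
    regime = chosen$regime, n_points = nrow(trace),
    twist_deg_per_um = twist, bias_estimate = bias,
    shape = shape, params = params, config = config,
    data = data.frame(x_um = X, y_um = Y, z_um = Z)),
    class = "bundle_fit")
}

#' @export
print.bundle_fit <- function(x, ...) {
  cat(sprintf("Bundle fit [%s]: Mx = %.2f, My = %.2f, Mz = %.2f pN um\n",
              x$regime, x$M[1], x$M[2], x$M[3]))
  cat(sprintf("  bending moment %.1f pN um, discrepancy %.4g um^2 (%s)\n",
              x$bend_moment, x$discrepancy,
              if (x$pass) "pass" else "fail"))
  invisible(x)
}

#' @export
summary.bundle_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.bundle_fit")
}

#' @export
print.summary.bundle_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  attachment (d_y, d_z) = (%.3f, %.3f) um, orientation %.1f deg\n",
              f$d_y, f$d_z, f$orientation_deg))
  cat(sprintf("  twist %.2f deg/um over the central window; n = %d points\n",
              if (is.na(f$twist_deg_per_um)) NA else f$twist_deg_per_um,
              f$n_points))
  if (!is.na(f$bias_estimate))
    cat(sprintf("  small-angle bias estimate: moments overestimated by ~%.0f%%\n",
                100 * f$bias_estimate))
  invisible(x)
}

#' @export
coef.bundle_fit <- function(object, ...) {
  c(Mx = object$M[1], My = object$M[2], Mz = object$M[3],
    orientation_deg = object$orientation_deg)
}

#' @export
predict.bundle_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) x <- object$data$x_um
  yz <- object$shape$f(x)
  phi <- object$orientation_deg * pi / 180
  # fitted shape lives in the fit frame; rotate back into the data frame
  cbind(x_um = x,
        y_um = yz[, 1] * cos(phi) - yz[, 2] * sin(phi),
        z_um = yz[, 1] * sin(phi) + yz[, 2] * cos(phi))
}

#' @export
fitted.bundle_fit <- function(object, ...) {
  predict(object)
}

#' @export
residuals.bundle_fit <- function(object, ...) {
  fit <- predict(object)
  cbind(y_um = object$data$y_um - fit[, "y_um"],
        z_um = object$data$z_um - fit[, "z_um"])
}

#' @export
simulate.bundle_fit <- function(object, nsim = 1, seed = NULL,
                                sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- sqrt(object$discrepancy / 2)
  curve <- predict(object)
  n <- nrow(curve)
  lapply(seq_len(nsim), function(i) {
    out <- as.data.frame(curve)
    out$y_um <- out$y_um + stats::rnorm(n, 0, sigma)
    out$z_um <- out$z_um + stats::rnorm(n, 0, sigma)
    out
  })
}

#' @export
plot.bundle_fit <- function(x, ...) {
  dat <- x$data
  xs <- seq(min(dat$x_um), max(dat$x_um), length.out = 200)
  crv <- predict(x, xs)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(px, py, cx, cy, xlab, ylab) {
    graphics::plot(px, py, xlab = xlab, ylab = ylab, asp = 1, pch = 1,
                   col = "grey30", ...)
    graphics::lines(cx, cy, col = "red3", lwd = 2)
  }
  panel(dat$x_um, dat$y_um, crv[, 1], crv[, 2], "x (um)", "y (um)")
  panel(dat$x_um, dat$z_um, crv[, 1], crv[, 3], "x (um)", "z (um)")
  panel(dat$y_um, dat$z_um, crv[, 2], crv[, 3], "y (um)", "z (um)")
  invisible(x)
}

#' Fit all bundles of an aligned trace table
#'
#' Runs \code{\link{fit_bundle}} on every bundle (typically after
#' \code{\link{filter_traces}(mode = "fitting")}), taking each cell's spindle
#' length from its pole distance.
#'
#' @param traces Aligned trace table (vertical convention).
#' @param config A \code{\link{fit_config}}.
#' @return A list with \code{fits} (named list of \code{bundle_fit}) and
#'   \code{table} (per-bundle data.frame of fit results).
#' @export
fit_spindle_traces <- function(traces, config = fit_config()) {
  .check_trace_table(traces)
  frames <- attr(traces, "spindle_frames")
  if (is.null(frames))
    stop("traces must first be aligned with align_spindle_frame()",
         call. = FALSE)
  body <- traces[!.is_pole_row(traces), ]
  keys <- unique(body[, c("cell_id", "condition", "bundle_id")])
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    cell <- keys$cell_id[i]; b <- keys$bundle_id[i]
    pts <- body[body$cell_id == cell & body$bundle_id == b, ]
    L <- frames[[as.character(cell)]]$L
    fit <- fit_bundle(pts, L, config = config, frame = "vertical")
    key <- paste(cell, b, sep = "/")
    fits[[key]] <- fit
    rows[[key]] <- data.frame(
      cell_id = cell, condition = keys$condition[i], bundle_id = b,
      Mx = fit$Mx, My = fit$My, Mz = fit$Mz,
      bend_moment = fit$bend_moment,
      orientation_deg = fit$orientation_deg,
      discrepancy = fit$discrepancy, pass = fit$pass,
      regime = fit$regime, n_points = fit$n_points)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Cohort summary of fitted moments
#'
#' Mean and standard error of the twisting moment \code{Mx} and of the
#' bending moment \code{sqrt(My^2 + Mz^2)} over the fits passing the
#' discrepancy criterion.
#'
#' @param fits A list of \code{bundle_fit} objects, the result of
#'   \code{\link{fit_spindle_traces}}, or a data.frame with columns
#'   \code{Mx}, \code{bend_moment}, \code{pass}.
#' @return A list of class \code{"moment_summary"}: \code{twist_mean},
#'   \code{twist_sem}, \code{bend_mean}, \code{bend_sem}, \code{n_pass},
#'   \code{n_total}.
#' @export
cohort_moments <- function(fits) {
  tab <- if (is.data.frame(fits)) fits
  else if (is.list(fits) && !is.null(fits$table)) fits$table
  else data.frame(Mx = vapply(fits, `[[`, 0, "Mx"),
                  bend_moment = vapply(fits, `[[`, 0, "bend_moment"),
                  pass = vapply(fits, `[[`, TRUE, "pass"))
  ok <- tab[tab$pass, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("no fits pass the discrepancy criterion", call. = FALSE)
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(twist_mean = mean(ok$Mx), twist_sem = sem(ok$Mx),
                 bend_mean = mean(ok$bend_moment),
                 bend_sem = sem(ok$bend_moment),
                 n_pass = nrow(ok), n_total = nrow(tab)),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("Twisting moment: %.1f +/- %.1f pN um; bending moment: %.0f +/- %.0f pN um\n",
              x$twist_mean, x$twist_sem, x$bend_mean, x$bend_sem))
  cat(sprintf("  (%d of %d bundles pass the discrepancy criterion)\n",
              x$n_pass, x$n_total))
  invisible(x)
}
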