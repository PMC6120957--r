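# Small-angle Kirchhoff rod model of a microtubule bundle spanning two
# spindle-pole spheres. Frame convention: right-handed, x along the pole-pole
# axis, origin at the centre of the left pole sphere. Torques M = (Mx, My, Mz)
# are those exerted by the left pole on the bundle; Mx is the twisting moment
# about the spindle axis, (My, Mz) the bending components.

#' Mechanical and geometric parameters of the two-sphere rod system
#'
#' @param kappa Flexural rigidity of the bundle, pN um^2. The default models a
#'   bundle of 30 microtubules of 30 pN um^2 each with free inter-microtubule
#'   sliding, giving 900 pN um^2.
#' @param L Pole-centre separation (spindle length), um.
#' @param d Radius of the pole sphere, um.
#' @param tau Torsional rigidity, pN um^2, or \code{NULL}. It only affects the
#'   orientation of the rod cross-section, never the 3D contour, and so is
#'   optional.
#' @return An object of class \code{"rod_params"}.
#' @export
rod_params <- function(kappa = 900, L = 12, d = 1, tau = NULL) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa), kappa > 0,
            is.numeric(L), length(L) == 1L, is.finite(L), L > 0,
            is.numeric(d), length(d) == 1L, is.finite(d), d > 0)
  if (d >= L / 2)
    stop("pole radius 'd' must be smaller than L/2", call. = FALSE)
  if (!is.null(tau)) stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(kappa = kappa, L = L, d = d, tau = tau),
            class = "rod_params")
}

#' @export
print.rod_params <- function(x, ...) {
  cat("Rod parameters: kappa =", x$kappa, "pN um^2, L =", x$L,
      "um, d =", x$d, "um")
  if (!is.null(x$tau)) cat(", tau =", x$tau, "pN um^2")
  cat("\n")
  invisible(x)
}

.check_torque <- function(M) {
  if (!is.numeric(M) || length(M) != 3L || any(!is.finite(M)))
    stop("torque must be a finite numeric vector (Mx, My, Mz)", call. = FALSE)
  unname(M)
}

#' Pole attachment point implied by a torque
#'
#' For the symmetric two-bundle solution the attachment of the bundle on the
#' left pole sphere is fixed by the torque: \code{d_y = Mx*L/(2*My)} and
#' \code{d_z = -d_y*My/Mz}, with \code{d_y^2 + d_z^2 = d^2}. A torque for which
#' \code{|d_y| >= d} cannot be balanced on the sphere and is rejected as
#' infeasible.
#'
#' @param M Numeric torque vector \code{c(Mx, My, Mz)}, pN um.
#' @param params A \code{\link{rod_params}} object.
#' @param rtol Relative tolerance on the sphere constraint.
#' @return A list with components \code{d_y}, \code{d_z} (um), of class
#'   \code{"pole_attachment"}.
#' @export
attachment_from_torque <- function(M, params, rtol = 1e-6) {
  M <- .check_torque(M)
  stopifnot(inherits(params, "rod_params"))
  if (M[1] == 0) stop("degenerate: Mx = 0 has no finite attachment solution",
                      call. = FALSE)
  if (M[2] == 0) stop("degenerate: My = 0 has no finite attachment solution",
                      call. = FALSE)
  d_y <- M[1] * params$L / (2 * M[2])
  if (abs(d_y) >= params$d) {
    if (abs(abs(d_y) - params$d) < 1e-12 * params$d)
      stop("degenerate: attachment lies on the pole equator (d_z = 0)",
           call. = FALSE)
    stop("infeasible torque: |Mx*L/(2*My)| exceeds the pole radius d",
         call. = FALSE)
  }
  dz_abs <- sqrt(params$d^2 - d_y^2)
  # Sign of d_z from d_z = -d_y * My / Mz with the supplied Mz
  d_z <- if (M[3] == 0) dz_abs else sign(-d_y * M[2] / M[3]) * dz_abs
  # Consistency: the supplied Mz must match the constraint-implied magnitude
  if (M[3] != 0) {
    Mz_implied <- -d_y * M[2] / d_z
    if (abs(abs(M[3]) - abs(Mz_implied)) > rtol * abs(Mz_implied))
      stop(sprintf(paste0("infeasible torque: supplied |Mz| = %.6g does not ",
                          "satisfy the sphere constraint (implied |Mz| = %.6g)"),
                   abs(M[3]), abs(Mz_implied)), call. = FALSE)
  }
  structure(list(d_y = d_y, d_z = d_z), class = "pole_attachment")
}

#' Build a feasible torque from twisting moment and attachment
#'
#' Inverse parameterization used during fitting: given \code{Mx} and the
#' attachment coordinate \code{d_y} (with the sign of \code{d_z} as a discrete
#' choice), the bending components follow from the balance relations
#' \code{My = Mx*L/(2*d_y)} and \code{Mz = -d_y*My/d_z}, so the sphere
#' constraint holds by construction.
#'
#' @param Mx Twisting moment, pN um; nonzero.
#' @param d_y Attachment y-coordinate, um, in \code{(-d, 0)} or \code{(0, d)}.
#' @param dz_sign Sign of \code{d_z}, +1 or -1.
#' @param params A \code{\link{rod_params}} object.
#' @return List with \code{M} (torque vector) and \code{attachment}.
#' @export
torque_from_attachment <- function(Mx, d_y, dz_sign = 1, params) {
  stopifnot(inherits(params, "rod_params"),
            is.numeric(Mx), length(Mx) == 1L, is.finite(Mx), Mx != 0,
            is.numeric(d_y), length(d_y) == 1L, is.finite(d_y),
            dz_sign %in% c(-1, 1))
  if (d_y == 0 || abs(d_y) >= params$d)
    stop("d_y must lie strictly between 0 and the pole radius in magnitude",
         call. = FALSE)
  d_z <- dz_sign * sqrt(params$d^2 - d_y^2)
  My <- Mx * params$L / (2 * d_y)
  Mz <- -d_y * My / d_z
  list(M = c(Mx, My, Mz),
       attachment = structure(list(d_y = d_y, d_z = d_z),
                              class = "pole_attachment"))
}

#' Right-pole torque of the symmetric solution
#'
#' The imposed left/right symmetry maps the left-pole torque \code{(Mx, My,
#' Mz)} to the right-pole torque \code{(-Mx, My, -Mz)}; the magnitude is
#' preserved.
#'
#' @param M Numeric torque vector.
#' @return The right-pole torque vector.
#' @export
mirror_pole_torque <- function(M) {
  M <- .check_torque(M)
  c(-M[1], M[2], -M[3])
}

#' Reaction force exerted by the pole on the bundle
#'
#' From the torque balance at the pole, the force reduces to
#' \code{F = (0, 0, -Mx/d_y)}: a pure z-force whose lever arm about the
#' spindle axis balances the twisting moment.
#'
#' @param M Numeric torque vector.
#' @param attachment A \code{"pole_attachment"} (from
#'   \code{\link{attachment_from_torque}}).
#' @return Numeric force vector \code{c(Fx, Fy, Fz)}, pN.
#' @export
reaction_force <- function(M, attachment) {
  M <- .check_torque(M)
  if (M[1] == 0) return(c(0, 0, 0))
  if (!is.list(attachment) || is.null(attachment$d_y))
    stop("'attachment' must have a d_y component", call. = FALSE)
  if (attachment$d_y == 0)
    stop("degenerate: d_y = 0 gives an unbounded reaction force", call. = FALSE)
  c(0, 0, -M[1] / attachment$d_y)
}

# Evaluate the general (Mx != 0) closed-form solution. Trig differences are
# rewritten as products so the evaluation stays accurate as Mx -> 0.
.shape_general <- function(M, att, params) {
  kap <- params$kappa; L <- params$L
  Mx <- M[1]; My <- M[2]
  # use the constraint-implied Mz so boundary conditions hold to machine precision
  Mz <- -att$d_y * My / att$d_z
  om <- Mx / kap
  s_half <- sin(om * L / 2)
  if (s_half == 0)
    stop("shape undefined: Mx*L/(2*kappa) is a multiple of pi", call. = FALSE)
  A <- (-2 * kap * My * Mz - L * Mx * (Mx^2 - Mz^2)) / (2 * Mx^2 * Mz)
  function(x) {
    sx2 <- sin(om * x / 2)
    ybr <- 2 * sin(om * (L - x) / 2) * sx2 / s_half
    zbr <- -2 * cos(om * (L - x) / 2) * sx2 / s_half
    y <- A * ybr - My / (L * Mx) * x^2 + My / Mx * x + L * Mx / (2 * My)
    z <- A * zbr + (Mz / Mx - 2 * kap * My / (L * Mx^2)) * x - L * Mx / (2 * Mz)
    cbind(y = y, z = z)
  }
}

#' Small-angle shape of a bundle under a pole torque
#'
#' Returns the closed-form solution of the linearized rod equations with the
#' boundary conditions \code{y(0) = y(L) = d_y}, \code{z(0) = -z(L) = d_z}.
#' For \code{|Mx|} below \code{mx_switch} the twist-free special cases are
#' used: a planar C-shape for a dominant \code{Mz} (symmetric in y, z = 0) or
#' a planar S-shape for a dominant \code{My} (y = 0, antisymmetric in z). A
#' near-zero twisting moment with both bending components of comparable size
#' has no supported closed form and is rejected.
#'
#' @param M Numeric torque vector \code{c(Mx, My, Mz)}, pN um; must be
#'   feasible (see \code{\link{attachment_from_torque}}).
#' @param params A \code{\link{rod_params}} object.
#' @param mx_switch Twisting-moment magnitude, pN um, below which the planar
#'   special cases are used. The trigonometric closed form loses precision as
#'   \code{Mx -> 0}.
#' @return An object of class \code{"rod_shape"}: a list with the evaluator
#'   \code{$f(x)} mapping axial positions (um) to a two-column matrix
#'   \code{(y, z)} (um), the \code{$regime} flag (\code{"general"},
#'   \code{"Mx0_bendZ"} or \code{"Mx0_bendY"}), \code{$M}, \code{$attachment},
#'   \code{$params}, and, when \code{params$tau} is set, the cross-section
#'   orientation angle \code{$phi(x)} (radians, slope \code{-Mx/tau}).
#' @export
rod_shape <- function(M, params, mx_switch = 1e-3) {
  M <- .check_torque(M)
  stopifnot(inherits(params, "rod_params"))
  d <- params$d; kap <- params$kappa; L <- params$L
  if (abs(M[1]) < mx_switch) {
    if (abs(M[3]) > 0 && abs(M[2]) <= 1e-3 * abs(M[3])) {
      regime <- "Mx0_bendZ"
      Mz <- M[3]
      f <- function(x) cbind(y = (2 * d * kap + Mz * (L - x) * x) / (2 * kap),
                             z = rep(0, length(x)))
      att <- structure(list(d_y = d, d_z = 0), class = "pole_attachment")
    } else if (abs(M[2]) > 0 && abs(M[3]) <= 1e-3 * abs(M[2])) {
      regime <- "Mx0_bendY"
      My <- M[2]
      f <- function(x) cbind(y = rep(0, length(x)),
                             z = (L - 2 * x) * (6 * d * kap + My * x * (x - L)) /
                               (6 * kap * L))
      att <- structure(list(d_y = 0, d_z = d), class = "pole_attachment")
    } else {
      stop(paste("unsupported branch: |Mx| below the switch threshold with",
                 "both bending components non-negligible"), call. = FALSE)
    }
  } else {
    regime <- "general"
    att <- attachment_from_torque(M, params)
    f <- .shape_general(M, att, params)
  }
  phi <- if (!is.null(params$tau)) {
    tau <- params$tau; Mx <- M[1]
    function(x) -Mx / tau * x
  } else NULL
  structure(list(f = f, regime = regime, M = M, attachment = att,
                 params = params, phi = phi),
            class = "rod_shape")
}

#' @export
print.rod_shape <- function(x, ...) {
  cat(sprintf("Rod shape [%s]: M = (%.4g, %.4g, %.4g) pN um, attachment (d_y, d_z) = (%.4g, %.4g) um\n",
              x$regime, x$M[1], x$M[2], x$M[3],
              x$attachment$d_y, x$attachment$d_z))
  invisible(x)
}

# slope of a least-squares line through (x, y)
.ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

# unwrap a sequence of angles (radians) so successive jumps lie in (-pi, pi]
.unwrap <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1] + cumsum(c(0, d))
}

#' Twist rate of a model shape over the central spindle window
#'
#' Evaluates the shape on a dense axial grid restricted to the stated window
#' of normalized spindle length, unwraps the azimuth of \code{(y, z)} about
#' the spindle axis and returns the least-squares slope of azimuth versus
#' axial position, in deg per um. Negative values are left-handed. This is the
#' same estimator applied to experimental traces by
#' \code{\link{bundle_helicity}}, so model and data are directly comparable.
#'
#' @param M Numeric torque vector, or a \code{"rod_shape"}.
#' @param params A \code{\link{rod_params}} object (ignored when \code{M} is
#'   already a shape).
#' @param window Fractions of \code{L} delimiting the axial window.
#' @param n Number of grid points.
#' @param radial_floor Minimal distance from the axis, um, below which the
#'   azimuth is considered ill-defined.
#' @return Twist rate, deg per um.
#' @export
twist_per_length <- function(M, params, window = c(0.3, 0.7), n = 201,
                             radial_floor = 0.05) {
  shape <- if (inherits(M, "rod_shape")) M else rod_shape(M, params)
  if (shape$regime != "general") return(0)  # planar shapes carry no twist
  L <- shape$params$L
  x <- seq(window[1] * L, window[2] * L, length.out = n)
  yz <- shape$f(x)
  r <- sqrt(yz[, 1]^2 + yz[, 2]^2)
  if (any(r < radial_floor))
    stop("ill-defined azimuth: shape crosses the radial floor inside the window",
         call. = FALSE)
  theta <- .unwrap(atan2(yz[, 2], yz[, 1]))
  .ls_slope(x, theta) * 180 / pi
}

#' Twist angle between the two attachment vectors
#'
#' The end-on view angle from the left attachment \code{(d_y, d_z)} to the
#' right attachment \code{(d_y, -d_z)}, measured about the +x axis, in
#' degrees. Exposed as a diagnostic alternative to the contour-based
#' \code{\link{twist_per_length}}.
#'
#' @inheritParams twist_per_length
#' @return Signed angle, degrees.
#' @export
attachment_twist_angle <- function(M, params) {
  M <- .check_torque(M)
  if (M[1] == 0) return(0)
  att <- attachment_from_torque(M, params)
  -2 * atan2(att$d_z, att$d_y) * 180 / pi
}

#' Force and torque balance residuals of the symmetric two-bundle system
#'
#' Constructs the full two-bundle system implied by the left-pole torque of
#' bundle 1 (bundle 2 via the rotational symmetry, right-pole quantities via
#' the left/right exchange symmetry and force reaction) and returns the
#' residuals of the pole force balance, the pole torque balance, the per-bundle
#' force balance and the per-bundle torque balance, for both poles.
#'
#' @param M1 Left-pole torque on bundle 1.
#' @param params A \code{\link{rod_params}} object.
#' @param F1 Optional override of the bundle-1 left-pole force (pN); defaults
#'   to the balanced reaction force. Useful for perturbation checks.
#' @return An object of class \code{"balance_residual"}: a list of residual
#'   vectors (\code{pole_force}, \code{pole_torque}, and per-bundle
#'   \code{bundle_force}, \code{bundle_torque}), each for the left and right
#'   pole/bundle pair.
#' @export
verify_balance <- function(M1, params, F1 = NULL) {
  M1 <- .check_torque(M1)
  stopifnot(inherits(params, "rod_params"))
  att1 <- attachment_from_torque(M1, params)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  d1 <- c(0, att1$d_y, att1$d_z)
  d2 <- -d1
  M2 <- c(M1[1], -M1[2], -M1[3])
  if (is.null(F1)) F1 <- reaction_force(M1, att1)
  F2 <- c(0, 0, -M2[1] / d2[2])
  # right pole: exchange symmetry
  M1p <- mirror_pole_torque(M1); M2p <- mirror_pole_torque(M2)
  F1p <- -F1; F2p <- -F2
  d1p <- c(0, d1[2], -d1[3]); d2p <- c(0, d2[2], -d2[3])
  Lv <- c(params$L, 0, 0)
  res <- list(
    pole_force = list(left = F1 + F2, right = F1p + F2p),
    pole_torque = list(
      left  = (M1 + cross3(d1, F1)) + (M2 + cross3(d2, F2)),
      right = (M1p + cross3(d1p, F1p)) + (M2p + cross3(d2p, F2p))),
    bundle_force = list(bundle1 = F1 + F1p, bundle2 = F2 + F2p),
    bundle_torque = list(
      bundle1 = M1 + M1p + cross3(d1, F1) + cross3(Lv + d1p, F1p),
      bundle2 = M2 + M2p + cross3(d2, F2) + cross3(Lv + d2p, F2p)))
  structure(res, class = "balance_residual")
}

#' @export
print.balance_residual <- function(x, ...) {
  mx <- max(abs(unlist(x)))
  cat(sprintf("Balance residuals: max |component| = %.3g (pN or pN um)\n", mx))
  invisible(x)
}

#' Numerical boundary-value solution of the linearized rod equations
#'
#' Independent verification oracle for \code{\link{rod_shape}}: solves the
#' coupled linear ODEs \code{kappa y'' = Mx z' - Mz} and
#' \code{kappa z'' = -Mx y' + Fz x + My} as a two-point boundary-value problem
#' by linear superposition of high-accuracy initial-value integrations
#' (\pkg{deSolve}), with the same boundary conditions as the closed form but
#' without using it.
#'
#' @param M Numeric torque vector.
#' @param params A \code{\link{rod_params}} object.
#' @param n_grid Number of output grid points (>= 16).
#' @param F Optional force vector (pN); defaults to the balanced reaction
#'   force implied by \code{M}.
#' @param attachment Optional boundary attachment; defaults to the one implied
#'   by \code{M} (or the planar special-case attachments).
#' @return A data.frame with columns \code{x}, \code{y}, \code{z} (um).
#' @export
linear_bvp_oracle <- function(M, params, n_grid = 101, F = NULL,
                              attachment = NULL) {
  M <- .check_torque(M)
  stopifnot(inherits(params, "rod_params"), n_grid >= 16)
  L <- params$L; kap <- params$kappa; d <- params$d
  if (is.null(attachment)) {
    attachment <- if (M[1] != 0 && M[2] != 0) {
      attachment_from_torque(M, params)
    } else if (M[1] == 0 && M[2] == 0 && M[3] != 0) {
      list(d_y = d, d_z = 0)
    } else if (M[1] == 0 && M[3] == 0 && M[2] != 0) {
      list(d_y = 0, d_z = d)
    } else if (all(M == 0)) {
      list(d_y = d, d_z = 0)
    } else stop("no default attachment for this torque; supply one",
                call. = FALSE)
  }
  if (is.null(F)) {
    F <- if (M[1] != 0) c(0, 0, -M[1] / attachment$d_y)
    else if (M[2] != 0) c(0, 0, -2 * M[2] / L)
    else c(0, 0, 0)
  }
  xs <- seq(0, L, length.out = n_grid)
  deriv <- function(x, u, p) {
    list(c(u[2],
           (M[1] * u[4] - M[3]) / kap,
           u[4],
           (-M[1] * u[2] + F[3] * x + M[2]) / kap))
  }
  run <- function(a, b) {
    out <- deSolve::ode(c(attachment$d_y, a, attachment$d_z, b), xs, deriv,
                        NULL, rtol = 1e-12, atol = 1e-12)
    if (attr(out, "istate")[1] < 0)
      stop("BVP oracle: initial-value integration failed to converge",
           call. = FALSE)
    out
  }
  s0 <- run(0, 0); s1 <- run(1, 0); s2 <- run(0, 1)
  endv <- function(s) c(s[nrow(s), 2], s[nrow(s), 4])
  Amat <- cbind(endv(s1) - endv(s0), endv(s2) - endv(s0))
  rhs <- c(attachment$d_y, -attachment$d_z) - endv(s0)
  ab <- solve(Amat, rhs)
  sol <- run(ab[1], ab[2])
  data.frame(x = sol[, 1], y = sol[, 2], z = sol[, 4])
}

#' Moment overestimation of the small-angle approximation
#'
#' The small-angle fit linearizes arc length along the spindle axis, which
#' inflates the estimated moments for strongly curved bundles. Following the
#' exact planar solution -- a rod under torque \code{(0, 0, Mz)} with
#' vanishing forces bends into a circle of radius \code{R = kappa/Mz} -- this
#' routine generates the small-angle planar C-shape for the supplied bending
#' moment, fits a circle to it, and returns the relative excess of the
#' small-angle moment over the exact-circle moment \code{kappa/R}.
#'
#' @param Mz_fit Bending moment from the small-angle fit, pN um; positive.
#' @param params A \code{\link{rod_params}} object.
#' @param n Number of sample points along the shape.
#' @param circle Circle-estimation method: least-squares algebraic fit
#'   (\code{"ls"}, default) or the circle through the two endpoints and the
#'   apex (\code{"three_point"}).
#' @return Relative overestimation, as a fraction (0.10 means 10\%).
#' @export
small_angle_error_estimate <- function(Mz_fit, params, n = 200,
                                       circle = c("ls", "three_point")) {
  stopifnot(inherits(params, "rod_params"),
            is.numeric(Mz_fit), length(Mz_fit) == 1L, Mz_fit > 0)
  circle <- match.arg(circle)
  L <- params$L; kap <- params$kappa; d <- params$d
  x <- seq(0, L, length.out = n)
  y <- (2 * d * kap + Mz_fit * (L - x) * x) / (2 * kap)
  if (circle == "ls") {
    # Kasa algebraic circle fit
    A <- cbind(2 * x, 2 * y, 1)
    sol <- qr.solve(A, x^2 + y^2)
    R <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  } else {
    h <- Mz_fit * L^2 / (8 * kap)  # sagitta of the parabola
    R <- (h^2 + (L / 2)^2) / (2 * h)
  }
  if (R < L / 2)
    stop("geometric error: a circular arc of the fitted radius cannot span L",
         call. = FALSE)
  Mz_exact <- kap / R
  (Mz_fit - Mz_exact) / Mz_exact
}

#' Residual of the sphere constraint for a torque triplet
#'
#' The symmetric two-bundle solution requires
#' \code{(2d/(Mx*L))^2 = 1/My^2 + 1/Mz^2}. Reported torque triplets are often
#' rounded and may violate this relation slightly; this helper quantifies the
#' violation as a relative residual (0 means exactly feasible).
#'
#' @param M Numeric torque vector.
#' @param params A \code{\link{rod_params}} object.
#' @return Relative constraint residual (dimensionless).
#' @export
torque_constraint_residual <- function(M, params) {
  M <- .check_torque(M)
  stopifnot(inherits(params, "rod_params"))
  if (M[1] == 0) return(NA_real_)  # constraint degenerates at Mx = 0
  lhs <- (2 * params$d / (M[1] * params$L))^2
  rhs <- 1 / M[2]^2 + 1 / M[3]^2
  abs(lhs - rhs) / lhs
}

#' Representative fitted pole torques
#'
#' Torque triplets \code{(Mx, My, Mz)} in pN um spanning the range estimated
#' for PRC1-labelled microtubule bundles in metaphase HeLa spindles, from
#' planar C- and S-shapes to strongly twisted shapes. Used as reference inputs
#' for the small-angle bias analysis; the typical mid-spindle bending moment
#' component is the median of the \code{Mz} column.
#'
#' @return A data.frame with columns \code{Mx}, \code{My}, \code{Mz}.
#' @export
example_bundle_torques <- function() {
  data.frame(
    Mx = c(0, -5, -10, -8, -3, 4, -11, -20, -5, 0, 1, -8),
    My = c(-5, -23, -68, -55, -26, 18, -43, -94, -31, -2, 0, 167),
    Mz = c(180, 113, 117, 69, 27, 68, 159, 208, 108, 8, 154, 71))
}
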