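# Geometry and calibration of microscopy-derived bundle traces: z-stack
# reorientation, physical-coordinate conversion with the axial correction for
# the refractive-index mismatch, rigid pole alignment, and the bundle
# selection filters used by the helicity and fitting analyses.
#
# Trace tables are plain data.frames with columns cell_id, condition,
# bundle_id, point_index, x_um, y_um, z_um; the two pole positions of each
# cell are rows with bundle_id "POLE1" / "POLE2". In the aligned ("spindle")
# frame the poles sit at the origin and at (0, 0, L) with the spindle axis
# along +z (vertical-spindle convention), so the azimuth about the axis is
# atan2(y, x).

TRACE_COLUMNS <- c("cell_id", "condition", "bundle_id", "point_index",
                   "x_um", "y_um", "z_um")
POLE_IDS <- c("POLE1", "POLE2")

#' Calibration of a confocal z-stack
#'
#' @param pixel_size Lateral pixel size, um.
#' @param z_step Axial plane spacing as acquired, um.
#' @param axial_correction Dimensionless factor applied to \code{z_step} to
#'   compensate the focal shift caused by the refractive-index mismatch
#'   between immersion oil and the aqueous sample. The default 0.81 is the
#'   ratio of the apparent cell diameters along y and z for a spherical
#'   mitotic cell.
#' @return An object of class \code{"cal_settings"}.
#' @export
cal_settings <- function(pixel_size, z_step, axial_correction = 0.81) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(z_step), z_step > 0,
            is.numeric(axial_correction), axial_correction > 0)
  structure(list(pixel_size = pixel_size, z_step = z_step,
                 axial_correction = axial_correction),
            class = "cal_settings")
}

#' Intensity stack with per-axis voxel pitch
#'
#' @param arr 3D numeric array, index order (i, j, k) = (row, column, plane).
#' @param pitch Numeric length-3 vector of physical voxel pitch per axis, um
#'   (any axial correction already applied), or a \code{\link{cal_settings}}
#'   from which the pitch \code{(pixel, pixel, z_step*correction)} is taken.
#' @return The array with class \code{"voxel_stack"} and a \code{pitch}
#'   attribute.
#' @export
voxel_stack <- function(arr, pitch) {
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("'arr' must be a 3D array", call. = FALSE)
  if (inherits(pitch, "cal_settings"))
    pitch <- c(pitch$pixel_size, pitch$pixel_size,
               pitch$z_step * pitch$axial_correction)
  stopifnot(is.numeric(pitch), length(pitch) == 3L, all(pitch > 0))
  structure(arr, pitch = pitch, class = "voxel_stack")
}

#' Reorient a horizontal-spindle stack into the vertical frame
#'
#' Applies the cyclic index permutation \code{I'(i, j, k) = I(k, i, j)}, which
#' turns a stack acquired with the spindle axis in the imaging plane into one
#' whose planes are perpendicular to the spindle axis. Being a cyclic
#' permutation of the three axes it is orientation-preserving: a rotation of
#' the image volume, never a mirroring. Pitch metadata is permuted alongside.
#'
#' @param stack A \code{\link{voxel_stack}} (or bare 3D array).
#' @return The reoriented stack; dimensions \code{(A, B, C)} become
#'   \code{(B, C, A)}.
#' @export
verticalize_stack <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("input must be a 3D array", call. = FALSE)
  out <- aperm(stack, c(2, 3, 1))
  p <- attr(stack, "pitch")
  if (!is.null(p)) out <- voxel_stack(out, p[c(2, 3, 1)])
  out
}

#' Convert voxel indices to physical coordinates
#'
#' Maps 0-based voxel indices \code{(i, j, k)} of an acquisition stack to
#' \code{(x, y, z) = (i*pixel, j*pixel, k*z_step*axial_correction)} in um.
#' The axial correction is applied along the original optical axis, i.e.
#' before any reorientation; for an already reoriented
#' \code{\link{voxel_stack}} use its stored pitch via the \code{stack}
#' argument instead.
#'
#' @param indices Numeric matrix (or length-3 vector) of 0-based voxel
#'   indices, one row per point.
#' @param cal A \code{\link{cal_settings}} object.
#' @param stack Alternatively, a \code{\link{voxel_stack}} whose pitch
#'   attribute supplies the per-axis scale.
#' @return Matrix of physical coordinates, um.
#' @export
to_physical_coordinates <- function(indices, cal = NULL, stack = NULL) {
  if (is.vector(indices)) indices <- matrix(indices, nrow = 1L)
  stopifnot(is.numeric(indices), ncol(indices) == 3L)
  pitch <- if (!is.null(stack)) {
    attr(stack, "pitch")
  } else {
    stopifnot(inherits(cal, "cal_settings"))
    c(cal$pixel_size, cal$pixel_size, cal$z_step * cal$axial_correction)
  }
  out <- sweep(indices, 2L, pitch, `*`)
  colnames(out) <- c("x_um", "y_um", "z_um")
  out
}

.is_pole_row <- function(traces) traces$bundle_id %in% POLE_IDS

.check_trace_table <- function(traces) {
  missing <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(missing))
    stop("trace table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(traces)
}

#' Pole positions of one cell
#'
#' @param traces Trace table.
#' @param cell Cell identifier.
#' @return 2 x 3 matrix of pole coordinates (rows POLE1, POLE2), um.
#' @export
pole_positions <- function(traces, cell) {
  .check_trace_table(traces)
  rows <- traces[traces$cell_id == cell & .is_pole_row(traces), ]
  if (nrow(rows) != 2L)
    stop(sprintf("cell '%s' must have exactly one POLE1 and one POLE2 row",
                 cell), call. = FALSE)
  rows <- rows[match(POLE_IDS, rows$bundle_id), ]
  if (anyNA(rows$bundle_id))
    stop(sprintf("cell '%s' must have exactly one POLE1 and one POLE2 row",
                 cell), call. = FALSE)
  m <- as.matrix(rows[, c("x_um", "y_um", "z_um")])
  rownames(m) <- POLE_IDS
  m
}

# rotation with det +1 mapping unit vector u onto unit vector v (Rodrigues)
.rotation_onto <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s2 <- sum(w^2)
  if (s2 < 1e-30) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- a - sum(a * u) * u; p <- p / sqrt(sum(p^2))
    return(2 * tcrossprod(p) - diag(3))
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s2)
}

#' Align traces to the spindle frame
#'
#' Applies, per cell, the rigid transform (rotation with determinant +1 plus
#' translation) that puts the first pole at the origin and the second pole on
#' the positive axial axis. Distances and handedness are preserved exactly, so
#' per-bundle helicity signs are unaffected.
#'
#' @param traces Trace table including pole rows.
#' @param axial Name of the axis the poles are placed on: \code{"z"}
#'   (vertical-spindle/helicity convention, default) or \code{"x"} (rod-model
#'   convention).
#' @return The transformed trace table, with a per-cell attribute
#'   \code{"spindle_frames"}: a named list holding pole positions, spindle
#'   length \code{L}, rotation and translation for each cell.
#' @export
align_spindle_frame <- function(traces, axial = c("z", "x")) {
  .check_trace_table(traces)
  axial <- match.arg(axial)
  e <- if (axial == "z") c(0, 0, 1) else c(1, 0, 0)
  frames <- list()
  for (cell in unique(traces$cell_id)) {
    P <- pole_positions(traces, cell)
    p1 <- P[1, ]; p2 <- P[2, ]
    L <- sqrt(sum((p2 - p1)^2))
    if (L == 0) stop(sprintf("cell '%s': coincident pole positions", cell),
                     call. = FALSE)
    R <- .rotation_onto(p2 - p1, e)
    idx <- traces$cell_id == cell
    xyz <- as.matrix(traces[idx, c("x_um", "y_um", "z_um")])
    xyz <- sweep(xyz, 2L, p1) %*% t(R)
    traces[idx, c("x_um", "y_um", "z_um")] <- xyz
    frames[[as.character(cell)]] <- list(p1 = p1, p2 = p2, L = L,
                                         rotation = R, translation = -p1,
                                         axial = axial)
  }
  attr(traces, "spindle_frames") <- frames
  traces
}

.axial_col <- function(traces) {
  frames <- attr(traces, "spindle_frames")
  if (is.null(frames))
    stop("traces must first be aligned with align_spindle_frame()",
         call. = FALSE)
  ax <- frames[[1]]$axial
  c(z = "z_um", x = "x_um")[[ax]]
}

.transverse_cols <- function(traces) {
  setdiff(c("x_um", "y_um", "z_um"), .axial_col(traces))
}

#' Bundle selection filters
#'
#' Applies the selection rules of the two analyses to an aligned trace table.
#' In \code{"helicity"} mode, only points with normalized axial coordinate in
#' [0.3, 0.7] are retained, and then only bundles whose retained points have a
#' mean distance from the spindle axis larger than 1.35 um. In
#' \code{"fitting"} mode, whole bundles are kept when their maximal distance
#' from the axis exceeds 1 um, they have at least 12 tracked points, and at
#' least 3 points on each side of the equatorial plane (normalized axial
#' coordinate 0.5). Pole rows always pass through. Both filters are
#' idempotent.
#'
#' @param traces Aligned trace table (see \code{\link{align_spindle_frame}}).
#' @param mode \code{"helicity"} or \code{"fitting"}.
#' @param central_window Normalized axial window for helicity mode.
#' @param min_mean_radius Mean-radial-distance threshold, um (helicity mode).
#' @param min_max_radius Maximal-radial-distance threshold, um (fitting mode).
#' @param min_points Minimal number of tracked points (fitting mode).
#' @param min_points_per_side Minimal points on each side of the equatorial
#'   plane (fitting mode).
#' @return The filtered trace table (attributes preserved).
#' @export
filter_traces <- function(traces, mode = c("helicity", "fitting"),
                          central_window = c(0.3, 0.7),
                          min_mean_radius = 1.35,
                          min_max_radius = 1,
                          min_points = 12,
                          min_points_per_side = 3) {
  mode <- match.arg(mode)
  .check_trace_table(traces)
  frames <- attr(traces, "spindle_frames")
  axc <- .axial_col(traces)   # errors if not aligned
  trc <- .transverse_cols(traces)
  keep <- rep(TRUE, nrow(traces))
  for (cell in unique(traces$cell_id)) {
    L <- frames[[as.character(cell)]]$L
    in_cell <- traces$cell_id == cell & !.is_pole_row(traces)
    s <- traces[[axc]] / L           # normalized axial coordinate
    r <- sqrt(traces[[trc[1]]]^2 + traces[[trc[2]]]^2)
    for (b in unique(traces$bundle_id[in_cell])) {
      idx <- which(in_cell & traces$bundle_id == b)
      if (mode == "helicity") {
        central <- idx[s[idx] >= central_window[1] & s[idx] <= central_window[2]]
        ok <- length(central) > 0 && mean(r[central]) > min_mean_radius
        keep[idx] <- FALSE
        if (ok) keep[central] <- TRUE
      } else {
        ok <- max(r[idx]) > min_max_radius &&
          length(idx) >= min_points &&
          sum(s[idx] < 0.5) >= min_points_per_side &&
          sum(s[idx] > 0.5) >= min_points_per_side
        keep[idx] <- ok
      }
    }
  }
  out <- traces[keep | .is_pole_row(traces), , drop = FALSE]
  attr(out, "spindle_frames") <- frames
  rownames(out) <- NULL
  out
}
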