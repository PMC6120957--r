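# Synthetic spindles with known ground truth: bundle traces drawn from the
# analytic rod solutions with sampled pole torques, sampled at the axial
# plane spacing of a confocal z-stack and perturbed by Gaussian localization
# noise. Every generated bundle carries its generating torque, attachment and
# true twist rate, so each pipeline stage can be validated end to end.

#' Configuration of the synthetic-spindle generator
#'
#' Defaults emulate the experimental cohorts: 10 cells of about 40 bundles,
#' spindle length around 12 um, bundles sampled every 0.5 um along the axis
#' (the z-spacing of the stacks), localization noise of 0.05 um, pole radius
#' 1 um and bundle rigidity 900 pN um^2.
#'
#' @param n_cells Number of cells.
#' @param bundles_per_cell Bundles per cell.
#' @param L_mean,L_sd Spindle length distribution, um.
#' @param d Pole radius, um.
#' @param kappa Flexural rigidity, pN um^2.
#' @param torque_mode How per-bundle torques are drawn: \code{"moment"}
#'   samples the twisting moment directly, \code{"twist"} samples a target
#'   twist rate and solves for the twisting moment that produces it.
#' @param mx_mean,mx_sd Twisting-moment distribution, pN um (moment mode).
#' @param twist_mean,twist_sd Twist-rate distribution, deg per um (twist
#'   mode).
#' @param dy_range Attachment coordinate range as fractions of \code{d}.
#' @param bend_mean,bend_sd Bending moment Mz for twist-free (planar) bundles,
#'   pN um.
#' @param axial_step Axial sampling step, um.
#' @param noise_sd Isotropic Gaussian localization noise, um.
#' @param tilt Apply a random rigid motion (rotation + translation) per cell
#'   so the raw table requires pole alignment, as acquired data does.
#' @param condition Condition label attached to every trace row.
#' @param seed Random seed (mandatory: generation is deterministic given the
#'   configuration).
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_cells = 10, bundles_per_cell = 40,
                       L_mean = 12, L_sd = 1, d = 1, kappa = 900,
                       torque_mode = c("moment", "twist"),
                       mx_mean = -8.4, mx_sd = 5,
                       twist_mean = -2.5, twist_sd = 1,
                       dy_range = c(0.3, 0.9),
                       bend_mean = 140, bend_sd = 30,
                       axial_step = 0.5, noise_sd = 0.05,
                       tilt = TRUE, condition = "control", seed) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility",
                          call. = FALSE)
  torque_mode <- match.arg(torque_mode)
  stopifnot(n_cells >= 1, bundles_per_cell >= 1, L_mean > 0, L_sd >= 0,
            d > 0, kappa > 0, axial_step > 0, noise_sd >= 0,
            dy_range[1] > 0, dy_range[2] < 1)
  structure(as.list(environment()), class = "sim_config")
}

# planar twist-free C-shaped bundle
.planar_torque <- function(cfg) {
  Mz <- max(20, stats::rnorm(1, cfg$bend_mean, cfg$bend_sd))
  list(M = c(0, 0, Mz), att = list(d_y = cfg$d, d_z = 0), planar = TRUE)
}

# sample one feasible torque according to the config; returns list(M, att)
# or a planar special case when the twisting moment vanishes
.sample_torque <- function(cfg, params) {
  max_retry <- 50L
  if (cfg$torque_mode == "moment") {
    for (i in seq_len(max_retry)) {
      dy <- stats::runif(1, cfg$dy_range[1], cfg$dy_range[2]) * cfg$d
      s <- sample(c(-1, 1), 1)
      Mx <- stats::rnorm(1, cfg$mx_mean, cfg$mx_sd)
      if (abs(Mx) < 2e-3) {
        if (cfg$mx_sd > 0) next  # resample away from the degenerate point
        return(.planar_torque(cfg))
      }
      return(c(torque_from_attachment(Mx, dy, s, params), planar = FALSE))
    }
    stop("failed to sample a feasible torque after ", max_retry, " attempts",
         call. = FALSE)
  }
  # twist mode: draw the target once, then invert the twist-rate curve for
  # Mx, resampling only the attachment until the target is reachable, so the
  # target distribution is not skewed by rejection. The inversion runs on the
  # canonical left-handed branch (Mx < 0, d_z > 0); right-handed targets flip
  # the chirality (Mx -> -Mx, d_z -> -d_z).
  target <- stats::rnorm(1, cfg$twist_mean, cfg$twist_sd)
  if (abs(target) < 1e-3) return(.planar_torque(cfg))
  for (i in seq_len(max_retry)) {
    dy <- stats::runif(1, cfg$dy_range[1], cfg$dy_range[2]) * cfg$d
    tw <- function(Mx) {
      tq <- torque_from_attachment(Mx, dy, 1, params)
      twist_per_length(tq$M, params)
    }
    root <- tryCatch(
      stats::uniroot(function(m) tw(m) + abs(target), c(-80, -5e-3),
                     tol = 1e-8),
      error = function(e) NULL)
    if (is.null(root)) next  # unreachable at this attachment; redraw it
    flip <- if (target < 0) 1 else -1
    tq <- torque_from_attachment(flip * root$root, dy, flip, params)
    return(c(tq, planar = FALSE))
  }
  # a twist rate below what any attachment can produce: emit a twist-free
  # planar bundle instead
  .planar_torque(cfg)
}

# random rotation matrix with small tilt (det +1) about a random axis
.random_tilt <- function(sd_deg = 10) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::rnorm(1, 0, sd_deg * pi / 180)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

#' Generate synthetic spindle traces with ground truth
#'
#' For each bundle a pole torque is drawn, the analytic rod shape is built,
#' rotated to a uniformly sampled azimuth about the spindle axis, sampled at
#' the axial step, perturbed with isotropic Gaussian noise, and emitted as
#' trace rows in the vertical-spindle convention (axial z), together with the
#' two pole rows per cell. When \code{tilt} is set, each cell is additionally
#' subjected to a random rigid motion so that pole alignment is exercised
#' downstream.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A list of class \code{"trace_sim"}: \code{traces} (trace table),
#'   \code{truth} (per-bundle generating torque, attachment, azimuth and true
#'   twist rate), and \code{config}.
#' @export
generate_spindle_traces <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- list(); truth <- list()
  for (ci in seq_len(cfg$n_cells)) {
    cell <- sprintf("cell%02d", ci)
    L <- max(cfg$d * 4, stats::rnorm(1, cfg$L_mean, cfg$L_sd))
    params <- rod_params(kappa = cfg$kappa, L = L, d = cfg$d)
    xs <- seq(0, L, by = cfg$axial_step)
    pts <- list()
    for (bi in seq_len(cfg$bundles_per_cell)) {
      b <- sprintf("b%03d", bi)
      tq <- .sample_torque(cfg, params)
      shape <- rod_shape(tq$M, params)
      yz <- shape$f(xs)
      theta <- stats::runif(1, 0, 2 * pi)
      y <- yz[, 1] * cos(theta) - yz[, 2] * sin(theta)
      z <- yz[, 1] * sin(theta) + yz[, 2] * cos(theta)
      # twist is ill-defined for shapes that cross the spindle axis
      twist_true <- tryCatch(twist_per_length(shape),
                             error = function(e) NA_real_)
      # model frame (x axial) -> vertical frame (z axial)
      P <- cbind(x_um = y, y_um = z, z_um = xs)
      if (cfg$noise_sd > 0)
        P <- P + matrix(stats::rnorm(length(P), 0, cfg$noise_sd), nrow(P))
      pts[[b]] <- data.frame(cell_id = cell, condition = cfg$condition,
                             bundle_id = b, point_index = seq_len(nrow(P)), P)
      truth[[paste(cell, b)]] <- data.frame(
        cell_id = cell, condition = cfg$condition, bundle_id = b, L = L,
        Mx = tq$M[1], My = tq$M[2], Mz = tq$M[3],
        d_y = tq$att$d_y, d_z = tq$att$d_z,
        azimuth_deg = theta * 180 / pi, twist_true = twist_true)
    }
    poles <- data.frame(cell_id = cell, condition = cfg$condition,
                        bundle_id = POLE_IDS, point_index = 1L,
                        x_um = 0, y_um = 0, z_um = c(0, L))
    cell_rows <- rbind(do.call(rbind, pts), poles)
    if (isTRUE(cfg$tilt)) {
      R <- .random_tilt(); tr <- stats::runif(3, -5, 5)
      xyz <- as.matrix(cell_rows[, c("x_um", "y_um", "z_um")]) %*% t(R)
      cell_rows[, c("x_um", "y_um", "z_um")] <- sweep(xyz, 2L, tr, `+`)
    }
    rows[[cell]] <- cell_rows
  }
  traces <- do.call(rbind, rows)
  rownames(traces) <- NULL
  structure(list(traces = traces, truth = do.call(rbind, truth),
                 config = cfg), class = "trace_sim")
}

#' @export
print.trace_sim <- function(x, ...) {
  cat(sprintf("Synthetic trace set: %d cells, %d bundles, %d points (condition '%s')\n",
              length(unique(x$truth$cell_id)), nrow(x$truth),
              sum(!.is_pole_row(x$traces)), x$config$condition))
  invisible(x)
}

#' Write a trace table to delimited text
#'
#' @param traces Trace table (see \code{\link{filter_traces}} for the column
#'   contract).
#' @param path Output file (comma-separated).
#' @export
write_traces <- function(traces, path) {
  .check_trace_table(traces)
  utils::write.csv(traces[, TRACE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a trace table from delimited text
#'
#' Reads the package's trace-table format, or an external deposit layout via
#' \code{column_map}. Every cell must carry its two pole rows (positions were
#' determined manually during tracking; they are required inputs, not
#' estimated).
#'
#' @param path CSV file.
#' @param column_map Optional named character vector mapping the package's
#'   column names to the file's (e.g. \code{c(x_um = "X", y_um = "Y")});
#'   unmapped columns are taken as-is. Entries for \code{cell_id},
#'   \code{condition}, \code{bundle_id} may also name constant fallbacks via
#'   \code{constants}.
#' @param constants Named list of constant values for columns absent from the
#'   file (e.g. \code{list(condition = "vertical")}).
#' @param require_poles Error when a cell lacks its POLE1/POLE2 rows.
#' @return The trace table.
#' @export
read_traces <- function(path, column_map = NULL, constants = NULL,
                        require_poles = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      src <- column_map[[nm]]
      if (!src %in% names(df))
        stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                     src, nm, path), call. = FALSE)
      df[[nm]] <- df[[src]]
    }
  }
  for (nm in names(constants)) if (!nm %in% names(df)) df[[nm]] <- constants[[nm]]
  if (!"point_index" %in% names(df)) df$point_index <- seq_len(nrow(df))
  missing <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing))
    stop("trace file is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, TRACE_COLUMNS]
  for (cc in c("x_um", "y_um", "z_um")) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad))
      stop(sprintf("malformed coordinate in column %s at data row %d",
                   cc, bad[1]), call. = FALSE)
  }
  if (require_poles) {
    for (cell in unique(df$cell_id)) {
      ids <- df$bundle_id[df$cell_id == cell]
      if (!all(POLE_IDS %in% ids))
        stop(sprintf("cell '%s' lacks POLE1/POLE2 rows in %s", cell, path),
             call. = FALSE)
    }
  }
  df
}

#' Generate a voxel-stack fixture with known spot centres
#'
#' Places Gaussian intensity spots at given (or randomly drawn) voxel
#' positions in a small stack, recording the ground-truth centres in physical
#' um including the axial correction. Used to validate the stack
#' reorientation and coordinate-conversion steps against an independent
#' centroid readout.
#'
#' @param dim Stack dimensions (each <= 64).
#' @param cal A \code{\link{cal_settings}}.
#' @param centers_index Optional matrix of 0-based voxel centres (one row per
#'   spot); drawn uniformly inside a margin when \code{NULL}.
#' @param n_spots Number of spots when centres are drawn.
#' @param sigma_vox Spot width in voxels.
#' @param seed Random seed.
#' @return List with \code{stack} (a \code{\link{voxel_stack}}),
#'   \code{centers_index} and \code{centers_um}.
#' @export
generate_voxel_fixture <- function(dim = c(32, 32, 24),
                                   cal = cal_settings(0.2, 0.5),
                                   centers_index = NULL, n_spots = 4,
                                   sigma_vox = 1.2, seed = 1) {
  stopifnot(length(dim) == 3L, all(dim >= 4), all(dim <= 64))
  set.seed(seed)
  if (is.null(centers_index)) {
    m <- pmin(4, (dim - 2) %/% 3)  # per-axis margin, voxels
    centers_index <- cbind(stats::runif(n_spots, m[1], dim[1] - 1 - m[1]),
                           stats::runif(n_spots, m[2], dim[2] - 1 - m[2]),
                           stats::runif(n_spots, m[3], dim[3] - 1 - m[3]))
  }
  centers_index <- matrix(centers_index, ncol = 3L)
  if (any(centers_index < 0) ||
      any(sweep(centers_index, 2L, dim - 1) > 0))
    stop("spot centres fall outside the stack volume", call. = FALSE)
  arr <- array(0, dim)
  gi <- 0:(dim[1] - 1); gj <- 0:(dim[2] - 1); gk <- 0:(dim[3] - 1)
  for (sp in seq_len(nrow(centers_index))) {
    cc <- centers_index[sp, ]
    wi <- exp(-(gi - cc[1])^2 / (2 * sigma_vox^2))
    wj <- exp(-(gj - cc[2])^2 / (2 * sigma_vox^2))
    wk <- exp(-(gk - cc[3])^2 / (2 * sigma_vox^2))
    arr <- arr + outer(outer(wi, wj), wk)
  }
  stack <- voxel_stack(arr, cal)
  list(stack = stack,
       centers_index = centers_index,
       centers_um = to_physical_coordinates(centers_index, cal))
}

#' Write or read a voxel stack as a multi-page TIFF
#'
#' Planes (third index) are stored as TIFF pages; intensities are scaled to
#' [0, 1] on write. Requires the \pkg{tiff} package.
#'
#' @param stack A \code{\link{voxel_stack}}.
#' @param path TIFF file path.
#' @return \code{read_voxel_stack} returns a \code{\link{voxel_stack}}.
#' @export
write_voxel_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  mx <- max(stack)
  if (mx == 0) mx <- 1
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) unclass(stack)[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_voxel_stack
#' @param pitch Per-axis voxel pitch of the stored stack, um.
#' @export
read_voxel_stack <- function(path, pitch) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  voxel_stack(arr, pitch)
}
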