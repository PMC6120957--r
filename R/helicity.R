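# The chirality statistic: per-bundle twist of the azimuthal angle with
# height along the spindle axis, cohort aggregation, and between-condition
# comparison. Sign convention: in the right-handed spindle frame with the
# tracing direction as +axis, clockwise rotation when traced upwards gives a
# negative slope, i.e. a left-handed helix.

#' Unwrapped azimuth of points about the spindle axis
#'
#' Computes \code{atan2(transverse2, transverse1)} per point, in degrees,
#' unwrapped so that successive differences lie in (-180, 180].
#'
#' @param t1,t2 Transverse coordinates of the points, um (for the
#'   vertical-spindle convention, \code{t1 = x}, \code{t2 = y}).
#' @param radial_floor Minimal radial distance from the axis, um; points
#'   closer than this have an ill-defined azimuth and raise an error.
#' @return Numeric vector of unwrapped angles, degrees.
#' @export
unwrap_azimuth <- function(t1, t2, radial_floor = 0.2) {
  stopifnot(length(t1) == length(t2))
  r <- sqrt(t1^2 + t2^2)
  if (any(r < radial_floor))
    stop(sprintf("ill-defined azimuth: %d point(s) within %.3g um of the axis",
                 sum(r < radial_floor), radial_floor), call. = FALSE)
  .unwrap(atan2(t2, t1)) * 180 / pi
}

#' Helicity of one bundle trace
#'
#' The per-bundle twist statistic: by default the least-squares slope of the
#' unwrapped azimuth (degrees) against the axial coordinate (um). The
#' \code{"endpoint"} variant -- total azimuth change divided by axial span --
#' is offered for sensitivity checks.
#'
#' @param points Data.frame of trace points in the aligned spindle frame with
#'   columns \code{x_um}, \code{y_um}, \code{z_um}; the spindle axis is
#'   \code{axial}.
#' @param axial Axial axis name, \code{"z"} (default) or \code{"x"}.
#' @param method \code{"regression"} (default) or \code{"endpoint"}.
#' @param radial_floor Passed to \code{\link{unwrap_azimuth}}.
#' @return A list of class \code{"helicity_record"}: \code{helicity} (deg per
#'   um, negative = left-handed), \code{n_points}, \code{span_um}.
#' @export
bundle_helicity <- function(points, axial = c("z", "x"),
                            method = c("regression", "endpoint"),
                            radial_floor = 0.2) {
  axial <- match.arg(axial)
  method <- match.arg(method)
  if (nrow(points) < 2L)
    stop("at least 2 points are required to estimate helicity", call. = FALSE)
  if (axial == "z") {
    h <- points$z_um; t1 <- points$x_um; t2 <- points$y_um
  } else {
    h <- points$x_um; t1 <- points$y_um; t2 <- points$z_um
  }
  ord <- order(h)
  h <- h[ord]
  theta <- unwrap_azimuth(t1[ord], t2[ord], radial_floor = radial_floor)
  span <- max(h) - min(h)
  if (span <= 0)
    stop("zero axial span: helicity is undefined", call. = FALSE)
  slope <- if (method == "regression") .ls_slope(h, theta)
  else (theta[length(theta)] - theta[1]) / span
  structure(list(helicity = slope, n_points = length(h), span_um = span),
            class = "helicity_record")
}

#' Per-bundle helicity table for a trace set
#'
#' Runs \code{\link{bundle_helicity}} on every bundle of an aligned (and
#' typically helicity-filtered) trace table.
#'
#' @param traces Aligned trace table (see \code{\link{align_spindle_frame}}
#'   and \code{\link{filter_traces}}).
#' @param ... Passed to \code{\link{bundle_helicity}}.
#' @return Data.frame with columns \code{cell_id}, \code{condition},
#'   \code{bundle_id}, \code{helicity}, \code{n_points}, \code{span_um}.
#' @export
helicity_table <- function(traces, ...) {
  .check_trace_table(traces)
  axial <- attr(traces, "spindle_frames")[[1]]$axial
  body <- traces[!.is_pole_row(traces), ]
  keys <- unique(body[, c("cell_id", "condition", "bundle_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    pts <- body[body$cell_id == keys$cell_id[i] &
                  body$bundle_id == keys$bundle_id[i], ]
    rec <- tryCatch(bundle_helicity(pts, axial = axial, ...),
                    error = function(e) stop(sprintf(
                      "helicity stage failed for %s/%s: %s",
                      keys$cell_id[i], keys$bundle_id[i], conditionMessage(e)),
                      call. = FALSE))
    cbind(keys[i, , drop = FALSE],
          helicity = rec$helicity, n_points = rec$n_points,
          span_um = rec$span_um)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of helicity records
#'
#' Mean and standard error over bundles (the bundle is the observation unit);
#' the number of cells is reported alongside. With a single record the s.e.m.
#' is undefined and reported as \code{NA}.
#'
#' @param records Data.frame from \code{\link{helicity_table}} (needs columns
#'   \code{helicity} and \code{cell_id}).
#' @param unit Observation unit for the mean: \code{"bundle"} (default) or
#'   \code{"cell"} (cell means are averaged).
#' @return A list of class \code{"cohort_summary"} with \code{mean},
#'   \code{sem}, \code{n_bundles}, \code{n_cells}.
#' @export
cohort_summary <- function(records, unit = c("bundle", "cell")) {
  unit <- match.arg(unit)
  if (is.null(records) || nrow(records) == 0L)
    stop("no helicity records to summarize", call. = FALSE)
  values <- if (unit == "bundle") records$helicity
  else tapply(records$helicity, records$cell_id, mean)
  n <- length(values)
  sem <- if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_
  structure(list(mean = mean(values), sem = sem,
                 n_bundles = nrow(records),
                 n_cells = length(unique(records$cell_id)),
                 unit = unit),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Helicity: %.2f +/- %.2f deg/um (mean +/- s.e.m.; %d bundles, %d cells)\n",
              x$mean, x$sem, x$n_bundles, x$n_cells))
  invisible(x)
}

.signif_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Compare helicity between two conditions
#'
#' Two-sample, two-tailed Welch test (unequal variances) on per-bundle
#' helicities, with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors of helicities, or data.frames with a
#'   \code{helicity} column.
#' @return A list of class \code{"helicity_comparison"}: \code{t},
#'   \code{df} (fractional), \code{p} (two-tailed), \code{n} (group sizes),
#'   \code{stars}.
#' @export
compare_conditions <- function(a, b) {
  if (is.data.frame(a)) a <- a$helicity
  if (is.data.frame(b)) b <- b$helicity
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, n = c(length(a), length(b)),
                 stars = .signif_stars(ht$p.value)),
            class = "helicity_comparison")
}

#' @export
print.helicity_comparison <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.1f, p = %.3g %s (n = %d vs %d)\n",
              x$t, x$df, x$p, x$stars, x$n[1], x$n[2]))
  invisible(x)
}
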