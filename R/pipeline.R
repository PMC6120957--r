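# Orchestration: simulate (or load) -> align -> helicity -> fit -> compare,
# with a single master seed feeding named substreams per stage and
# machine-readable outputs.

.substream_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + k * 104729) %% 2147483647)
}

#' Configuration of the analysis pipeline
#'
#' @param input Exactly one input source: a \code{\link{sim_config}} (or list
#'   of them, one per condition), a trace table data.frame, or a path to a
#'   trace CSV.
#' @param seed Master seed; per-stage substreams are derived from it.
#' @param stages Stages to run after input/alignment; any subset of
#'   \code{"helicity"}, \code{"fit"}, \code{"compare"}.
#' @param fit_cfg A \code{\link{fit_config}} for the fitting stage.
#' @param column_map,constants Passed to \code{\link{read_traces}} for path
#'   input.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input, seed,
                            stages = c("helicity", "fit", "compare"),
                            fit_cfg = fit_config(),
                            column_map = NULL, constants = NULL) {
  if (missing(input)) stop("an input source is required", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(all(stages %in% c("helicity", "fit", "compare")))
  structure(list(input = input, seed = as.integer(seed), stages = stages,
                 fit_cfg = fit_cfg, column_map = column_map,
                 constants = constants),
            class = "pipeline_config")
}

#' Run the spindle-chirality analysis pipeline
#'
#' Executes the enabled stages in order: obtain traces (simulating per
#' condition when the input is one or more \code{\link{sim_config}}s), align
#' every cell to its spindle frame, apply the helicity filters and compute
#' per-bundle helicities with per-condition cohort summaries, fit the rod
#' model to the fitting-filtered bundles with per-condition moment summaries,
#' and compare helicity between all condition pairs. Identical configuration
#' and seed give identical outputs.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return An object of class \code{"spindle_report"}: a list with
#'   \code{helicity} (per-bundle table), \code{helicity_summaries} (per
#'   condition), \code{fits} (per-bundle fit table),
#'   \code{moment_summaries}, \code{comparisons}, \code{truth} (when
#'   simulated), and a \code{provenance} block (seed, stages, n per table).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  input <- cfg$input
  if (inherits(input, "sim_config")) input <- list(input)
  if (is.list(input) && length(input) && inherits(input[[1]], "sim_config")) {
    sims <- lapply(seq_along(input), function(k) {
      sc <- input[[k]]
      sc$seed <- .substream_seed(cfg$seed, k)
      # keep cell ids unique across conditions
      sim <- generate_spindle_traces(sc)
      sim$traces$cell_id <- paste(sc$condition, sim$traces$cell_id, sep = ".")
      sim$truth$cell_id <- paste(sc$condition, sim$truth$cell_id, sep = ".")
      sim
    })
    traces <- do.call(rbind, lapply(sims, `[[`, "traces"))
    truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  } else if (is.character(input)) {
    traces <- read_traces(input, column_map = cfg$column_map,
                          constants = cfg$constants)
  } else if (is.data.frame(input)) {
    traces <- input
  } else stop("unsupported input source", call. = FALSE)

  aligned <- align_spindle_frame(traces, axial = "z")
  conditions <- unique(aligned$condition[!.is_pole_row(aligned)])
  report <- list(provenance = list(seed = cfg$seed, stages = cfg$stages,
                                   n_cells = length(unique(aligned$cell_id)),
                                   conditions = conditions),
                 truth = truth)

  if ("helicity" %in% cfg$stages) {
    central <- filter_traces(aligned, mode = "helicity")
    tab <- helicity_table(central)
    report$helicity <- tab
    report$helicity_summaries <- lapply(
      stats::setNames(conditions, conditions),
      function(cd) cohort_summary(tab[tab$condition == cd, ]))
  }
  if ("fit" %in% cfg$stages) {
    fitable <- filter_traces(aligned, mode = "fitting")
    res <- fit_spindle_traces(fitable, config = cfg$fit_cfg)
    report$fits <- res$table
    report$moment_summaries <- lapply(
      stats::setNames(conditions, conditions),
      function(cd) {
        tb <- res$table[res$table$condition == cd, ]
        if (nrow(tb)) cohort_moments(tb) else NULL
      })
  }
  if ("compare" %in% cfg$stages && "helicity" %in% cfg$stages &&
      length(conditions) > 1L) {
    prs <- utils::combn(conditions, 2, simplify = FALSE)
    report$comparisons <- do.call(rbind, lapply(prs, function(pr) {
      cmp <- compare_conditions(report$helicity[report$helicity$condition == pr[1], ],
                                report$helicity[report$helicity$condition == pr[2], ])
      data.frame(condition_a = pr[1], condition_b = pr[2],
                 t = cmp$t, df = cmp$df, p = cmp$p, stars = cmp$stars,
                 n_a = cmp$n[1], n_b = cmp$n[2])
    }))
  }
  structure(report, class = "spindle_report")
}

#' @export
print.spindle_report <- function(x, ...) {
  cat("Spindle chirality report (seed", x$provenance$seed, ")\n")
  for (cd in names(x$helicity_summaries)) {
    cat(sprintf("  [%s] ", cd)); print(x$helicity_summaries[[cd]])
  }
  for (cd in names(x$moment_summaries)) {
    if (is.null(x$moment_summaries[[cd]])) next
    cat(sprintf("  [%s] ", cd)); print(x$moment_summaries[[cd]])
  }
  if (!is.null(x$comparisons)) {
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("  %s vs %s: t = %.2f, df = %.1f, p = %.3g %s\n",
                  x$comparisons$condition_a[i], x$comparisons$condition_b[i],
                  x$comparisons$t[i], x$comparisons$df[i],
                  x$comparisons$p[i], x$comparisons$stars[i]))
  }
  invisible(x)
}

#' Write the tables of a report to delimited text files
#'
#' @param report A \code{\link{run_pipeline}} result.
#' @param outdir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "spindle_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wr(report$helicity, "helicity_per_bundle.csv")
  wr(report$fits, "fits_per_bundle.csv")
  wr(report$comparisons, "comparisons.csv")
  wr(report$truth, "ground_truth.csv")
  if (!is.null(report$helicity_summaries)) {
    hs <- do.call(rbind, lapply(names(report$helicity_summaries), function(cd) {
      s <- report$helicity_summaries[[cd]]
      data.frame(condition = cd, mean = s$mean, sem = s$sem,
                 n_bundles = s$n_bundles, n_cells = s$n_cells)
    }))
    wr(hs, "helicity_summaries.csv")
  }
  if (!is.null(report$moment_summaries)) {
    ms <- do.call(rbind, lapply(names(report$moment_summaries), function(cd) {
      s <- report$moment_summaries[[cd]]
      if (is.null(s)) return(NULL)
      data.frame(condition = cd, twist_mean = s$twist_mean,
                 twist_sem = s$twist_sem, bend_mean = s$bend_mean,
                 bend_sem = s$bend_sem, n_pass = s$n_pass,
                 n_total = s$n_total)
    }))
    wr(ms, "moment_summaries.csv")
  }
  sink(file.path(outdir, "report.txt")); print(report); sink()
  invisible(outdir)
}

#' Mirror a trace table
#'
#' Negates one transverse coordinate of every row (poles included), producing
#' the mirror image of the data. Running the pipeline on a mirrored copy must
#' negate all helicities and twisting moments while leaving bending moments
#' and discrepancies unchanged.
#'
#' @param traces Trace table.
#' @param axis Coordinate to negate (default \code{"x_um"}).
#' @return The mirrored table.
#' @export
mirror_traces <- function(traces, axis = "x_um") {
  .check_trace_table(traces)
  traces[[axis]] <- -traces[[axis]]
  attr(traces, "spindle_frames") <- NULL  # frames must be recomputed
  traces
}
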