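.check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  for (col in required) {
    if (col == "molecule_id") next
    vals <- suppressWarnings(as.numeric(as.character(df[[col]])))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(what, ": non-numeric/missing value in column '", col,
           "' at row ", bad[1])
    df[[col]] <- vals
  }
  df
}

.event_cols <- c("molecule_id", "duration_s", "mean_force_pN",
                 "force_amp_pN", "displacement_nm")

#' Read and write interaction-event tables
#'
#' CSV with header \code{molecule_id,duration_s,mean_force_pN,force_amp_pN,}
#' \code{displacement_nm} (an optional \code{start_time_s} column is kept).
#' Numeric values round-trip losslessly to at least 9 significant digits;
#' schema violations report the offending column and row.
#'
#' @param events Event data frame.
#' @param path CSV path.
#' @return \code{read_events} returns the event data frame;
#'   \code{write_events} returns \code{path} invisibly.
#' @export
write_events <- function(events, path) {
  .check_columns(events, .event_cols, "events")
  out <- events
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- format(out[[col]], digits = 15)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, .event_cols, basename(path))
}

#' Read and write trap traces
#'
#' Traces are a CSV (\code{time_s,bead_A_nm,bead_B_nm,stage_nm}) plus a JSON
#' sidecar (same path with extension \code{.json}) holding the trap
#' constants and, when available, the truth event table for round-trip
#' benchmarks.
#'
#' @param trace A \code{"trap_trace"} object.
#' @param path CSV path (the sidecar path is derived from it).
#' @return \code{read_trace} returns a \code{"trap_trace"};
#'   \code{write_trace} returns \code{path} invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trap_trace"))
  df <- data.frame(time_s = trace$time, bead_A_nm = trace$bead_A,
                   bead_B_nm = trace$bead_B, stage_nm = trace$stage)
  for (col in names(df)) df[[col]] <- format(df[[col]], digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(consts = unclass(trace$consts), truth = trace$truth,
                  package_version = as.character(utils::packageVersion("hfskinetics")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  df <- .check_columns(df, c("time_s", "bead_A_nm", "bead_B_nm", "stage_nm"),
                       basename(path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  consts <- do.call(trap_constants, side$consts[c(
    "temperature_C", "oscillation_freq", "trap_stiffness_A",
    "trap_stiffness_B", "sampling_rate")])
  truth <- if (is.null(side$truth) || length(side$truth) == 0) NULL
           else as.data.frame(side$truth)
  structure(list(time = df$time_s, bead_A = df$bead_A_nm,
                 bead_B = df$bead_B_nm, stage = df$stage_nm,
                 consts = consts, truth = truth),
            class = "trap_trace")
}

#' Read and write fitted parameter records
#'
#' JSON records of an \code{hfs_fit}: per-molecule estimates, the group
#' summary, the fit settings, the package version and the seed used
#' upstream (if supplied).
#'
#' @param fit An \code{hfs_fit} object.
#' @param path JSON path.
#' @param seed Optional seed to embed in the record.
#' @return \code{read_fits} returns a list with \code{molecules} and
#'   \code{group}; \code{write_fits} returns \code{path} invisibly.
#' @export
write_fits <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "hfs_fit"))
  g <- fit$group
  rec <- list(
    package_version = as.character(utils::packageVersion("hfskinetics")),
    seed = seed, method = fit$method, t_min = fit$t_min, label = fit$label,
    molecules = fit$molecules,
    group = if (is.null(g)) NULL else
      list(label = g$label, n_molecules = g$n_molecules,
           k0_mean = g$k0_mean, k0_sem = g$k0_sem,
           delta_mean = g$delta_mean, delta_sem = g$delta_sem,
           step_mean = g$step_mean, step_sd = g$step_sd))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full seeded analysis pipeline on synthetic constructs
#'
#' Orchestrates simulate -> (detect) -> fit -> compare -> ensemble for a
#' named set of constructs. The first construct is the reference (WT); each
#' other construct is compared to it molecule-by-molecule and at the
#' ensemble-power level. All randomness derives from \code{seed} through
#' per-construct, per-stage offsets, so a rerun with the same seed
#' reproduces the report exactly.
#'
#' @param constructs Named list of \code{\link{motor_params}} (truth values;
#'   each needs \code{kcat} and \code{step_d} for the ensemble stage).
#' @param consts A \code{\link{trap_constants}} object.
#' @param n_molecules,events_per_molecule Experiment size per construct.
#' @param use_detection If \code{TRUE}, events are rendered into traces and
#'   re-extracted with \code{\link{detect_events}} before fitting (slower);
#'   otherwise the simulated event tables feed the fits directly.
#' @param seed Integer master seed.
#' @param force_grid Resistive grid for the ensemble stage.
#' @param n_mc Monte-Carlo draws for ensemble bands.
#' @param ... Additional arguments to \code{\link{sim_config}}.
#' @return An object of class \code{"hfs_report"}: per-construct fits,
#'   ensemble curves, comparisons against the reference, and a summary
#'   table.
#' @export
run_pipeline <- function(constructs, consts = trap_constants(),
                         n_molecules = 10, events_per_molecule = 300,
                         use_detection = FALSE, seed = 1,
                         force_grid = seq(0, 10, by = 0.1), n_mc = 2000,
                         ...) {
  stopifnot(is.list(constructs), !is.null(names(constructs)))
  fits <- list(); curves <- list()
  for (i in seq_along(constructs)) {
    label <- names(constructs)[i]
    p <- constructs[[i]]
    cfg <- sim_config(p, n_molecules = n_molecules,
                      events_per_molecule = events_per_molecule,
                      seed = seed + 1000 * i, ...)
    events <- if (use_detection) {
      traces <- simulate_hfs_trace(cfg, consts, seed = seed + 1000 * i + 1)
      do.call(rbind, lapply(seq_along(traces), function(m) {
        ev <- detect_events(traces[[m]])
        if (nrow(ev)) ev$molecule_id <- sprintf("mol%02d", m)
        ev
      }))
    } else simulate_events(cfg, consts)
    t_min <- if (use_detection) detection_config()$min_event_duration
             else cfg$min_detectable_duration
    fits[[label]] <- fit_hfs(events, consts, t_min = t_min, label = label)
    g <- fits[[label]]$group
    fitted_p <- motor_params(
      k0 = g$k0_mean, delta = g$delta_mean, kcat = p$kcat,
      step_d = if (is.na(g$step_mean)) p$step_d else g$step_mean,
      sem_k0 = g$k0_sem, sem_delta = g$delta_sem,
      sem_kcat = if (is.na(p$sem_kcat)) 0 else p$sem_kcat,
      sd_step = if (is.na(g$step_sd)) 0 else g$step_sd)
    curves[[label]] <- ensemble_curves(fitted_p, consts, force_grid,
                                       n_mc = n_mc, seed = seed + 1000 * i + 2)
  }
  ref <- names(constructs)[1]
  comparisons <- list(); ensemble_labels <- character(0)
  for (label in setdiff(names(constructs), ref)) {
    comparisons[[label]] <- compare_groups(fits[[label]], fits[[ref]])
    ensemble_labels[label] <- compare_ensembles(curves[[label]],
                                                curves[[ref]])$label
  }
  summary_tab <- do.call(rbind, lapply(names(fits), function(label) {
    g <- fits[[label]]$group
    data.frame(construct = label, n_molecules = g$n_molecules,
               k0 = g$k0_mean, k0_sem = g$k0_sem,
               delta = g$delta_mean, delta_sem = g$delta_sem,
               step = g$step_mean, step_sd = g$step_sd,
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, curves = curves, comparisons = comparisons,
                 ensemble_labels = ensemble_labels, summary = summary_tab,
                 reference = ref, seed = seed,
                 package_version = as.character(utils::packageVersion("hfskinetics"))),
            class = "hfs_report")
}

#' @export
print.hfs_report <- function(x, ...) {
  cat(sprintf("HFS pipeline report (seed %d, reference %s)\n\n",
              x$seed, x$reference))
  print(x$summary, digits = 4)
  if (length(x$comparisons)) {
    cat("\nComparisons vs", x$reference, ":\n")
    for (label in names(x$comparisons)) {
      print(x$comparisons[[label]])
      cat("  ensemble power:", x$ensemble_labels[label], "\n")
    }
  }
  invisible(x)
}
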