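# Configuration and file I/O glue: flat YAML model configs, tidy CSV
# trajectory export and JSON reports.

#' Read a model configuration file
#'
#' A model variant is stored as one flat key-value YAML document: the 22
#' rate constants, the four loop toggles, and optional metadata keys
#' (prefixed `meta_`, e.g. the calibration seed and budget that produced
#' the parameter set).
#'
#' @param path Path to the YAML file.
#' @return List with `params` (validated named vector), `loops`
#'   (`uprt_loops`) and `meta` (named list of the remaining keys).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  params <- validate_parameters(unlist(cfg[PARAM_NAMES]))
  toggles <- vapply(cfg[LOOP_NAMES], isTRUE, logical(1))
  loops <- loop_config("custom",
                       gadd34_to_atf4 = toggles[["gadd34_to_atf4"]],
                       chop_to_atf4 = toggles[["chop_to_atf4"]],
                       chop_to_gadd34 = toggles[["chop_to_gadd34"]],
                       gadd34_to_eif2aP = toggles[["gadd34_to_eif2aP"]])
  if (all(toggles)) attr(loops, "variant") <- "full"
  if (identical(unname(toggles), c(FALSE, FALSE, TRUE, TRUE))) {
    attr(loops, "variant") <- "null"
  }
  meta <- cfg[setdiff(names(cfg), c(PARAM_NAMES, LOOP_NAMES))]
  list(params = params, loops = loops, meta = meta)
}

#' Write a model configuration file
#'
#' @param params Named rate-constant vector.
#' @param loops A [loop_config()].
#' @param path Output path.
#' @param meta Named list of extra scalar keys to record (e.g.
#'   `meta_calibration_seed`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, loops, path, meta = list()) {
  params <- validate_parameters(params)
  cfg <- c(as.list(params), as.list(setNames(as.logical(loops[LOOP_NAMES]),
                                             LOOP_NAMES)), meta)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export trajectories to tidy CSV
#'
#' Writes `scenario, variant, species, time_min, value` rows.  By default
#' only the reporting grid (30-min cadence) is written; `dense = TRUE`
#' writes the full fine-grid trajectory.
#'
#' @param panel A `uprt_panel` or `uprt_timecourse`.
#' @param path Output CSV path.
#' @param dense Write the dense grid instead of the reporting grid.
#' @return `path`, invisibly.
#' @export
export_timecourses <- function(panel, path, dense = FALSE) {
  d <- as_tibble(panel)
  if (!dense) {
    grid <- attr(panel, "grid") %||% seq(0, 120, by = 30)
    d <- d[d$time_min %in% grid, ]
  }
  write.csv(d[, c("scenario", "variant", "species", "time_min", "value")],
            path, row.names = FALSE)
  invisible(path)
}

#' Write an agreement or discrimination report as JSON
#'
#' @param x A `uprt_agreement` or `uprt_discrimination` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  obj <- if (inherits(x, "uprt_agreement")) {
    list(score = x$score, n_rows = x$n_rows, diff = x$diff)
  } else if (inherits(x, "uprt_discrimination")) {
    list(full_score = x$full_score, null_score = x$null_score,
         discriminating_rows = x$discriminating_rows)
  } else if (inherits(x, "uprt_calibration")) {
    list(seed = x$seed, budget = x$budget, evaluations = x$evaluations,
         n_satisfied = x$n_satisfied, n_constraints = x$n_constraints,
         params = as.list(x$params))
  } else {
    stop("no JSON report writer for class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
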