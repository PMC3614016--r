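# Trace CSV and JSON configuration round-trips. CSV traces use a '.'
# decimal separator, UTF-8, header `time_s,signal_au`, time printed with 6
# significant digits and signal with 8. Configs are JSON; unknown keys are
# errors (fail-fast).

#' Read a two-column stopped-flow trace CSV
#'
#' @param path CSV file with header `time_s,signal_au`, one row per sample.
#' @return A tibble with columns `time_s`, `signal_au`. Malformed rows,
#'   non-monotone time (reported with the offending row index) and empty
#'   files are distinct errors.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric", fileEncoding = "UTF-8"),
    error = function(e) stop("malformed trace file ", path, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed trace file ", path, ": ",
                               conditionMessage(w), call. = FALSE)
  )
  if (!identical(names(df), c("time_s", "signal_au"))) {
    stop("expected header `time_s,signal_au` in ", path, call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty trace (header only): ", path, call. = FALSE)
  if (anyNA(df)) {
    stop("malformed row ", which(rowSums(is.na(df)) > 0)[1L], " in ", path,
         call. = FALSE)
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    stop("time not strictly increasing at row ", bad[1L] + 1L, " in ", path,
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a trace CSV
#'
#' @param trace A tibble/data frame with `time_s`, `signal_au`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as_trace_df(trace)
  out <- data.frame(time_s = signif(df$time, 6),
                    signal_au = signif(df$signal, 8))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a species trajectory as CSV
#'
#' Columns: `time_s`, then one column per species label.
#'
#' @param trajectory A `clamp_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  names(df)[1L] <- "time_s"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

design_to_list <- function(design) {
  list(
    kind = design$kind,
    syringe_a = as.list(design$syringe_a),
    syringe_b = as.list(design$syringe_b),
    syringe_c = if (is.null(design$syringe_c)) NULL
                else as.list(design$syringe_c),
    pulse_duration = design$pulse_duration,
    dead_time = design$dead_time,
    end_blocked = design$end_blocked,
    total_duration = design$total_duration,
    preincubation = design$preincubation
  )
}

list_to_design <- function(x) {
  known <- c("kind", "syringe_a", "syringe_b", "syringe_c", "pulse_duration",
             "dead_time", "end_blocked", "total_duration", "preincubation",
             "schedule")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown design field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  syr <- function(s) if (is.null(s)) NULL else unlist(s)
  experiment_design(
    kind = x$kind, syringe_a = syr(x$syringe_a), syringe_b = syr(x$syringe_b),
    syringe_c = syr(x$syringe_c),
    pulse_duration = x$pulse_duration %||% 0.037,
    dead_time = x$dead_time %||% 0.002,
    end_blocked = x$end_blocked %||% TRUE,
    total_duration = x$total_duration %||% 60,
    preincubation = x$preincubation
  )
}

#' Write / read a run configuration as JSON
#'
#' The effective configuration of a simulation run (rate parameters, design,
#' noise sigma, seed, observable calibration) round-trips losslessly, so any
#' output can be regenerated from its logged config and seed.
#'
#' @param path JSON file path.
#' @param params A [rate_parameters()] object.
#' @param design An [experiment_design()].
#' @param sigma,seed,scale,baseline Run settings.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a list with elements `params`, `design`, `sigma`, `seed`,
#'   `scale`, `baseline`. Unknown top-level keys are errors.
#' @export
write_run_config <- function(path, params, design, sigma = NULL, seed = NULL,
                             scale = 1, baseline = 0) {
  cfg <- list(
    params = unclass(validate_rate_parameters(params)),
    design = design_to_list(design),
    sigma = sigma, seed = seed, scale = scale, baseline = baseline
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("params", "design", "sigma", "seed", "scale", "baseline")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  list(
    params = as_rate_parameters(as.list(cfg$params)),
    design = list_to_design(cfg$design),
    sigma = cfg$sigma, seed = cfg$seed,
    scale = cfg$scale %||% 1, baseline = cfg$baseline %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize the reference experiment set as CSV fixtures
#'
#' Simulates the canonical designs (loading, pulse-chase, chase control,
#' unload-trap, reload with and without polymerase) with fixed derived seeds
#' and writes each as a trace CSV plus its JSON config into a directory.
#'
#' @param dir Output directory (created if needed).
#' @param params A [rate_parameters()] object.
#' @param seed Base seed; member i uses `seed + i`.
#' @param sigma Noise sigma (`NULL` for the 1% default, 0 for noise-free).
#' @return Tibble of written files, invisibly.
#' @export
write_reference_traces <- function(dir, params = rate_parameters(),
                                   seed = 1L, sigma = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  designs <- list(
    loading = design_loading(),
    pulse_chase = design_pulse_chase(),
    chase_control = design_chase_control(),
    unload_trap = design_unload_trap(),
    reload = design_reload(),
    reload_poldelta = design_reload(poldelta = 100)
  )
  rows <- purrr::imap(designs, function(d, nm) {
    i <- match(nm, names(designs))
    clean <- run_design(d, params)
    noisy <- add_noise(clean, sigma = sigma, seed = seed + i)
    csv <- file.path(dir, paste0(nm, ".csv"))
    cfg <- file.path(dir, paste0(nm, ".json"))
    write_trace(noisy, csv)
    write_run_config(cfg, params, d, sigma = attr(noisy, "noise_sigma"),
                     seed = seed + i)
    tibble::tibble(name = nm, trace = csv, config = cfg)
  })
  invisible(dplyr::bind_rows(rows))
}
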