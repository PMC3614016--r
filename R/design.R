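# Declarative stopped-flow experiment designs and their simulation:
# two-syringe 1:1 mixing (concentrations halve on mixing), optional
# pre-equilibration of pre-assembled complexes, a pulse stage for pulse-chase
# layouts, instrument sampling schedules and dead-time censoring.

DESIGN_KINDS <- c("loading", "pulse_chase", "chase_control", "unload_trap",
                  "reload", "reload_poldelta")
SYRINGE_SPECIES <- c("loader", "clamp_labeled", "clamp_unlabeled", "dna",
                     "poldelta")

#' Declarative description of one stopped-flow experiment
#'
#' Syringe contents are given at pre-mix (syringe) concentrations, as stated
#' in experimental protocols; every 1:1 mix halves all concentrations of the
#' combined streams. Time 0 is the completion of the final mix.
#'
#' @param kind One of `"loading"`, `"pulse_chase"`, `"chase_control"`,
#'   `"unload_trap"`, `"reload"`, `"reload_poldelta"`.
#' @param syringe_a,syringe_b Named numeric concentration maps (nM) over
#'   `loader`, `clamp_labeled`, `clamp_unlabeled`, `dna`, `poldelta`.
#' @param syringe_c Chase syringe for `pulse_chase` designs.
#' @param pulse_duration Pulse length (s) before the chase mix; the measured
#'   instrument value is 0.037 s.
#' @param dead_time Instrument dead time (s); samples earlier than this are
#'   unobservable and censored from traces. Default 0.002 s.
#' @param end_blocked Logical; `FALSE` removes the block at the DNA end,
#'   opening the slide-off channel.
#' @param total_duration Observed duration (s) after the final mix.
#' @param preincubation Either `NULL` (default: pre-assembled syringe-A
#'   complexes are integrated to steady state before the mix) or a finite
#'   pre-incubation time in seconds. A finite time matters when leak channels
#'   (slide-off, subunit exchange) would fully drain a true steady state.
#' @param schedule Optional [sampling_schedule()] override; by default
#'   loading-type kinds use the 8000-point loading schedule and
#'   unloading-type kinds 1000 points per 60 s.
#'
#' @return An object of class `experiment_design`.
#' @examples
#' design_loading()
#' experiment_design("loading", c(loader = 200, clamp_labeled = 200),
#'                   c(dna = 200))
#' @export
experiment_design <- function(kind, syringe_a, syringe_b, syringe_c = NULL,
                              pulse_duration = 0.037, dead_time = 0.002,
                              end_blocked = TRUE, total_duration = 60,
                              preincubation = NULL, schedule = NULL) {
  kind <- match.arg(kind, DESIGN_KINDS)
  check_syringe <- function(s, nm) {
    if (is.null(s)) return(NULL)
    bad <- setdiff(names(s), SYRINGE_SPECIES)
    if (length(bad)) stop("unknown species in ", nm, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(s < 0)) stop("concentrations in ", nm, " must be >= 0",
                         call. = FALSE)
    s
  }
  syringe_a <- check_syringe(syringe_a, "syringe_a")
  syringe_b <- check_syringe(syringe_b, "syringe_b")
  syringe_c <- check_syringe(syringe_c, "syringe_c")
  if (kind == "pulse_chase") {
    if (is.null(syringe_c)) stop("pulse_chase requires a chase syringe_c")
    if (!is.numeric(pulse_duration) || pulse_duration <= 0) {
      stop("pulse_duration must be > 0 for pulse_chase designs")
    }
  }
  if (dead_time < 0) stop("dead_time must be >= 0")
  if (total_duration <= dead_time) stop("total_duration must exceed dead_time")
  pol <- sum(c(syringe_a["poldelta"], syringe_b["poldelta"],
               syringe_c["poldelta"]), na.rm = TRUE)
  if (pol > 0 && kind != "reload_poldelta") {
    stop("polymerase is only permitted in reload_poldelta designs")
  }
  structure(
    list(kind = kind, syringe_a = syringe_a, syringe_b = syringe_b,
         syringe_c = syringe_c, pulse_duration = pulse_duration,
         dead_time = dead_time, end_blocked = end_blocked,
         total_duration = total_duration, preincubation = preincubation,
         schedule = schedule),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$kind, ", ", x$total_duration,
      " s, dead time ", x$dead_time * 1000, " ms\n", sep = "")
  show <- function(s, nm) {
    if (!is.null(s) && length(s)) {
      cat("  ", nm, ": ", paste(names(s), s, sep = " = ", collapse = ", "),
          " nM\n", sep = "")
    }
  }
  show(x$syringe_a, "syringe A")
  show(x$syringe_b, "syringe B")
  show(x$syringe_c, "syringe C (chase)")
  invisible(x)
}

#' Canonical experiment designs
#'
#' Constructors pre-filled with the concentrations of the reference
#' experiments (all values are pre-mix syringe concentrations, nM):
#' `design_loading()` mixes a pre-formed loader-clamp complex with DNA;
#' `design_pulse_chase()` adds a brief DNA pulse followed by an unlabeled
#' clamp chase; `design_chase_control()` pre-mixes the trap with the loader
#' before the labeled clamp ever sees it; `design_unload_trap()`
#' pre-equilibrates a loaded complex and chases with excess unlabeled clamp;
#' `design_reload()` pre-equilibrates an unlabeled loaded complex and mixes
#' with labeled clamp (optionally with polymerase, which switches the kind to
#' `reload_poldelta`).
#'
#' @param loader,clamp_labeled,clamp_unlabeled,dna,chase,poldelta Syringe
#'   concentrations, nM.
#' @param total_duration Observed duration (s).
#' @param ... Passed on to [experiment_design()].
#' @return An `experiment_design`.
#' @name canonical_designs
NULL

#' @rdname canonical_designs
#' @export
design_loading <- function(loader = 200, clamp_labeled = 200, dna = 200,
                           total_duration = 60, ...) {
  experiment_design("loading",
                    c(loader = loader, clamp_labeled = clamp_labeled),
                    c(dna = dna), total_duration = total_duration, ...)
}

#' @rdname canonical_designs
#' @export
design_pulse_chase <- function(loader = 100, clamp_labeled = 100, dna = 100,
                               chase = 2000, total_duration = 60, ...) {
  experiment_design("pulse_chase",
                    c(loader = loader, clamp_labeled = clamp_labeled),
                    c(dna = dna), c(clamp_unlabeled = chase),
                    total_duration = total_duration, ...)
}

#' @rdname canonical_designs
#' @export
design_chase_control <- function(loader = 100, chase = 2000,
                                 clamp_labeled = 100, dna = 100,
                                 total_duration = 60, ...) {
  experiment_design("chase_control",
                    c(loader = loader, clamp_unlabeled = chase),
                    c(clamp_labeled = clamp_labeled, dna = dna),
                    total_duration = total_duration, ...)
}

#' @rdname canonical_designs
#' @export
design_unload_trap <- function(loader = 100, clamp_labeled = 100, dna = 200,
                               chase = 2000, total_duration = 60, ...) {
  experiment_design("unload_trap",
                    c(loader = loader, clamp_labeled = clamp_labeled,
                      dna = dna),
                    c(clamp_unlabeled = chase),
                    total_duration = total_duration, ...)
}

#' @rdname canonical_designs
#' @export
design_reload <- function(loader = 100, clamp_unlabeled = 100, dna = 200,
                          clamp_labeled = 100, poldelta = 0,
                          total_duration = 60, ...) {
  kind <- if (poldelta > 0) "reload_poldelta" else "reload"
  b <- c(clamp_labeled = clamp_labeled)
  if (poldelta > 0) b <- c(b, poldelta = poldelta)
  experiment_design(kind,
                    c(loader = loader, clamp_unlabeled = clamp_unlabeled,
                      dna = dna),
                    b, total_duration = total_duration, ...)
}

#' Instrument sampling schedule
#'
#' The loading schedule densely samples the fast phases: 5000 points over the
#' initial 10 s plus 3000 points over the remainder (8000 points for a 60 s
#' trace). The unloading schedule records 1000 points per 60 s.
#'
#' @param kind `"loading"` or `"unloading"`.
#' @param total_duration Total observed duration (s), > 0.
#' @return An object of class `sampling_schedule`: a tibble of segments
#'   `(duration, n_points)`.
#' @examples
#' sum(sampling_schedule("loading", 60)$n_points)   # 8000
#' sum(sampling_schedule("unloading", 180)$n_points) # 3000
#' @export
sampling_schedule <- function(kind = c("loading", "unloading"),
                              total_duration) {
  kind <- match.arg(kind)
  if (!is.numeric(total_duration) || total_duration <= 0) {
    stop("total_duration must be > 0")
  }
  seg <- if (kind == "loading") {
    if (total_duration > 10) {
      tibble::tibble(duration = c(10, total_duration - 10),
                     n_points = c(5000L, 3000L))
    } else {
      tibble::tibble(duration = total_duration,
                     n_points = as.integer(round(5000 * total_duration / 10)))
    }
  } else {
    tibble::tibble(duration = total_duration,
                   n_points = as.integer(round(1000 * total_duration / 60)))
  }
  structure(seg, class = c("sampling_schedule", class(seg)))
}

# Concrete time grid of a schedule: starts at 0, strictly increasing.
schedule_times <- function(schedule) {
  t0 <- 0
  out <- 0
  for (i in seq_len(nrow(schedule))) {
    d <- schedule$duration[i]
    n <- schedule$n_points[i]
    if (i == 1L) {
      out <- seq(0, d, length.out = n)
    } else {
      out <- c(out, t0 + seq_len(n) * d / n)
    }
    t0 <- t0 + d
  }
  out
}

default_schedule <- function(design) {
  if (!is.null(design$schedule)) return(design$schedule)
  sched_kind <- if (design$kind %in% c("loading", "pulse_chase",
                                       "chase_control")) {
    "loading"
  } else {
    "unloading"
  }
  sampling_schedule(sched_kind, design$total_duration)
}

# Integrate a state to (near) steady state: chunked integration until the
# largest relative concentration change drops below `tol` per second.
equilibrate <- function(network, state, chunk = 200, max_chunks = 100,
                        tol = 1e-9) {
  mat <- network_matrices(network)
  deriv <- mass_action_deriv(mat)
  for (i in seq_len(max_chunks)) {
    dy <- deriv(0, state, NULL)[[1L]]
    if (max(abs(dy)) / max(state, 1e-12) < tol) return(state)
    out <- deSolve::lsoda(state, c(0, chunk), deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    state <- stats::setNames(out[nrow(out), -1L], names(state))
    state[state < 0] <- 0
  }
  warning("pre-equilibration did not reach steady state within ",
          chunk * max_chunks, " s", call. = FALSE)
  state
}

#' Simulate a stopped-flow experiment design to a noise-free trace
#'
#' Realizes the mixing scheme of a design: syringe contents are assembled
#' into species states (loader paired with clamp pools), any syringe-A
#' pre-assembled complex containing DNA is pre-equilibrated, each 1:1 mix
#' halves all concentrations, pulse-chase designs integrate the pulse stage
#' for `pulse_duration` before the chase mix, and time is reset to 0 at the
#' final mix. Samples earlier than the dead time are censored.
#'
#' @param design An [experiment_design()].
#' @param params A [rate_parameters()] object.
#' @param scale,baseline FRET observable calibration (arbitrary units).
#' @param fret_coefficients Passed to [build_network()].
#' @param keep_trajectory Logical; attach the full species trajectory as
#'   attribute `"trajectory"`.
#' @return A tibble (class `clamp_trace`) with columns `time_s`, `signal_au`
#'   and attributes `design`, `params`, `scale`, `baseline`, plus
#'   `uncensored` (the trace including sub-dead-time samples, from which the
#'   true t = 0+ jump can be read).
#' @examples
#' tr <- run_design(design_loading(total_duration = 2), rate_parameters())
#' head(tr)
#' @export
run_design <- function(design, params, scale = 1, baseline = 0,
                       fret_coefficients = c(engaged = 0.5, notched = 1.0,
                                             released = 0.6),
                       keep_trajectory = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  params <- validate_rate_parameters(params)

  network_kind <- switch(design$kind,
    loading = "loading",
    pulse_chase = "pulse_chase",
    chase_control = "pulse_chase",
    unload_trap = "unload_trap",
    reload = "reload",
    reload_poldelta = "reload_poldelta"
  )
  all_syr <- c(design$syringe_a, design$syringe_b, design$syringe_c)
  labels <- "lab"
  if (sum(all_syr[names(all_syr) == "clamp_unlabeled"]) > 0 ||
      network_kind != "loading") {
    labels <- c("lab", "unlab")
  }
  network <- build_network(params, network_kind,
                           end_blocked = design$end_blocked,
                           fret_coefficients = fret_coefficients,
                           labels = labels)

  state_a <- initial_state(network, design$syringe_a)
  dna_a <- design$syringe_a["dna"]
  if (!is.na(dna_a) && dna_a > 0) {
    state_a <- if (is.null(design$preincubation)) {
      equilibrate(network, state_a)
    } else {
      out <- integrate_network(network, state_a,
                               c(0, design$preincubation / 2,
                                 design$preincubation))
      y <- unlist(out[nrow(out), network$species$name])
      pmax(y, 0)
    }
  }
  state <- (state_a + initial_state(network, design$syringe_b)) / 2

  if (design$kind == "pulse_chase") {
    pulse_times <- seq(0, design$pulse_duration, length.out = 50)
    pulse <- integrate_network(network, state, pulse_times)
    end <- pmax(unlist(pulse[nrow(pulse), network$species$name]), 0)
    state <- (end + initial_state(network, design$syringe_c)) / 2
  }

  times <- schedule_times(default_schedule(design))
  traj <- integrate_network(network, state, times)
  full <- fret_signal(traj, network, scale = scale, baseline = baseline)
  trace <- full[full$time_s >= design$dead_time, ]

  structure(trace, class = c("clamp_trace", class(trace)),
            design = design, params = params, scale = scale,
            baseline = baseline, uncensored = full,
            trajectory = if (keep_trajectory) traj else NULL,
            network = if (keep_trajectory) network else NULL)
}

#' Add seeded Gaussian measurement noise to a trace
#'
#' Independent zero-mean Gaussian perturbation of every sample, reproducible
#' per seed. The default sigma is 1% of the clean trace's full-scale
#' amplitude.
#'
#' @param trace A trace tibble (`time_s`, `signal_au`).
#' @param sigma Noise standard deviation (a.u.); `NULL` (default) uses
#'   `0.01 * diff(range(signal))`.
#' @param seed Integer RNG seed.
#' @return A tibble (class `noisy_trace`) with metadata attributes
#'   `seed`, `noise_sigma` and the originating design, if available.
#' @export
add_noise <- function(trace, sigma = NULL, seed = 1L) {
  if (is.null(sigma)) sigma <- 0.01 * diff(range(trace$signal_au))
  if (sigma < 0) stop("sigma must be >= 0")
  noisy <- trace
  if (sigma > 0) {
    noisy$signal_au <- trace$signal_au +
      withr::with_seed(seed, stats::rnorm(nrow(trace), 0, sigma))
  }
  structure(tibble::as_tibble(noisy),
            class = c("noisy_trace", class(tibble::as_tibble(noisy))),
            design = attr(trace, "design"), params = attr(trace, "params"),
            scale = attr(trace, "scale"), baseline = attr(trace, "baseline"),
            seed = as.integer(seed), noise_sigma = sigma)
}

#' Simulate a titration series
#'
#' Re-runs a base design while varying one syringe species over a set of
#' concentrations; each member is simulated noise-free and then perturbed
#' with seed `seed + index` so the whole series is reproducible from the
#' base seed. Varying `poldelta` from 0 switches members between the plain
#' reload and the polymerase-capture design automatically.
#'
#' @param base_design An [experiment_design()].
#' @param varied_species One of `loader`, `clamp_labeled`, `clamp_unlabeled`,
#'   `dna`, `poldelta`.
#' @param values Concentrations (nM), all >= 0.
#' @param params A [rate_parameters()] object.
#' @param sigma Noise sigma passed to [add_noise()] (`NULL` for the 1%
#'   default; use 0 for noise-free members).
#' @param seed Base seed.
#' @param ... Passed to [run_design()].
#' @return A tibble with one row per member: `value` (nM),
#'   `labeled_fraction` (post-mix solution labeled-clamp fraction) and a
#'   `trace` list-column of noisy traces (metadata marks them as titration
#'   members).
#' @export
generate_titration_series <- function(base_design, varied_species, values,
                                      params = rate_parameters(),
                                      sigma = NULL, seed = 1L, ...) {
  varied_species <- match.arg(varied_species, SYRINGE_SPECIES)
  if (any(values < 0)) stop("titration values must be >= 0")
  members <- purrr::imap(values, function(v, i) {
    d <- set_design_species(base_design, varied_species, v)
    clean <- run_design(d, params, ...)
    tr <- add_noise(clean, sigma = sigma, seed = seed + i)
    attr(tr, "titration_member") <- list(species = varied_species, value = v,
                                         index = i)
    tr
  })
  tibble::tibble(
    value = values,
    labeled_fraction = purrr::map_dbl(members, ~ labeled_fraction(attr(.x, "design"))),
    trace = members
  )
}

# Replace one species concentration within whichever syringe holds it (the
# chase syringe is never modified); species absent everywhere are added to
# syringe B. Re-validates through the constructor so kind switches (e.g.
# reload <-> reload_poldelta when poldelta crosses 0) stay consistent.
set_design_species <- function(design, species, value) {
  a <- design$syringe_a
  b <- design$syringe_b
  if (species %in% names(a)) {
    a[species] <- value
  } else {
    b[species] <- value
  }
  kind <- design$kind
  if (species == "poldelta" && kind %in% c("reload", "reload_poldelta")) {
    kind <- if (value > 0) "reload_poldelta" else "reload"
  }
  if (species == "poldelta" && value > 0 &&
      !(kind %in% "reload_poldelta")) {
    stop("polymerase cannot be titrated into a ", design$kind, " design")
  }
  experiment_design(kind, a, b, design$syringe_c,
                    pulse_duration = design$pulse_duration,
                    dead_time = design$dead_time,
                    end_blocked = design$end_blocked,
                    total_duration = design$total_duration,
                    preincubation = design$preincubation,
                    schedule = design$schedule)
}

#' Post-mix labeled fraction of the solution clamp pool
#'
#' @param design An [experiment_design()].
#' @return Labeled clamp / total clamp over all syringes (the 1:1 mixes
#'   dilute both pools equally, so syringe totals give the same fraction).
#' @export
labeled_fraction <- function(design) {
  s <- c(design$syringe_a, design$syringe_b, design$syringe_c)
  lab <- sum(s[names(s) == "clamp_labeled"])
  tot <- lab + sum(s[names(s) == "clamp_unlabeled"])
  if (tot == 0) return(NA_real_)
  lab / tot
}
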