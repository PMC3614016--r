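# Microscopic rate constants of the clamp loading/unloading/capture mechanism.
# Units: first-order rates s^-1, bimolecular rates nM^-1 s^-1, K_d nM.

#' Rate parameters of the clamp-loading mechanism
#'
#' Container for every microscopic rate constant and population fraction of
#' the stepwise loading / unloading / polymerase-capture mechanism. Defaults
#' are the values measured for the human RFC/PCNA system by stopped-flow FRET:
#' a conformational step of 6.4 s^-1 producing the FRET rise, a
#' hydrolysis-coupled ring-closure/release step of 1.4 s^-1 producing the FRET
#' drop, and biphasic loader dissociation at 0.40 and 0.039 s^-1 carried by
#' two loader populations present at an 83:17 ratio.
#'
#' @param k_conf First-order rate (s^-1) of the conformational transition of
#'   the initial loader-clamp-DNA encounter complex into the high-FRET
#'   "notched" complex; this is the observed rise rate of loading traces.
#' @param k_close First-order rate (s^-1) of the ATP-hydrolysis-coupled ring
#'   closure and clamp release, producing the observed FRET decrease while the
#'   clamp remains DNA-bound.
#' @param p_fast Fraction in `[0, 1]` of the loader pool belonging to the
#'   fast-dissociating population. Released complexes whose resident loader is
#'   in this population depart at `k_off_fast`, the remainder at `k_off_slow`.
#' @param k_off_fast First-order rate (s^-1) at which the fast loader
#'   population dissociates from DNA, carrying its clamp back into solution.
#' @param k_off_slow Same for the slow loader population.
#' @param k_capture Bimolecular rate (nM^-1 s^-1) of polymerase capture of a
#'   released, DNA-bound clamp (irreversible; forms the holoenzyme and blocks
#'   unloading by physical occlusion).
#' @param k_on_dna Bimolecular rate (nM^-1 s^-1) of association of the
#'   loader-clamp complex with DNA, or the sentinel string
#'   `"instantaneous"` (the default): DNA binding was never rate-limiting at
#'   any loader concentration, so by default it is modelled as
#'   diffusion-limited (numerically 100 nM^-1 s^-1) and completes within the
#'   instrument dead time.
#' @param K_d_rfc_pcna Dissociation constant (nM) of the solution
#'   loader-clamp complex; ~0.2 nM, far below working concentrations, so the
#'   solution loader is essentially always clamp-bound and re-partitions
#'   among clamp pools in proportion to their concentrations.
#' @param k_slide First-order rate (s^-1) at which a released clamp slides off
#'   an unblocked DNA end (active only when a design is simulated with
#'   `end_blocked = FALSE`). Default 0.
#' @param k_subunit_exchange First-order rate (s^-1) of spontaneous clamp
#'   trimer disassembly from DNA (subunit exchange). Default 0; the measured
#'   value for human PCNA is 6.3e-3 s^-1.
#' @param hydrolysis_enabled Logical; `FALSE` models the slowly-hydrolysable
#'   ATP analogue ATPgammaS, forcing the effective `k_close` and `k_off_fast`
#'   to exactly 0 (no hydrolysis-dependent step can proceed).
#'
#' @return An object of class `rate_parameters` (a validated named list).
#' @examples
#' rate_parameters()
#' rate_parameters(hydrolysis_enabled = FALSE)
#' @export
rate_parameters <- function(k_conf = 6.4,
                            k_close = 1.4,
                            p_fast = 0.83,
                            k_off_fast = 0.40,
                            k_off_slow = 0.039,
                            k_capture = 0.01,
                            k_on_dna = "instantaneous",
                            K_d_rfc_pcna = 0.2,
                            k_slide = 0,
                            k_subunit_exchange = 0,
                            hydrolysis_enabled = TRUE) {
  p <- structure(
    list(
      k_conf = k_conf, k_close = k_close, p_fast = p_fast,
      k_off_fast = k_off_fast, k_off_slow = k_off_slow,
      k_capture = k_capture, k_on_dna = k_on_dna,
      K_d_rfc_pcna = K_d_rfc_pcna, k_slide = k_slide,
      k_subunit_exchange = k_subunit_exchange,
      hydrolysis_enabled = isTRUE(hydrolysis_enabled)
    ),
    class = "rate_parameters"
  )
  validate_rate_parameters(p)
}

validate_rate_parameters <- function(p) {
  rates <- c("k_conf", "k_close", "k_off_fast", "k_off_slow", "k_capture",
             "k_slide", "k_subunit_exchange")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  if (!identical(p$k_on_dna, "instantaneous") &&
      (!is.numeric(p$k_on_dna) || length(p$k_on_dna) != 1L ||
       is.na(p$k_on_dna) || p$k_on_dna <= 0)) {
    stop("`k_on_dna` must be a positive rate or \"instantaneous\"",
         call. = FALSE)
  }
  if (!is.numeric(p$p_fast) || length(p$p_fast) != 1L || is.na(p$p_fast) ||
      p$p_fast < 0 || p$p_fast > 1) {
    stop("`p_fast` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(p$K_d_rfc_pcna) || p$K_d_rfc_pcna <= 0) {
    stop("`K_d_rfc_pcna` must be > 0", call. = FALSE)
  }
  p
}

# Numerical stand-in for "instantaneous" bimolecular steps: diffusion-limited
# on the nM scale, > 1e4 s^-1 pseudo-first-order at working concentrations,
# i.e. complete well inside the instrument dead time.
.k_instantaneous <- 100

# Rates after applying the hydrolysis toggle and resolving the sentinel.
effective_rates <- function(params) {
  r <- unclass(params)
  if (identical(r$k_on_dna, "instantaneous")) r$k_on_dna <- .k_instantaneous
  if (!r$hydrolysis_enabled) {
    r$k_close <- 0
    r$k_off_fast <- 0
  }
  r
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters>\n")
  cat(sprintf("  k_conf  %8.4g s^-1   (FRET rise, conformational)\n", x$k_conf))
  cat(sprintf("  k_close %8.4g s^-1   (FRET drop, ring closure/release)\n",
              x$k_close))
  cat(sprintf("  loader populations: %.0f%% fast (k_off %.3g s^-1), %.0f%% slow (k_off %.3g s^-1)\n",
              100 * x$p_fast, x$k_off_fast, 100 * (1 - x$p_fast),
              x$k_off_slow))
  cat(sprintf("  k_capture %.3g nM^-1 s^-1; k_on_dna %s; K_d(loader-clamp) %.3g nM\n",
              x$k_capture,
              if (identical(x$k_on_dna, "instantaneous")) "instantaneous"
              else format(x$k_on_dna), x$K_d_rfc_pcna))
  cat(sprintf("  k_slide %.3g s^-1; k_subunit_exchange %.3g s^-1; hydrolysis %s\n",
              x$k_slide, x$k_subunit_exchange,
              if (x$hydrolysis_enabled) "enabled" else "disabled (ATPgS)"))
  invisible(x)
}

#' Coerce a plain list to rate parameters
#'
#' Used when reading configuration files; unknown fields are an error
#' (fail-fast) so that typos in configs cannot silently fall back to defaults.
#'
#' @param x Named list with a subset of the `rate_parameters()` fields.
#' @return A `rate_parameters` object.
#' @export
as_rate_parameters <- function(x) {
  if (inherits(x, "rate_parameters")) return(x)
  known <- names(formals(rate_parameters))
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("unknown rate parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(rate_parameters, x)
}
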