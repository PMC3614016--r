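# Amplitude-ratio stoichiometry inference: the total amplitude of a reload
# trace divided by the total amplitude of the matched unload trace equals the
# labeled fraction of the solution clamp pool when the loader unloads every
# clamp it loads; with saturating polymerase capture the ratio reaches 1.

#' Reload/unload amplitude ratio
#'
#' Ratio of the total fitted amplitude of the reload (FRET increase) trace to
#' that of the unload (FRET decrease) trace, both on the magnitude
#' convention with the dead-time amplitude excluded (these designs start
#' from equilibrated or trap-quenched states with no sub-dead-time jump).
#' Under full unloading the ratio equals the labeled clamp fraction; with a
#' stoichiometric amount of polymerase it reaches 1. Because both amplitudes
#' are measured in the same arbitrary units the ratio is scale-invariant.
#'
#' @param reload_fit,unload_fit `exp_fit` objects for the reload and unload
#'   traces.
#' @param labeled_fraction Optional known labeled fraction, carried through
#'   for downstream regression.
#' @return A one-row tibble: `a_t_reload`, `a_t_unload`, `ratio`,
#'   `labeled_fraction`.
#' @export
amplitude_ratio <- function(reload_fit, unload_fit,
                            labeled_fraction = NA_real_) {
  stopifnot(inherits(reload_fit, "exp_fit"), inherits(unload_fit, "exp_fit"))
  a_unload <- total_amplitude(unload_fit, include_dead = FALSE)
  if (a_unload <= 0) stop("unload amplitude must be > 0")
  a_reload <- total_amplitude(reload_fit, include_dead = FALSE)
  tibble::tibble(
    a_t_reload = a_reload,
    a_t_unload = a_unload,
    ratio = a_reload / a_unload,
    labeled_fraction = labeled_fraction
  )
}

#' Regression of amplitude ratio on labeled fraction
#'
#' Ordinary least squares of ratio against labeled clamp fraction. Under
#' full unloading the points fall on the identity line: slope ~1, intercept
#' ~0, showing that no clamp is left behind on DNA.
#'
#' @param fractions,ratios Equal-length numeric vectors (>= 2 points).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fraction_regression <- function(fractions, ratios) {
  if (length(fractions) != length(ratios) || length(fractions) < 2L) {
    stop("need equal-length vectors with at least 2 points")
  }
  if (diff(range(fractions)) == 0) stop("degenerate x-values")
  fit <- stats::lm(ratios ~ fractions)
  tss <- sum((ratios - mean(ratios))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  tibble::tibble(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    n = length(fractions)
  )
}

# RSS of the continuous rise-then-plateau model for a fixed junction x0:
# y = intercept + slope * pmin(x, x0), linear in (intercept, slope).
segmented_rss <- function(x0, x, y) {
  X <- cbind(1, pmin(x, x0))
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2),
       intercept = unname(fit$coefficients[1L]),
       slope = unname(fit$coefficients[2L]))
}

#' Break point of a titration series
#'
#' Fits a continuous two-segment model (a rising line joined to a flat
#' plateau) to response-versus-concentration data and returns the junction
#' abscissa: the titrant concentration at which the response saturates.
#' Candidate junctions at the data abscissae are scanned first and the best
#' is refined by golden-section search between its neighbours. When the best
#' junction lies at (or beyond) the last abscissa the rise never saturates
#' and the break point is reported as unbounded (`NA` with
#' `bounded = FALSE`) rather than a number; an all-flat series returns the
#' first abscissa with `slope` 0.
#'
#' @param concentrations Titrant concentrations (nM), >= 4 points spanning
#'   both regimes.
#' @param ratios Response values (e.g. amplitude ratios).
#' @return A one-row tibble: `breakpoint` (nM or `NA`), `bounded`, `slope`,
#'   `intercept`, `plateau` (fitted plateau level), `rss`.
#' @export
titration_breakpoint <- function(concentrations, ratios) {
  x <- as.numeric(concentrations)
  y <- as.numeric(ratios)
  if (length(x) != length(y) || length(x) < 4L) {
    stop("need at least 4 points spanning both regimes")
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  cand <- x[x > min(x)]
  scan <- vapply(cand, function(x0) segmented_rss(x0, x, y)$rss, numeric(1))
  best_i <- which.min(scan)
  # golden-section refinement between the neighbours of the best candidate
  lo <- if (best_i == 1L) min(x) else cand[best_i - 1L]
  hi <- if (best_i == length(cand)) max(x) else cand[best_i + 1L]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  while (b - a > 1e-9 * max(1, max(x))) {
    if (segmented_rss(c1, x, y)$rss < segmented_rss(d1, x, y)$rss) {
      b <- d1
    } else {
      a <- c1
    }
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  }
  x0 <- (a + b) / 2
  sol <- segmented_rss(x0, x, y)

  flat <- diff(range(y)) <= 1e-12 * max(1, max(abs(y)))
  if (flat) {
    return(tibble::tibble(breakpoint = x[1L], bounded = TRUE, slope = 0,
                          intercept = mean(y), plateau = mean(y), rss = 0))
  }
  # unbounded: the two-segment fit is no better than a single line through
  # all points, i.e. the series rises monotonically to the last point
  line <- segmented_rss(max(x), x, y)
  tol <- 1e-10 * max(line$rss, sum(y^2), 1e-300)
  if (x0 >= max(x) - 1e-9 * max(1, max(x)) || line$rss <= sol$rss + tol) {
    return(tibble::tibble(breakpoint = NA_real_, bounded = FALSE,
                          slope = line$slope, intercept = line$intercept,
                          plateau = NA_real_, rss = line$rss))
  }
  tibble::tibble(breakpoint = x0, bounded = TRUE, slope = sol$slope,
                 intercept = sol$intercept,
                 plateau = sol$intercept + sol$slope * x0, rss = sol$rss)
}
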