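# Multi-exponential trace models: y(t) = sum_i A_i exp(-k_i t) + c_inf,
# fitted by variable projection (amplitudes solved linearly for given rates,
# rates optimised on a log scale with deterministic multi-start), plus the
# dead-time amplitude recovery A_dead = c_inf - y0 - sum A_i and derived
# amplitude quantities.

as_trace_df <- function(trace) {
  df <- as.data.frame(trace)
  nms <- names(df)
  tcol <- if ("time_s" %in% nms) "time_s" else nms[1L]
  ycol <- if ("signal_au" %in% nms) "signal_au" else nms[2L]
  out <- data.frame(time = as.numeric(df[[tcol]]),
                    signal = as.numeric(df[[ycol]]))
  if (nrow(out) == 0L) stop("empty trace")
  if (any(diff(out$time) <= 0)) stop("trace time must be strictly increasing")
  out
}

# Linear amplitude/offset solve for fixed rates; returns coefficients and RSS.
varpro_solve <- function(tt, y, k) {
  X <- cbind(exp(-outer(tt, k)), 1)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # rank deficiency from (near-)collapsed rates
  rss <- sum(fit$residuals^2)
  list(amplitude = coefs[seq_along(k)],
       c_inf = coefs[length(k) + 1L], rss = rss)
}

varpro_rss <- function(logk, tt, y) {
  k <- exp(logk)
  X <- cbind(exp(-outer(tt, k)), 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(sum((y - mean(y))^2))
  sum(qr.resid(qrX, y)^2)
}

# Deterministic multi-start seeds: all n-subsets of a log-spaced rate grid,
# pre-screened by projected RSS; the best few are refined with nlminb.
multistart_rates <- function(tt, y, n, n_refine = 6L) {
  grid <- 10^seq(-4, 2, by = 1)
  span_hi <- min(2, log10(10 / max(diff(tt)[1L], 1e-6)))
  grid <- unique(c(grid, 10^span_hi, 1 / max(tt)))
  grid <- sort(grid[grid > 0])
  combos <- utils::combn(seq_along(grid), n)
  score <- apply(combos, 2L, function(ix) varpro_rss(log(grid[ix]), tt, y))
  keep <- order(score)[seq_len(min(n_refine, ncol(combos)))]
  lapply(keep, function(j) log(grid[combos[, j]]))
}

#' Fit a sum of exponentials to a stopped-flow trace
#'
#' Least-squares fit of `y(t) = sum_i A_i exp(-k_i t) + c_inf` with signed
#' amplitudes: in this convention rising phases carry negative amplitudes, so
#' the canonical loading-trace model (one rise, one decay, offset) is the
#' dead-time-modified double exponential. Amplitudes and the offset are
#' solved linearly for any candidate rate vector (variable projection); rates
#' are optimised on a logarithmic scale from a deterministic log-spaced
#' multi-start grid, so the fit is reproducible for fixed inputs.
#'
#' @param trace A data frame with columns `time_s`/`signal_au` (or time and
#'   signal as the first two columns), time strictly increasing.
#' @param n_phases Number of exponential phases, 1 to 4. At least
#'   `10 * n_phases` samples are required.
#' @param y0 Optional signal value at time zero (a.u.), conventionally taken
#'   from a flat no-loader control. When supplied, the unresolvable
#'   within-dead-time amplitude `A_dead` (the fitted curve extrapolated to
#'   time zero minus `y0`; see [dead_time_amplitude()]) is stored.
#' @param reduce_on_collapse Logical (default `FALSE`): when two fitted rates
#'   collapse within 5%, automatically refit with one phase fewer (the action
#'   the collapse warning recommends) instead of returning the ill-conditioned
#'   fit.
#' @return An object of class `exp_fit` with fields `phases` (tibble of
#'   signed `amplitude`, `rate`, standard errors, sorted by descending rate),
#'   `c_inf`, `y0`, `a_dead`, `rss`, `sigma`, `n_points`, and
#'   `phase_collapse` (TRUE when two fitted rates agree within 5%,
#'   with a warning recommending `n_phases - 1`).
#' @examples
#' tt <- seq(0, 60, by = 0.06)
#' y <- 0.35 * exp(-0.32 * tt) + 0.080 * exp(-0.026 * tt)
#' fit <- fit_multiexponential(data.frame(tt, y), 2)
#' fit$phases
#' @export
fit_multiexponential <- function(trace, n_phases, y0 = NULL,
                                 reduce_on_collapse = FALSE) {
  df <- as_trace_df(trace)
  if (!(n_phases %in% 1:4)) stop("n_phases must be between 1 and 4")
  if (nrow(df) < 10 * n_phases) {
    stop("need at least ", 10 * n_phases, " samples for ", n_phases,
         " phases")
  }
  tt <- df$time
  y <- df$signal

  starts <- multistart_rates(tt, y, n_phases)
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, varpro_rss, tt = tt, y = y,
                         lower = log(1e-8), upper = log(1e6),
                         control = list(rel.tol = 1e-14, iter.max = 300))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("multi-exponential fit failed to converge")

  k <- exp(best$par)
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]
  lin <- varpro_solve(tt, y, k)
  A <- unname(lin$amplitude)
  c_inf <- unname(lin$c_inf)
  rss <- lin$rss

  # ill-conditioning: two rates within 5% of each other, or a phase whose
  # amplitude is numerically negligible (an unidentifiable extra phase)
  y_scale <- max(abs(y), diff(range(y)))
  collapse <- n_phases > 1 &&
    (any(k[-length(k)] / k[-1L] < 1.05) || any(abs(A) < 1e-8 * y_scale))
  if (collapse && reduce_on_collapse) {
    return(fit_multiexponential(trace, n_phases - 1L, y0 = y0,
                                reduce_on_collapse = n_phases > 2L))
  }
  if (collapse) {
    warning("phase collapse: two fitted rates agree within 5%; ",
            "consider n_phases = ", n_phases - 1L, call. = FALSE)
  }

  se <- exp_fit_se(tt, y, A, k, rss)
  n <- length(tt)
  p <- 2L * n_phases + 1L
  # dead-time jump: model value extrapolated to t = 0 minus the zero-time
  # reference (the stored amplitudes are exponential coefficients, the
  # negatives of the per-phase net signal changes)
  a_dead <- if (is.null(y0)) NA_real_ else c_inf + sum(A) - y0

  structure(
    list(
      phases = tibble::tibble(amplitude = A, rate = k,
                              se_amplitude = se$A, se_rate = se$k),
      c_inf = c_inf,
      y0 = if (is.null(y0)) NA_real_ else y0,
      a_dead = a_dead,
      rss = rss,
      sigma = sqrt(rss / max(n - p, 1L)),
      n_points = n,
      n_phases = n_phases,
      phase_collapse = collapse,
      trace = tibble::tibble(time_s = tt, signal_au = y)
    ),
    class = "exp_fit"
  )
}

# Asymptotic standard errors from the full (amplitudes, rates, offset)
# Jacobian at the optimum.
exp_fit_se <- function(tt, y, A, k, rss) {
  n <- length(tt)
  p <- 2L * length(k) + 1L
  E <- exp(-outer(tt, k))
  J <- cbind(E, -sweep(E * tt, 2L, A, `*`), 1)
  s2 <- rss / max(n - p, 1L)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(A = rep(NA_real_, length(k)), k = rep(NA_real_, length(k))))
  }
  se <- sqrt(pmax(diag(cov), 0))
  list(A = se[seq_along(k)], k = se[length(k) + seq_along(k)])
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> ", x$n_phases, " phase(s), ", x$n_points, " points, rss ",
      format(x$rss, digits = 4), "\n", sep = "")
  ph <- x$phases
  for (i in seq_len(nrow(ph))) {
    cat(sprintf("  phase %d: A = %+.5g (se %.2g), k = %.5g s^-1 (se %.2g)\n",
                i, ph$amplitude[i], ph$se_amplitude[i], ph$rate[i],
                ph$se_rate[i]))
  }
  cat(sprintf("  c_inf = %.5g", x$c_inf))
  if (!is.na(x$a_dead)) {
    cat(sprintf("; y0 = %.5g; A_dead = %.5g", x$y0, x$a_dead))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a fitted multi-exponential model
#'
#' @param object An `exp_fit`.
#' @param newdata Optional data frame with a `time_s` (or first) column.
#' @param ... Unused.
#' @return Numeric vector of fitted signal values.
#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$trace$time_s
        else as_trace_times(newdata)
  as.vector(exp(-outer(tt, object$phases$rate)) %*%
              object$phases$amplitude) + object$c_inf
}

as_trace_times <- function(newdata) {
  if (is.data.frame(newdata)) {
    if ("time_s" %in% names(newdata)) as.numeric(newdata$time_s)
    else as.numeric(newdata[[1L]])
  } else {
    as.numeric(newdata)
  }
}

#' Dead-time amplitude of a fit
#'
#' The FRET change completed within the instrument dead time cannot be fit to
#' a rate, but its amplitude is recovered from the fitted curve and a
#' zero-time reference: the value at infinite time equals the zero-time value
#' plus the dead-time amplitude plus the net change of every resolved phase,
#' so `A_dead = c_inf - y0 - sum(dA_i)` where `dA_i = -A_i` is the net signal
#' change of phase i (the stored amplitudes are exponential coefficients:
#' rises negative). Equivalently, `A_dead` is the fitted curve extrapolated
#' to time zero minus `y0`, the signal of a flat no-loader control.
#'
#' @param fit An `exp_fit`.
#' @param y0 Signal at time zero (a.u.).
#' @return `A_dead` in arbitrary units.
#' @export
dead_time_amplitude <- function(fit, y0) {
  stopifnot(inherits(fit, "exp_fit"))
  fit$c_inf + sum(fit$phases$amplitude) - y0
}

#' Total amplitude A_T of a fitted trace
#'
#' The sum of the amplitude magnitudes of all resolved phases, optionally
#' including the dead-time amplitude magnitude. Loading-type fits, which have
#' a sub-dead-time jump, conventionally include it; unloading/reload fits
#' start from an equilibrated or trap-quenched state with no dead phase and
#' exclude it.
#'
#' @param fit An `exp_fit`.
#' @param include_dead Logical; default `TRUE` whenever the fit has a stored
#'   dead-time amplitude (i.e. `y0` was supplied).
#' @return `A_T` in arbitrary units.
#' @export
total_amplitude <- function(fit, include_dead = !is.na(fit$a_dead)) {
  stopifnot(inherits(fit, "exp_fit"))
  at <- sum(abs(fit$phases$amplitude))
  if (include_dead) {
    if (is.na(fit$a_dead)) stop("fit has no dead-time amplitude (no y0)")
    at <- at + abs(fit$a_dead)
  }
  at
}

#' Relative amplitudes of the resolved phases
#'
#' Percent of the total resolved amplitude carried by each phase
#' (`100 |A_i| / sum |A_j|`, dead-time amplitude excluded), reported
#' fastest phase first.
#'
#' @param fit An `exp_fit` with at least one phase.
#' @return A tibble with `rate`, `amplitude` and `percent` (sums to 100).
#' @export
relative_amplitudes <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"), nrow(fit$phases) >= 1L)
  a <- abs(fit$phases$amplitude)
  tibble::tibble(rate = fit$phases$rate, amplitude = fit$phases$amplitude,
                 percent = 100 * a / sum(a))
}

#' Half-life of a first-order process
#'
#' @param k First-order rate constant (s^-1), > 0.
#' @return `ln(2) / k` in seconds.
#' @examples
#' half_life(0.058) # ~12 s
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("k must be > 0")
  log(2) / k
}

#' Choose the number of exponential phases
#'
#' Fits models with 0 (constant only) to `max_phases` phases and returns the
#' smallest number of phases n for which adding an (n+1)-th phase either
#' fails an extra-sum-of-squares F-test at `alpha` or collapses onto an
#' existing rate. Fits that already reproduce the data to numerical
#' precision stop the search immediately.
#'
#' @param trace A trace data frame (see [fit_multiexponential()]).
#' @param max_phases Maximum phases to consider (1 to 4).
#' @param alpha F-test significance level (default 0.01).
#' @param y0 Optional zero-time signal, forwarded to the fits.
#' @return A list with `n_phases` (the chosen n), `fit` (the chosen model;
#'   `NULL` for a flat trace), `fits` (all candidates) and `report` (a tibble
#'   of rss, F statistic and p-value per candidate).
#' @export
select_phase_count <- function(trace, max_phases = 4, alpha = 0.01,
                               y0 = NULL) {
  df <- as_trace_df(trace)
  m <- nrow(df)
  rss0 <- sum((df$signal - mean(df$signal))^2)
  scale2 <- sum(df$signal^2) + 1e-300
  fits <- list()
  rss <- c(`0` = rss0)
  report <- tibble::tibble(n_phases = 0L, rss = rss0, f_stat = NA_real_,
                           p_value = NA_real_, collapsed = FALSE)
  chosen <- 0L
  for (n in seq_len(max_phases)) {
    if (rss[[as.character(chosen)]] / scale2 < 1e-18) break  # already exact
    if (m < 10 * n) break
    collapsed <- FALSE
    fit_n <- withCallingHandlers(
      fit_multiexponential(df, n, y0 = y0),
      warning = function(w) {
        if (grepl("phase collapse", conditionMessage(w))) {
          collapsed <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    fits[[as.character(n)]] <- fit_n
    rss[[as.character(n)]] <- fit_n$rss
    p_prev <- 2L * chosen + 1L
    p_new <- 2L * n + 1L
    f <- ((rss[[as.character(chosen)]] - fit_n$rss) / (p_new - p_prev)) /
      (fit_n$rss / max(m - p_new, 1L))
    pval <- stats::pf(f, p_new - p_prev, max(m - p_new, 1L),
                      lower.tail = FALSE)
    report <- dplyr::bind_rows(report, tibble::tibble(
      n_phases = as.integer(n), rss = fit_n$rss, f_stat = f, p_value = pval,
      collapsed = collapsed))
    if (collapsed || !(is.finite(f) && pval < alpha)) break
    chosen <- n
  }
  list(n_phases = chosen,
       fit = if (chosen > 0L) fits[[as.character(chosen)]] else NULL,
       fits = fits, report = report)
}

#' Synthesize a noise-free trace from a fitted model
#'
#' Inverse of [fit_multiexponential()]; useful for self-consistency checks.
#'
#' @param fit An `exp_fit`.
#' @param times Time grid (s).
#' @return A tibble with `time_s`, `signal_au`.
#' @export
synthesize_trace <- function(fit, times = fit$trace$time_s) {
  tibble::tibble(time_s = times,
                 signal_au = predict(fit, data.frame(time_s = times)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multi-exponential fit
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`
#'   (broom convention); phases are numbered fastest first.
#' @export
tidy.exp_fit <- function(x, ...) {
  ph <- x$phases
  n <- nrow(ph)
  tibble::tibble(
    term = c(paste0("A_", seq_len(n)), paste0("k_", seq_len(n)), "c_inf"),
    estimate = c(ph$amplitude, ph$rate, x$c_inf),
    std.error = c(ph$se_amplitude, ph$se_rate, NA_real_)
  )
}

#' Summarise a multi-exponential fit in one row
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return A one-row tibble with phase count, offset, dead-time amplitude,
#'   total amplitude, rss, residual sigma and sample count.
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    n_phases = x$n_phases,
    c_inf = x$c_inf,
    y0 = x$y0,
    a_dead = x$a_dead,
    a_total = total_amplitude(x, include_dead = FALSE),
    rss = x$rss,
    sigma = x$sigma,
    n_points = x$n_points,
    phase_collapse = x$phase_collapse
  )
}
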