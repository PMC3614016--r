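# End-to-end parameter recovery: simulate the reference experiments from a
# known parameter set, analyze them exactly as real data would be, and
# compare fitted quantities with their generating values.

#' End-to-end parameter recovery report
#'
#' Simulates the canonical experiment set from a generating parameter set
#' (with seeded noise), fits each trace with the appropriate exponential
#' model, and tabulates fitted against generating values: the loading rise
#' and decay rates, the biphasic unloading rates and the fast-phase relative
#' amplitude, and the reload/unload amplitude ratios without and with
#' polymerase.
#'
#' @param params Generating [rate_parameters()].
#' @param seed Base seed for the noise.
#' @param sigma Noise sigma (`NULL` = 1% of full scale).
#' @return A tibble with `quantity`, `generating`, `fitted`,
#'   `relative_error`.
#' @export
recover_parameters <- function(params = rate_parameters(), seed = 1L,
                               sigma = NULL) {
  loading <- add_noise(run_design(design_loading(), params),
                       sigma = sigma, seed = seed + 1L)
  unload <- add_noise(run_design(design_unload_trap(), params),
                      sigma = sigma, seed = seed + 2L)
  reload <- add_noise(run_design(design_reload(), params),
                      sigma = sigma, seed = seed + 3L)
  reload_pol <- add_noise(run_design(design_reload(poldelta = 100), params),
                          sigma = sigma, seed = seed + 4L)

  f_load <- fit_multiexponential(loading, 2, y0 = 0)
  f_unload <- fit_multiexponential(unload, 2)
  f_reload <- fit_multiexponential(reload, 2)
  f_reload_pol <- fit_multiexponential(reload_pol, 2)

  rel_amp_fast <- relative_amplitudes(f_unload)$percent[1L]
  rows <- tibble::tribble(
    ~quantity, ~generating, ~fitted,
    "loading rise rate k_inc (s^-1)", params$k_conf,
      f_load$phases$rate[1L],
    "loading decay rate k_dec,1 (s^-1)", params$k_close,
      f_load$phases$rate[2L],
    "unload fast rate k_dec,2 (s^-1)", params$k_off_fast,
      f_unload$phases$rate[1L],
    "unload slow rate k_dec,3 (s^-1)", params$k_off_slow,
      f_unload$phases$rate[2L],
    "unload fast-phase relative amplitude (%)", 100 * params$p_fast,
      rel_amp_fast,
    "amplitude ratio, no polymerase", 0.5,
      amplitude_ratio(f_reload, f_unload)$ratio,
    "amplitude ratio, stoichiometric polymerase", 1.0,
      amplitude_ratio(f_reload_pol, f_unload)$ratio
  )
  dplyr::mutate(rows,
                relative_error = abs(.data$fitted - .data$generating) /
                  abs(.data$generating))
}
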