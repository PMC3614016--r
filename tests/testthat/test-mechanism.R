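# Reaction-network construction, mass-action integration, the FRET
# observable and the analytic sequential-kinetics oracle.

test_that("network construction follows the design kind", {
  p <- ref_params()
  loading <- build_network(p, "loading")
  expect_false(any(grepl("^H", loading$species$name)))
  expect_false(any(loading$species$stage == "trapped/escaped sink"))
  expect_true(all(loading$species$label[loading$species$fret > 0] == "lab"))

  pol <- build_network(p, "reload_poldelta")
  expect_true("H_lab" %in% pol$species$name)
  # a captured clamp has no unloading reaction: no reaction consumes a
  # holoenzyme species and returns clamp to solution
  h_idx <- which(pol$species$name %in% c("H_lab", "H_unlab"))
  consuming <- purrr::keep(pol$reactions, ~ any(.x$reactants %in% h_idx))
  expect_length(consuming, 0L)

  # hydrolysis disabled: nothing downstream of the notched complex
  net_gs <- build_network(rate_parameters(hydrolysis_enabled = FALSE),
                          "loading")
  expect_false(any(grepl("^close_", purrr::map_chr(net_gs$reactions, "name"))))

  slide <- build_network(rate_parameters(k_slide = 0.1), "unload_trap",
                         end_blocked = FALSE)
  expect_true("Xslide_lab" %in% slide$species$name)
})

test_that("FRET coefficients are zero except for DNA-bound labeled clamp", {
  net <- build_network(ref_params(), "reload_poldelta")
  off_dna <- net$species$location == "solution" | net$species$label != "lab"
  expect_true(all(net$fret[off_dna] == 0))
  expect_true(all(net$fret >= 0 & net$fret <= 1))
})

test_that("invalid parameters are rejected", {
  expect_error(rate_parameters(k_conf = -1), "non-negative")
  expect_error(rate_parameters(p_fast = 1.2), "0, 1")
  expect_error(rate_parameters(K_d_rfc_pcna = 0), "> 0")
  expect_error(rate_parameters(k_on_dna = "fast"), "instantaneous")
})

test_that("with all rate constants zero, concentrations stay constant", {
  p <- rate_parameters(k_conf = 0, k_close = 0, k_off_fast = 0,
                       k_off_slow = 0, k_on_dna = 1e-300,
                       K_d_rfc_pcna = 1e-300)
  net <- build_network(p, "loading")
  # drop the fast loader-clamp pairing reactions as well by starting from a
  # state with no free loader or clamp
  y0 <- initial_state(net, c(loader = 50, clamp_labeled = 50, dna = 100))
  tr <- integrate_network(net, y0, seq(0, 5, by = 0.5))
  for (nm in net$species$name) {
    expect_equal(unname(unlist(tr[, nm])), rep(y0[[nm]], nrow(tr)),
                 tolerance = 1e-10)
  }
})

test_that("integrator matches the closed-form sequential oracle", {
  # E -> N -> R with unloading switched off is exactly the A -> B -> C chain
  p <- rate_parameters(k_off_fast = 0, k_off_slow = 0, p_fast = 1)
  net <- build_network(p, "loading")
  y0 <- stats::setNames(numeric(nrow(net$species)), net$species$name)
  y0[["E_fast_lab"]] <- 1
  tt <- seq(0, 10, by = 0.005)
  tr <- integrate_network(net, y0, tt)
  cf <- closed_form_sequential(6.4, 1.4, tt)
  expect_lt(max(abs(tr$E_fast_lab - cf$A)), 1e-6)
  expect_lt(max(abs(tr$N_fast_lab - cf$B)), 1e-6)
  expect_lt(max(abs(tr$R_fast_lab - cf$C)), 1e-6)
  # intermediate peaks at ln(k1/k2)/(k1-k2)
  t_peak <- log(6.4 / 1.4) / (6.4 - 1.4)
  expect_equal(tt[which.max(tr$N_fast_lab)], t_peak, tolerance = 0.01)
})

test_that("closed-form sequential kinetics behaves at its boundaries", {
  cf0 <- closed_form_sequential(6.4, 1.4, 0)
  expect_equal(unlist(cf0[, c("A", "B", "C")]), c(A = 1, B = 0, C = 0))
  cf_inf <- closed_form_sequential(6.4, 1.4, 1e4)
  expect_equal(unlist(cf_inf[, c("A", "B", "C")]), c(A = 0, B = 0, C = 1),
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(closed_form_sequential(2, 3, 0:10)[, -1]) - 1)
                  < 1e-12))
  # dB/dt = 0 at the peak, from the differentiated closed form
  t_peak <- log(6.4 / 1.4) / (6.4 - 1.4)
  dB <- function(t) 6.4 / (1.4 - 6.4) *
    (-6.4 * exp(-6.4 * t) + 1.4 * exp(-1.4 * t))
  expect_lt(abs(dB(t_peak)), 1e-6)
  expect_error(closed_form_sequential(2, 2, 1), "degenerate")
  expect_error(closed_form_sequential(-1, 2, 1), "positive")
})

test_that("every conserved total is constant along trajectories", {
  p <- ref_params()
  for (kind in c("loading", "unload_trap", "reload_poldelta")) {
    net <- build_network(p, kind)
    conc <- c(loader = 50, clamp_labeled = 25, clamp_unlabeled = 50,
              dna = 100)
    if (kind == "loading") conc <- conc[names(conc) != "clamp_unlabeled"]
    if (kind == "reload_poldelta") conc <- c(conc, poldelta = 50)
    y0 <- initial_state(net, conc)
    tr <- integrate_network(net, y0, seq(0, 60, length.out = 200))
    drift <- clampflow:::conservation_drift(tr, net)
    expect_lt(max(drift), 1e-6)
    expect_true(all(as.matrix(tr[, net$species$name]) > -1e-9))
  }
})

test_that("fret_signal is the weighted species sum and validates alignment", {
  p <- ref_params()
  net <- build_network(p, "loading")
  y0 <- initial_state(net, c(loader = 50, clamp_labeled = 50, dna = 100))
  tr <- integrate_network(net, y0, seq(0, 1, by = 0.01))
  # a single unit coefficient reproduces that species' concentration series
  net1 <- net
  net1$fret[] <- 0
  net1$fret[["N_fast_lab"]] <- 1
  sig <- fret_signal(tr, net1)
  expect_equal(sig$signal_au, tr$N_fast_lab)
  # zero coefficients give a flat baseline
  net0 <- net
  net0$fret[] <- 0
  expect_true(all(fret_signal(tr, net0, baseline = 0.3)$signal_au == 0.3))
  # misaligned species are an error
  tr2 <- tr[, 1:5]
  expect_error(fret_signal(tr2, net), "aligned")
})

test_that("unloading is complete: with a large trap the signal returns to baseline", {
  d <- design_unload_trap(chase = 2e5, total_duration = 240)
  tr <- run_design(d, ref_params())
  expect_lt(tr$signal_au[nrow(tr)], 0.01 * max(tr$signal_au))
})

test_that("polymerase occlusion makes the final bound signal invariant to unload rates", {
  final_bound <- function(koff_f, koff_s) {
    p <- rate_parameters(k_off_fast = koff_f, k_off_slow = koff_s,
                         k_capture = 1)
    d <- design_reload(poldelta = 400, total_duration = 200)
    tr <- run_design(d, p, keep_trajectory = TRUE)
    b <- bound_labeled_signal(tr)
    b[length(b)]
  }
  b1 <- final_bound(0.40, 0.039)
  b2 <- final_bound(0.80, 0.020)
  expect_equal(b1, b2, tolerance = 0.01)
})

test_that("integrate_network validates its inputs", {
  net <- build_network(ref_params(), "loading")
  y0 <- initial_state(net, c(loader = 10, clamp_labeled = 10, dna = 10))
  expect_error(integrate_network(net, y0, c(1, 2)), "starting at 0")
  expect_error(integrate_network(net, y0, c(0, 1, 1)), "strictly increasing")
  expect_error(integrate_network(net, -y0, c(0, 1)), ">= 0")
  expect_error(initial_state(net, c(widget = 5)), "unknown species")
})
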