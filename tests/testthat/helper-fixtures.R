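# Shared fixtures: everything is generated in code at test time.

# Mechanism defaults used throughout (the reference parameter set).
ref_params <- function(...) rate_parameters(...)

# A clean multi-exponential trace y = sum A_i exp(-k_i t) + c on a grid.
synth_multiexp <- function(tt, A, k, c = 0) {
  tibble::tibble(
    time_s = tt,
    signal_au = as.vector(exp(-outer(tt, k)) %*% A) + c
  )
}

# Sum of DNA-bound labeled-clamp signal from a kept trajectory.
bound_labeled_signal <- function(trace) {
  traj <- attr(trace, "trajectory")
  net <- attr(trace, "network")
  stopifnot(!is.null(traj), !is.null(net))
  sp <- net$species
  keep <- sp$name[sp$label == "lab" & sp$location == "DNA-bound"]
  w <- net$fret[keep]
  as.vector(as.matrix(traj[, keep, drop = FALSE]) %*% w)
}
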