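# Reaction-network construction for the stepwise clamp loading/unloading/
# capture mechanism, and deterministic mass-action integration.
#
# Species bookkeeping. Clamps are Cy5-labeled ("lab") or unlabeled ("unlab");
# the loader exists as two populations ("fast"/"slow") differing only in
# their DNA dissociation rate. DNA-bound stages, per (population, label):
#   E  - initial loader-clamp-DNA encounter complex (intermediate FRET)
#   N  - notched (spiral) high-FRET complex, pre-hydrolysis
#   R  - released complex: ring closed around DNA, loader still resident
#   HP - holoenzyme with loader still resident (polymerase has captured R)
# plus, per label: H (holoenzyme after loader departure), sink species for
# slide-off and subunit exchange. Solution species: free loader L_<pop>,
# free clamps C_<label>, loader-clamp complexes LC_<pop>_<label>, free DNA D,
# free polymerase P. FRET is emitted only by DNA-bound Cy5-labeled stages.

LOADER_POPS <- c("fast", "slow")
CLAMP_LABELS <- c("lab", "unlab")

#' Build the clamp loading/unloading/capture reaction network
#'
#' Encodes the stepwise mechanism as an explicit mass-action reaction list:
#' the solution loader-clamp complex binds DNA, converts to the high-FRET
#' notched complex at `k_conf`, closes/releases the ring at `k_close`, and the
#' resident loader finally departs together with the clamp at `k_off_fast` or
#' `k_off_slow` depending on its population (no clamp is left behind on DNA).
#' A polymerase-capture branch from released complexes to the holoenzyme is
#' present only for the `reload_poldelta` design; a captured clamp has no
#' unloading reaction (capture blocks unloading by physical occlusion) and its
#' resident loader departs at the unchanged population rate. A slide-off sink
#' exists only when `end_blocked = FALSE`; a subunit-exchange sink only when
#' `k_subunit_exchange > 0`.
#'
#' @param params A [rate_parameters()] object.
#' @param design_kind One of `"loading"`, `"pulse_chase"`, `"unload_trap"`,
#'   `"reload"`, `"reload_poldelta"`. Controls which clamp label pools and
#'   whether the polymerase branch are present.
#' @param end_blocked Logical; `TRUE` (default) models the biotin/Neutravidin
#'   block at the DNA end. `FALSE` opens the slide-off channel at `k_slide`.
#' @param fret_coefficients Named numeric FRET weight per DNA-bound stage of a
#'   labeled clamp: `engaged` (default 0.5), `notched` (1.0), `released`
#'   (0.6, also used for captured/holoenzyme stages where the closed ring
#'   remains DNA-bound). All solution species and unlabeled species are 0.
#' @param labels Character subset of `c("lab", "unlab")`; defaults depend on
#'   `design_kind` (`loading` uses only the labeled pool).
#'
#' @return An object of class `clamp_network`: species table, reaction list,
#'   FRET coefficient vector and conservation (composition) matrix.
#' @examples
#' net <- build_network(rate_parameters(), "loading")
#' net$species$name
#' @export
build_network <- function(params,
                          design_kind = c("loading", "pulse_chase",
                                          "unload_trap", "reload",
                                          "reload_poldelta"),
                          end_blocked = TRUE,
                          fret_coefficients = c(engaged = 0.5, notched = 1.0,
                                                released = 0.6),
                          labels = NULL) {
  params <- validate_rate_parameters(params)
  design_kind <- match.arg(design_kind)
  r <- effective_rates(params)

  fc <- c(engaged = 0.5, notched = 1.0, released = 0.6)
  fc[names(fret_coefficients)] <- fret_coefficients
  if (any(fc < 0 | fc > 1)) stop("fret coefficients must lie in [0, 1]")

  if (is.null(labels)) {
    labels <- if (design_kind == "loading") "lab" else CLAMP_LABELS
  }
  labels <- match.arg(labels, CLAMP_LABELS, several.ok = TRUE)
  pops <- LOADER_POPS[c(params$p_fast > 0, params$p_fast < 1)]
  has_pol <- design_kind == "reload_poldelta"
  has_slide <- !end_blocked
  has_sx <- r$k_subunit_exchange > 0

  # --- species table -------------------------------------------------------
  sp <- list()
  add_sp <- function(name, label, pop, location, stage, fret,
                     n_dna, n_clamp, n_loader, n_pol) {
    sp[[length(sp) + 1L]] <<- tibble::tibble(
      name = name, label = label, pop = pop, location = location,
      stage = stage, fret = fret, n_dna = n_dna, n_clamp = n_clamp,
      n_loader = n_loader, n_pol = n_pol
    )
  }
  add_sp("D", "none", NA, "solution", "free reagent", 0, 1, 0, 0, 0)
  for (pp in pops) {
    add_sp(paste0("L_", pp), "none", pp, "solution", "free reagent",
           0, 0, 0, 1, 0)
  }
  for (lb in labels) {
    add_sp(paste0("C_", lb), lb, NA, "solution", "free reagent",
           0, 0, 1, 0, 0)
  }
  if (has_pol) add_sp("P", "none", NA, "solution", "free reagent",
                      0, 0, 0, 0, 1)
  for (pp in pops) {
    for (lb in labels) {
      sfx <- paste0("_", pp, "_", lb)
      lab_fret <- lb == "lab"
      add_sp(paste0("LC", sfx), lb, pp, "solution", "loader-clamp complex",
             0, 0, 1, 1, 0)
      add_sp(paste0("E", sfx), lb, pp, "DNA-bound", "initial DNA-bound complex",
             if (lab_fret) fc[["engaged"]] else 0, 1, 1, 1, 0)
      add_sp(paste0("N", sfx), lb, pp, "DNA-bound", "engaged (notched) complex",
             if (lab_fret) fc[["notched"]] else 0, 1, 1, 1, 0)
      add_sp(paste0("R", sfx), lb, pp, "DNA-bound",
             paste0("released-", pp),
             if (lab_fret) fc[["released"]] else 0, 1, 1, 1, 0)
      if (has_pol) {
        add_sp(paste0("HP", sfx), lb, pp, "DNA-bound", "holoenzyme",
               if (lab_fret) fc[["released"]] else 0, 1, 1, 1, 1)
      }
    }
  }
  for (lb in labels) {
    if (has_pol) {
      add_sp(paste0("H_", lb), lb, NA, "DNA-bound", "holoenzyme",
             if (lb == "lab") fc[["released"]] else 0, 1, 1, 0, 1)
    }
    if (has_slide) {
      add_sp(paste0("Xslide_", lb), lb, NA, "solution", "trapped/escaped sink",
             0, 0, 1, 0, 0)
    }
    if (has_sx) {
      add_sp(paste0("Xsx_", lb), lb, NA, "solution", "trapped/escaped sink",
             0, 0, 1, 0, 0)
    }
  }
  species <- dplyr::bind_rows(sp)
  idx <- stats::setNames(seq_len(nrow(species)), species$name)

  # --- reactions -----------------------------------------------------------
  rx <- list()
  add_rx <- function(name, reactants, products, rate) {
    if (rate > 0) {
      rx[[length(rx) + 1L]] <<- list(
        name = name, reactants = unname(idx[reactants]),
        products = unname(idx[products]), rate = rate,
        molecularity = length(reactants)
      )
    }
  }
  k_pc_on <- .k_instantaneous                 # loader (re)binding free clamp
  k_pc_off <- k_pc_on * r$K_d_rfc_pcna        # keeps K_d at its stated value
  for (pp in pops) {
    L <- paste0("L_", pp)
    koff <- if (pp == "fast") r$k_off_fast else r$k_off_slow
    for (lb in labels) {
      sfx <- paste0("_", pp, "_", lb)
      C <- paste0("C_", lb)
      LC <- paste0("LC", sfx); E <- paste0("E", sfx)
      N <- paste0("N", sfx); R <- paste0("R", sfx)
      add_rx(paste0("bind_clamp", sfx), c(L, C), LC, k_pc_on)
      add_rx(paste0("release_clamp", sfx), LC, c(L, C), k_pc_off)
      add_rx(paste0("bind_dna", sfx), c(LC, "D"), E, r$k_on_dna)
      add_rx(paste0("notch", sfx), E, N, r$k_conf)
      add_rx(paste0("close", sfx), N, R, r$k_close)
      # joint departure: loader and clamp leave DNA together, both to solution
      add_rx(paste0("unload", sfx), R, c(L, C, "D"), koff)
      if (has_pol) {
        HP <- paste0("HP", sfx)
        add_rx(paste0("capture", sfx), c(R, "P"), HP, r$k_capture)
        add_rx(paste0("loader_departs", sfx), HP,
               c(paste0("H_", lb), L), koff)
      }
      if (has_slide) {
        add_rx(paste0("slide_off", sfx), R,
               c(paste0("Xslide_", lb), L, "D"), r$k_slide)
      }
      if (has_sx) {
        X <- paste0("Xsx_", lb)
        add_rx(paste0("sx_E", sfx), E, c(X, L, "D"), r$k_subunit_exchange)
        add_rx(paste0("sx_N", sfx), N, c(X, L, "D"), r$k_subunit_exchange)
        add_rx(paste0("sx_R", sfx), R, c(X, L, "D"), r$k_subunit_exchange)
        if (has_pol) {
          add_rx(paste0("sx_HP", sfx), paste0("HP", sfx),
                 c(X, L, "D", "P"), r$k_subunit_exchange)
        }
      }
    }
  }
  if (has_pol && has_sx) {
    for (lb in labels) {
      add_rx(paste0("sx_H_", lb), paste0("H_", lb),
             c(paste0("Xsx_", lb), "D", "P"), r$k_subunit_exchange)
    }
  }

  structure(
    list(
      species = species,
      reactions = rx,
      fret = stats::setNames(species$fret, species$name),
      composition = as.matrix(species[, c("n_dna", "n_clamp",
                                          "n_loader", "n_pol")]),
      params = params,
      design_kind = design_kind,
      end_blocked = end_blocked,
      pops = pops,
      labels = labels
    ),
    class = "clamp_network"
  )
}

#' @export
print.clamp_network <- function(x, ...) {
  cat("<clamp_network> ", x$design_kind, ": ", nrow(x$species),
      " species, ", length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

# Stoichiometry matrix (species x reactions) and vectorised propensity data.
network_matrices <- function(network) {
  ns <- nrow(network$species)
  nr <- length(network$reactions)
  S <- matrix(0, ns, nr)
  r1 <- integer(nr)
  r2 <- rep.int(ns + 1L, nr)  # index of a constant-1 dummy entry
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    rx <- network$reactions[[j]]
    for (i in rx$reactants) S[i, j] <- S[i, j] - 1
    for (i in rx$products) S[i, j] <- S[i, j] + 1
    r1[j] <- rx$reactants[1L]
    if (rx$molecularity == 2L) r2[j] <- rx$reactants[2L]
    k[j] <- rx$rate
  }
  list(S = S, r1 = r1, r2 = r2, k = k, ns = ns)
}

mass_action_deriv <- function(mat) {
  force(mat)
  function(t, y, parms) {
    ye <- c(y, 1)
    v <- mat$k * ye[mat$r1] * ye[mat$r2]
    list(as.vector(mat$S %*% v))
  }
}

#' Build a full initial-state vector for a network
#'
#' Distributes named reagent totals over the network's species: free DNA and
#' polymerase map directly; the loader is split `p_fast : (1 - p_fast)` over
#' its populations and paired with clamp pools in proportion to their
#' concentrations (the loader-clamp complex is far below its K_d, so loader
#' in solution is essentially always clamp-bound); clamp left over remains
#' free.
#'
#' @param network A `clamp_network`.
#' @param concentrations Named numeric (nM): any of `loader`, `clamp_labeled`,
#'   `clamp_unlabeled`, `dna`, `poldelta`.
#' @return Named numeric vector over all network species.
#' @export
initial_state <- function(network, concentrations) {
  allowed <- c("loader", "clamp_labeled", "clamp_unlabeled", "dna", "poldelta")
  bad <- setdiff(names(concentrations), allowed)
  if (length(bad)) stop("unknown species label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  gv <- function(nm) if (nm %in% names(concentrations))
    unname(concentrations[[nm]]) else 0

  y <- stats::setNames(numeric(nrow(network$species)), network$species$name)
  clamp <- c(lab = gv("clamp_labeled"), unlab = gv("clamp_unlabeled"))
  for (lb in CLAMP_LABELS) {
    if (clamp[[lb]] > 0 && !(lb %in% network$labels)) {
      stop("design supplies ", lb, " clamp but the network lacks that pool")
    }
  }
  if (gv("poldelta") > 0 && !("P" %in% names(y))) {
    stop("polymerase supplied but this design kind has no polymerase branch")
  }
  if ("D" %in% names(y)) y[["D"]] <- gv("dna")
  if ("P" %in% names(y)) y[["P"]] <- gv("poldelta")

  loader <- gv("loader")
  ctot <- sum(clamp[network$labels])
  pool_frac <- c(fast = network$params$p_fast,
                 slow = 1 - network$params$p_fast)
  complexed <- min(loader, ctot)
  for (pp in network$pops) {
    free_l <- (loader - complexed) * pool_frac[[pp]]
    if (free_l > 0) y[[paste0("L_", pp)]] <- free_l
    for (lb in network$labels) {
      if (ctot > 0) {
        y[[paste0("LC_", pp, "_", lb)]] <-
          complexed * pool_frac[[pp]] * clamp[[lb]] / ctot
      }
    }
  }
  for (lb in network$labels) {
    y[[paste0("C_", lb)]] <- clamp[[lb]] -
      if (ctot > 0) complexed * clamp[[lb]] / ctot else 0
  }
  y
}

#' Integrate a reaction network deterministically
#'
#' Mass-action ODE integration with `deSolve::lsoda` (stiff-capable; the
#' "instantaneous" binding steps make the system stiff by design). The
#' returned trajectory is checked for conservation of total DNA, clamp,
#' loader and polymerase to a relative 1e-6.
#'
#' @param network A `clamp_network`.
#' @param init Named initial concentrations (nM) over all species, e.g. from
#'   [initial_state()].
#' @param times Strictly increasing time grid (s) starting at 0.
#' @param rtol,atol Integrator tolerances (defaults 1e-8, 1e-10).
#' @return A tibble (class `clamp_trajectory`): `time` plus one column per
#'   species.
#' @examples
#' net <- build_network(rate_parameters(), "loading")
#' y0 <- initial_state(net, c(loader = 100, clamp_labeled = 100, dna = 100))
#' tr <- integrate_network(net, y0, seq(0, 2, by = 0.01))
#' @export
integrate_network <- function(network, init, times, rtol = 1e-8,
                              atol = 1e-10) {
  stopifnot(inherits(network, "clamp_network"))
  if (any(init < 0)) stop("initial concentrations must be >= 0")
  if (length(times) < 2L || times[1L] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be a strictly increasing grid starting at 0")
  }
  y0 <- stats::setNames(numeric(nrow(network$species)),
                        network$species$name)
  y0[names(init)] <- init
  mat <- network_matrices(network)
  out <- deSolve::lsoda(y0, times, mass_action_deriv(mat), parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (nrow(out) < length(times)) {
    stop("integrator failed to converge at t = ", out[nrow(out), 1L], " s")
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj)[1L] <- "time"
  check_conservation(traj, network)
  structure(traj, class = c("clamp_trajectory", class(traj)),
            network = network)
}

# Relative drift of each conserved total across a trajectory.
conservation_drift <- function(trajectory, network) {
  Y <- as.matrix(trajectory[, network$species$name, drop = FALSE])
  totals <- Y %*% network$composition
  t0 <- totals[1L, ]
  scale <- pmax(abs(t0), 1e-12)
  apply(abs(sweep(totals, 2L, t0)), 2L, max) / scale
}

check_conservation <- function(trajectory, network, tol = 1e-6) {
  drift <- conservation_drift(trajectory, network)
  if (any(drift > tol)) {
    warning("conservation drift exceeds ", tol, ": ",
            paste(sprintf("%s %.2e", names(drift), drift), collapse = ", "),
            call. = FALSE)
  }
  invisible(drift)
}

#' FRET observable of a trajectory
#'
#' The scalar stopped-flow signal: a linear combination of species
#' concentrations weighted by their FRET coefficients (non-zero only for
#' species carrying a Cy5-labeled clamp on DNA, where the Cy3 donor on the
#' DNA and the Cy5 acceptor on the clamp are in close proximity), scaled to
#' arbitrary units plus a baseline.
#'
#' @param trajectory A `clamp_trajectory` from [integrate_network()].
#' @param network The `clamp_network` the trajectory was produced from.
#' @param scale Arbitrary-units multiplier (default 1).
#' @param baseline Additive offset in arbitrary units (default 0).
#' @return A tibble with columns `time_s`, `signal_au`.
#' @export
fret_signal <- function(trajectory, network, scale = 1, baseline = 0) {
  nms <- network$species$name
  if (!all(nms %in% names(trajectory))) {
    stop("trajectory and network species are not aligned")
  }
  Y <- as.matrix(trajectory[, nms, drop = FALSE])
  tibble::tibble(
    time_s = trajectory$time,
    signal_au = baseline + scale * as.vector(Y %*% network$fret[nms])
  )
}

#' Closed-form occupancies of the irreversible two-step chain A -> B -> C
#'
#' Textbook sequential first-order kinetics, used as an independent analytic
#' oracle for the numerical integrator: `A = exp(-k1 t)`,
#' `B = k1/(k2-k1) (exp(-k1 t) - exp(-k2 t))`, `C = 1 - A - B`, with unit
#' starting occupancy of A. The intermediate peaks at
#' `t = ln(k1/k2)/(k1-k2)`.
#'
#' @param k1,k2 Positive, distinct first-order rates (s^-1).
#' @param t Vector of times (s).
#' @return A tibble with columns `time`, `A`, `B`, `C` (occupancies summing
#'   to 1).
#' @examples
#' closed_form_sequential(6.4, 1.4, c(0, 0.304))
#' @export
closed_form_sequential <- function(k1, k2, t) {
  if (!is.numeric(k1) || !is.numeric(k2) || k1 <= 0 || k2 <= 0) {
    stop("k1 and k2 must be positive")
  }
  if (k1 == k2) stop("degenerate case k1 == k2 is not supported")
  A <- exp(-k1 * t)
  B <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  tibble::tibble(time = t, A = A, B = B, C = 1 - A - B)
}
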