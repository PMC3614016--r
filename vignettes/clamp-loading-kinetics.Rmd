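---
title: "Modelling stopped-flow FRET kinetics of sliding-clamp loading and unloading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stopped-flow FRET kinetics of sliding-clamp loading and unloading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampflow)
```

## The system and the observable

The human sliding clamp PCNA is loaded onto primer/template (P/T) DNA
junctions by its ATP-driven loader RFC, and the same loader also removes it.
DNA polymerase delta completes holoenzyme assembly by capturing a loaded
clamp, which occludes the loader's unloading activity. `clampflow` models
this cycle as a mass-action reaction network and reproduces the stopped-flow
FRET experiments used to dissect it: a Cy3 donor on the DNA and a Cy5
acceptor on the clamp produce signal only while a labeled clamp is on DNA,
so the arbitrary-units fluorescence trace is a weighted sum of DNA-bound
labeled species concentrations.

The mechanism, per clamp label and loader population:

1. the solution loader-clamp complex binds DNA (not rate-limiting at any
   loader concentration tested, so "instantaneous" by default);
2. a conformational step at `k_conf` (default 6.4 s^-1) forms the spiral
   "notched" complex, observed as the FRET rise of loading traces;
3. ATP-hydrolysis-coupled ring closure and clamp release at `k_close`
   (default 1.4 s^-1), observed as the FRET decrease while the closed clamp
   remains DNA-bound;
4. the resident loader departs together with its clamp at `k_off_fast`
   (default 0.40 s^-1) or `k_off_slow` (default 0.039 s^-1) depending on
   which loader population carries it — no clamp is left behind on DNA;
5. when polymerase is present, it captures released clamps bimolecularly
   (`k_capture`, default 0.01 nM^-1 s^-1, irreversible), forming the
   holoenzyme; the captured clamp has no unloading reaction, and the
   occluded loader still departs at its unchanged population rate.

Optional channels: clamp slide-off from an unblocked DNA end (`k_slide`,
active only with `end_blocked = FALSE`) and spontaneous clamp-trimer
disassembly (`k_subunit_exchange`, measured at 6.3e-3 s^-1, default 0).
Setting `hydrolysis_enabled = FALSE` models ATPgammaS: the effective
`k_close` and `k_off_fast` are forced to zero, so no step downstream of the
notched complex can proceed and simulated traces never show a FRET decrease.

## Why two pre-existing loader populations

Biphasic loader dissociation could arise either from a branch at ring
closure (each released complex becoming fast- or slow-dissociating with
probability `p_fast`) or from two pre-existing loader forms. Both schemes
are biexponential in a single-turnover (pulse-chase) experiment and cannot
be distinguished there. They differ sharply, however, in experiments that
start from the *loading equilibrium*: with a branch at closure, steady-state
occupancies weight each released pool by the inverse of its exit rate, so
the slow pool dominates the pre-equilibrated population and a trap-chase
decay would show a fast:slow amplitude split of roughly 38:62. The measured
split is 83:17. With two pre-existing loader populations present at
`p_fast : (1 - p_fast)`, essentially all of each population's clamp is
DNA-bound at equilibrium and the trap-decay amplitudes directly report the
population fractions, matching the measurement. `clampflow` therefore
implements loader heterogeneity, with `p_fast = 0.83` taken from the
measured relative amplitudes.

## Numerical realization

The network is integrated with `deSolve::lsoda` (relative tolerance 1e-8,
absolute 1e-10). Two conventions keep the system pure mass action while
honouring steps the experiments show to be effectively instantaneous:

* **DNA binding** uses 100 nM^-1 s^-1 for the sentinel `"instantaneous"` —
  over 1e4 s^-1 pseudo-first-order at working concentrations, complete well
  inside the 2 ms dead time.
* **Solution re-partitioning**: unloading returns loader and clamp to
  solution as separate species; the free loader re-binds free clamp at
  100 nM^-1 s^-1 (dissociating at `100 * K_d` to preserve the ~0.2 nM
  dissociation constant). Because all clamp pools compete at the same
  diffusion-limited rate, the loader re-partitions in proportion to pool
  concentrations, as the tight loader-clamp interaction implies. These fast
  finite stand-ins leave sub-percent residues in quantities that would be
  exact under truly instantaneous partitioning (e.g. the amplitude-ratio =
  labeled-fraction identity holds to ~0.5%).

Every trajectory is checked for conservation of total DNA, clamp trimers,
loader and polymerase to a relative 1e-6, and the integrator is verified
pointwise (to 1e-6 over 0-10 s) against the closed-form solution of the
irreversible two-step chain, whose intermediate peaks at
`ln(k1/k2)/(k1 - k2)` — about 0.304 s for the default loading rates.

Pre-assembled complexes (the loaded state that unload-trap and reload
experiments start from) are pre-equilibrated by chunked integration until
the largest relative concentration change falls below 1e-9 per second.
When a leak channel (slide-off, subunit exchange) would drain the true
steady state entirely, a finite `preincubation` time is used instead,
mirroring the finite bench incubation; the recovered rate constants do not
depend on the choice.

## Experiment designs and the synthetic-data generator

Designs are declarative (`experiment_design()`, with constructors for the
canonical layouts). Syringe contents are *pre-mix* concentrations; every
1:1 stopped-flow mix halves all concentrations, pulse-chase designs
integrate a 37 ms pulse before the chase mix, and time zero is the
completion of the final mix. Sampling follows the instrument schedules:
5000 points over the first 10 s plus 3000 over the remainder for loading
traces, 1000 points per 60 s for unloading traces. Samples earlier than the
dead time (default 2 ms — any positive value exercises the dead-time
amplitude recovery; the instrument value is not published) are censored.
Measurement noise is additive, Gaussian, seeded, with sigma defaulting to
1% of the clean full-scale amplitude. Titration members derive their seeds
as `seed + index`, so a whole series is reproducible from one seed.

FRET weights per DNA-bound stage of a labeled clamp are conventions
(`engaged` 0.5, `notched` 1.0, `released`/holoenzyme 0.6, solution species
0); the true per-stage FRET efficiencies are not published. The defaults
reproduce the dead-time jump, the rise, and the decrease-to-plateau of
loading traces, and because unload and reload experiments start and end in
the same stage distributions, the stoichiometric amplitude *ratios* are
insensitive to these weights. What the generator deliberately omits:
photophysics (bleaching, blinking), shot noise, temperature effects and
instrument response beyond dead-time censoring — recovery results on this
synthetic data therefore validate the analysis pipeline, not those
instrument artifacts.

## Trace fitting

`fit_multiexponential()` fits `y(t) = sum_i A_i exp(-k_i t) + c_inf` by
variable projection: for any candidate rate vector the amplitudes and offset
are solved linearly, and the rates are optimised on a log scale from a
deterministic multi-start (all n-subsets of a log-spaced grid spanning
1e-4 to 1e2 s^-1, pre-screened by projected residual, the best few refined
with `nlminb` to relative tolerance 1e-14). Amplitudes are stored as
exponential coefficients, so rising phases are negative; relative
amplitudes and total amplitudes use magnitudes. Fits are unweighted (no
weighting scheme is published for the reference data).

Two forms of ill-conditioning are flagged as *phase collapse*: two fitted
rates within 5% of each other, or a numerically negligible amplitude (an
unidentifiable extra phase). The warning recommends one phase fewer;
`reduce_on_collapse = TRUE` applies that recommendation automatically,
which matters for titration members whose slow phase carries almost no
amplitude. `select_phase_count()` automates the choice with an
extra-sum-of-squares F-test at alpha = 0.01, stopping early when a model
already reproduces the data to numerical precision.

The signal change completed within the dead time cannot be fit to a rate;
its amplitude is recovered as `A_dead = c_inf + sum(A_i) - y0` — the fitted
curve extrapolated to time zero minus the zero-time reference `y0`, read
from a flat no-loader control. Equivalently, the infinite-time value equals
`y0` plus the dead-time amplitude plus the net change of every resolved
phase. `y0` must be supplied explicitly (for synthetic data it is the
generating baseline); without it `A_dead` is not identifiable and is stored
as `NA`.

## Stoichiometry from amplitude ratios

If the loader unloads every clamp it loads, the probability that a
dissociating loader re-loads a labeled clamp equals the labeled fraction of
the solution pool, so the total reload amplitude over the total unload
amplitude equals that fraction — 0.5 at 1:1 pools — and regressing the
ratio on the fraction gives slope 1, intercept 0. With polymerase capturing
every loaded clamp, no unlabeled clamp returns to solution and the ratio
reaches 1. `amplitude_ratio()` uses amplitude magnitudes with the dead-time
amplitude excluded (these designs start from equilibrated or trap-quenched
states with no sub-dead-time jump), which also makes the ratio independent
of the arbitrary-units scale. `titration_breakpoint()` fits a continuous
rising-line-plus-plateau model, scanning candidate junctions at the data
abscissae and refining by golden-section search; a series that rises to its
last point is reported as an unbounded break point rather than a number.

Two systematic offsets of order a few percent are inherent to the designs
and worth knowing about. First, the 20-fold unlabeled trap leaves ~5% of
the labeled clamp re-loadable, so unload amplitudes underestimate the
loaded amount slightly and measured ratios sit a few percent above the
ideal value (the measured 1:1 ratio is 0.51, not 0.50, for the same
reason). Second, early in a reload time course the solution pool is richer
in labeled clamp than at steady state, so simulated reload rises are
initially faster than the loader dissociation rate and double-exponential
fits extrapolate slightly below zero at time zero, inflating total reload
amplitudes by a few percent. Both effects are visible in the package's
recovered ratios (about 0.54 at 1:1) and stay inside the experimental
uncertainty of the reference values.

## Problem sizes and runtimes

The reference simulations use the published conditions directly: 60 s
loading traces at 8000 points, 60-180 s unloading traces at 1000 points per
60 s, pre-equilibration to steady state, and 100-seed replicate censuses
for the noisy-recovery property. Everything runs in seconds to a few
minutes on one core; these sizes were chosen because they are the
instrument's own, so no scaling down was needed.

## Known limitations

* The two-population loader model reproduces all trace shapes and
  amplitudes here, but the data do not rule out branch-at-closure schemes
  with different population logic; only equilibrium-start experiments
  distinguish them.
* Per-stage FRET efficiencies, the instrument dead time and bench
  incubation times are conventions, not measured values.
* ATP-concentration dependence is modelled only as the hydrolysis on/off
  toggle; nucleotide exchange and per-site hydrolysis are out of scope.
* The slide-off rate with the DNA end unblocked is not published; the
  channel is implemented but its default is zero.

## A worked example

```{r example, eval = FALSE}
params <- rate_parameters()

# unload-trap and reload experiments, fitted as measured data would be
unload <- run_design(design_unload_trap(), params)
reload <- run_design(design_reload(), params)
f_un <- fit_multiexponential(unload, 2)
f_re <- fit_multiexponential(reload, 2, reduce_on_collapse = TRUE)
amplitude_ratio(f_re, f_un, labeled_fraction = 0.5)

# noisy loading trace: recover the conformational rise rate
noisy <- add_noise(run_design(design_loading(), params), seed = 1)
fit <- fit_multiexponential(noisy, 2, y0 = 0)
tidy(fit)
glance(fit)
```
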