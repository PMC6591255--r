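---
title: "Modelling and closed-loop abatement of spike-and-wave discharges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and closed-loop abatement of spike-and-wave discharges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdcontrol)
```

## The model

`swdcontrol` simulates a four-population thalamocortical neural mass model
of absence epilepsy and closed-loop controllers that abate its
spike-and-wave discharges (SWD).  The populations are the cortical
pyramidal (PY) and interneuron (IN) pools and the thalamic relay (TC) and
reticular (RE) nuclei, each described by one fractional-firing-activity
variable:

$$
\begin{aligned}
\dot{PY} &= \tau_e\,(h_e - PY + c_{ee} f[PY] - c_{ei} f[IN] + c_{et} f[TC])\\
\dot{IN} &= \tau_i\,(h_i - IN + c_{ie} f[PY])\\
\dot{TC} &= \tau_t\,(h_t - TC + c_{te} f[PY] - c_{tr} s[RE])\\
\dot{RE} &= \tau_r\,(h_r - RE + c_{re} f[PY] + c_{rt} s[TC] - c_{rr} s[RE])
\end{aligned}
$$

with the steep cortical sigmoid $f[x] = 1/(1+\varepsilon^{-x})$
($\varepsilon = 2\cdot 10^5$) and the linear thalamic activation
$s[x] = a x + b$ ($a = 2.8$, $b = 0.5$).  The observed EEG is
$y = c_1 PY + c_2 IN$ with $c_1 = c_2 = 0.5$.  `tc_params()` carries the
reference values of every symbol.

**Units.** The source material leaves time units implicit.  We interpret
the timescale constants $\tau_\ast$ as s$^{-1}$, which places the seizure
rhythm of the reference regime at 3.0 Hz — inside the clinical 2.5–4 Hz
absence band — and makes the 1 ms integration step meaningful.  All state
variables are dimensionless.

**Numerics.** Integration is classical fixed-step RK4 at `dt = 0.001` s
(a compiled core; step-halving experiments show the expected
$\mathcal{O}(h^4)$ global error, ratio ≈ 16 per halving).  The sigmoid is
evaluated as $1/(1+\exp(-x\ln\varepsilon))$ with the exponent clipped at
±700, so the steep default never overflows.  Exogenous inputs —
background noise, disturbance pulses and the control signal — enter the
state derivatives additively ($\dot{\mathbf x} = F(\mathbf x) + \mathbf d
+ \mathbf u$), held constant across the four RK4 stages (zero-order
hold).

**Noise.** Background noise is Gaussian, redrawn once per step and held
for the step, applied to RE by default.  Its standard deviation is in
input units per step, *not* scaled by $\sqrt{dt}$: changing `dt` changes
the effective noise power.  This convention keeps RK4 valid and matches
the qualitative role of the noise (weak jitter around the background
state at `sd = 1`, `dt` = 1 ms); it is deliberate and documented rather
than an SDE discretization.

## Regimes and their classification

Depending on the two cortico-thalamic couplings — `c_te` (top-down PY→TC
excitation) and `c_tr` (RE→TC feedforward inhibition) — the model
produces tonic oscillations (TO), a low-saturated background state (LS),
a high-saturated state (HS), m-spike-and-wave discharges (m-SWD) and
clonic oscillations (CO).  `classify_state()` labels a noise-free probe
trajectory:

* **Steady** tails (peak-to-peak < `1e-3` over the last 5 s) are LS or HS
  by their level; the split `0.351` is the midpoint of the two saturated
  EEG levels measured at the reference LS point (`c_tr = 0.15, c_te =
  2.3`; y = 0.174) and HS point (`c_tr = 0.15, c_te = 3`; y = 0.528).
* **Fast** oscillations are TO.  The floor is 10 Hz: measured tonic
  rhythms span 14.0–15.8 Hz while the fastest non-tonic cycle found
  anywhere in the studied plane is 9.5 Hz, so 10 Hz sits in an empty
  band.  (A 15 Hz floor would cut through the tonic band itself.)
* **Slow** oscillations are split by waveform: a *spike* is a prominent
  local maximum whose width at half prominence is below 25% of the
  fundamental period.  Measured SWD spikes are ~50 ms wide regardless of
  m, while slow-wave crests and clonic/tonic peaks span 40–85% of the
  cycle, so the width test separates them cleanly.  m = modal spike
  count per period (phase-anchored at the tallest spike); m ≥ 1 gives
  m-SWD, m = 0 gives CO.  The prominence threshold `0.008` keeps the
  faintest spike of the 4- and 5-spike patterns (prominence ≈ 0.01)
  while rejecting sub-0.003 ripple.  We considered a duty-cycle
  asymmetry test instead, but the clonic cycle itself is strongly
  asymmetric (duty 0.66), so asymmetry does not discriminate.
* A **decaying** oscillation (second half of the analysis window under
  30% of the first half's range) returns an explicit `UNRESOLVED` label
  rather than a guess.  Probe drivers re-integrate such runs from their
  final state until they settle.

Classification uses the study's own observation timescale: probes of
10–20 s after a 5 s transient.  This matters because some SWD states are
*metastable* — at the reference operating point (`c_tr = 0.6, c_te = 3`)
the noise-free 3 Hz SWD collapses to the background state after roughly
40 s, while noisy runs sustain it indefinitely.  Labels therefore
describe what an electroencephalographer would see in a finite recording,
not the $t\to\infty$ limit.

## Bifurcation machinery

`find_equilibria()` exploits the model's triangular structure (IN is
explicit in PY; TC and RE are linear given PY) to seed damped Newton
iterations from a deterministic PY grid, returning all roots with
eigenvalue stability flags.  `continue_equilibria()` follows a branch by
pseudo-arclength continuation (so folds are traversed), and
`detect_hopf()` locates sign changes of the leading complex-pair real
part, bisecting to a parameter tolerance of `1e-4`.  Crossings where the
branch's overall stability flips are flagged `dominant` — the textbook
Hopf scenario; additional complex-pair crossings on saddle segments near
folds are reported but not dominant.  On the closed-form Hopf normal form
the detector recovers the crossing at $\mu = 0$ and the cycle frequency
$\omega/2\pi$ to four decimals.

Folds of limit cycles ("double cycles") are located by
`estimate_double_cycle()` with attractor-following brute force: slow up-
and down-sweeps of the parameter reusing the final state, reporting an
edge wherever the cycle's amplitude drops discontinuously, refined by
bisection.  Unstable cycles are *not* tracked — only their consequences
(hysteresis edges) are observed.  A supercritical Hopf, whose amplitude
shrinks continuously, correctly yields no fold.

`multistability_probe()` inventories coexisting attractors.  Uniform
random initial states alone are provably insufficient here: at the
strongly coupled point (`c_tr = 1.5, c_te = 3.5`) two of the three
attractors have basins so thin that 400 random draws hit neither.  The
probe therefore augments the seeded random draws with (a) every located
equilibrium and (b) seeded Gaussian clouds around the orbits of
attractors found so far, mimicking the pulse-perturbation protocol that
exposes coexisting states experimentally.  Discovery is monotone in the
number of initials, and all seeding is deterministic given the seed.

`two_param_map()` classifies a grid over `(c_tr, c_te)` from several
probe initials per cell plus the analytic stable-equilibrium labels, then
merges 4-connected cells with identical label *sets* into regions.  For
region identity the spike count m is ignored: the qualitative partition
separates coexistence patterns, and m ladders smoothly inside the SWD
territory.  On a 25×25 grid over `c_tr ∈ [0.05, 1.65]`, `c_te ∈ [0.5, 4]`
(a window covering every printed anchor point and the stated qualitative
extremes) the census finds 12 distinct coexistence patterns; the
qualitative layout — tonic band below `c_te ≈ 2`, background wedge, m-SWD
territory, HS corner, clonic region and bistable seams — matches the
reference partition, with two extra patterns traceable to a deep
saturated equilibrium (y ≈ −1.8) that coexists with TO at low `c_te` and
to probe resolution at the seams.

## The controllers

Seizure abatement is formulated as tracking: force the EEG $y$ toward a
normal reference $y_d$.  The sliding variable is the tracking error
$s = e = y - y_d$, and the four laws are

| method | control law |
|---|---|
| feedback | $u = -\lambda s$ |
| feedback+rbf | $u = -\lambda s - \hat\theta^{T}\phi(s)$ |
| feedback+smc | $u = -\lambda s - \rho z$ |
| hybrid | $u = -\lambda s - \hat\theta^{T}\phi(s) - \rho z$ |

with $u$ applied to PY and IN ($u_1 = u_2 = u$, $u_3 = u_4 = 0$),
defaults $\lambda = \rho = k_c = 1$, $m = 11$ Gaussian RBF nodes of width
$p = 1$ (we read the printed constant $p$ as the RBF width — the only
unnamed RBF constant) with centers uniform on $[-1, 1]$ of $s$, and a
first-order low-pass filter $\tau \dot z = -z + \mathrm{sign}(s)$
($\tau$ = 10 ms, advanced by its exact exponential update so the
discretization is `dt`-independent).  `sign(0) = +1` throughout.  A raw
unfiltered switching variant exists purely to quantify chattering; the
filtered law reduces the mean $|du/dt|$ by more than half.

**Adaptive law sign.** The weight update is
$\dot{\hat\theta} = \gamma s \phi(s) - k_c \gamma |s| \hat\theta$
(gradient adaptation with σ-modification leakage).  The gradient term's
sign is the one that makes the Lyapunov cross terms cancel, i.e. the
stabilizing direction: a persistent positive error grows the weights,
which lowers $u$.  With the opposite sign the weight loop is positive
feedback — in simulation it saturates the weights at the leakage bound
and locks the plant in the high-saturated state.  The adaptation rate
$\gamma$ is not printed in the source material; the default is 10, and
the settled tracking error is insensitive over $\gamma \in \{1, 10,
100\}$ (the weights remain far from the leakage bound once tracking is
achieved).  Weights integrate by explicit Euler at the plant step, with
$\hat\theta = 0$ at switch-on.

The discrete loop order is: measure $y$, form $s$, update $z$ and
$\hat\theta$, compute $u$, advance the plant one RK4 step with $u$ held
across the stages.  The controller is off before `switch_on_time`
(default 4 s); moving the switch-on to 6 s changes the settled error by
well under 20%.

**Disturbances.** Robustness runs add Gaussian noise (sd 1) and a random
rectangular pulse series (Poisson 0.25/s, width 20 ms, random sign) on
RE.  Under the additive input convention a 20 ms pulse displaces RE by
roughly amplitude × width; the measured basin-escape threshold at the
reference bistable point is a displacement of ~0.3–0.5, so the default
pulse amplitude is 25 — disturbances genuinely re-evoke seizures, which
is what separates the methods.  With these defaults the trailing-12 s
error ordering is hybrid < feedback+smc < feedback, and the hybrid's
robustness costs control energy (largest rms of $u$), reproducing the
qualitative method ranking.  Uniform ultimate boundedness is checked
across ten disturbance seeds.

**On-demand control.** `variance_trigger_control()` implements the
variance-based responsive mode: the moving-window variance of $y$ (0.5 s
window, 0.05 s step) is a seizure indicator; sustained exceedance of
`Var_th = 0.002` for 0.1 s switches the plain feedback law on for 1 s.
The background state sits orders of magnitude below the threshold
(max windowed variance ≈ 4×10⁻⁵) while SWD exceeds it by ~500×, so the
indicator separates the states with a wide margin.

## Reference signals

* `generate_background_reference()` simulates from the stable LS
  equilibrium with background noise — the "normal EEG from an unaffected
  area".
* `generate_alpha_surrogate()` is seeded white noise band-passed
  (4th-order Butterworth, zero-phase) to 12 ± 2 Hz and scaled to an exact
  target RMS (default 0.05, comparable to the model's oscillation
  amplitudes); it stands in for a clinical alpha-band channel so the
  alpha-tracking case runs fully offline.  How a clinical trace should be
  scaled into model units is unknowable from the source material, so the
  amplitude is a configurable choice.
* `load_reference_from_file()` reads a two-column CSV (time, amplitude)
  and resamples it to the plant grid, covering the real-recording path.

## What the synthetic setup does and does not show

All validation runs on trajectories of the model itself plus the
synthetic references.  Passing tests demonstrate that the dynamics,
bifurcation structure and controllers behave as designed *within this
model world*: four smooth population ODEs, stationary Gaussian noise,
rectangular disturbances.  Real scalp EEG adds measurement noise,
nonstationarity, artifacts and spatial mixing that none of the tests
exercise; the variance trigger's clean 500× margin in particular will
narrow on real recordings.

## Known limitations

* Unstable limit cycles are not continued; fold locations are inferred
  from hysteresis edges at sweep resolution.
* Regime labels are defined on finite windows; metastable SWD segments
  are labelled as seizures, by design.
* The region census counts probe-resolved coexistence patterns; very
  thin basins (below the probe budget) and sliver regions at the seams
  can shift the count by one or two.
* The adaptive controller's RBF network takes the scalar $s$ as input, so
  it can only cancel drift correlated with the instantaneous error; the
  switching term covers the remainder.

## Reproducing the study-scale numbers

`scripts/acceptance.R` re-runs every headline computation from scratch —
the 3 Hz SWD rhythm, the sweep frequency band, the nine regime anchors,
the 25×25 region census, the multistability counts, the variance
threshold margin, the four-method comparison and the stability
properties — and writes them to JSON.  Problem sizes (20 s single runs,
25×25×5 map probes, 10-seed robustness loops) are the package's chosen
study scale; every quantity is recomputed at call time from the model
equations and seeds.
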