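---
title: "The vesicle-state model: simulation, fitting and energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vesicle-state model: simulation, fitting and energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclefit)
```

## The model

Hypertonic sucrose (HS) releases the readily releasable pool (RRP) of
synaptic vesicles independently of calcium, which makes HS-evoked
excitatory postsynaptic currents (EPSCs) a direct probe of the fusion
step itself. `vesiclefit` implements a minimal vesicle-state model of
that experiment: a depot pool $D$ of non-primed vesicles, the RRP $R$,
and a fused pool $F$, coupled by

$$\frac{dD}{dt} = -k_1 D + k_{-1} R, \qquad
  \frac{dR}{dt} = k_1 D - (k_{-1} + k_2(t))\,R,$$

with $k_1$ the priming and $k_{-1}$ the unpriming rate constant and
$k_2(t)$ the fusion rate constant. Pools are measured in charge (nC),
so the fusion rate $k_2 R$ is directly a current (nA). At rest the RRP
sits at the dynamic equilibrium

$$R_\infty = \frac{k_1 D}{k_{-1} + k_2},$$

evaluated at $k_2 = 0$ when the RRP is reported, since the resting
fusion rate is three orders of magnitude below $k_{-1}$.

The action of sucrose is modelled entirely as a time-dependent rise of
the fusion rate constant with a Gompertz ("expo-exponential") onset,

$$k_2(t) = k_{2,max}\, e^{-e^{-(t - t_0 - t_{del})/\tau}}, \quad t \ge t_0,$$

which captures the delay ($t_{del}$) between solution exchange and the
response and the smooth, rather than abrupt, transition ($\tau$) to the
evoked current. Priming and unpriming are unaffected by the stimulus:
all concentration dependence is carried by $k_{2,max}$.

### Parameters and units

| parameter | meaning | unit | default |
|---|---|---|---|
| `k1` | priming rate constant | 1/s | 0.09 |
| `k_minus1` | unpriming rate constant | 1/s | 0.16 |
| `k2_max` | maximal fusion rate constant | 1/s | 3.5 |
| `t0` | stimulus onset | s | 0.5 |
| `t_del` | onset delay of `k2` | s | 0.60 |
| `tau` | rise time constant of `k2` | s | 0.20 |
| `D0` | depot pool size | nC | 1 |
| `k2_baseline` | resting fusion rate constant | 1/s | 0 |

Internal units are seconds, nC and nA (1 nC/s = 1 nA); traces are read
and written in pA. The default set gives a resting RRP of
$0.09/0.16 = 0.5625$ nC and peak currents near 0.9 nA — with 10 pA
recording noise this reproduces the signal-to-noise regime of simulated
HS responses with a 1000 pC depot. The default `k2_max` of 3.5 1/s is a
strongly depleting (0.5 M-like) stimulus.

## Simulation and trace synthesis

`integrate_pools()` integrates the dynamics from the resting steady
state. Two modes mirror the two fitting regimes: `constant_k1D`
freezes the depot (the priming flux $k_1 D$ is one constant, the
assumption of the initial fit) and `depletable_D` runs both pools. The
canonical engine is an adaptive explicit Runge-Kutta 4(5) solver
(deSolve's `ode45`) with the solution interpolated onto the requested
grid; a fixed-step RK4 integrator in C++ (`engine = "fixed"`) computes
the same trajectories at a fraction of the cost and is used inside the
fitting loop and for depletion curves. The two engines agree to better
than 1e-8 (tested). Because the pool derivatives cancel term by term,
$D + R + F$ is conserved to near machine precision in depletable mode;
the cumulative fused charge $F$ is tracked explicitly for this check
and for charge bookkeeping against synthesized currents.

Default tolerances for the adaptive solver are `rtol = 1e-10`,
`atol = 1e-12`, chosen so that trajectory errors and conservation drift
stay at least an order of magnitude below the 1e-9 bound the tests
assert over 60 s simulations.

EPSCs are synthesized by convolving the release rate $k_2(t)R(t)$ with
a canonical miniature EPSC and negating the result (inward currents are
negative; pools are positive charge). The kernel is a
difference-of-exponentials with 0.5 ms rise and 3 ms decay,
unit-charge normalized so that pool units flow through the convolution
unchanged — the waveform itself is a design choice, since only its
(quantal) charge matters on the seconds timescale of HS responses. The
default quantal charge of 110 fC follows from a ~1.3 nC RRP containing
roughly 12,000 vesicles. Gaussian white noise (default sd 10 pA) is
added after convolution, emulating recording noise. Sampling defaults
to 10 kHz.

```{r synth}
p <- default_model_params()
tr <- synthesize_trace(p, noise_sd = 10, seed = 1)
tr
```

### What the generator does and does not emulate

The generator reproduces the features the fit exploits: the delayed
sigmoid onset, the concentration-dependent peak and decay (via
`k2_max`), the steady-state replenishment phase, and additive Gaussian
recording noise. It does not emulate receptor saturation or
desensitization (which bias real recordings above 0.5 M), quantal
granularity (release is a continuous rate), stochastic channel noise,
baseline drift, or solution-exchange artefacts. Passing
parameter-recovery tests on these fixtures therefore demonstrates that
the estimation machinery is sound under the model's own assumptions,
not that real traces are free of systematic error.

## Fitting

`fit_traces()` minimizes the sum of squared errors between the model
current and the data over the stimulus window (up to the time the
sucrose concentration starts to decay), with the model interpolated at
each retained sample. The initial fit treats $k_1 D$ as one constant
and integrates only the RRP equation; the RRP is *not* a fit parameter
but derived afterwards as $k_1 D / k_{-1}$. For joint fits of several
concentrations from one cell, $k_1 D$ and $k_{-1}$ are shared and
`k2_max`, `t_del`, `tau` are free per trace, and the per-trace costs
are summed.

Optimization runs in log-parameter space (rates span four orders of
magnitude) within bounds of $10^{-5}$ and $10^6$ on the natural scale,
with a budget of 400 iterations per fitted parameter per stage. The
global stage is simulated annealing by default; a compact differential
evolution optimizer is the selectable alternative, and both hand over
to a Nelder-Mead simplex. The pipeline restarts from jittered initial
conditions (`n_starts`, default 10) and keeps the best solution;
starting values come from data-driven heuristics (steady current →
$k_1 D$, released charge → RRP → $k_{-1}$, onset time → $t_{del}$,
peak amplitude → $k_{2,max}$). The mean pre-stimulus current is
subtracted as baseline before fitting (configurable). All stochastic
elements derive from the configured seed, so identical inputs and seed
give identical results. Non-convergence is flagged on the result,
never silently dropped.

Simplex and annealing tolerances are this package's documented
constants (`reltol = 1e-10`, evaluation budgets as above), not claims
about any other software.

Where runtime matters (test suites, the bundled studies) the cost is
evaluated on a 1 ms grid with 4 multi-starts and no global stage; a
noiseless default-set trace is still recovered to better than 1% and
the scaled-down recovery study reproduces log-log slopes of 1 within
a few percent. These problem sizes are the package's own choices and
are stated where used.

### Two-stage depot refinement

When a long stimulus makes the refill phase sag, `refine_depot()`
frees $k_1$ and $D_0$ (all other parameters fixed, their product
constrained within 2% of the stage-one $k_1 D$) and refits with the
depletable-depot dynamics. The split is only identifiable from the
decay of the refill phase; on traces generated with a constant priming
flux the refinement is flagged unidentifiable. Because the stage-one
estimates are themselves biased when the depot depletes strongly, the
refinement is accurate when the sag is mild (tested at ~20% depot
depletion, where $k_1$ and $D_0$ are recovered within 10%).

### Fit-quality screening

Accept/reject decisions that were originally visual are replaced by
quantitative flags in `quality_screen()`: onset-time mismatch (0.15 s),
relative peak-amplitude error (10%) and time-to-peak mismatch (0.15 s),
same-sign residual excursions beyond twice the noise SD lasting more
than 0.5 s in the decay phase, and steady-state residual bias above 2%
of the peak. Thresholds are configurable; flagged fits are reported,
never deleted.

## Derived quantities

Three RRP estimators are implemented for comparison:
baseline-subtraction (end-steady current removed, then integrate),
integrate-to-timepoint (default: peak + 2 s, the "arbitrary" variant),
and the model-corrected estimator that subtracts the reconstructed
replenishment current $-k_2 R_{new}$ obtained from the linear split
$R = R_{old} + R_{new}$. In this model the corrected integral equals
the fused charge from the initially primed pool, which sits below
$R(0)$ by the charge lost to unpriming while $k_2$ builds up (~15% at
the default set); the unbiased estimator of the resting pool is the
model steady state $k_1 D / k_{-1}$, which is what the package reports
as the RRP. A subtlety worth knowing: vesicles primed during the onset
delay fuse after it, so the replenishment current transiently
overshoots its steady level and the baseline-subtraction estimate
lands slightly *above* the model-corrected one (C ≤ A ≤ B), not below
it as the gradual-replenishment intuition suggests.

The depleted RRP fraction (release normalized to a reference,
maximally depleting RRP) links release kinetics to pool depletion. For
long pulses with a constant priming flux it approaches the closed form
$k_{2,max}/(k_{-1} + k_{2,max})$; `depletion_curve()` computes the
simulated relation on a `k2_max` grid with either the steady-state
estimator ($1 - R_{end}/R_0$) or the released-charge estimator; the
two coincide for depleting stimuli and both are exposed because which
one a given analysis convention uses is ambiguous. Fractions may
exceed 1 when the reference itself under-depletes (a 0.5 M-like
reference depletes ~94%).

## Energetics

With a constant Arrhenius prefactor, fusion-rate changes map to
activation-energy changes via
$\Delta E_a = \bar{R}T \ln(k_{2,b}/k_{2,a})$; energies are carried as
dimensionless multiples of $\bar{R}T$
($\bar{R} = 1.9872 \times 10^{-3}$ kcal/(mol K), default 293 K, where
1 RT = 0.582 kcal/mol). Only energy *changes* are computed — the
prefactor is never estimated. Additive barrier changes act
multiplicatively on rates (`apply_energy_deltas()`), the allosteric
calcium-sensor ladder $k_{2,n} = l_+ f^n$ is the special case of $n$
equal reductions of $\ln f$, and the concentration dependence
$\Delta E(M) = a e^{-bM} + c$ is fitted by Levenberg-Marquardt
(`fit_energy_dose_response()`), then back-transformed into a
fusion-rate dose-response around a stated reference rate
(`energy_to_rate_curve()`) — the reference is a configuration input,
as no absolute anchor exists in the energy differences themselves.
When symmetric rate-domain errors are mapped to the energy domain, the
larger of the two asymmetric halves is reported.

```{r energetics}
delta_Ea_from_rates(2e-4, 2)         # a 10^4-fold rate increase
rt_to_kcal(energy_delta(9.3, 293))   # in kcal/mol
```

## Numerical choices and degenerate inputs

* Steady-state initialization with $k_{-1} = 0$ is rejected; the
  caller must supply `R0` explicitly.
* After stimulus offset the model holds $k_2$ at its course unless an
  offset time is given, at which it returns instantaneously to
  baseline — the offset kinetics is outside the fitted window and this
  choice is a documented stand-in.
* The delay-free single-exponential fusion-rate onset is used only in
  the closed-form oracle; the Gompertz onset is canonical elsewhere.
* `fit_energy_dose_response()` flags constant data as degenerate
  ($b$ unidentifiable) instead of failing, and falls back to the raw
  Levenberg-Marquardt solver when the exact-fit (zero-residual) corner
  case trips the `nls` wrapper.
* Bootstrap summaries use the percentile 95% CI of 10,000 resampled
  means by default and sort the input first, making them
  order-invariant at fixed seed.
* Kernel resampling to a coarser fit grid keeps the discrete waveform
  unit-charge normalized, so charge is conserved even when the rise
  time is under-resolved.

## Known limitations

Priming is calcium-independent by construction (appropriate for HS
stimuli, not action-potential trains); there is a single homogeneous
RRP (no fast/slow sub-pools); receptor saturation and desensitization
are not modelled, so fitted `k2_max` above 0.5 M-equivalent stimuli
should be read with the same caution as the recordings they mimic; and
the spontaneous rate constant computed from mEPSC frequency
overestimates the calcium-independent component, since spontaneous
calcium fluctuations contribute ~2-4e-4 1/s of the resting rate.
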