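---
title: "Modelling DSC reheating experiments with dscfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DSC reheating experiments with dscfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscfit)
library(ggplot2)
```

## The problem

Differential scanning calorimetry (DSC) records the apparent molar heat
capacity of a protein solution as the temperature ramps linearly. The
position, height and shape of the unfolding peak encode the protein's
thermodynamic stability (equilibrium constants, melting temperature,
enthalpy) and its kinetic stability (activation energies of irreversible
steps). A standard DSC run, however, continues past the first heating: the
instrument cools the sample back down and heats it again. The second
(reheated) scan is usually discarded or used only as a yes/no reversibility
check, even though it is recorded at the same resolution as the first scan
and its shape is a direct function of how much protein survived the first
heat-cool excursion in a refoldable state.

`dscfit` treats the first scan, the cooling, and the reheated scan as one
experiment governed by one unfolding model, and fits all recorded scans
simultaneously. This recovers the information the reheats carry: the extent
and rate of the irreversible step, the heat-capacity increment
$\Delta C_p$ (through the vertical shift of the reheat baseline), and a
residual-based diagnostic for refolding into a non-native conformation.

## Models

Unfolding is described as an ordered chain of transitions from the native
state N. Four canonical single-peak schemes are built in:

* **A** — reversible two-state, $N \rightleftharpoons D$ with equilibrium
  constant $K(T)$;
* **B** — irreversible two-state, $N \xrightarrow{k} D$ with Arrhenius rate
  $k(T)$;
* **C** — partially reversible three-state,
  $N \rightleftharpoons I \rightarrow D$, with the first step fast enough to
  stay at equilibrium throughout the scan;
* **D** — the general Lumry–Eyring three-state scheme
  $N \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} I
  \xrightarrow{k_2} D$ with explicit forward and reverse rate constants.

Chains may append further irreversible steps, including exothermic ones
(negative $\Delta H$) that model the aggregation peak seen at high
temperatures for some proteins.

Parameterization follows calorimetric convention. A reversible step carries
$(T_m, \Delta H, \Delta C_p)$ with $K(T_m) = 1$; an irreversible step
carries $(E, T_f, \Delta H, \Delta C_p)$ with $k(T) =
\exp\{-(E/R)(1/T - 1/T_f)\}$ so that $k(T_f) = 1\,\mathrm{s^{-1}}$. With a
temperature-independent $\Delta C_p$, each step's enthalpy is linear in
temperature, $\Delta H(T) = \Delta H(T_\mathrm{ref}) + \Delta C_p
(T - T_\mathrm{ref})$, and the unique entropy convention for which
$\Delta G(T_m) = 0$ gives
$\Delta S(T) = \Delta H(T_m)/T_m + \Delta C_p \ln(T/T_m)$. The reference
temperatures $T_m$ and $T_f$ are the ground-state anchors; a fitted
$\Delta C_p$ on a step whose true increment varies with temperature should
be read as an average over the transition range.

A reversible step may carry an independent van't Hoff enthalpy
$\Delta H_{vH}$: it then governs $K(T)$ — the sharpness of the transition —
while the calorimetric $\Delta H$ sets the peak area. This is the classical
treatment of reversible peaks whose effective cooperative unit differs from
the monomer, and it is what the Protein A case requires.

## Propagation through heat–cool–reheat programs

All kinetic chains obey ODEs that are *linear* in the state fractions at
any fixed temperature. Writing $v$ for the signed scan rate (negative on
cooling) and working in temperature as the independent variable:

* model B: $dx_n/dT = -(k/v)\,x_n$, whose solution over a ramp is the decay
  factor $X(T_2, T_1, v) = \exp\{-\frac{1}{|v|}\int k\,dT\}$. The native
  fraction after heating to $T'$ and cooling back is $X(T', T_0, v)^2$, and
  a reheat starts from that amount — the path-reversal identity
  $X(T_0, T', -v) = X(T', T_0, v)$ makes the cooling leg cost exactly as
  much as the heating leg;
* model C: the fast-equilibrium constraint $x_i = K x_n$ reduces the chain
  to $dx_n/dT = -\frac{K}{1+K} x_n \left(\frac{k_2}{v} +
  \frac{\Delta H_R(T)}{R T^2}\right)$; the van't Hoff term redistributes
  N and I (and reverses its effect on cooling, refolding I back to N),
  while the $k_2$ term drains the pool irreversibly;
* model D: the full pair of linear ODEs in $(x_n, x_i)$;
* appended steps: sequential first-order drains on the last populated state.

The propagator exploits the linearity: each accepted step applies the
matrix exponential of the local coefficient matrix frozen at the step
midpoint (exponential midpoint rule) with step-doubling error control and
Richardson extrapolation. The matrix exponential is exact for frozen
coefficients, so stability is unconditional and accuracy is limited only by
how fast the coefficients drift with temperature. Defaults are a 0.1 K
output grid, relative tolerance $10^{-8}$ and absolute tolerance
$10^{-12}$ on the fractions (the fitting path relaxes these to $10^{-6}$ /
$10^{-10}$, far below the noise level of any realistic thermogram).

Two numerical regimes of model D deserve mention. When the first step
relaxes much faster than its equilibrium drifts — the scale is
$R T^2 / (E_1 - E_{-1})$, a few kelvin — the N/I split is slaved to its
quasi-static value and the midpoint rule's error estimate stalls on the
fast components. The propagator detects this regime and switches to the
algebraically reduced chain: the N+I pool is propagated (the same equation
as model C with $K = k_1/k_{-1}$), then split with a first-order
quasi-static correction $u^* = -\mathrm{pool}\, f(1-f)\,(k_2 + v\,
d\ln K/dT)/(k_1+k_{-1})$ that restores the lag of the fast components
behind their moving equilibrium. This makes the D$\to$C limit exact to a
few parts in $10^4$ while keeping the resolved-kinetics regime (slow
$k_{-1}$, the regime where model D is actually distinguishable) untouched.
In the narrow crossover band between the regimes a floor of $10^{-3}$ of
the local grid interval is placed on the internal step: structure below a
millikelvin carries no calorimetric information, and the floor prevents
the error controller from stalling there.

The apparent heat capacity is synthesised as
$C_p(T) = B_0 + B_1 T + \frac{d}{dT}\sum_s x_s(T) H_s(T)$, with $H_s$ the
cumulative enthalpy of state $s$ relative to N and the derivative expanded
analytically using the exact ODE right-hand sides (no numerical
differencing). For model B this reduces to the familiar
$B_0 + B_1 T + (1-x_n)\Delta C_p + (k/v)\,x_n\,\Delta H(T)$, which is
pinned by a unit test.

## Global fitting

`global_fit()` minimises the unweighted sum of squared residuals over all
scans at once. Thermodynamic and kinetic parameters are global; the linear
instrument baseline $(B_0, B_1)$ is shared within a scan-rate group (a
first run and its reheats), with one group per scan rate. Reheat curves
are always generated through the full heat–cool–reheat propagation — they
are never free curves — which is precisely why they constrain the model.

The optimizer is bounded Levenberg–Marquardt (MINPACK via `minpack.lm`),
parameterized in kJ and K for conditioning. Because the objective is
multimodal in the kinetic parameters, a deterministic multistart perturbs
the energy-like parameters (activation energies, enthalpies) over
log-spaced factors in [0.6, 1.6]; `compare_models()` additionally stops
the multistart early once a start reaches the data's noise floor
(estimated from within-scan second differences). Infeasible parameter
excursions during the search return a large constant residual vector, so
the trust region contracts instead of the fit aborting.

Initial values, when not supplied, come from the shape of the first run:
reference temperatures at the apparent peak, enthalpy from the
baseline-corrected *endothermic* peak area (an appended exothermic peak
would otherwise cancel area and deflate the estimate), activation energy
from the peak width via $E \approx e\,R\,T_p^2\,C_p^{max}/\mathrm{area}$,
and $\Delta C_p$ from the pre/post baseline offset. These are deliberately
rough; the multistart does the rest.

Confidence intervals are linearized at the optimum: half-width equals the
$t$ quantile at the residual degrees of freedom times the standard error
from the Jacobian-based covariance $\hat\sigma^2 (J^\top J)^{-1}$. A
rank-deficient Jacobian marks the affected parameters unavailable rather
than inventing numbers. A Monte-Carlo check in the test suite verifies
near-nominal coverage for the activation energy, and a paired test
verifies the package's central claim: including reheats strictly narrows
the confidence intervals of second-step parameters relative to fitting
first runs alone.

## Model selection

`compare_models()` fits each candidate scheme and applies the reasoning a
calorimetrist would: a model whose reheat residuals are much worse than
its first-run residuals is wrong regardless of its total fit quality
(rejection when the reheat/first residual-SD ratio reaches 2, or the
reheat residual bias exceeds 5% of the first-run peak amplitude); among
the surviving candidates, any fit within 20% of the best SSR is adequate,
and the adequate candidate with the fewest parameters wins. This
SSR-plus-reheat-diagnostic rule (AIC is reported, but only informationally)
mirrors the limiting-case structure of the schemes: A, B, and C are all
limits of D, so on data generated by a simpler scheme the richer ones fit
equally well and lose on parsimony, while on data generated by D with a
slow reverse rate the simpler schemes are betrayed by their reheats.

## Diagnostics and planning

`refold_statistics()` splits the global-fit residuals into first-run and
reheat groups and summarises each by signed mean, mean absolute value and
SD over each scan's full recorded range (the window choice matters for the
absolute numbers and is therefore fixed and documented here).
`flag_alternative_refolding()` raises a flag when the reheat group's
signed mean exceeds 5% of the first-run peak amplitude or the SD ratio
reaches 2. In the bundled simulated benchmark — a one-step irreversible
protein whose "reheat" is generated from an alternative native state with
half the enthalpy ($E_a = 300$ kJ/mol, $T_f = 360$ K, $\Delta H = 800$
kJ/mol, 20–100 °C at 1 °C/min, noise SD 2.1 kJ/mol/K) — the fitted reheat
residual SD is ≈ 11.8 kJ/mol/K and the SD ratio ≈ 4.3. At these exact
conditions the SD ratio of ≈ 4 is robust, but the absolute reheat residual
SD scales with the peak amplitude relative to the scan window; narrower
windows or smaller peaks give proportionally smaller values, which is why
the diagnostic thresholds are expressed as ratios and signal fractions,
not absolute numbers. With the reheat area lowered to 10% of the first
run, the ratio under this window sits near 1.5 — clearly elevated above
the matched-model level of 1, but close to the flag threshold; weak
alternative refolding is at the edge of detectability in a wide window.

`classify_reversibility()` implements the foot-of-the-peak test: reheat
from a first run terminated just after the transition, and compare
baseline-corrected peak heights. A surviving fraction of at least 99%
indicates the reversible scheme; 20–99% the partially reversible
three-state scheme; less the irreversible two-state scheme.
`suggest_reheat_temperatures()` returns the three terminal temperatures
worth spending instrument time on: the apparent peak (III), the
post-transition foot (V, where the excess signal above the post-transition
plateau falls below 2% of the peak height — the plateau matters whenever
$\Delta C_p > 0$), and their midpoint (IV), where the reheat peak height
declines steepest and the general three-state scheme separates from its
limits.

## The synthetic-data generators

All test and benchmark inputs are generated in code, seeded, and
bit-reproducible. `table2_preset()` returns the fitted parameter sets of
the six case-study proteins (lysozyme, the Protein A mutant, DbjA, LinB,
DhaA, DhaA115). Two reconstruction choices deserve a note. For DhaA the
published second-step enthalpy is reported both at the apparent peak
(~70 kJ/mol) and at the step's own reference temperature (1126 kJ/mol at
436 K); the only way both can hold with a constant heat-capacity increment
is to carry the combined $\Delta C_p$ on the irreversible step, so that is
how the preset is built. Elsewhere — including the DhaA-style fixtures used
for fraction benchmarks and model discrimination — the package default
applies: a combined $\Delta C_p$ rides on the first step of the chain
(`dcp` of step 1), because reheating constrains only the native-versus-
final difference and a per-step split is generally not identifiable.
`make_refolding_case()` generates the alternative-refolding benchmark
described above.

What the generators emulate: peak shapes, reheat propagation, baseline
offsets and i.i.d. Gaussian point noise at instrument-realistic levels
(0.1–2.1 kJ/mol/K). What they do not emulate: thermal lag and feedback
transients of a real instrument, correlated (1/f) baseline drift,
concentration errors between consecutive scans, and aggregation kinetics
with concentration dependence. Passing the test suite therefore
demonstrates correctness of the mathematics and the estimation machinery,
not robustness to every instrumental artefact; replicate experiments and
the superimposition helper (`superimpose()`) remain necessary in practice.

## Problem sizes and determinism

The test suite and the acceptance script simulate scans on 0.1–1 K grids
(n ≈ 100–800 points per scan), fit one to four experiments at a time, use
60–100 replicate fits for coverage and false-positive-rate checks, and ten
seeded replicates per generating scheme for model discrimination. These
sizes keep every simulation comfortably converged (the propagator's error
control is far below the noise levels used) while completing quickly on a
single core. Every random draw flows through an explicit seed, and
generator functions restore the global RNG state, so reruns are
bit-identical.

## Worked example

```{r example, fig.width = 6.5, fig.height = 4, eval = requireNamespace("dscfit", quietly = TRUE)}
truth <- table2_preset("DbjA")
truth$b0 <- 20e3; truth$b1 <- 50

# one full first run plus a reheat experiment terminated near the peak
full <- simulate_thermogram(truth, heat_cool_reheat(293.15, 348.15, 1/60,
                                                    reheat = FALSE),
                            grid_step = 0.25, noise_sd = 500, seed = 1,
                            experiment = "e0")
reh <- simulate_thermogram(truth, heat_cool_reheat(293.15, 328.15, 1/60,
                                                   t_end = 348.15),
                           grid_step = 0.25, noise_sd = 500, seed = 2,
                           experiment = "e1")
scans <- dsc_scans(dplyr::bind_rows(full, reh))

fit <- global_fit(scans, init_model(scans, "B"), n_starts = 2)
tidy(fit)
glance(fit)
autoplot(fit)
```

## Known limitations

* A per-step split of a combined $\Delta C_p$ is not identifiable from
  first+reheat data unless the intermediate survives into the reheat; the
  package exposes per-step `dcp` parameters but fitting more than one per
  apparent peak is rarely warranted.
* The linearized confidence intervals inherit the usual caveats near
  parameter bounds and for strongly correlated kinetic parameters
  (poorly constrained $T_f$ values drifting to thousands of kelvin are a
  symptom, and are reported with a warning rather than hidden).
* The diagnostic for alternative refolding is magnitude-based, following
  the published procedure; it is not a formal hypothesis test.
* Scan-rate-dependent mechanisms (a first step that equilibrates at one
  rate but not another) are representable via model D, but the fit assumes
  one mechanism across all scans in the problem.
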