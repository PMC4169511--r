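---
title: "Modelling mRNA lipoplex transfection kinetics with lipoplexsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mRNA lipoplex transfection kinetics with lipoplexsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lipoplexsim` simulates the delivery of mRNA into cells by cationic
lipid–mRNA particles (lipoplexes) and the resulting GFP reporter
expression, at single-cell resolution.  The process is a chain of
first-order, mass-action events:

* external lipoplexes $L_{ex}$ attach to the cell surface at rate $k_A$,
  collecting in clathrin-coated pits;
* pits are endocytosed at rate $k_E$, becoming endosomes;
* an endosome either lyses ($k_L$), releasing its cargo into the cytosol,
  or is degraded ($d_E$) together with its cargo — $d_E$ is a catch-all
  for endosomes never observed to release, including intra-endosomal mRNA
  decay;
* cytosolic lipoplexes unpack ($k_U$, effectively instantaneous) into $S$
  free mRNA molecules ($S = 350$ for the 120 nm particles modelled here);
* mRNA decays at $d_M$ and is translated at $k_{TL}$ into immature GFP $G$,
  which matures (folding + oxidation) at $k_M$ into fluorescent GFP $G^*$;
  both GFP pools decay at $d_G$.

At the incubation time $t_{inc}$ (1 h by default) the cells are washed:
the washing rate $k_W$ jumps from zero to a large value, which the
simulators implement as instantaneous removal of the remaining external
lipoplexes (an explicit finite-$k_W$ mode is retained and agrees with the
truncation in the large-$k_W$ limit).

Two network variants exist.  The *streamlined* variant carries one
lipoplex per pit and endosome (species $L_{ex}, P, E, L_{in}, M, G, G^*$).
The *multiple-lipoplex* variant resolves pit and endosome occupancy,
$P_1 \dots P_{N}$ and $E_1 \dots E_{N}$ with capacity $N = 10$: attachment
splits into a new-pit channel $L_{ex} \to P_1$ and join channels
$L_{ex} + P_i \to P_{i+1}$, every channel sharing the pit-normalised
constant $k_{AX} = k_A / (n_{pits} + 1)$, so the *total* attachment
propensity stays $k_A \cdot L_{ex}$ no matter how many pits exist.  Lysis
of $E_i$ releases all $i$ lipoplexes in a single event; degradation
destroys the endosome with its cargo; pits themselves do not degrade.
When every pit is full, attachment can still open a new pit, which keeps
the state space bounded without stalling uptake.

Occupancy resolution is the point of the exercise: carrying the full
lipoplex size distribution (roughly 175 distinct sizes between 270 and
445 mRNA) through endosomes of capacity 10 would need
$175^{10} \approx 2.7\times 10^{22}$ species
(`count_full_nested_species(175, 10)` computes this exactly), which is why
all lipoplexes are fixed at $S = 350$ and only the occupancy index is
enumerated.  A consequence of the fixed size is that per-cell expression
levels cluster at integer multiples of the single-packet amplitude, a
known artefact of the simplification.

Rates are per hour; amounts are molecule/particle counts per cell.  The
three published parameter columns are available as presets
(`rate_preset()`): `streamlined_slow`, `multilipoplex_fast`
(literature maturation rate, $k_M = 9.23$), and `multilipoplex_slow`
(optimised maturation, $k_M = 5.5$); the fixed rates are
$k_{TL} = 170$, $d_M = 0.062$, $d_G = 0.056$, $k_U = 10^6$,
$d_L = 10^{-6}$.

## Dose calibration

The dose proxy is the initial per-cell external count $L_{ex0}$.  Because
the total attachment propensity is $k_A L_{ex}$ regardless of the pit
population, the expected number of lipoplexes attaching during the
incubation is $L_{ex0}(1 - e^{-k_A t_{inc}})$, and `calibrate_dose()`
inverts this for the reference condition of 6 lipoplexes adhering per
cell (`reference_design()`).  Per cell the dose becomes an integer by
deterministic rounding (attachment itself already Poissonises the
delivered number); Bernoulli-fractional and Poisson initialisation are
available as options.  For the slow multilipoplex preset the reference
dose is $L_{ex0} = 25.36$, so the realised mean attachment of the rounded
dose is $25 \times 0.2366 = 5.92$, 1.4% under the nominal 6 — negligible
against ensemble variability, but worth knowing when checking the
calibration to high precision.

## Simulation engines

`simulate_deterministic()` integrates the mass-action rate equations with
`deSolve::lsoda` (the system is stiff: $k_U = 10^6$ against decay rates of
order $10^{-2}$), with the wash as a solver event.  Default tolerances are
`rtol = atol = 1e-8`, comfortably inside the 1e-6 agreement the tests
demand against closed forms.

`simulate_ssa()` is an exact Gillespie direct-method implementation
(compiled core) with the attach-channel propensities recomputed from the
current pit count at every step and the wash handled as a time event at
$t_{inc}$ — the process is piecewise-homogeneous, so jumping to $t_{inc}$
and redrawing the waiting time is exact.  Identical seeds give identical
event sequences; per-cell seeds derive from the master seed by a
counter-based map (`derive_seeds()`), making ensembles reproducible and
order-independent.

`simulate_hybrid()` exploits the structure of the problem: every species
up to mRNA release is low-copy (1–25 per cell) and genuinely stochastic,
while the expression cascade is linear and high-copy ($10^5$–$10^6$
molecules).  The delivery subnetwork runs by exact SSA; each unpacking
event $(t_r, S)$ then contributes the analytic cascade solution

$$M(t) = S e^{-d_M \tau},\qquad
G^*(t) = S\,k_{TL} k_M \sum_{r \in \{a,b,c\}} \frac{e^{-r\tau}}{\prod_{s \neq r}(s-r)},$$

with $\tau = t - t_r$, $a = d_M$, $b = k_M + d_G$, $c = d_G$ (nearly
coincident decay rates are nudged apart by one part in $10^7$ before the
distinct-root formula is used).  The hybrid trace is therefore the
conditional expectation of the full stochastic trace given the delivery
history: delivery statistics agree with full SSA exactly in distribution,
expression means agree up to Monte-Carlo error (verified in the tests at a
100-fold reduced translation rate, where full SSA is affordable), and the
per-cell trace is smooth.  What the hybrid deliberately discards is the
copy-number noise of the expression phase itself — relative fluctuations
of order $1/\sqrt{G^*} \lesssim 0.5\%$ at the amplitudes involved.  Full
SSA at the published $k_{TL} = 170$ fires $10^6$–$10^7$ events per
transfected cell and is kept as a validation engine behind an event-budget
warning.

## Single-cell observables

The expression **onset time** is measured exactly as in the single-cell
tracking analysis the model is compared against: by least-squares fitting
of the analytic expression solution over free $(t_0, m_0)$ with all rates
fixed, not by thresholding.  Two curve families are available.  The
default (`maturation = FALSE`) is the two-stage translation + degradation
solution used by the original tracking analysis, which did not model
maturation — the maturation delay is then absorbed into the fitted onset,
which is precisely why the onset distribution discriminates maturation
rates.  The three-stage family (`maturation = TRUE`) is available for
fitting with the maturation stage explicit; on noiseless synthetic traces
either family recovers its own parameters to 0.01 h and 0.1% in amplitude.
The amplitude enters the model linearly, so the fit profiles $m_0$ out
analytically and optimises only $t_0$ (coarse grid, then 1-d refinement);
a whole ensemble is fitted with one matrix product per grid value.
Flat or empty traces are flagged `converged = FALSE`, never silently
zeroed.

**Maximum GFP** is the maximum of the fitted curve,
$m_0^{eff} \times$ the unit-curve peak (closed form
$\tau^* = \ln(d_M/d_G)/(d_M - d_G) \approx 17$ h for the two-stage
family).  Onset times are summarised by a Gaussian (sample mean and SD);
expression levels by the standard two-parameter lognormal summary on the
log scale, $\exp(\overline{\ln x})$ and $\mathrm{sd}(\ln x)$ — reported as
"mean" and "width".  Non-positive values are excluded and counted.

**Transfection efficiency** (TE) is the fraction of cells expressing GFP;
on simulations the ground truth is at least one mRNA release event, and a
fit-based variant (converged fit with maximum above a detection floor of
$10^3$ molecules, far below the $\sim 3.7\times10^5$ single-packet
amplitude) is available for trace-only inputs; the two agree on simulated
ensembles.

**Dose–response** curves run independent ensembles at multiples of the
reference dose.  Two parametric TE models are provided.  The
single-Poissonian form $TE(d) = 1 - e^{-a d}$ is the zero-class of one
Poisson delivery process.  For the nested process — a Poisson number of
endosomal delivery events whose per-endosome lipoplex load grows with
dose — we use $TE(d) = 1 - \exp(-N(1 - e^{-L d}))$.  The load factor must
carry the dose for the two forms to differ at all: if dose instead scales
the outer mean, the double form collapses to a single exponential in $d$
for every $(N, L)$ and nothing could distinguish the two models.  As
$L \to 0$ with $NL$ fixed the double form reduces to the single form with
$a = NL$; consequently, on data of single-Poisson shape the pair $(N, L)$
is non-identifiable and the fit is flagged.  The package's qualitative
dose-response check mirrors the published comparison: the streamlined
sweep is fit well by the single form (the double fit brings no
substantial residual improvement), while the multilipoplex sweep needs
the nested form (residual ratio above 4 in the acceptance test).

## Parameter estimation

Five rates are free: $k_A, k_E, k_L, d_E, k_M$.  `compute_goals()`
reduces a candidate to the five experimental determinants — mean attached
lipoplexes, the TE dose–response on a relative grid
(0.25, 0.5, 1, 2, 4 by default), onset mean, onset width, and mean
maximum GFP.  `objective()` is the equal-weight sum of squared relative
deviations, with the dose–response contributing the mean squared TE
deviation across the grid (TE is already dimensionless and bounded);
the paper gives the determinants but not its weighting, so equal weights
are the package's choice.  `anneal()` is a classic simulated annealer:
log-space Gaussian proposals ($\sigma = 0.2$) reflected at the bounds
($[10^{-3}, 10]$ h$^{-1}$ for the delivery rates, $[0.5, 20]$ h$^{-1}$
for $k_M$, spanning the literature ranges), Boltzmann acceptance
$\min(1, e^{-\Delta/T})$, geometric cooling (0.95 per step), and an
initial temperature set to the median absolute score change of 20 pilot
proposals unless given.  One caveat on that default: when the start is far
from the optimum, the pilot scale reflects the start's large score rather
than the score differences that matter near the optimum, and most of the
schedule is then spent in a random walk — for recovery studies we set the
initial temperature explicitly, at roughly ten times the evaluation noise,
so the whole budget is selective.  Each evaluation uses a fresh sub-seed so
the optimiser cannot overfit a single stochastic realisation; the returned
best candidate is re-evaluated at a larger ensemble.

Identifiability is uneven, and deliberately reported as such.  The mean
attachment pins $k_A$ sharply; onset timing constrains $k_E$ and
$k_L + d_E$; the TE level constrains the branching ratio
$k_L/(k_L + d_E)$.  The maturation rate, by contrast, moves the onset
mean only by roughly $1/k_M$ (about 0.18 h at $k_M = 5.5$), which is of
the same order as the Monte-Carlo uncertainty of the onset mean at
desk-scale ensembles — so recovery experiments reliably pin the four
delivery rates while $k_M$ wanders; maturation delays between roughly 10
and 30 minutes fit the determinants equally well.  This mirrors the
sloppiness the original analysis itself acknowledges, and is why the
estimates should be read as effective rates, not measurements.

## Synthetic trace fixtures

`make_fixtures()` generates per-cell GFP tables from the analytic curve
with known ground truth: onsets from a truncated normal (3.2 h mean,
1.6 h SD by default, the published onset scale), amplitudes as whole
packets of 350 mRNA (1 plus a Poisson(0.7) number of extras, mimicking
packet-quantised delivery), multiplicative Gaussian noise (5% default)
plus an optional additive floor.  They emulate the *shape* and noise
level of experimental single-cell traces for testing the fitting
pipeline; they do not emulate cell-to-cell variability of the kinetic
rates, fluorescence calibration, background, bleaching, or the lipoplex
size dispersion — so recovery results on fixtures validate the fitting
machinery, not the biology of real traces.

## Numerical choices and problem sizes

* ODE tolerances `1e-8`; analytic-vs-ODE agreement asserted at `1e-6`.
* Degenerate rate coincidences ($d_M \approx d_G$, etc.) handled by a
  $10^{-7}$ relative perturbation of the offending rate.
* Onset-fit grid 0.1 h with local refinement to $10^{-4}$ h; amplitude
  clamped non-negative; peak-time extraction is the grid argmax of the
  trace (output grid 0.1 h).
* Ensembles in the tests and the acceptance script use 3000 cells for the
  distribution summaries, 5000 for SSA-vs-ODE means, 500–700 per dose or
  sweep point, and annealing evaluations of 1000–1500 cells — sizes at
  which every asserted band is several Monte-Carlo standard errors wide
  while a full run stays in the minutes range on one core.
* All randomness flows from one master seed through counter-based per-cell
  and per-ensemble streams.

## Known limitations

* Fixed lipoplex size (350 mRNA): expression levels cluster at packet
  multiples; real size dispersion (270–445) would smear them.
* The hybrid engine's traces are noise-free in the expression phase, so
  trace-shape statistics that depend on fluctuations around a flat
  maximum (e.g. the spread of per-cell peak *times*) reflect delivery
  variability only — of order 2 h here, whereas measured single-cell data
  carry additional cell-to-cell expression variability that this model
  does not represent.
* TE saturates with dose and incubation time; the often-quoted linear
  TE–incubation relation holds only while uptake is far from saturation
  and the external pool is not depleted, which at the reference dose
  (about a quarter of the pool attaching per hour) is only approximately
  true.
* The per-endosome occupancy that the pit-normalised attachment rule
  produces at the reference dose (about two lipoplexes per endosome at
  the published rates) sets the multilipoplex expression-level scale;
  summaries that depend on it (mean/location of maximum GFP) are
  correspondingly sensitive to that rule, while onset timing, peak-time
  location and dose-response shape are not.
* Intra-endosomal unpacking and mRNA degradation, variable-size
  bookkeeping through the network, spatial transport, and toxicity are
  all outside the model's scope.
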