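# lipoplexsim

Stochastic multi-level kinetics of mRNA delivery by lipoplex transfection.

When mRNA is delivered into cells with cationic lipid particles
(lipoplexes), single-cell tracking shows broad cell-to-cell variability:
GFP expression switches on after a delay of a few hours with an
hour-scale spread, expression levels cluster over an order of magnitude,
and only a fraction of cells express at all. The copy numbers driving
this — a handful of particles per cell — make deterministic rate
equations a poor description of any one cell. `lipoplexsim` is for
modellers and quantitative biologists who want to simulate this process,
extract the same per-cell observables that tracking experiments report,
and estimate the kinetic rates from ensemble statistics.

## The model

A chain of first-order mass-action events (rates per hour, counts per
cell):

```
L_ex --k_A--> pit --k_E--> endosome --k_L--> L_in --k_U--> S x mRNA
 |                           |                 |              |
k_W (wash at t_inc)         d_E               d_L            d_M
                                          mRNA --k_TL--> G --k_M--> G*
                                                          |          |
                                                         d_G        d_G
```

Two variants: a *streamlined* network (one lipoplex per pit/endosome, 7
species, 12 reactions) and a *multiple-lipoplex* network that resolves
pit/endosome occupancy up to capacity 10 (25 species, 48 reactions).  In
the latter, attachment splits into a new-pit channel and join channels
`L_ex + P_i -> P_(i+1)`, all sharing the pit-normalised constant
`k_AX = k_A/(n_pits + 1)` so the total attachment flux stays `k_A * L_ex`.
Endosomes either lyse, releasing all their cargo, or are degraded with it.
The delivery chain is low-copy and is simulated by exact Gillespie SSA
(compiled core); the expression cascade is linear and high-copy and is
superposed analytically per released mRNA packet (hybrid engine).  A
deterministic ODE engine (stiff `lsoda`) and a full-SSA validation engine
are included, as are SBML Level 3 export, a YAML-configured CLI
(`inst/cli/lipoplexsim`), synthetic trace fixtures and a simulated
annealer for the five free rates (`k_A`, `k_E`, `k_L`, `d_E`, `k_M`).

See the methods vignette (`vignettes/transfection-kinetics.Rmd`) for the
modelling decisions, numerical choices, and known limitations.

## Worked example

```r
library(lipoplexsim)
rates  <- rate_preset("multilipoplex_slow")
design <- reference_design(rates)          # dose calibrated to 6 attached
net    <- build_network("multilipoplex", rates, design)

ens <- simulate_ensemble(net, n_cells = 2000, seed = 1)
summary(ens)
#> cells: 2000
#> mean attached: 5.863
#> mean endocytosed: 5.863
#> mean delivered: 0.838
#> lysed endosome fraction: 0.145
#> transfection efficiency: 0.376
#> mean first release (transfected cells): 2.801 h

tf   <- ens$cells$transfected
fits <- fit_onset_batch(ens$gfp[, tf], ens$times, rates)
onset_distribution(fits)
#> gaussian summary: location 3.171, width 1.757 (n = 752)
maxgfp_distribution(fits)
#> lognormal summary: location 6.854e+05, width 0.5834 (n = 752)
```

Reading this: of 2000 simulated cells, on average 5.9 lipoplexes attached
during the 1 h incubation and 14.5% of endosomes lysed
(= k_L/(k_L + d_E) = 0.11/0.78), so 38% of cells received at least one
packet of 350 mRNA.  Fitting the analytic expression solution to each
transfected cell's mature-GFP trace puts the expression onset at
3.2 ± 1.8 h and the per-cell maximum GFP around 7e5 molecules with a
log-scale width of 0.58.  A dose sweep with the nested two-Poisson TE
model shows the sub-exponential bend that occupancy produces:

```r
dr <- dose_response(rates, design, c(0.25, 0.5, 1, 2, 4), n_cells = 500,
                    seed = 1)
fit_poissonian(dr, "double")
#> double-Poissonian dose-response fit: N = 0.981, L = 0.719 (rss 0.00226)
```

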