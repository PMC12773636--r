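---
title: "Methods: fermentation balances and acetogen bioenergetics in fermflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fermentation balances and acetogen bioenergetics in fermflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermflux)
```

fermflux implements the quantitative backbone of a fermentation-physiology
study of the acetogenic gut bacterium *Blautia luti*: molar fermentation
balances with carbon and electron recoveries, growth-rate estimation, a
stoichiometric model of glucose fermentation coupled to a formate-fed
Wood–Ljungdahl pathway (WLP) with chemiosmotic ATP accounting, enzyme
specific activities, and a synthetic-data generator that emulates the
experimental designs so that every analysis stage can be tested end to end.

## Molar balances and recoveries

A fermentation balance reduces endpoint concentration changes to molar
yields per mole of primary substrate,
$y_p = \Delta c_p / \Delta c_{\mathrm{substrate}}$, rendered in the
customary equation form
(`1glucose→1.12acetate+0.83succinate+...`). Two recovery statistics
summarize completeness:

* **Carbon recovery**, $100\sum_p C_p\,\Delta c_p / \sum_s C_s\,\Delta c_s$,
  with $C$ the carbon count per molecule.
* **Electron recovery**, the same ratio weighted by the degree of reduction
  $\gamma = 4C + H - 2O$ (available electrons per mole). By construction
  $\gamma(\mathrm{CO_2}) = \gamma(\mathrm{H_2O}) = 0$, so the electron
  balance is blind to CO2 and water and is the sharper closure check for
  fermentations that exchange CO2.

Design choices worth knowing:

* Organic acids are registered as neutral (fully protonated) species, which
  keeps elemental bookkeeping charge-free and matches molar equations.
* CO2/bicarbonate is excluded from both sides of the recoveries by default.
  A bicarbonate-buffered culture that fixes CO2 (succinate production via PEP
  carboxykinase; acetate via the WLP) therefore shows carbon recovery
  *above* 100% — this is a feature of the convention, not an error. For
  synthetic closure tests, CO2 can be listed explicitly as a co-substrate,
  in which case balanced stoichiometries recover exactly 100%.
* Endpoint deltas are last-mean minus first-mean per channel. A nominal
  product whose endpoint delta is negative is clamped to zero with a
  warning; formate in particular is a transient intermediate (produced by
  pyruvate-formate lyase, later consumed by the WLP), and the `"peak"` mode
  reports transient maxima instead.
* Yields are rendered at two decimals; the underlying floats are retained.
  Whether published per-product carbon fractions were computed from rounded
  yields or unrounded concentration means is generally unknowable; fermflux
  computes from unrounded means by default.

## Growth-rate estimation

The specific growth rate $\mu$ is the slope of a least-squares fit of
$\ln(\mathrm{OD})$ on time over the exponential window. The default fits the
mean OD series (matching the mean ± SEM presentation of N = 3 replicate
experiments); `fit_growth_rate_replicates()` fits each replicate for an SEM
of $\mu$.

The exponential window is selected by scanning all contiguous windows of at
least 4 points and keeping, among those with $r^2 \ge 0.98$, the window
maximizing $r^2$ (ties: longer, then earlier). Maximizing $r^2$ rather than
window length matters: with densely sampled courses, windows that leak into
the stationary-phase plateau can still clear an $r^2$ threshold because the
exponential range spans decades, and a length-first rule then
underestimates $\mu$ systematically. With $r^2$-first selection, recovery
simulations at the study's conditions ($\mu$ ∈ {0.3, 0.69, 0.77} h⁻¹, 5%
multiplicative noise, N = 3) yield median absolute errors well under
0.03 h⁻¹ — the property asserted in the test suite. On noise-free
exponential data every window gives the generating $\mu$ exactly and the
full series is selected. If no window reaches the threshold the best
4-point window is used and flagged (`fallback = TRUE`), with $r^2$ of a
constant series reported as 0.

The maximal OD is the maximum of the mean series, not the final point,
since cultures may decline after their peak.

## The stoichiometric flux model

`build_network()` declares glucose fermentation at the granularity of the
study's pathway map, per mole of glucose:

* Embden–Meyerhof–Parnas glycolysis to 2 PEP + 2 NADH (net 0 ATP to PEP;
  the +2 ATP of glycolysis appear at pyruvate kinase);
* pyruvate kinase (+1 ATP) and the succinate branch — PEP carboxykinase
  (+1 ATP, fixes CO2), NADH-dependent malate dehydrogenase, fumarase, and
  fumarate reductase;
* the pyruvate node: pyruvate-formate lyase (PFL), pyruvate:ferredoxin
  oxidoreductase (PFOR), and NADH-dependent lactate dehydrogenase;
* phosphotransacetylase/acetate kinase (+1 ATP per acetate from
  acetyl-CoA);
* the WLP lumped to a single reaction per acetate:
  formate + CO2 + NADPH + NADH + Fd$_{red}$ → acetate, net 0 ATP
  (−1 formyl-THF synthetase, +1 acetate kinase). The carrier assignment
  follows the organism's enzymes: NADPH-dependent methylene-THF
  dehydrogenase, NADH-dependent (non-bifurcating) methylene-THF reductase,
  ferredoxin at CO dehydrogenase. Because the organism lacks formate
  dehydrogenase, the methyl branch is fed by PFL-derived formate — the
  pathway feature the model exists to capture;
* carrier coupling: the electron-bifurcating transhydrogenase Nfn
  (NADH + Fd$_{red}$ + 2 NADP⁺ → 2 NADPH, the canonical stoichiometry; the
  study names the complex without one), the proton-translocating Rnf
  (Fd$_{red}$ → NADH, 2 H⁺/2 e⁻ by default, reversible), the ATP synthase
  (3.6 H⁺/ATP by default, reversible), and the scenario's hydrogenase —
  ferredoxin-only HydM, or electron-bifurcating HydABC drawing half its
  electrons from NADH.

Redox carriers are modelled as two-electron tokens (formula H2), so every
reaction is element-balanced for C, H, O with phosphoryl groups untracked
(PEP and acetyl-CoA are represented by their free-acid parents).
`check_element_balance()` verifies this for any built network.

### Solving

`solve_fluxes()` fixes the exchange fluxes (glucose = 1; measured yields of
acetate, succinate, lactate, formate, H2), balances every internal
metabolite, carrier, and the translocated-proton pool to zero, and solves
$S v = b$ by a minimum-norm least-squares SVD solution. Singular values
below `max(dim(S)) * eps * max(d)` are treated as zero. Irreversible
reactions driven negative are removed one at a time (most negative first)
and the system re-solved — a small active-set iteration; Rnf and the ATP
synthase stay reversible (Rnf is a reversible ion pump; a reversed synthase
consumes ATP to pump protons). A solution is *feasible* when every node
residual is below 1e−9. Measured yields whose electron balance is below
100% cannot close; the least-squares compromise is then returned with
per-node residuals flagged rather than silently forced, and the pipeline
treats it as an error unless run permissively.

Because all exchanges are pinned, the system is essentially determined:
total electron conservation per reaction makes the final carrier node
redundant exactly when the exchange electrons balance. Alternative
objectives (e.g. maximizing ATP) are unnecessary at this granularity.

The ATP ledger separates substrate-level phosphorylation (pyruvate kinase +
PEP carboxykinase + acetate kinase − formyl-THF synthetase) from
chemiosmotic ATP ($\mathrm{flux_{Rnf}} \times$ H⁺/2e⁻ ÷ H⁺/ATP). Reference
behaviours the tests pin down: complete homoacetogenic conversion (glucose
→ 3 acetate) gives exactly 4 substrate-level ATP/hexose; homolactate
fermentation gives exactly 2; diverting pyruvate toward lactate along an
electron-balanced path never increases net ATP.

### The idealized resting-cell distribution

The study's two bioenergetic variants state assumed stoichiometries
(H⁺/ATP = 3.6, 2 H⁺/2e⁻ at Rnf) and two net outcomes: 3.05 ATP/glucose
with HydM — a pathway arrangement that runs *independently of Rnf* — and
3.15 ATP/glucose with HydABC, where halving the ferredoxin demand of H2
production frees ferredoxin for Rnf. The per-reaction fluxes behind those
figures are not published as numbers. fermflux therefore ships
`yields_preset("resting_cells_closed")`: the exchange-yield vector
*derived* from exactly those stated constraints plus full carrier closure
and the measured trace-lactate level. The constraints pin the vector
uniquely (acetate 1.137, succinate 0.92, lactate 0.03, formate 0.473,
H2 0.36); solving it reproduces 3.05/3.15 with zero tuned constants, the
Rnf flux in the HydM scenario coming out at exactly 0. It is an idealized
reconstruction, labelled as such — the as-measured resting-cell yields
(`"resting_cells"`) have a 94.5% electron balance and are deliberately left
unclosable.

The net-ATP gap between the scenarios is structural:
$\Delta = y_{\mathrm{H_2}}/2 \times (\mathrm{H^+/2e^-}) / (\mathrm{H^+/ATP})$.
The test suite checks this exactly on electron-balanced yield families,
using the fact that formate ↔ H2 swaps are electron-neutral (γ = 2 both).

## Enzyme specific activities

Photometric assays convert an absorbance slope to a rate by Beer–Lambert:
rate (mM/min) = |ΔA/Δt| / (ε·d) with ε in mM⁻¹cm⁻¹ and the 0.2 cm anoxic
cuvette path; specific activity (mU/mg = nmol min⁻¹ mg⁻¹) divides by
protein (mg/mL) and by the number of chromophore molecules converted per
substrate turnover (2 for methylviologen-linked fumarate reduction).
Defaults: NADH 340 nm ε = 6.22; methylviologen radical 604 nm ε = 13.9; the
ferredoxin-monitored PFOR assay at 430 nm has no published Δε and requires
a user-supplied value. PFL is a product-formation assay (formate vs time);
its slope divided by protein gives mU/mg directly, and windows with
decreasing formate are rejected.

The linear window follows the initial-rate convention: the earliest ≥ 4
point window reaching $r^2 \ge 0.99$, extended to the end point maximizing
$r^2$ so that a post-exhaustion plateau bend is excluded rather than
averaged in. Published absolute activities are reference context only —
raw traces are unpublished — so correctness is enforced through synthetic
recovery: noise-free simulated traces are exact inverse pairs with the
analyzers, and noisy recovery is tested statistically.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
the biology underneath:

* **Growth courses**: OD(t) = min(od₀·e^{μt}, od_max), with
  growth-associated substrate consumption and product formation
  (Luedeking–Piret, zero non-growth term) scaled so the substrate is
  exhausted at the plateau. Defaults mirror the studied glucose condition:
  μ = 0.69 h⁻¹, plateau OD 5.05, 20 mM substrate, 5% multiplicative noise,
  N = 3, half-hour sampling for 12 h, 5% inoculum. (The study's text and
  table report slightly different glucose growth rates, 0.69 vs 0.67 h⁻¹;
  both are retained as references and the preset uses the text value.)
* **Resting-cell courses**: constant-rate substrate consumption (10 mM
  glucose over the grid), products per yield, optional piecewise-linear
  transient formate (rise to a peak, fall to the terminal yield), optional
  CO co-substrate consumed in ratio.
* **Assay traces**: linear absorbance change at the Beer–Lambert-implied
  slope, optional plateau at substrate exhaustion, additive noise.

Noise is multiplicative on concentrations (HPLC error scales with signal)
and each simulation uses one seeded RNG stream, restored afterwards, so
fixed seeds give identical tables without disturbing the caller's RNG.
Where a condition's growth parameters are unreported (maltose +
phosphinate), the value of the matching reported inhibitor condition
(0.38 h⁻¹) is used.

What passing the round-trip tests does **not** show: real cultures have
lag and death phases, non-growth-associated maintenance metabolism,
gas–liquid partitioning of H2/CO2, and instrument-specific error structure.
The generator has none of these, by design — it validates the estimators'
algebra and statistical behaviour, not their robustness to un-modelled
biology.

## Numerical choices and degenerate inputs

* Feasibility/node tolerance 1e−9; SVD rank tolerance as above.
* Window ties break toward longer, then earlier windows (growth) and
  toward longer windows at the earliest admissible start (assays).
* Constant OD: μ = 0 with $r^2$ reported as 0 and the fallback flag set.
* Zero substrate consumption, unregistered compounds, non-monotone time,
  negative concentrations, and unknown config keys raise structured errors
  naming the offender.
* Problem sizes in tests: recovery sweeps use 40–200 simulated courses of
  25 timepoints × 3 replicates; the flux systems are 16 nodes × ≤ 15
  reactions. All suites run in seconds.

## Limitations

* The flux model is deliberately small: no genome-scale reconstruction, no
  thermodynamics, no biomass drain (growing-culture yields are expected to
  leave residuals), no kinetic/dynamic modelling.
* The in vivo electron donor of fumarate reductase is unresolved
  (the assay used methylviologen); it is a scenario parameter, NADH by
  default, and `"none"` removes the reaction.
* H2 yields are treated as dissolved-equivalent mM per culture volume; no
  gas-phase partitioning model.
* Published specific activities cannot be recomputed without the raw
  traces; only synthetic recovery is testable.
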