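---
title: "Carbon-budget modelling and statistical model checking for Pelagia noctiluca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon-budget modelling and statistical model checking for Pelagia noctiluca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jellysmc)
```

## The model

`jellysmc` simulates the daily carbon budget of an individual *Pelagia
noctiluca*. Seven processes move carbon: predation, ingestion,
assimilation, respiration, excretion, reproduction and egestion. The state
is a single pool, the individual's carbon mass `CM`; bell diameter and wet
mass are diagnostic, linked by the allometries `WM = 0.075·BD^2.993` (g)
and `CM = 0.26·BD^3.017` (mg). The growth increment and the egested flux
are

    dG = A − (R_C + Ex + Re),        Eg = I − A,

and the simulator enforces both identities to machine precision at every
step (they are bookkeeping, not approximations).

Assumptions worth making explicit:

* **0-D, individual-based.** No population structure, mortality, jelly
  falls or advection. The organism is a carbon pool exposed to a
  temperature and a prey concentration.
* **Michaelis–Menten predation with a derived ceiling.** The maximum
  predation rate is not free: assuming the feeding observations behind the
  allometric coefficient were made at food saturation (`F_sat = 1.2e-4`
  gC L⁻¹), `p_max = 0.1399·(1 + k_p/F_sat)` follows from any candidate
  `k_p`, and the package recomputes it wherever `k_p` changes
  (`p_max_from_kp()`). Note `F_sat` is described as twice the maximum
  in-situ prey concentration, yet the climatology peaks near 5–6·10⁻⁶
  gC L⁻¹, twenty times lower; the constant 1.2·10⁻⁴ is used as printed.
* **Assimilated fraction falls with food.** `A = I·(1 − a_max·F/(F+k_a))`
  is implemented literally: at saturating food the assimilated fraction
  tends to `1 − a_max`, so `a_max = 1` starves the animal at high food.
  This is a property of the model as formulated (its calibrations do push
  `a_max` toward 1 in situ, which is one of its known structural
  weaknesses), not a defect of the implementation.
* **Q₁₀ temperature scaling.** Every temperature-dependent rate carries
  `t₁₀^T` with `t₁₀ = 1.066` (Q₁₀ ≈ 1.9). A single shared `t₁₀` is the
  default because only one value is tabulated; per-process overrides
  (`t_10p`, `t_10r`) exist because predation and respiration were
  calibrated from different datasets.
* **Nycthemeral migration as rate averaging.** When a deep temperature is
  supplied (13 °C in the Mediterranean scenarios), each rate is evaluated
  at both temperatures and averaged with equal weight — an equal 12 h
  day/night split.
* **Maturity gate.** Reproduction is zero strictly below 4 cm bell
  diameter and active at 4 cm and above (closed threshold). Spawning is a
  continuous rate (`spn` per day), not discrete pulse events, because the
  reproduction term is formulated as a rate.

### Unit bases: two deliberate choices

Two places in the model are genuinely ambiguous about which mass enters an
allometry, and both are exposed as configuration switches:

* **Respiration** (`respiration_mass_basis`, default `"wm"`): the tabulated
  coefficient `R_o = 2.80` µmol O₂ d⁻¹ is defined for a 1 g *wet mass*
  individual at 0 °C, although the rate equation is written on CM. The
  default follows the coefficient's definition; `"cm"` evaluates the same
  law on carbon mass in grams.
* **Reproduction** (`reproduction_size_basis`, default `"bd_cm"`): the
  egg-production power law `a_re·X^4.66` is written on CM. Evaluated on
  carbon mass in mg, a mature 4.5 cm animal would produce ~4·10⁴ eggs per
  spawn — a reproductive loss of ~0.57 gC d⁻¹ against a body pool of
  0.024 gC, killing every mature animal within a day and making the
  observed growth-to-plateau behaviour impossible. On carbon mass in g it
  produces ~10⁻⁹ eggs. Evaluated on bell diameter in cm it yields ~80 eggs
  per spawn at 4.5 cm and ~3000 at 10 cm (the observed "hundreds of
  eggs"), reproduces the ~47 %/53 % respiration/reproduction split of
  starved-adult carbon loss near 8 cm, and lets a fed animal plateau near
  10 cm, inside the observed 2.1–21 cm range. The bell-diameter basis is
  therefore the default; the carbon-mass readings remain available.

### Integration

Forward Euler with `dt = 1` day, the native resolution of the rates
(`dt` is configurable down to sub-daily steps, holding forcing constant
within a day; the integrator is first order, which the test suite verifies
directly). A trajectory whose carbon pool would go non-positive is
truncated and flagged `"exhausted"` — never silently clamped — and the
tunnel check counts it as outside the observation band from the truncation
time onward: a simulated animal that dies before the experiment ends is a
wrong fit, not a missing value.

## The calibration engine

Six parameters (`k_p`, `a_max`, `k_a`, `c_re`, `spn`, `c_e`) plus the
laboratory prey concentration `F_lab` are unknown. The engine treats a
candidate parameter vector not as a point but as a box: each searched
value is wrapped in a uniform interval of half-width its *pseudo standard
deviation* (±0.05 for `spn`, `a_max`, `c_re`; ±5·10⁻⁶ for `k_a`; ±1·10⁻⁵
for `k_p`; ±0.025 for `c_e`; ±5·10⁻⁷ for `F_lab`, half its grid
resolution, consistent with the pattern of the other brackets). Draws are
truncated at 0 from below, and at 1 for `a_max` (its invariant). Each
random simulation draws one realization per scenario set, re-deriving
`p_max` from the drawn `k_p`.

A simulation *matches* when the compared variable (bell diameter or carbon
mass, interpolated linearly between daily outputs) lies inside the
observation tunnel at **every** tunnel time in **every** scenario. The
match probability Θ of a candidate is estimated as the pass fraction of up
to `n_sims` simulations; candidates with Θ above the threshold γ = 0.70
are retained.

Three statistical details:

* **Precision.** The run configuration (500 simulations, ε = 5 %,
  δ = 1 %) mirrors the published setup, but the Chernoff–Hoeffding bound
  for |Θ − P| ≤ ε at confidence 1 − δ actually requires
  `ch_required_n(0.05, 0.01) = 1060` draws. The bound-implied size is a
  package function, and the estimator-consistency test runs the toy model
  at that size; the default `n_sims = 500` is kept for fidelity to the
  published configuration.
* **SPRT pruning, one-sided.** Wald's sequential test of
  H₀: p ≥ γ+ε against H₁: p ≤ γ−ε with both error rates δ stops a
  candidate as soon as the log-likelihood ratio crosses the rejection
  boundary `log((1−δ)/δ)` — after 14 straight failures at the defaults. It
  never *accepts* early: surviving candidates always complete their
  `n_sims` simulations. The δ-bound on falsely rejecting a good candidate
  applies to p ≥ γ+ε; inside the indifference region (p ≈ γ) the
  likelihood drift is near zero and no bound exists, which is the price of
  the speedup.
* **Determinism.** Every candidate derives its RNG seed from the master
  seed and its own grid index, so serial, parallel and permuted runs
  return bit-identical results.

Accepted vectors are ranked by a combined error summed over scenarios:
per scenario, (mean violated tunnel times per simulation)/(tunnel size) +
mean excursion beyond the band in local half-width units. The per-point
normalization keeps the weekly 365-day in-situ record from out-voting a
30-day laboratory experiment — each condition contributes through its
per-observation behaviour, not its sampling density. Scenario weights are
equal by default; nothing in the calibration compromise justifies others.
Excursions beyond a degenerate (zero-width) band are measured raw, since
no half-width exists.

The Spearman correlogram over accepted vectors (`correlogram()`) uses rank
correlation because parameter–output relations here are monotone but not
linear; a constant column has no ranks and its correlations are reported
as missing (`NA`), never coerced to zero.

## The synthetic study

The package carries no observational data. The generator
(`synthetic_spec()`, `synth_scenarios()`) emulates the structure of the
study's three calibration settings:

* **Laboratory degrowth**: 18 °C, no food, 30 days, observations every
  2 days; starting bell diameter 4.5 cm. Starting sizes are surrogate
  values — the culturing experiments' exact initial sizes are not
  published.
* **Laboratory growth**: 18 °C, constant `F_lab` (truth 9·10⁻⁶ gC L⁻¹, a
  grid value mid-bracket), 30 days, same cadence; starting at 1 cm.
* **In-situ**: a smooth 365-day climatology — sinusoidal SST spanning
  13–22 °C peaking in late August (day 235), zooplankton at a 1·10⁻⁶
  gC L⁻¹ floor with a Gaussian spring bloom peaking at 5.5·10⁻⁶ around
  day 120 (width 30 d) — deep temperature 13 °C, weekly observations,
  single cohort starting at 2.1 cm. Timing and levels follow the narrative
  seasonal description of the Villefranche climatology; the phase
  parameters are the generator's own choices within that narrative.

Observation noise is multiplicative Gaussian (10 % of signal by default, 5
replicates per time), because size measurements scale with organism size;
tunnels are replicate mean ± `k_std`·sd with `k_std = 1`.

What the generator does *not* emulate: observation gaps and weather-driven
biases, cohort mixing (the synthetic tunnels track one cohort), interannual
variability, and the actual magnitude of in-situ growth — at the
laboratory best-fit `k_p = 1.9·10⁻⁴` the in-situ feeding term `F/(F+k_p)`
never exceeds ~3 %, so the synthetic annual cycle oscillates between ~1.2
and ~2.7 cm from a 2.1 cm start rather than climbing through the full
observed 2.1–21 cm envelope. Passing tests therefore demonstrate that the
pipeline recovers known parameters from data with the assumed noise
structure — not that the model reproduces any particular field year.

### Tunnel-width coverage, and what recovery can show

The all-times match criterion interacts sharply with the tunnel
construction. A mean ± 1·sd band built from 5 replicates covers the true
value at a single observation time with probability
P(|t₄| < √5) ≈ 0.911; across the ~85 observation times of the three
scenarios, the *true* model's probability of sitting inside everywhere is
≈ 0.911⁸⁵ ≈ 3·10⁻⁴. With `k_std = 1`, then, no candidate — including the
truth — can reach a 70 % match, whatever the implementation; the match
threshold is only attainable with wider tunnels (`k_std ≈ 3` gives ~80 %
coverage; the multiplier is exposed precisely because the appropriate
value depends on how many observation times a study checks). The
parameter-recovery experiment (`recovery_experiment()`) therefore reports
two things: whether the truth is *retained* (Match > γ — not attainable at
`k_std = 1`, for the coverage reason above), and where the
truth *ranks* by combined error — which is the discriminating quantity, is
robust to tunnel width, and places the truth within one normalized error
unit of the best candidate in 20 of 20 seeds on the default reduced grid
(3 values per searched parameter, 2187 candidates, 100 simulations each;
roughly five seconds per seed on one core). Engine retention itself is
verified separately under wide, low-noise tunnels, where the truth passes
and a grossly wrong competitor is SPRT-rejected.

## Carbon export

Egestion — ingested but unassimilated carbon, released as mucus — is the
model's vector of particulate export. The export chain multiplies a
per-individual egestion rate by an areal abundance and by the carbon
surviving the descent. The surviving fraction uses first-order decay in
transit, `1 − exp(−k·z/w)` lost (default; a linear variant `k·z/w` is also
provided): the product form "egestion × speed × rate" is dimensionally
inconsistent as a flux and is intentionally not implemented — both
implemented forms reproduce the measured ~1 % loss over 0–200 m at
w = 751 m d⁻¹ and k = 0.034 d⁻¹. Abundance enters as quantile summaries
(median 0.018, quartiles 0.003–0.1 ind m⁻², the 2013 Ligurian transect
summary) so export is bracketed rather than point-estimated, and
`export_table()` expresses monthly fluxes against a reference total POC
climatology.

One loose end is documented rather than resolved: the mucus share of total
spawn reported for the calibrated model (67.5 %, 62.5 %, 67.5 % across
conditions) is not reproducible from any obvious function of the
calibrated `c_re` ∈ {2.7, 2.5} — `(c_re−1)/c_re` gives 63 %/60 %,
`c_re/(1+c_re)` gives 73 %/71 % — so neither formula is asserted anywhere;
the reproduction flux itself uses `c_re` multiplicatively as defined.

## Numerical choices and limitations

* Grids are index-generated (`lo + i·step`), never accumulated, so bracket
  endpoints are exact; bracket upper bounds need not lie on the grid (the
  `k_p` bracket ends at 1.9·10⁻⁴).
* Tunnel interpolation is linear in time; observation times need not align
  with integration steps.
* Exhausted trajectories score the compared variable as 0 after
  truncation, which is always an excursion below a positive band.
* The full 4.2-million-candidate grid is enumerable but guarded
  (`max_size`): evaluating it is a cluster-scale computation by design;
  the package's experiments run reduced grids.
* The model has no mortality, no jelly falls, no DOC pathway beyond the
  excretion scalar, and treats reproduction as a continuous drain; its
  calibrations push `a_max` and `c_e` to their bounds, which is informative
  about the model structure rather than about the animal.
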