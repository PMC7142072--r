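# jellysmc

Carbon-budget modelling and statistical model checking for the
Mediterranean jellyfish *Pelagia noctiluca*.

Gelatinous zooplankton are poorly represented in ocean biogeochemical
models largely because their ecophysiological parameters are hard to pin
down: laboratory measurements carry large uncertainties, and field patterns
constrain different parameters than culturing experiments do. `jellysmc`
implements, for modellers and biological oceanographers working on
gelatinous carbon fluxes:

1. a **0-D ecophysiological carbon-budget model** of an individual
   jellyfish, driven by temperature and prey concentration;
2. a **statistical model checking engine (SMCE)** that calibrates the
   model's unknown parameters *with* their uncertainty, by estimating for
   each candidate parameter vector the probability that random simulations
   stay inside observation "tunnels";
3. a **synthetic-data generator** that emulates the laboratory
   growth/degrowth experiments and an annual Mediterranean climatology, so
   the whole pipeline is testable end to end without any external dataset;
4. **POC-export arithmetic** converting modelled egestion (mucus) into a
   particulate organic carbon flux at depth.

## The model

The daily change in an individual's carbon mass balances assimilation
against respiration, excretion and reproduction, with egestion the
unassimilated remainder of ingestion:

    dG = A − (R_C + Ex + Re)          Eg = I − A

with the process rates (CM carbon mass, T temperature in °C, F prey
concentration in gC L⁻¹):

    P  = p_max · CM^b_p · t₁₀^T / (F + k_p)        predation
    I  = P · F                                      ingestion
    A  = I · (1 − a_max · F / (F + k_a))            assimilation
    R  = R_o · M^b_r · t₁₀^T                        respiration (µmol O₂ d⁻¹)
    R_C = R · β · α                                 respiration in carbon
    Ex = R_C · c_e                                  excretion
    Re = (a_re · BD^b_re) · W_e · c_re · spn        reproduction (mature only)

`t₁₀` is the tenth root of the Q₁₀ coefficient, so every
temperature-dependent rate scales by `t₁₀^10` per 10 °C. Bell diameter
(BD, cm), wet mass (WM, g) and carbon mass (CM, mg) are linked by the
allometries `WM = 0.075·BD^2.993` and `CM = 0.26·BD^3.017` (carbon is
~0.36 % of wet mass). Animals reproduce from 4 cm bell diameter; the
vertical day/night migration is represented by averaging each rate at the
surface and the 13 °C bathypelagic temperature. Six parameters (`k_p`,
`a_max`, `k_a`, `c_re`, `spn`, `c_e`) plus the laboratory prey
concentration `F_lab` are unknown and searched; the rest come from
published experiments.

The SMCE wraps each candidate vector from the search grid (4,191,264
candidates for the full published brackets) in uniform uncertainty
intervals, Monte Carlo-estimates the probability ("Match") that perturbed
simulations stay inside time-indexed observation bands built from replicate
mean ± k·std, prunes hopeless candidates early with Wald's sequential
probability ratio test (one-sided: it only ever rejects), and ranks
accepted vectors by a per-point-normalized combined error across the
laboratory degrowth, laboratory growth and in-situ scenarios. A Spearman
correlogram over the accepted vectors exposes dependencies between
parameters.

## Worked example

Starve a mature 4.5 cm adult for 30 days at 18 °C:

```r
library(jellysmc)
p  <- jelly_params()                       # laboratory best-fit defaults
fz <- forcing_series(0:30, T_surface = 18, F = 0)
tr <- simulate_jelly(4.5, fz, p)
print(tr)
#> Jellyfish trajectory: 31 records (ok)
#>   t = [0, 30] d; bell diameter 4.5 -> 3.46 cm

signif(as.data.frame(tr)[c(1, 16, 31), c("t_day","bd_cm","cm_gC","R_C","Re","Eg")], 3)
#>  t_day bd_cm  cm_gC      R_C       Re Eg
#>      0  4.50 0.0243 0.000537 0.000223  0
#>     15  3.88 0.0156 0.000356 0.000000  0
#>     30  3.46 0.0110 0.000257 0.000000  0
```

The starved animal shrinks quasi-exponentially; on day 0 respiration and
reproduction account for 70.7 % and 29.3 % of the carbon loss (excretion is
0 at the best-fit `c_e = 0`), and reproduction switches off once the animal
shrinks below the 4 cm maturity threshold. Egestion is zero without food —
it is the unassimilated share of ingested prey, and it is what sinks:

```r
100 * loss_fraction(w = 751, k = 0.034, z = 200)
#> [1] 0.9013724   # ~1% of mucus carbon remineralizes over the top 200 m
```

Calibration runs the same way on any scenario bundle. A fully synthetic
parameter-recovery experiment (ground truth on a reduced 3-values-per-
parameter grid, 2187 candidates, 100 simulations each):

```r
rec <- recovery_experiment(seed = 1)
rec$rank          #> 10      rank of the truth by combined error, of 2187
rec$truth_error   #> 0.556   vs. minimum 0.538 (well within one unit)
rec$retained      #> FALSE   see the vignette on tunnel-width coverage
```

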