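# kinmem — kinetic memory in enzyme-limited modification networks

`kinmem` simulates and analyses multisite protein-modification kinetics in
the *enzyme-limited competition* (ELC) regime, where cellular memory is
stored not in multiple attractors but in a relaxation process so slow that
the modification state keeps a continuous record of past stimulation. It is
aimed at systems/computational biologists studying post-translational
modification dynamics (CaMKII- or CREB-like multisite phosphorylation,
receptor methylation) who want a rigorous, tested reference implementation
of the ELC mechanism.

## The models

A substrate with N modification sites occupies levels i = 0…N with total
concentrations X_i (free + catalyst-bound). Binding/unbinding is fast, so
the free catalyst is eliminated adiabatically through the conservation law

    E_tot = E_free + Σ_i X_i · E_free / (K_i + E_free),

and each modification lowers the substrate–catalyst binding energy
linearly, so the dissociation constants grow exponentially with the
modification level:

    K_i = K · exp(θ·i).

Three reduced models share this core:

* **chained modification model** — uncatalysed modification at rate
  k_mod + I(t) (I is the stimulus), catalysed demodification at rate
  k̃ · X_i · E_free/(K_i + E_free);
* **kinase–phosphatase model** — both directions catalysed, two conserved
  catalysts, total kinase as the stimulus;
* **extended Asakura–Honda model** — a two-conformation receptor with fast
  ligand-dependent flip-flop and one shared co-factor; its activity shows
  perfect adaptation with fast response and catalyst-limited slow
  relaxation.

When the catalyst total drops below the substrate total, the differently
modified forms compete for the catalyst, the per-level relaxation
timescales spread as e^{θi}, and the relaxation time jumps by orders of
magnitude — the kinetic memory transition. Full mass-action reference
models (explicit complexes, finite k_on with k_off,i = k_on·K_i) validate
the adiabatic reduction, and a matrix-exponential first-order-chain oracle
validates the catalyst-saturated limit.

## Worked example

```r
library(kinmem)

p <- preset("fig2")          # reference enzyme-limited condition
p
#> Chained modification model parameters
#>   N = 10 sites; k_mod = 0, k_demod = 1
#>   K_i = 0.0001 * exp(1 * i)  (K_N = 2.20265)
#>   S_total = 1, E_total = 0.001

## relax from the fully modified state; the integrator stops by root
## finding when the modified mass crosses the 0.01 threshold
tr <- simulate_chain(p, t_end = 1e10, stop_below = 0.01)
summ <- classify_decay(tr)
summ
#> relaxation summary: tau = 8.179e+07, class = intermediate
#>   R2 exp/stretched/log = 0.9647 / 0.9976 / 0.9311; log slope -0.125
#>   site order: 1 2 3 4 5 6 7 8 9 10 (ascending); plateaus: 0

ph <- p; ph$E_total <- 10    # catalyst-rich: fast exponential phase
tau_fast <- relaxation_time(simulate_chain(ph, t_end = 1e4, stop_below = 1e-3))
summ$tau / tau_fast
#> [1] 4181373
```

Reading the output: at one-thousandth of the substrate concentration the
catalyst is sequestered by the weakly modified pool and the relaxation time
τ (first crossing of the modified mass below 0.01) reaches 8.2·10⁷ time
units — more than 10⁶ times the catalyst-rich value of ~20. The decay is
much slower than exponential (R² 0.96 vs 0.998 for a stretched exponential
with small exponent; the modification level loses ≈ 0.125 per unit ln t on
the interior window), and the sites complete their relaxation in ascending
order — the reversal characteristic of enzyme-limited competition, opposite
to first-order kinetics. `sweep_catalyst()`, `memory_map()`,
`sweep_sites()` and `scaling_below_critical()` script the full experiments:
the τ(E) transition and its sharpness, the stimulus magnitude × duration
memory map, and the site-number dependence.

A thin command-line front end is installed with the package
(`system.file("cli", "kinmem.R", package = "kinmem")`) with subcommands
`simulate`, `sweep`, `memory`, `classify`, `oracle-check` and
`presets list`; every run writes TSV output plus a JSON manifest echoing
the configuration.

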