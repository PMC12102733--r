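# kinhibit

Determining *how* a small molecule inhibits an enzyme — competitively,
uncompetitively, noncompetitively or by a mixed mechanism — is a routine but
error-prone step in early drug discovery. kinhibit implements the classical
graphical workflow for answering that question from fluorogenic microplate
assays, end to end and fully tested: progress curves → initial velocities →
Michaelis–Menten and general-inhibitor-model fits → Dixon and Cornish–Bowden
secondary plots → a mechanism verdict with an inhibition-constant estimate.
It was built around the kinetic characterisation of a cysteine-protease
(cathepsin B class) inhibitor, but nothing in it is specific to that enzyme.

## The model

Steady-state velocities follow the general (mixed) inhibitor rate law

    v = Vmax [S] / ( KM (1 + [I]/Ki) + [S] (1 + [I]/Ki') )

where `Ki` and `Ki'` are the dissociation constants of the inhibitor from
free enzyme and from the enzyme–substrate complex. Mechanisms are finiteness
patterns of `(Ki, Ki')`; infinite constants are represented as `Inf`, never
as large numbers. Two linear replots at fixed `[S]` discriminate the
patterns:

* **Dixon** (`1/v` vs `[I]`): parallel lines ⇔ uncompetitive; otherwise
  concurrent at `[I] = −Ki`.
* **Cornish–Bowden** (`[S]/v` vs `[I]`): parallel ⇔ competitive; otherwise
  concurrent at `[I] = −Ki'`, with ordinate `KM/Vmax` when the inhibitor
  does not bind free enzyme.

With noisy data the lines do not meet in a point, so the common intersection
is estimated by minimising the summed squared perpendicular distances
`Σᵢ (aᵢx + bᵢy + cᵢ)² / (aᵢ² + bᵢ²)` over all lines — a closed-form 2×2
solve. Parallelism is decided by an extra-sum-of-squares F-test;
noncompetitive vs mixed by the nested F-test of `Ki = Ki'` on the velocity
scale. A seeded plate simulator (substrate depletion, detector gain and
noise, pipetting error, triplicates) provides ground-truthed data for every
stage.

## Worked example

Simulate a realistic triplicate assay (KM = 93.9 µM, Vmax = 33.02
pmol min⁻¹ µg⁻¹, uncompetitive inhibitor with Ki' = 44.3 µM, 2% pipetting
CV, 5 AU read noise) and analyse it:

```r
library(kinhibit)

truth  <- kinetic_params(KM = 93.9, Vmax = 33.02, Ki_prime = 44.3)
plate  <- simulate_plate(assay_design(seed = 7), truth)
rates  <- build_rate_table(plate)
res    <- analyze_rate_table(rates)
res$mechanism
#> Mechanism verdict: uncompetitive
#>   Dixon lines parallel: TRUE (p = 0.113, spread = 0.272)
#>   S/v lines parallel:   FALSE (p = 1.89e-17, spread = 2.1)
#>   Ki' = 40.56 uM
#>   KM/Vmax consistency: 5.15% difference
```

The Dixon pencil is statistically parallel while the S/v pencil converges at
a negative abscissa: the uncompetitive signature. `Ki'` is the negated
abscissa of the closest-neighbour intersection (truth: 44.3 µM), and the
consistency line compares the intersection ordinate with `KM/Vmax` from the
zero-inhibitor fit. The per-inhibitor-level fits show the uncompetitive
fingerprint — Vmax and KM falling together:

```r
round(res$per_inhibitor[, 1:5], 3)
#>    I_uM KM_app KM_se Vmax_app Vmax_se
#> 1  0.00 90.970 2.468   32.795   0.392
#> 2  6.25 82.609 0.557   28.966   0.083
#> 3 12.00 72.810 0.503   25.840   0.072
#> 4 20.00 66.668 1.749   22.906   0.234
#> 5 25.00 59.616 0.758   21.073   0.100

res$global$comparison
#>        mechanism residual_ss      aic_c converged
#> 1           none  57.8772111   26.63687      TRUE
#> 2    competitive  14.7185546  -11.76265      TRUE
#> 3 noncompetitive   2.3958202  -66.22415      TRUE
#> 4          mixed   0.1955853 -138.48867      TRUE
#> 5  uncompetitive   0.2202715 -137.82275      TRUE
```

The uncompetitive global fit ties with the (more flexible) mixed model that
nests it and beats everything else; the AICc table is reported for context
but the verdict rests on the graphical analysis. `cmd_analyze()` wraps the
same chain for CSV inputs (raw plates or pre-computed rate tables) and
writes a JSON report, and `cmd_benchmark()` measures classifier accuracy
and Ki' recovery across seeded simulations.

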