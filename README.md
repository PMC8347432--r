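# nmrbind

Thermodynamic and kinetic inference from solution-NMR observables for small
aromatic drugs that stack — with themselves and with DNA.  The motivating
systems are camptothecin-family topoisomerase-I inhibitors interacting with a
short self-complementary DNA duplex, but the models are generic:

* **Self-association** from dilution chemical shifts, by the *isodesmic*
  (indefinite, equal-constant) stacking model
  Δδ_obs = Δδ_max · K_a·L₀ · (2/(1+√(1+4·K_a·L₀)))², whose concentration
  factor equals K_a·[L], the fraction of stacked contacts;
* **1:1 DNA binding** from chemical-shift titrations,
  Δδ = Δδ_DNA·L · K_a[DNA]/(1+K_a[DNA]), with [DNA] the equilibrium free
  duplex from the exact 1:1 quadratic (or the total-titrant approximation);
* **1:1 DNA binding again, independently,** from fast-exchange-averaged
  diffusion coefficients (DOSY): MF_L = (D_obs − D_complex)/(D_free −
  D_complex), [DNA·L] = (1−MF_L)·C_L, K_a = [DNA·L]/(([DNA]_tot−[DNA·L])
  ([L]_tot−[DNA·L])) — a closed form that exactly inverts the package's own
  forward model;
* **Degradation kinetics** f(t) = A₀·e^(−kt) with half-life t½ = ln2/k.

Every analysis ships with a seeded synthetic-data generator built on the same
forward model, so each fit is verifiable by parameter recovery, and an
end-to-end `run_study()` compares the titration- and diffusion-derived
binding constants per compound.

Intended users: NMR spectroscopists and medicinal chemists reducing
dilution/titration/DOSY/stability tables (CSV) to constants, and method
developers who need a transparent, testable reference implementation.

## Worked example

```r
library(nmrbind)

# --- self-association from a dilution series ------------------------------
d <- simulate_dilution(Ka = 1.71, seed = 42)   # 6 protons, 0.003-1.2 mM
fit <- fit_isodesmic(d)
fit
#> Isodesmic self-association fit (per_proton_average)
#>   Ka = 1.895 +/- 0.454 mM^-1  (6 protons, 0 excluded)
#> # A tibble: 6 x 6
#>   proton    Ka delta_mon delta_max       rss excluded
#>   <chr>  <dbl>     <dbl>     <dbl>     <dbl> <lgl>
#> 1 H11     1.89      7.62    0.305  0.0000632 FALSE
#> 2 H12     1.57      7.98    0.416  0.0000417 FALSE
#> ...
```

The per-proton table shows each proton's fitted constant (mM⁻¹), its
infinite-dilution shift and limiting stacking shift (ppm), and the residual
sum of squares; the header line is the pooled mean ± SD over protons — here
recovering the generating K_a = 1.71 mM⁻¹ within the per-proton scatter.
`autoplot(fit)` draws the isotherms.  Real data come in the same shape via
`read_dilution_csv()`:

```r
csv <- system.file("extdata", "dilution_synthetic.csv", package = "nmrbind")
fit2 <- fit_isodesmic(read_dilution_csv(csv))
```

```r
# --- 1:1 binding, two independent routes ----------------------------------
glance(fit_binding_titration(simulate_titration(Ka = 5.0, seed = 42)))
#> # A tibble: 1 x 6
#>   Ka_mean Ka_sd dna_mode   baseline_mode n_protons n_excluded
#>     <dbl> <dbl> <chr>      <chr>             <int>      <int>
#> 1    5.47  1.23 free_exact fixed                 6          0

ka_from_diffusion(simulate_dosy(Ka = 5.9, C_L = 0.1, C_DNA = 0.3))
#> # A tibble: 1 x 5
#>   sample_id mf_L_free complex_mM Ka_mM_inv assumption_flag
#>   <chr>         <dbl>      <dbl>     <dbl> <chr>
#> 1 mix01         0.413     0.0587      5.90 D_complex = D_obs_DNA

# --- degradation half-life -------------------------------------------------
fit_decay(simulate_decay(t_half = 50, seed = 42))
#> Degradation fit (order 1, fixed_1): k = 0.01333 /day, t1/2 = 52.0 days
```

The diffusion route reports, per mixture, the free-ligand mole fraction, the
complex concentration (mM) and the binding constant (mM⁻¹); on noiseless
input it returns the generating constant exactly.  The decay fit reports the
first-order rate (1/day) and half-life (days); 52.0 days here is the noisy
recovery of a true 50-day half-life.

See the methods vignette (`vignettes/nmr-thermodynamics.Rmd`) for the models,
conventions (free vs. total duplex, baseline drift correction, pooling) and
the generators' design.

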