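# lanmkit

Quantitative models for lanmodulin rare-earth recognition and separation.

Lanmodulins (LanMs) are small, four-EF-hand proteins that bind
lanthanide(III) ions with picomolar affinity and respond with a
disorder-to-order transition — the basis of an all-aqueous alternative to
solvent-extraction rare-earth separations. The LanM from *Hansschlegelia
quercus* (*Hans*-LanM) additionally couples its monomer–dimer equilibrium
to the bound ion's radius: light rare earths (La³⁺, Nd³⁺) drive tight
dimerization while heavy ones (Dy³⁺) do not, and that difference can be
leveraged for single-stage Nd/Dy separation on an immobilized-protein
column.

lanmkit is an R package for scientists characterizing such systems. It
implements, end to end:

* **Sequence screening** — EF-hand loop scanning with a configurable
  position-class pattern, LanM curation rules (length < 200, ≥ 4 hands,
  adjacent hands < 14 residues apart, proline-2 hallmark), ProtParam-style
  sequence properties (MW, ε₂₈₀ = 5500·nTrp + 1490·nTyr + 125·n_cystine),
  and identity-thresholded sequence similarity networks with connected-
  component clustering.
* **Binding models** — 1:1 chelator-buffer speciation
  (K·x² − (K·M_T + K·L_T + 1)·x + K·M_T·L_T = 0, solved in
  cancellation-free form), Hill fits
  S(x) = S₀ + (S₁−S₀)·xⁿ/(Kⁿ + xⁿ) with bootstrap errors, and
  four-parameter-logistic desorption midpoints [chelator]₁/₂ with
  selectivity ratios.
* **Oligomeric state** — the dimer-dissociation equilibrium
  2[M]² + K_dimer[M] − K_dimer[P] = 0, weight-average MW for SEC–MALS
  interpretation, and a dilution-ITC forward model + fit yielding
  K_dimer, ΔH, ΔS, with profile-likelihood detection of bound-only
  (unobservably tight) dimers.
* **Luminescence** — single-exponential lifetime fits, the 1/τ vs D₂O
  fraction slope, and hydration numbers
  q = 1.11[τ_H₂O⁻¹ − τ_D₂O⁻¹ − 0.31 + 0.45·n_OH + 0.99·n_NH + 0.075·n_O–CNH].
* **Separation** — distribution ratios with the bead-carryover correction
  [M]_LanM = (4[M]_de − [M]_ad)/4, separation factors SF = D₁/D₂, pooled
  purity/yield over explicit elution windows, and breakthrough detection.
* **Structure sites** — PDB/mmCIF parsing, lanthanide coordination
  numbers and donor inventories, Asp/Glu carboxylate denticity
  (bidentate/monodentate shifts), second-sphere contact distances, and
  Shrake–Rupley buried interface areas.
* **Synthetic data** — seeded generators emulating every input above, so
  each stage is testable with no downloads.

All user-facing functions take data frames and return tibbles; fitted
objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Simulate a chelator-buffered La³⁺ titration at the characterized
*Hans*-LanM conditions (K_d,app = 68 pM, Hill n = 2, 2% noise) and
recover the parameters — the fit recomputes free metal from the buffer
mass balance before fitting:

```r
library(lanmkit)

sim <- gen_titration(68e-12, 2, n_points = 12, conc_range = c(1e-12, 1e-8),
                     noise = 0.02, buffered = TRUE, seed = 7)
fit <- fit_hill(sim$data, buffered = TRUE, seed = 7)
fit
#> <hill_fit> K_d,app = 7.077e-11 M (se 1.9e-12), n = 1.94 (se 0.087)
tidy(fit)
#> # A tibble: 4 × 3
#>   term   estimate std.error
#>   <chr>     <dbl>     <dbl>
#> 1 kd     7.08e-11  1.92e-12
#> 2 n      1.94e+ 0  8.72e- 2
#> 3 s0    -1.27e- 3  8.04e- 3
#> 4 s1     1.03e+ 0  7.32e- 3
```

The recovered K_d,app (70.8 ± 1.9 pM) and cooperativity (n = 1.94)
match the planted 68 pM / 2 within noise; `autoplot(fit)` draws the
curve. The same round trip for dilution ITC of the apo dimer
(K_dimer = 117 µM, 0.2 µl + 17 × 2 µl schedule, 185 µl cell, 300 µM
syringe, 30 °C):

```r
itc <- gen_itc(117e-6, 30000, noise = 0.02, seed = 7)
fit_itc(itc$data)
#> <itc_fit> K_dimer = 0.0001309 M, dH = 29.73 kJ/mol, dG = 22.54 kJ/mol,
#>           dS = 23.72 J/mol/K (T = 303.15 K)
```

K_dimer comes back at 131 µM (12% from truth at this seed and noise
level) with ΔH within 1%; ΔG is computed at the 1 M standard state and
ΔS = (ΔH − ΔG)/T. A dimer too tight to observe dissociating is reported
as a one-sided bound (`bound_only`) instead of a sham point estimate.

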