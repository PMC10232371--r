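---
title: "Models and methods behind lanmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lanmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanmkit)
```

Lanmodulins (LanMs) are small EF-hand proteins that respond to picomolar
lanthanide(III) with a disorder-to-order transition, and they are the
basis of an all-aqueous rare-earth separation chemistry. The LanM from
*Hansschlegelia quercus* (*Hans*-LanM) adds a twist to the family: its
monomer–dimer equilibrium is sensitive to the bound rare earth's ionic
radius, with light rare earths (La, Nd) driving much tighter dimerization
than heavy ones (Dy). lanmkit implements the quantitative models used to
characterize such a system end to end — from mining candidate sequences
to scoring a column separation — together with seeded generators that
emulate every input, so the whole pipeline is testable without external
data. This vignette records the models, the tunable parameters, and the
numerical and design decisions.

## Sequence screening

EF hands carry a 12-residue metal-coordinating loop. In lanmodulins the
loop donates a monodentate Asn/Asp at position 1, carboxylates at
positions 3, 5, 9 and 12, a backbone carbonyl at position 7, and — a
family hallmark — often a proline at position 2. No exact regular
expression for the family is established, so `scan_ef_hands()` matches a
*configurable* position-class table, defaulting to position 1 ∈ {D,N},
3 ∈ {D,N,E}, 5 ∈ {D,N,E,S,T}, 12 ∈ {D,E} with all other positions free
(`ef_hand_pattern()`). These classes are the ligand sets compatible with
lanmodulin-style ten-coordinate sites; they are deliberately permissive
at position 9, which varies across the family. `X` never matches a
constrained position. Matching is left-greedy and non-overlapping,
mirroring how one reads loops off a sequence.

`classify_lanm()` applies the curation rules used when mining candidate
lanmodulins: length below 200 residues, at least four EF hands, at least
one adjacent pair of hands separated by 13 or fewer residues (spacing =
residues strictly between one loop's position 12 and the next loop's
position 1; classical calcium-sensor proteins space hands by roughly 25),
and at least one proline-2 hand. Two ambiguities were resolved as
follows: "four EF hands" is implemented as *at least* four with an
`exact_hands` toggle, because several family members carry a degenerate
fifth match and excluding them by default would silently discard true
positives; and the proline-2 hallmark is enforced by default
(`require_p2 = TRUE`) but always reported separately in `has_p2`, so a
screen can be rerun without it at zero cost. Signal peptides are assumed
removed before scanning.

Pairwise similarity uses Needleman–Wunsch global alignment (BLOSUM62,
gap open 11 / extend 1 — the classic protein-search parameterization)
via Biostrings. Percent identity counts identities over the alignment
length *including internal gaps but excluding terminal gap runs*; the
convention matters because popular network tools differ subtly here, and
excluding overhangs keeps a short true fragment 100% identical to its
full-length parent. Database E-values are not reproducible offline (they
depend on database size), so `build_ssn()` replaces the E-value cutoff
with an alignment-score floor (default: score > 0) alongside the percent
identity threshold. `rethreshold_ssn()` re-filters a computed all-vs-all
table without re-aligning, which makes threshold sweeps (40→90%) cheap.

## Chelator-buffered binding and Hill fits

Apparent affinities in the picomolar range cannot be titrated directly;
free metal is instead buffered by a competitive chelator. For a 1:1
chelator the mass balance is a quadratic in the complex concentration,
and `free_metal()` evaluates its physical root through a
cancellation-free form (the naive quadratic formula loses all precision
when one species is in vast excess). `buffer_speciation()` returns all
three species, each from its own stable quadratic, so the mass balances
close to better than 1e-10 relative — a property the test suite checks
over random draws spanning ten orders of magnitude. Conditional
stability constants fold the chelator's protonation state into a single
pH-specific number and are user input; the defaults used by the
generator (`total_chelator = 5 mM`, `k_cond = 1e7` L/mol) are merely
illustrative of a citrate-like buffer at mildly acidic pH and are not
authoritative.

The conformational response is modelled as a Hill curve
$S(x) = S_0 + (S_1 - S_0)\,x^n/(K^n + x^n)$ in free metal $x$.
`fit_hill()` fits on a log-spaced axis (titrations span four or more
decades), initializes $K$ at the concentration nearest the signal
midpoint with $n = 1$, and bounds $n \in [0.3, 4]$ and $K$ within the
data range × [1e-2, 1e2]; a fit ending on the $K$ bound is flagged
rather than reported as converged. Standard errors come from seeded
residual-resampling bootstrap (default 200 replicates). Desorption-shaped
(decreasing) data are rejected with an explicit flag — fitting a rising
model to a falling curve would otherwise "succeed" at a boundary.
Desorption curves themselves go through `fit_desorption()`, a
four-parameter logistic on log10 chelator concentration whose midpoint
is the `[chelator]_1/2` metric; because the plateau parameters carry the
curve's direction, the logistic slope is constrained positive to remove
the mirror-image degeneracy. `selectivity_ratio()` compares two metals'
midpoints.

## Monomer–dimer equilibrium and dilution ITC

For the dissociation D ⇌ 2M with $K_\mathrm{dimer} = [M]^2/[D]$ and
total protein $[P] = [M] + 2[D]$, the monomer concentration solves
$2[M]^2 + K[M] - K[P] = 0$; `monomer_concentration()` evaluates the
positive root in conjugate form (again to avoid cancellation in the
fully monomeric limit). `weight_average_mw()` converts speciation into
the mass-weighted mean molecular weight that SEC–MALS reports for a
rapidly exchanging mixture; because the on-column protein concentration
is generally unknown, apparent MW is exposed as a function of $[P]$
rather than asserted against any particular trace.

Dilution ITC titrates a concentrated, partly dimeric stock into buffer
and watches the dimer dissociate. The perfusion cell is modelled with
the instantaneous-mixing-with-overflow convention,
$P_i = P_{i-1}(1 - v_i/V_0) + P_\mathrm{syr}\, v_i/V_0$ — instruments
handle the displaced volume internally and do not document the exact
convention, so this standard choice is stated explicitly and the test
suite verifies its mole ledger independently. The heat of injection $i$
is $\Delta H_\mathrm{diss}$ (per mole of dimer — the per-monomer
alternative differs by a factor of two and is a frequent source of
confusion) times the moles of dimer dissociating on re-equilibration,
relative to the no-reaction mixture of cell carryover plus injected
material. Defaults mirror a low-volume instrument: 185 µl cell, 300 µM
syringe, a 0.2 µl pre-injection followed by 17 × 2 µl injections, 30 °C.

`fit_itc()` exploits the model's structure: $\Delta H$ (and an optional
blank) enter linearly, so the fit reduces to a one-dimensional profile
over $\log_{10} K$ (box [-9, -1]), minimized by grid search plus local
polish. This is robust to the nearly flat profiles that arise when $K$
sits far from the working concentrations — exactly the regime where a
multi-start gradient optimizer silently returns an arbitrary interior
point. The 95% profile-likelihood interval doubles as an
identifiability check: when it reaches a box bound the fit reports
`bound_only` with the supported one-sided limit (a La-like dimer too
tight to watch monomerize yields "$K <$ limit"). The first injection is
excluded from the residuals by default (pre-injections are unreliable on
real instruments) but still advances the concentration ledger. The
dilution blank is assumed measured and subtracted, as a buffer-into-
buffer control normally provides; a free blank constant is nearly
collinear with the tail of the dissociation curve and inflates the
sampling error of $K$ about threefold at 2% noise, so it is fitted only
on request (`fit_blank = TRUE`). Thermodynamics use the 1 M standard
state: $\Delta G = -RT\ln(K/1\,\mathrm{M})$,
$\Delta S = (\Delta H - \Delta G)/T$.

## Luminescence hydration numbers

Eu(III) luminescence decays faster in H2O than D2O because O–H
oscillators quench the excited state. `fit_decay()` fits a single
exponential (with an instrument-offset baseline, toggleable) to traces
on a microsecond grid and reports the lifetime in milliseconds — the
unit the hydration constants assume. `solvent_slope()` regresses
$1/\tau$ on the D2O *fraction* (percent inputs are converted), so the
slope magnitude directly equals
$\tau_{H2O}^{-1} - \tau_{D2O}^{-1}$ and the fraction-1 extrapolation
supplies $\tau_{D2O}^{-1}$ without requiring a pure-D2O measurement.
The hydration number is then

$$q = 1.11\,[\tau_{H2O}^{-1} - \tau_{D2O}^{-1} - 0.31
      + 0.45\,n_{OH} + 0.99\,n_{NH} + 0.075\,n_{O\text{–}CNH}]$$

with the exchangeable-oscillator counts supplied by the user (for a
lanmodulin site with coordinated Asn amides, $n_{O-CNH} = 1$ and the
expression simplifies to $q = 1.11\,[-m - 0.235]$). The counts are never
inferred from data: they come from structural knowledge of the site. A
slightly negative $q$ near zero is reported as-is rather than clamped —
it is informative about measurement noise.

## Separation metrics

Batch distribution ratios use the carryover-corrected sorbent
concentration $[M]_\mathrm{LanM} = (V_{de}[M]_{de} - V_{bead}[M]_{ad})/V_{de}$
with defaults $V_{de} = 4$ ml and $V_{bead} = 1$ ml, so the familiar
$(4[M]_{de} - [M]_{ad})/4$ correction is the default behaviour;
negative corrected values (noise near zero) clamp to zero with a
warning. $D = [M]_\mathrm{LanM}/[M]_\mathrm{ad}$, the separation factor
is $\mathrm{SF} = D_1/D_2$, and `separation_factors()` returns the full
reciprocal-consistent matrix. `purity_yield()` pools fractions over
explicit bed-volume windows (purity $= C_1/\sum C$; yield = recovered
over loaded moles); pooling is always explicit user input because
reported column results depend on which inter-peak fractions are
included. Fraction volumes default to the bed-volume increment times a
0.7 ml bed. `breakthrough_point()` interpolates the first crossing of a
threshold fraction of feed (default 10%), reporting the fraction's own
bed volume when there is no prior signal to interpolate from.

## Structure sites

`load_structure()` parses PDB/mmCIF through bio3d and resolves alternate
locations by highest occupancy (ties to altloc A). Metal sites are
heteroatoms of the requested elements at occupancy ≥ 0.5.
`coordination_shell()` counts O/N donors within 3.0 Å — lanthanide–O
bonds run 2.3–2.7 Å and no universal cutoff exists, so the cutoff is a
parameter and donor lists are distance-sorted to make sensitivity
auditable. Backbone carbonyl oxygens count as donors; hydrogens are
ignored and hydrogen bonds are assessed as heavy-atom distances.
Waters are included in the coordination number but tagged, so a
solvent-excluded site (q ≈ 0) and a two-water site can be compared
explicitly. Carboxylate denticity groups Asp OD1/OD2 and Glu OE1/OE2 by
residue: bidentate when both oxygens are within the cutoff, monodentate
when exactly one; near-misses within a 1 Å slack remain listed so a
carboxylate shift never silently disappears from a report.
`site_comparison()` pairs sites across two models and flags any
denticity change as a carboxylate shift.

Buried interface area uses an in-package Shrake–Rupley implementation:
deterministic golden-spiral sphere sampling (960 points/atom by
default; the test suite checks <1% change at 4000), probe 1.4 Å, and
standard van der Waals radii. Buried area is reported as
$SASA_A + SASA_B - SASA_{AB}$ — the total over both chains — with the
per-side half alongside, since "buried area" is quoted in both
conventions in the literature.

## Synthetic data and what the tests show

Every generator seeds its own RNG stream from its `seed` argument and
restores the caller's stream, so adding a generator never perturbs
another's output, and identical arguments are byte-identical. Defaults
are the study conditions of the *Hans*-LanM system: La-like titrations
(K 68 pM, n 2) and Dy-like ones (2.6 nM, n 1.3) at 2% multiplicative
noise on 12 log-spaced points; the dilution-ITC schedule above with
K_dimer 117 µM (apo) or 60 µM (Dy); decay series over D2O fractions
0/0.25/0.5/0.75 with ~5,000-count peaks over a 2,500 µs window; 95:5
Nd:Dy elution loads on a 0.7 ml bed; and idealized ten-coordinate metal
sites at a 2.5 Å shell. The dissociation enthalpy used by the ITC
generator (30 kJ/mol of dimer, endothermic) is a typical magnitude for
a weak protein dimer and is a generator convention, not a measured
value. Sequence generators draw background residues from an alphabet
excluding Asp/Asn/Glu/Ser/Thr/Pro, which makes planted loops the only
possible matches — ideal for recall tests, but real proteomes contain
near-miss motifs, so scanner *precision* on real data is not addressed
by these tests. Similarly, Gaussian elution peaks ignore tailing and
column dispersion, the ITC model ignores kinetic corrections, and
multiplicative titration noise understates the absolute noise floor of
real detectors: passing tests demonstrate correctness of the estimators
under the stated models, not instrument realism.

Problem sizes in the test suite and acceptance script (12-point
titrations, 18-injection ITC runs, 50-sequence networks, 100-seed recall
sweeps, 1e4-draw root checks) were chosen as the smallest sizes at which
the statistical checks are stable; all run in about a minute on a single
CPU.

## Known limitations

Multi-site sequential binding, linked metal–dimerization equilibria,
chelator protonation beyond the conditional-constant approximation,
multi-exponential decay deconvolution, transport-level chromatography
simulation, and coordination-polyhedron shape classification are all out
of scope. Deposited crystal structures are not bundled; the
structure-benchmark test documents where to place them and runs the
full geometric analysis when they are available.
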