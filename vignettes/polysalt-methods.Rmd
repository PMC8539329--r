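---
title: "polysalt: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polysalt: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysalt)
```

## Scope and units

`polysalt` builds single-chain polymer/NaCl/water systems and computes the
five trajectory statistics used to characterise water-soluble polymers in
saline solution. It deliberately does **not** contain a molecular-dynamics
engine: force-field parameterisation (RESP charges, GAFF bonded terms) and
the thermostatted/barostatted production runs that would generate real
trajectories are out of scope. Analyses operate on any trajectory bound to
a topology; ground-truth fixtures and a coarse-grained surrogate stand in
for production data.

All lengths are nm, times ps, charges e, masses g/mol, energies kJ/mol
(the GROMACS unit system, in which 1 amu nm²/ps² = 1 kJ/mol).

## The builder

**Monomer library.** Acrylamide (AM), acrylate (AA, formal charge −1),
2-acrylamido-2-methylpropanesulfonate (AMPS, −1), ethylene oxide (EO) and
a guar trisaccharide repeat. Each template records atoms (element, mass,
raw partial charge, electronegative-atom role), the internal bond pattern,
ordered backbone atoms, hydrogen-bond donor pairs and a formal charge.
Polymers are assembled as PAM = 48×AM, PAA = 48×AA, HPAM/PAMPS = 48-mers
with every fourth monomer charged (three acrylamides, then one AA or AMPS
— the reading of "25% substitution" that yields 36 + 12), PEO = 32×EO,
GUAR = 12 trisaccharide repeats.

**Charge normalisation.** Raw per-monomer charges are shifted uniformly so
they sum exactly to the monomer's formal charge,
$q_i = q_i^0 - (\sum_j q_j^0 - Q_{tg})/N$. The operation is idempotent and
makes the chain's net charge exactly minus the number of charged monomers,
so an integer number of Na⁺ counterions restores neutrality to machine
precision. The shipped raw charges are reference values anchored to the
published electronegative-atom charges for this family (carbonyl O
−0.52 e, carboxylate O −0.80 e, sulfonate O −0.61 e); everything else is
generic, because only differences on the electronegative atoms matter to
the distance-criterion analyses and the normalisation fixes the sums.

**Mass table.** Fixed to C 12.011, H 1.008, N 14.0067, O 15.9994, S 32.06.
This table reproduces all six reference molecular weights (3413.81,
3413.53, 5035.69, 3412.69, 1427.72, 5855.16 g/mol) to ±0.1 g/mol, which is
how it was selected; no other standard table was tried afterwards.

**Geometry.** Vinyl backbones are all-trans zigzags (C–C 0.154 nm,
tetrahedral angles) with pendant groups alternating sides on consecutive
monomers (syndiotactic). The guar repeat uses idealized planar hexagon
rings (two β-1,4 mannoses, one α-1,6 galactose per repeat) translated
1.04 nm per repeat — chair conformers and glycosidic torsions are not
modelled; the unit is a mass/bond/role-correct placeholder with sane
sterics, not carbohydrate geometry. The whole chain is then scaled
uniformly so that the end-to-end length of the *reference-size* chain
(48/32/12 monomers) equals the reference extended length (11.8/11.5/12.5
nm). Computing the factor at the reference size and reusing it for any
chain length keeps short chains at sane bond lengths. `contour_length()`
is the end-to-end distance between first and last backbone atoms: the
zigzag arc length (≈ 14.6 nm for the 48-mer) is *not* what the 11.8 nm
refers to. End groups: two H for the vinyl polymers, an H/OH pair for PEO
and guar; caps join their terminal monomer's normalisation group.

**Ions.** Counterions first, then salt. The pair count is
`round(molarity × 0.6022140857 nm⁻³M⁻¹ × box³)` with half-away-from-zero
rounding — the unique convention reproducing 4/36/361 pairs at
0.006/0.06/0.6 M in the 10 nm box. Guar uses the nominal 10 nm volume for
ion counts even though its box is 12 nm, following the reference counts
(which list 361 pairs at 0.6 M for all six polymers); this is a recorded
oddity, not a physical choice. Placement is uniform in the box with
rejection of any position closer than 0.8 nm (minimum image) to a polymer
atom; no ion–ion constraint is applied. A bounded number of rejection
rounds guards against overcrowded boxes (capacity error).

**Water.** Rigid three-site SPC/E geometry (O–H 0.1 nm, H–O–H 109.47°),
random orientations, on a jittered simple-cubic lattice thinned to exactly
`round(33.4 × V)` molecules (bulk density at 300 K); waters with any atom
within 0.2 nm of a non-water atom are deleted. An empty 10 nm box yields
exactly 33,400 waters; around the solvated PAM system the count lands
within 3% of the equilibrated reference (32,408) — lattice filling cannot
do better than a few percent against a pre-equilibrated, NPT-relaxed box,
and the tests assert exactly that tolerance.

## The analyses

All pair distances use the minimum-image convention in cubic boxes.
Normalizing length *L* for the per-length densities defaults to the
builder's extended end-to-end length, not any per-frame length.

- **Radius of gyration** — mass-weighted, over the *carbon* atoms of the
  main chain (PEO's backbone oxygens are excluded by the default
  selection). In periodic boxes the molecule is made whole by walking the
  bond graph; a selected bond longer than 0.25 nm afterwards raises a
  broken-molecule error rather than returning a silently wrong value.
- **Condensation** — distinct Na⁺ strictly within 0.3 nm of any polymer
  atom, per frame, divided by *L*. The cutoff is strict: an ion at exactly
  0.30 nm does not count.
- **Manning parameter** — ξ = l_B/b with b = L/n_charges and l_B =
  0.714 nm (300 K, water); condensation predicted for ξ > 1 strictly. The
  threshold symbol in the source literature is ambiguous between ξ and the
  measured condensed fraction; both quantities are provided
  (`manning_parameter()`, `counterion_condensation()`) and never equated.
- **Water orientation** — for each water oxygen within 0.5 nm of the
  polymer, cos φ between the dipole (O toward the H–H midpoint) and the
  vector from the *nearest polymer atom* to the oxygen. The nearest-atom
  pairing is a choice (the criterion "around all polymer atoms" does not
  define one); it reproduces the landmark geometry cleanly: −1 for both
  hydrogens toward the atom, −cos 54.735° = −0.577 for one O–H in direct
  line, +1 for hydrogens pointing away. Histogram: 40 bins over [−1, 1],
  normalised to unit sum; invariant under rigid rotations.
- **MSD / diffusion** — time origins evenly spaced, capped at 20,000;
  lags log-spaced; msd(0) = 0 by definition. The Einstein fit is
  unweighted OLS with intercept on the 1–10,000 ps window; D = slope/6
  with the exact conversion 1 nm²/ps = 10⁻² cm²/s (tested against
  ballistic and exactly linear inputs).
- **Cation bridges** — a cation strictly within 0.3 nm of ≥ 2 tagged
  electronegative oxygens counts **once**, regardless of how many atoms it
  touches (per-cation convention, switchable to per-pair via
  `count = "pairs"`).
- **Hydrogen bonds** — distance-only criterion (< 0.30 nm between
  electronegative heavy atoms, one of which carries a covalent H), no
  angular term, intra-polymer only. Pairs within two covalent bonds are
  excluded; the criterion itself is silent on this, but without the
  exclusion directly bonded O–C=O geometry would be counted as bonded
  pairs, which no practitioner intends.

## The synthetic module

Fixtures encode their own answers (`ground_truth`), so every analysis is
tested as parameter recovery rather than against copied numbers:

- *Freely-jointed chains*: ⟨R_g²⟩ = n b²/6. Note the tested quantity,
  the ensemble mean of R_g, sits ≈ 4% below √(n b²/6) (Jensen's
  inequality), so the 5% recovery band is intrinsically tight — the test
  uses enough samples that sampling noise does not add materially.
- *Brownian tracers*: steps with variance 2 D dt per axis. A single
  tracer's time-averaged MSD at lag τ has a relative standard deviation
  of roughly √(4τ/3T) — about 35% at the 1:10 lag-to-length ratio of the
  prescribed fit window — so *no* single-trajectory estimator can meet a
  10% recovery target. The acceptance tests therefore average 64
  independent tracers over 10⁵ ps (expected slope error ≈ 4–5%), a choice
  made from this error budget *a priori*, mirroring how production
  analyses average restarts and replicas.
- *Condensation fixtures*: planted inside (< 0.29 nm) and outside
  (> 0.4 nm) cations around a straight chain; Γ = n_inside/L exactly.
- *Water shells*: rigid waters with exactly prescribed dipole cosines;
  `rigid_water()` builds the geometry from an O–H direction instead, for
  landmark constructions that do not presuppose the answer.

**Coarse-grained surrogate.** An overdamped Langevin (Brownian dynamics)
bead-spring chain: harmonic bonds (k = 1000 kJ/mol/nm², r₀ = 0.25 nm),
WCA excluded volume (σ = 0.25 nm, ε = 2.5 kJ/mol), Debye–Hückel
electrostatics U = k_BT·l_B·q_iq_j·e^(−r/λ_D)/r between charged beads,
1–2 pairs excluded from non-bonded terms; λ_D = (8π l_B N_A c)^(−1/2)
(3.93 nm at 0.006 M, 0.39 nm at 0.6 M). Integration: Δr = FΔt/γ +
√(2k_BTΔt/γ)ξ with γ = 50/ps per unit mass and Δt = 0.01 ps.
A per-step displacement clamp of 0.2 nm (≈ 4× the thermal step) tames the
stiff WCA core during transient overlaps; it engages only where the
Boltzmann weight is negligible, so equilibrium averages are unaffected,
and it is disabled (set to `Inf`) when testing the blow-up error path.
The surrogate is used **only** for trend-level statements — the fully
charged chain's mean R_g decreases from 0.006 M to 0.6 M while a neutral
chain's is salt-insensitive — never for quantitative comparison with
atomistic results.

## What a green test does and does not establish

The fixtures emulate ideal statistics (ideal chains, exact Brownian steps,
rigidly placed waters, planted contacts). They validate the *estimators*
— selection logic, minimum-image handling, cutoff strictness, origin
averaging, unit conversions — not the physics of any real polymer.
Fig.-level quantities from long atomistic runs (R_g curves, condensation
magnitudes like tens of ions per nm at 0.6 M, diffusion orderings across
polymers, bridge densities) require hundreds of ns of explicit-solvent MD
and are deliberately not reproduced; the acceptance suite substitutes
brute-force oracle equivalence on small systems, closed-form recovery,
histogram invariances and the CG trend.

## Numerical choices and degenerate inputs

- Strict inequalities at every cutoff (0.3, 0.30, 0.5 nm) and at the
  Manning threshold ξ > 1.
- Block averaging with 5 blocks for standard errors (NA for very short
  series rather than a misleading number).
- `manning_parameter()` with zero charges returns ξ = 0, flag FALSE.
- `salt_ion_count()` uses half-away-from-zero rounding (R's `round()`
  half-to-even would give the same values for the reference cases, but
  the convention is pinned to be explicit).
- Zero-temperature, zero-charge CG chains started at the bond minimum are
  exactly static — the integrator adds no spurious drift.
- Orientation samples at exactly ±1 are clamped into the outermost bins.

## Known limitations

- Guar geometry is schematic (planar rings); only masses, bonds, roles
  and approximate sterics are faithful.
- Water insertion approximates an equilibrated solvent box to a few
  percent; it is a starting configuration, not an equilibrium ensemble.
- The CG surrogate has no explicit solvent and its ion beads (optional)
  are not used in the shipped trend checks; Debye screening carries the
  entire salt dependence.
- Hydrogen-bond detection is distance-only by design; angular criteria
  would change absolute counts.
- The XYZ/GRO/JSON readers target files written by this package and
  well-formed files of the same dialect; they are not general-purpose
  format sniffers.
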