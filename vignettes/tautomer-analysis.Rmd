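---
title: "Methods: tautomer enumeration and redox analysis of the DHI cyclotetramer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tautomer enumeration and redox analysis of the DHI cyclotetramer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kporphyrin)
```

## The system and its state space

The molecule is the porphyrin-like cyclotetramer of 5,6-dihydroxyindole
(DHI): four indole-5,6-diol units joined head-to-tail by single 2,7′ bonds
and closed into a macrocycle. Its heavy-atom graph has 44 atoms and 52
bonds (12 per unit plus the four inter-ring bonds), built once by
`build_skeleton()` with a fixed deterministic ordering.

Oxidation proceeds by loss of electron/proton pairs from the twelve
mobile-hydrogen sites — N1, O5 and O6 on each unit. A tautomer is a choice
of removed hydrogens, named `a16_b6_c16_d6`-style; its oxidation level is
the number removed. Because the 2,7′ connectivity is directional (each
unit's C2 bonds to the *next* unit's C7), the symmetry group of the
labelling is the cyclic group of order 4, not a dihedral group: reversing
the ring is not a graph automorphism. Deduplication therefore quotients by
the four rotations only, and `canonical_form()` picks the
lexicographically smallest rotation of the per-unit bitmask tuple
(N1 = 1, O5 = 2, O6 = 4). Any other representative convention would be
equally valid; published representative strings need not coincide with
ours, so equality of species is always tested by orbit
(`same_orbit()`), never by string comparison. Burnside's lemma fixes the
total orbit count at (8⁴ + 8 + 8² + 8)/4 = 1044, which the test suite
asserts by direct enumeration.

## Closed-shell feasibility as perfect matching

Each atom demands `valence − σ-degree − attached hydrogens` double bonds:
every carbon demands exactly one, while N1 and the oxygens demand one
precisely when deprotonated. This single rule covers catechol, *o*-quinone,
quinone-methide and quinone-imine rings with no per-ring special cases. A
Kekulé structure is a perfect matching on the demand-1 atoms over the graph
bonds, and a tautomer is closed-shell iff one exists; an odd removal count
fails by parity (radicals).

`kekule_structures()` enumerates *all* matchings by backtracking with a
fewest-alive-neighbours pivot. Exhaustive enumeration (rather than a
maximum-matching shortcut) is deliberate: the circuit search below needs
the complete set, and the counts are tiny (16 structures for the fully
reduced form, often just one for highly oxidized species). Enumeration of
tautomers at a level iterates over per-unit state assignments (8 states per
unit, 4096 total) rather than the 2¹² hydrogen placements, filters by
level, per-unit cap and matching feasibility, and canonicalizes; brute
force at this size is fast (well under a second per level) and fully
auditable.

Two design parameters govern `enumerate_closed_shell()`:

* `max_unit_oxidation = 2` — the generation procedure for the published
  censuses combines units of at most two-electron oxidation; the
  three-electron unit state {N1,O5,O6} is a high-energy site excluded from
  low-level generation. Raising the cap at level 6 would admit additional
  tautomers containing a three-electron unit, which is why the cap is a
  default and not hard-wired.
* `include_three_electron_blocks` — admits that state, which is how the
  impossibility of closed-shell KP-10e and KP-12e is demonstrated (both
  censuses are empty even with it).

The building-block formulation is retained as an independent route:
`derive_block_library()` derives admissible (state, dangling-2, dangling-7)
triples from single-unit matching feasibility, and
`composable_from_blocks()` composes them around the directed 4-cycle. The
suite verifies block composition ≡ whole-graph matching on all 4096 state
assignments, and Burnside counts over labelled valid configurations against
the deduplicated census at every even level.

## Macrocyclic conjugation and the Hückel rule

A macrocyclic conjugation circuit is a cycle through all four inter-ring
bonds whose edges alternate strictly double/single with respect to some
Kekulé structure. Within a unit the circuit follows a simple C7→C2 path; a
DFS on the unit graph shows there are exactly four such paths (4, 5, 7 and
8 atoms), so the search space is the 4⁴ path combinations × Kekulé
structures, exhaustive by construction. Each on-circuit atom contributes
one π electron, so the π count equals the circuit's atom count and twice
its double-bond count — the suite asserts all three agree.

Two emergent regularities are verified exhaustively rather than assumed: a
macrocyclic circuit exists iff every unit is in state {N1}, {O6} or
{N1,O6}, and the π count is then the sum of per-unit contributions
7/5/4 respectively. The contract of `macrocyclic_pi_counts()` is
nonetheless set-valued: the engine does not *assume* a unique count per
tautomer, it merely finds uniqueness empirically for every enumerated
species. `huckel_class()` applies 4n+2: counts ≡ 2 (mod 4) aromatic,
≡ 0 antiaromatic.

Motif classification (`classify_motifs()`) reads the inter-ring double-bond
patterns across Kekulé structures: none anywhere → localized (or, when two
distinct localized states alternate x,y,x,y, the alternating-quinonoid
motif); a single inter-ring double → a two-unit extended system; two
adjacent → a three-unit chain; an alternating circuit → macrocyclic. These
tags are descriptive conveniences layered on the same matching machinery.

## Thermochemistry

Energies enter as composite free energies in hartree under three schemes:
`vacuum` (in-vacuo electronic energy), `vacuum_rrho` (+ rigid-rotor /
harmonic-oscillator thermal correction) and `smd_rrho` (solution-phase
electronic + nonelectrostatic solvation + thermal). Conversions live in one
constants table (`kp_constants()`): 627.5095 kcal/mol and 27.2114 eV per
hartree; at the default 298.15 K, RT ln 10 = 1.364 kcal/mol per pKa unit.

* **Populations.** `relative_energies_and_weights()` reports energies above
  the level minimum and Boltzmann weights ∝ exp(−ΔG/RT), normalized to 1;
  ties are broken by name order for determinism.
* **pKa.** `estimate_pka()` uses the linear free-energy comparison against
  user-supplied reference AH/A⁻ pairs, averaging the per-reference
  estimates and reporting the min–max spread. The arithmetic mean is the
  natural choice when nothing distinguishes the references; the proton's
  solvation free energy cancels in the comparison and is never taken from
  an absolute value.
* **Disproportionation.** `balance_disproportionation(n, p, q)` returns the
  smallest coprime coefficients of m KP-n → x KP-p + y KP-q (m = x + y,
  mn = xp + yq); `disproportionation_dG()` evaluates ΔG and the per-mole
  normalization ΔG/m, whose sign is scheme-dependent but whose
  comproportionation counterpart is the exact negative. The representative
  record per level is the caller's choice; the natural one is the
  Boltzmann minimum under the selected scheme, and because a balanced
  reaction conserves both units and removed hydrogens, any per-species
  constant (such as a uniform thermal correction) cancels identically.
* **Gaps.** `homo_lumo_gap()` is simply lowest-virtual minus
  highest-occupied, converted to eV.

## Spectra

`uv_spectrum()` drops transitions at or above the 5.6 eV cutoff, gives each
survivor a Gaussian in the *energy* domain with amplitude ∝ oscillator
strength, and evaluates the sum on a wavelength grid through
E(λ) = 1239.842/λ. "Line width" is interpreted as the full width at half
maximum (0.25 eV default) — the looser of the two common conventions — and
is exposed as a parameter precisely because conventions differ. The
energy-to-wavelength Jacobian is omitted by default, matching common
quantum-chemistry visualization practice, and can be switched on
(`jacobian = TRUE`). `ir_spectrum()` scales harmonic frequencies by 0.9547
before broadening with a 20 cm⁻¹ FWHM. Default grids are 200–1400 nm and
400–2000 cm⁻¹ at unit step; amplitudes are arbitrary units throughout — no
molar-absorptivity normalization is attempted. Linearity in the line list,
peak location and energy-integrated area ∝ Σf are asserted in the suite.

## The synthetic-data generator

`make_scenario("paper_like")` produces species records with the
*qualitative* structure of quantum-chemistry summaries: per-level minimum
tautomers for KP-Red, KP-1e, KP-2e, KP-4e, KP-6e, KP-8e plus a few
higher-lying tautomers per level, each with energy components, orbital
energies, transitions and modes. Records are marked
`provenance = "synthetic"`; they are honest fakes, not DFT values.

The minima carry exact free-energy offsets (kcal/mol above KP-Red) chosen
once to encode the redox landscape the analysis stages must handle: in
vacuo (0, 2, 3, 5, 6, 60 for levels 0, 1, 2, 4, 6, 8) every intermediate
level disproportionates spontaneously toward KP-Red + KP-6e and
KP-6e → KP-Red + KP-8e is strongly uphill (+39 kcal/mol per mole); in
water (0, 2, 4.5, 10, 12.6, 66) the KP-1e disproportionations become
slightly endoergonic (+0.25 and +0.1 per mole), KP-2e → KP-Red + KP-4e
turns unfavorable, and KP-2e → KP-Red + KP-6e stays spontaneous (−0.3).
One record set serves both media: the vacuum fields carry the in-vacuo
offsets and the solution-phase fields the aqueous ones, so the scheme
selector switches the medium. The thermal correction is constant across
species, which makes balanced-reaction ΔG identical under `vacuum` and
`vacuum_rrho` — a deliberate property used to test that cancellation.

Gaussian energy noise (sd 0.25 kcal/mol, truncated at ±0.45) is applied
only to the non-minimum records: the smallest engineered margin
(KP-1e in water, 0.1 kcal/mol per mole) could not survive noise on the
minima, and the truncation bound keeps every non-minimum record strictly
above its level minimum. A generation-time guard re-evaluates the full
sign structure and the within-level ordering and stops on any violation.
HOMO–LUMO gap targets (3.6, 3.0, 1.7, 1.4, 1.6, 1.7 eV along the series)
follow the qualitative trend of a gap minimum near the four-electron level;
the orbital block is built so the gap is exact, and the lowest transition
is pinned at the gap (the absorption onset in a one-particle picture).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: absolute electronic energies, conformer multiplicity
within a tautomer, realistic oscillator-strength or mode-intensity
patterns, solvent shifts beyond the engineered offsets, open-shell
character of odd levels, and vibronic structure. Conclusions about real
spectra or energetics require real electronic-structure records, which the
same JSON format accepts.

## Numerical and I/O choices

Record files are versioned JSON with fixed units (hartree, eV, cm⁻¹);
writing is normalized so write–read–write round-trips are byte-identical,
and unknown fields pass through untouched. SDF export writes a V2000
connection table with bond orders from the lexicographically first Kekulé
structure (a deterministic tie-break among equivalent resonance forms) and
a schematic radial 2D layout — units on a circle — flagged as schematic in
the comment line, since molecular geometry is outside the package's scope.

Problem sizes are small by design: 4096 state assignments per enumeration
pass, ≤ 4⁴ circuit candidates × a handful of Kekulé structures per
tautomer, and the full test suite (including both 4096-point
route-equivalence sweeps and per-level Burnside recounts) completes in
about a minute and a half on one core.

## Known limitations

* Open-shell (odd-level) species are enumerated as hydrogen-placement
  orbits only; no radical valence model is attempted.
* Aromaticity is classified purely by the Hückel count on the macrocyclic
  circuit; no quantitative indices (NICS, HOMA) or resonance energies.
* The pKa estimator is only as good as the supplied reference set; none is
  bundled.
* Whether some un-enumerated species could support alternating circuits of
  two different sizes is left open by the set-valued contract; for every
  species the enumerator produces, the count is unique.
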