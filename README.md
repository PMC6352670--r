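# kporphyrin

Combinatorial and thermodynamic analysis of the porphyrin-type cyclotetramer
of 5,6-dihydroxyindole (DHI) — a theoretical structural model for eumelanin
pigments, built from four indole-5,6-diol units joined head-to-tail by 2,7′
bonds. The package is aimed at computational chemists studying the redox
chemistry of this tetracatechol macrocycle: it answers, exactly and by
construction, which tautomers exist at each oxidation level, which of them
are aromatic, and how stabilities, pKa values, disproportionation equilibria
and spectra follow from quantum-chemistry summary data.

## The model

Oxidation of the tetramer removes electron/proton pairs from the twelve
mobile-hydrogen sites (N1, O5, O6 on each of the four units); a species that
has lost *n* hydrogens is the *n*-electron oxidized form KP-*n*e, and a
*tautomer* is one particular choice of which hydrogens are gone, written
`a56_b16_c0_d0`-style (digits = removed sites per unit).

Three combinatorial ideas drive the package:

1. **Closed-shell = perfect matching.** Assign every atom a double-bond
   demand of `valence − σ-degree − attached H` (all carbons demand 1; N1 and
   the oxygens demand 1 exactly when deprotonated). A tautomer is
   closed-shell iff the demand-1 atoms admit a perfect matching using the
   molecular-graph bonds — a Kekulé structure. Enumeration over the 8⁴ =
   4096 per-unit states, filtered by this criterion and deduplicated under
   the cyclic rotation a→b→c→d→a (the 2,7′ link is directional, so there are
   no reflections), yields the censuses 1, 7, 49, 74, 24 at levels
   0, 2, 4, 6, 8 and proves no closed-shell KP-10e/KP-12e exists.
2. **Building blocks.** The same feasibility, restricted to a single unit
   with prescribed dangling-bond orders at its 2- and 7-positions, *derives*
   the classical building-block library (1 reduced, 4 one-electron, 3 + 1
   two-electron, and exactly one three-electron block); composing blocks
   around the ring is an independent route that agrees with whole-graph
   matching on all 4096 states.
3. **Macrocyclic aromaticity.** A conjugation circuit through all four
   inter-ring bonds, with strict double/single alternation in some Kekulé
   structure, carries one π electron per atom; the Hückel rule (4n+2
   aromatic, 4n antiaromatic) then classifies each tautomer. Per unit the
   circuit contributes 7, 5 or 4 atoms for the states {N1}, {O6}, {N1,O6},
   giving e.g. 18 π electrons for `a16_b6_c16_d6` — a porphyrin-like
   aromatic system.

Downstream, the thermo module turns composite free energies
(ΔG_SMD,RRHO-style: solution electronic energy + nonelectrostatic solvation
+ RRHO thermal correction) into Boltzmann populations, reference-pair pKa
estimates (pKaᵢ = pKa_ref,ᵢ + ΔΔG/(RT ln 10)), balanced disproportionation
free energies (m KP-n → x KP-p + y KP-q with m = x+y, mn = xp+yq) and
HOMO–LUMO gaps; the spectra module convolutes electronic transitions
(Gaussian FWHM 0.25 eV, cutoff 5.6 eV, wavelength axis via
E = 1239.842/λ) and scaled harmonic modes (factor 0.9547, FWHM 20 cm⁻¹)
into UV–Vis and IR curves. A synthetic-record generator
(`make_scenario("paper_like")`) emulates the qualitative redox landscape so
every stage runs without electronic-structure software.

## Worked example

```r
library(kporphyrin)

c6 <- enumerate_closed_shell(6)
c6
#> <kp_census> level 6: 74 closed-shell tautomer(s)
#> motifs:
#>         interring-pair macrocyclic-conjugated  single-ring-localized
#>                     36                      7                     27
#>       three-ring-chain
#>                      8

macro <- Filter(function(nm) length(macrocyclic_pi_counts(nm)) > 0, c6$names)
for (nm in macro)
  cat(nm, ":", macrocyclic_pi_counts(nm), huckel_class(macrocyclic_pi_counts(nm)), "\n")
#> a1_b1_c16_d16 : 22 aromatic
#> a1_b16_c1_d16 : 22 aromatic
#> a1_b16_c16_d6 : 20 antiaromatic
#> a1_b16_c6_d16 : 20 antiaromatic
#> a1_b6_c16_d16 : 20 antiaromatic
#> a6_b16_c6_d16 : 18 aromatic
#> a6_b6_c16_d16 : 18 aromatic
```

Of the 74 six-electron tautomers, seven support a macrocyclic conjugation
circuit and two reach the porphyrin-like 18 π-electron aromatic count
(`a6_b16_c6_d16` is the rotation orbit of `a16_b6_c16_d6`; names are orbit
representatives).

```r
sc   <- make_scenario("paper_like", seed = 1)
mins <- scenario_records(sc, minima_only = TRUE)
rx   <- balance_disproportionation(2, 0, 6)
rx
#> <kp_reaction> 3 KP-2e -> 2 KP-0e + 1 KP-6e
round(disproportionation_dG(mins, rx, "vacuum"), 3)
#>    total per_mole
#>       -3       -1
round(disproportionation_dG(mins, rx, "smd_rrho"), 3)
#>    total per_mole
#>     -0.9     -0.3
```

Disproportionation of the two-electron form to KP-Red + KP-6e is spontaneous
in both media for this scenario (−1 kcal/mol per mole of reactant in vacuo,
−0.3 in water), reflecting the special stability of the six-electron,
18 π-electron aromatic state.

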