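# chemion

Minimal-basis vertex-orbital quantum chemistry for torsion scans of chain
molecules.

`chemion` is aimed at molecular modellers who want to see which torsional
features of flexible chains (alkanes, alcohols, amines, alkyl halides, and
by extension biopolymer backbones) follow from *topology alone*. A molecule
is a tree of **vertices** — central atoms, hydrogen ligands, and lone-pair
positions — each carrying exactly one spherical Slater orbital; a tree
always satisfies the Euler rule

```
#vtx = #chp + 1
```

with `#chp` the number of shared electron pairs ("chemion pairs"). A subset
of pairs forms a **chemion ensemble** ε that is solved as its own
closed-shell problem with *proportional nuclear charges*

```
Z_prop(C) = Z_val(C) · 2·#chp(ε) / Σ_D Z_val(D),
```

restricted Hartree–Fock (Roothaan, density convergence
σ = rms(ΔD) < 1e-4, tightened to 1e-8 before CI) and full configuration
interaction in the vertex basis. Because `#vtx = #chp + 1` there is exactly
one virtual orbital, so the complete singlet and triplet CI blocks have
only `(#chp+1)(#chp+2)/2` and `(#chp+1)#chp/2` rows. The ensemble energy is

```
E_0 = E_nucl(ε) + min(¹E₁, ³E₁).
```

For a chain `H–(CH₂)n–X` the n-dimensional torsion space is replaced by n
one-dimensional potential curves: each backbone bond's pair (an ensemble
with `#chp = 1`, basis condensed to the two fragments it joins) is scanned
over `[0, 2π)` while all other torsions stay frozen. **Vertex
condensation** makes this cheap: a fragment's orbitals collapse into one
normalized "recursion orbital", every condensed integral is a normalized
block sum of precursor values, and a **fragment bank** reuses precursor
blocks so that each chain-growth step only evaluates the `a^k − b^k` new
integral entries (`a = 3n+8`, `b = 3n+4`, `a − b = 4` at every step).

## Worked example

Methane as the anchor unit, then the ethane torsion curve:

```r
library(chemion)

mol  <- build_monofocal("C")
euler_counts(mol)
#> vtx chp nuc
#>   5   4   5

ints <- build_anchor_integrals(mol)            # S, K, U, R over 5 vertices
fit  <- scf(ints, full_molecule_ensemble(mol), tol = 1e-8)
ci   <- run_fci(fit)
glance(ci)
#> # A tibble: 1 × 7
#>   n_singlet n_triplet e_singlet e_triplet e_rhf e_chem multiplicity
#> 1        15        10     -18.0     -17.9 -17.9  -18.0 singlet
```

The 15×15 singlet and 10×10 triplet blocks are the complete CI spaces for
`#chp = 4`; the correlated singlet lies below the RHF energy, as the
variational bound requires. The chain-bond scan:

```r
curve <- scan_torsion(build_chain(1, "CH3"), grid_size = 12)
attr(curve, "argmin") * 180 / pi
#> [1] 60
range(curve$e_total)
#> [1] -0.2934025 -0.2931930
autoplot(curve)
```

The ethane curve is three-fold periodic with a ~0.2 mhartree barrier and a
staggered minimum; `e_total = e_nucl + e_chem` holds at every grid point.
`aufbau_polymerize("CH3", max_n = 2)` grows the chain step by step, freezing
each optimized torsion, and reports per-step curves plus the final geometry
(`write_xyz()`).

A thin command-line wrapper is installed as `exec/chemion`
(`chemion anchor C`, `chemion scan --terminal CH3 --n 1 --grid 12`,
`chemion polymerize --terminal OH --max-n 2`, `chemion validate`).

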