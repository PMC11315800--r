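---
title: "The vertex-orbital model behind chemion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vertex-orbital model behind chemion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemion)
```

## The model in one paragraph

`chemion` implements a deliberately minimal quantum-chemical picture of
singly bound molecules. A molecule is a tree of *vertices* -- bonding sites:
central atoms, hydrogen ligands, and lone-pair positions -- and every vertex
carries exactly one spherical Slater orbital. Because the graph is a tree,
the number of vertices always exceeds the number of shared electron pairs
("chemion pairs") by one: `#vtx = #chp + 1`. Subsets of pairs form *chemion
ensembles* that are solved as independent closed-shell problems with
rescaled ("proportional") nuclear charges; restricted Hartree-Fock followed
by full configuration interaction in the tiny vertex basis gives each
ensemble's ground energy. The main use is conformational: the
n-dimensional torsion space of a flexible chain is replaced by n
one-dimensional potential curves, each obtained by scanning a single bond's
ensemble energy while all other torsions stay frozen.

This is a topological sketch, not a quantitative method: it aims to expose
which torsional features follow from connectivity and electron-pair
bookkeeping alone.

## Geometry

All centres are ideal tetrahedra: bond angle `acos(-1/3)` (109.471 deg),
dihedral spacing `2*pi/3` (120 deg). Internally everything is in atomic
units (bohr, hartree); file I/O uses angstrom with
1 bohr = 0.529177249 angstrom.

* **Bond lengths.** Standard single-bond covalent lengths (C-C 1.54 A,
  C-H 1.09 A, O-H 0.96 A, ...; see `default_bond_lengths()`), all
  overridable per call or in a molecule spec. These are deliberately
  idealized; no empirical refinement is attempted.
* **Lone pairs** occupy a peripheral tetrahedron direction at exactly one
  Bohr radius from the parent atom, carry the parent's valence-shell
  orbital, and carry no nuclear charge. One known artifact follows: bonds
  that are physically free rotors (e.g. a methyl against a halogen's lone
  pairs) acquire a small three-fold barrier, because the lone-pair vertices
  break axial symmetry. The test suite pins this behaviour down rather than
  hiding it.
* **Torsions.** A torsion is defined per backbone bond, measured between
  the first-listed ligand on each side of the bond with the right-hand rule
  looking from the terminal-group side; the full range `[0, 2*pi)` is used.
  `set_torsion()` rigidly rotates the leading-hydrogen side, so the
  terminal-side fragment's coordinates never move -- chains are built
  anchored at the terminal group, which keeps a growing chain's shared
  fragment bit-identical across growth steps and makes banked integral
  blocks exactly reusable.

## Basis set and integrals

Each vertex carries one node-less Slater function `r^(n-1) exp(-zeta r)`
with `n` = 1 (H), 2 (C, N, O, F and their lone pairs) or 3 (Si, P, S, Cl
and theirs), and exponent `zeta = z_val / n_val` by default (`z_val` the
main-group valence charge). Both choices are overridable.

Integrals are evaluated by expanding each Slater orbital in spherical
Gaussian primitives (maximum-overlap least-squares fit, default order 6).
The fit is done once per shell at `zeta = 1` and transferred exactly by the
`alpha -> alpha * zeta^2` scaling; the expansion is re-normalized so
self-overlaps are 1 to machine precision. With order 6 the two-centre 1s-1s
overlap at 1.4 bohr is reproduced to about 3e-7 of the closed form
`exp(-R)(1 + R + R^2/3)`; one-centre kinetic, attraction and repulsion
values are accurate to roughly 2e-3 relative, which is far below the
model's own idealization error. All three- and four-centre integrals are
analytic over the primitives, so no external integral code is needed.

An optional `two-center` mode zeroes repulsion entries spanning more than
two distinct centres and attraction entries whose nucleus sits on neither
orbital's centre. That rule is one concrete reading of a two-centre-only
evaluation scheme; it is off by default and clearly flagged, because the
restriction is an interpretation rather than a derived result.

## Vertex condensation and the fragment bank

A fragment's orbitals can be *condensed* into a single normalized
"recursion orbital": the sum of the members scaled by
`N = (sum of the members' overlap block)^(-1/2)`. Linearity of integration
turns every condensed integral into a normalized block sum of precursor
values, so condensation costs no quadrature.

One design choice deserves a note. Taken literally, summing *condensed*
values again at the next level weights each member by its group norm, which
makes two-step condensation differ from condensing all anchors in one shot.
`condense_integrals()` therefore divides out the previous level's norms
before summing and applies a fresh normalization afterwards: a recursion
orbital of recursion orbitals is then literally the same function as the
one-shot normalized sum of its anchors. This keeps condensation associative
(checked to 1e-10 in the tests) and, more importantly, makes banked
fragment blocks exactly reusable inside larger fragments. For anchor-level
input the two formulations coincide.

The `fragment_bank()` stores anchor sub-blocks, condensed blocks and Fock
blocks under keys that hash everything able to change an integral: element
sequence, orbital exponents, bond-length table, torsion values rounded to
1e-9 rad, evaluation mode and expansion order. Reuse happens only under an
identical key; any mismatch is a miss and triggers a fresh computation,
never a silent approximation. Fock blocks are additionally keyed by the
ensemble they were built for, and stored blocks for different ensembles are
never mixed. Within a scan, condensed blocks are stored per torsion-grid
point (default 24 points, 15 deg spacing).

## Restricted Hartree-Fock

The Roothaan equations are solved per ensemble by symmetric (Loewdin)
orthogonalization, from a core-Hamiltonian start (`D = 0`), with optional
density damping (0.3 is a sensible value for oscillatory cases; plain
iteration is the default and suffices for every molecule in the test set).
Convergence is the root-mean-square density change
`sigma(i) = sqrt(mean((D_i - D_{i-1})^2))`. The documented standalone
threshold is 1e-4; whenever the result feeds configuration interaction the
drivers tighten it to 1e-8, because the CI coupling between the reference
and single excitations is proportional to the residual Fock off-diagonals
and 1e-4 would leave visible Brillouin violations. The iteration cap is
200; a non-convergent solve returns a flagged state instead of raising.
Orbital phases are fixed (largest coefficient positive), occupied orbitals
are filled aufbau, and degenerate frontier ties resolve by index order, so
repeated runs are bit-identical.

## Full configuration interaction

Since `#vtx = #chp + 1`, every ensemble has exactly one virtual orbital
`r`. The complete singlet space over configuration state functions is
`[reference, singles a->r, pair doubles aa->rr, open-shell doubles ab->rr
(a<b)]` with dimension `(#chp+1)(#chp+2)/2`; the M_S = 0 triplet space is
`[singles, open-shell doubles]` with dimension `(#chp+1)#chp/2` (the three
M_S blocks are degenerate, so only one is built). The chemionic energy is
the lower of the two lowest eigenvalues, singlets winning ties; a
singlet-triplet gap below 1e-9 is reported as `"degenerate"` rather than
silently resolved.

The matrix elements are closed forms over the MO-transformed integrals.
Every element class was validated -- and where necessary derived -- against
an independent determinant-space Slater-Condon evaluation with S^2
projection (`tests/testthat/helper-detci.R`), to machine precision over
random symmetric integral draws at `#chp` up to 4. Three points are worth
recording because plausible-looking alternatives fail that arbitration:

* the two pair-double states `aa->rr` and `bb->rr` couple through the
  exchange integral `K_ab`; omitting that element breaks the agreement with
  determinant CI for `#chp >= 2`;
* the triplet diagonal corrections are `-2K_ar` (singles) and `-2K_ab`
  (open doubles), and the off-diagonal single-single correction is
  `-2(ar|rb)` -- i.e. exactly the exchange swap demanded by spin algebra,
  not twice it;
* the open-shell triplet CSF is antisymmetric under exchange of its two
  members (`T_ba = -T_ab`), so mixed elements carry role-dependent signs
  that any fixed `a < b` storage order must apply explicitly.

In all sums of the closed forms, an exclusion like "n != a" runs over the
full orbital set (occupied plus the virtual) minus the named index;
restricting such sums to occupied orbitals only also fails the determinant
arbitration.

The variational chain (lowest singlet <= RHF energy, interlacing of nested
CSF blocks) is asserted in the tests for every molecule exercised.

## Torsion scans and recursive growth

The potential assigned to a backbone bond is the total energy of that
bond's chain-bond ensemble: one chemion pair, basis condensed to the two
fragments the bond joins, proportional charges spread over all nuclei, plus
the nuclear repulsion of those charges. Energies of different bond
ensembles are deliberately *not* recombined into one molecular total: the
picture defines per-ensemble Hamiltonians, and no well-defined mixing rule
exists for adding them; the per-bond curves themselves are the product.

`scan_torsion()` uses a uniform half-open grid (default 24 points); the
reported optimum is the grid argmin (smallest angle on ties), with a
three-point parabolic refinement reported separately so that the raw grid
result stays exactly reproducible. `aufbau_polymerize()` grows
`H3C-(CH2)n-X` one unit at a time: previously optimized torsions are
frozen, only the newly created bond is scanned, and the precursor's anchor
block (the molecule minus its leading hydrogen) is banked so the next step
only evaluates integral entries that touch the new methyl unit -- with
`a = 3n + 8` total and `b = 3n + 4` reused vertices, that is `a^2 - b^2`
overlap/kinetic entries, at most `a^3 - b^3` attraction entries and
`a^4 - b^4` repulsion entries per grid point, with `a - b = 4` at every
step. The scanner's bank-miss accounting reproduces these counts exactly
and the tests assert it.

## Problem sizes and what the tests show

The test suite and the examples run monofocal hydrides (5 vertices), ethane
(8) and propane-like chains (11), with expansion order 3 and grids of 3-6
points where only structural properties (periodicity, decomposition, reuse
accounting) are at stake, and order 6 where integral accuracy itself is
asserted. These sizes exercise every code path -- all matrix-element
classes appear from `#chp = 3` on, and chain growth from step 1 on -- so
larger chains add cost, not coverage. Passing tests demonstrate internal
consistency of the model (oracle equivalences, variational bounds,
symmetry), not agreement with experimental conformational energetics; the
model's idealized geometries and one-orbital basis are far too coarse for
that.

## Known limitations

* Only s-type orbitals and single bonds: no multiple bonds, aromatic
  systems, or hydrogen bridges; only the eight monofocal hydrides and
  chains `H-(CH2)n-X`.
* One ensemble at a time; no recombination of per-bond energies into a
  molecular total.
* Idealized geometry throughout; bond lengths are user-configurable but
  never optimized.
* The two-centre-only mode is an interpretation and is validated only for
  internal consistency, not against an external reference.
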