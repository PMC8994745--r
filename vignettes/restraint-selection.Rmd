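---
title: "Selecting inter-molecular distance restraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting inter-molecular distance restraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restraintr)
```

## The problem

In a linked dual-topology relative free-energy calculation two (or more)
ligands coexist in one simulation without interacting with each other.
Harmonic distance restraints between a few atom pairs — one atom from each
ligand — keep the ligands superposed so that the alchemical transformation
retains phase-space overlap. A good restraint set must satisfy four
conditions simultaneously: the molecules are pre-aligned in one frame;
restrained atoms lie close together *across* molecules (so the restraint
holds them where they already are); the restrained pairs are spread as far
apart as possible *over* each molecule (so the tether controls relative
rotation, not just translation); and only conformationally rigid atoms —
ring atoms — are restrained, so the bias does not distort internal
sampling. `restraintr` turns this into a graph problem and solves it
greedily.

## The selection model

Every cross-molecule ring-atom pair within the cutoff `d_res` becomes a
candidate restraint, represented by the midpoint of its two atoms. The
candidates are the nodes of a complete graph whose edge weights are the
Euclidean distances between midpoints. Selection is max-min dispersion on
this graph:

1. take the two candidates with the largest midpoint separation;
2. discard every candidate that shares an atom with the selection
   (an atom participates in at most one restraint);
3. weight each survivor by the *minimum* of its midpoint distances to the
   selected restraints;
4. add the maximum-weight survivor; repeat from 2 until `n_res`
   restraints are selected or no candidates remain.

If fewer than `n_res` restraints are feasible under atom-disjointness the
maximal feasible set is returned with a warning — for a short chain of a
molecule pair this is more useful than an error, and the remaining
restraints still pin the pair.

### Tie handling

Because alignments are imperfect and coordinates finite-precision,
several survivors can carry nearly identical weights. When the top
weights lie within `tie_tolerance` (default 0.02 nm), the candidate whose
midpoint is farthest from the centre of geometry (COG) of the already
selected midpoints wins; exact residual ties fall back to ascending
(`atom_id_a`, `atom_id_b`). This chain makes the selection a pure function
of the candidate *set* — the input row order never matters, which the
tests verify over shuffled inputs.

The *initial* pair is maximised exactly, with ties only at the exact
maximum (broken by proximity of the pair's own COG to the COG of all
candidate midpoints, then lexicographically). Applying the 0.02 nm window
to the initial pick as well would let the selector open with a
sub-maximal separation, breaking the invariant that the first two
restraints realise the true maximum — a property we verify by O(m²)
enumeration on every random instance.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `n_res` | 4 | — | restraints per molecule pair; 4 non-collinear midpoints are the minimum that fixes all six relative rigid-body degrees of freedom |
| `d_res` | 0.1 | nm | candidate cutoff; about the length of a C–C bond, so only genuinely superposed atoms qualify |
| `tie_tolerance` | 0.02 | nm | width of the near-tie window on selection weights |
| `restrict_to_rings` | `TRUE` | — | restrain only ring atoms; bypassed (with a warning) for bond-free inputs |
| `force_constant` | 5000 | kJ/(mol·nm²) | harmonic restraint strength written by the exporters |
| `r0` | 0 | nm | reference distance; selected pairs overlap by construction, so a full harmonic about zero is the default |

Internally every length is in nm; Ångström inputs (PDB, SDF) are converted
at the I/O boundary only.

## Ring perception

"Ring atoms" are defined as atoms lying on at least one simple cycle of
the bond graph — the endpoints of non-bridge edges (2-edge-connected
core). This deliberately includes *all* atoms of fused and bridged
polycyclic systems, whereas an SSSR-based definition could exclude
bridgehead environments; since the criterion exists to capture rigidity,
the broader definition is the right one. Acyclic molecules have no
eligible atoms; molecules without bond information (toy systems) bypass
the filter entirely.

## Multi-state rings

For `M ≥ 3` end-states the pairwise selector runs on every unordered pair
and each pair is weighted by the convex-hull volume (CHV) of its restraint
midpoints — a pair whose restraints span a 3-D volume constrains relative
rotation far better than one whose midpoints are nearly collinear. A
Kruskal-style greedy then accepts edges by descending CHV, rejecting any
edge that would give a molecule three neighbours or close a cycle early;
the resulting Hamiltonian path is closed into a ring, so every molecule is
restrained to exactly two neighbours.

Design choices worth recording:

* **Missing pairs are absent edges, not zero-weight edges.** A pair with
  candidates but coplanar midpoints (CHV = 0) is still linkable; a pair
  with no candidates at all is not.
* **The closure edge reuses the precomputed pair set** when available.
  The two path endpoints are by construction the pair the greedy liked
  least, and may have the weakest restraints of the ring; if the pair had
  no candidates at all, closure retries once with `d_res` doubled before
  failing.
* **Greedy dead-ends fall back to exact search.** Degree-constrained
  Kruskal can strand a molecule even when a Hamiltonian path exists
  (e.g. a hub saturating on its two heaviest edges while a leaf hangs off
  it). For up to 8 molecules the fallback enumerates Hamiltonian paths
  exhaustively and returns the maximum-weight one; larger stuck instances
  raise a chaining error rather than silently degrading.

## Numerical choices

* **Convex-hull volume** is computed by supporting-plane enumeration:
  every plane through three points with all remaining points on one side
  is a hull facet; facets are merged by their vertex sets, triangulated
  via the planar 2-D hull, and summed with the divergence theorem. This
  is O(n⁴) but exact and robust for the point counts that occur here
  (restraint midpoints, ≤ ~10 points); sets of fewer than four points or
  rank < 3 within 1e-9 nm return volume 0. For four points the volume is
  the closed-form tetrahedron determinant, which the brute-force CHV
  oracle exploits in vectorised form.
* **Degeneracy tolerance** 1e-9 nm sits far below coordinate precision
  (PDB files carry 1e-4 nm) while comfortably above double-precision
  noise at these magnitudes.
* **Exact-tie epsilon** for the initial pair is `sqrt(.Machine$double.eps)`,
  i.e. ties are "equal to floating-point accuracy", distinct from the
  physical 0.02 nm near-tie window of the iteration steps.
* **Brute-force cap.** The exhaustive selectors refuse instances above a
  configurable subset cap (default 2×10⁶) with an error naming the
  instance size — their O(N⁴) growth is the reason the greedy selector
  exists, and the counter attribute `n_enumerated` lets tests assert the
  count equals `choose(m, n_res)` exactly.

## What the toy generator emulates — and what it does not

`toy_system()` reproduces the validation setting for the selector:
`n_particles` points uniform in a cube, split randomly into two balanced
entities, no bonds. The default box edge is **0.2 nm**: at the default
0.1 nm cutoff this makes the two clouds overlap strongly, so a
12-particle system typically yields around ten candidates (enough for
four atom-disjoint restraints most of the time) and a 30-particle system
around 60–90, keeping exhaustive enumeration tractable. A larger box
starves the candidate graph — at 0.4 nm a 12-particle system averages
about two candidates and four restraints are usually infeasible.

Toy clouds exercise the algorithmic properties (feasibility,
determinism, oracle dominance) but are *not* molecules: they have no
bonds, hence no ring filter; no chemical regularity in distances; and
uniformly random geometry rather than the correlated, aligned structures
of real ligand pairs. Passing the toy benchmark therefore validates the
selection machinery, not force-field or alignment quality, and says
nothing about the free-energy accuracy of any particular restraint set.
The validation sweep used by the tests and `scripts/acceptance.R` runs
sizes {12, 16, 20, 24, 30} with 20 replicates each, four restraints and
100-trial random baselines — the exhaustive oracles at the largest size
enumerate a few hundred thousand to a few million subsets, which keeps
the whole protocol under a minute or two on one CPU. Instances that
cannot host four atom-disjoint restraints are compared at the greedy's
achieved cardinality, with the oracles re-run at that size.

## Export conventions

GROMOS files carry a `TITLE` and a `DISTANCERESSPEC` block (DISH/DISC
constants 0.1/0.153 nm, virtual-atom type code 0 for real atoms, unit
weight, `rah = 0` full harmonic, fixed-point six-decimal reals). GROMACS
output is a `[ distance_restraints ]` fragment with type-1 restraints and
`low = 0`, `up1 = r0 + d_res`, `up2 = up1 + 0.1 nm`,
`fac = force_constant / disre-fc`; there is no single canonical mapping of
"hold at ~0 nm" onto the GROMACS three-threshold form, so this convention
is declared in the written file's header and tested byte-exactly. Merged
dual-topology indices keep molecule A's atom numbers and offset molecule
B's by A's atom count (overridable via `atom_offset_b`). The JSON format
stores full atom records (ids, names, elements, coordinates in nm) plus
`r0` and the force constant; midpoints are recomputed on reading, and
write∘read∘write is byte-identical.

## Known limitations

* Alignment is an input, not a service: molecules must already share a
  frame (use an MCS or shape alignment tool first). A poor alignment
  simply yields few or no candidates.
* The greedy selector is locally optimal only; the included exhaustive
  selectors bound its gap on small instances but no global guarantee is
  claimed for real molecules.
* Ring perception uses bond connectivity only — no aromaticity,
  protonation or flexibility analysis; a large flexible macrocycle counts
  as "rigid" by this definition.
* The multi-state exact fallback is limited to 8 molecules; beyond that a
  stuck greedy chain is reported as an error.
* Restraint quality is measured geometrically (midpoint spread, CHV);
  validating the effect on free-energy estimates requires molecular
  dynamics and is outside this package's scope.
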