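---
title: "Rigidity analysis of molecular frameworks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity analysis of molecular frameworks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidmol)
```

## The model

rigidmol determines which parts of a biomolecule move together as rigid
units and which parts are flexible, using combinatorial rigidity theory
rather than dynamics. The pipeline has five stages.

**Curation.** A PDB structure is reduced to the molecule of interest:
chain selection, removal of solvent and (optionally) ligands, model
selection for multi-model files, and alternate-location resolution. Every
action is recorded in an ordered log; replaying the log on the same input
reproduces a byte-identical molecule, so a curation is a reproducible
experiment record rather than an interactive session.

**Interaction network.** Covalent bonds are perceived coordinate-free from
residue templates (with a distance fallback, summed covalent radii + 0.4 Å,
for non-template residues). Non-covalent constraints are then detected:
hydrogen bonds (donor–acceptor distance ≤ 3.5 Å, donor–hydrogen–acceptor
angle ≥ 90°), hydrophobic contacts (C/S pairs within van der Waals contact
+ 0.25 Å, one per residue pair), and disulfides (SG–SG ≤ 2.5 Å). Each
hydrogen bond is scored with a Mayo-style closed form

$$E(R,\theta) = D_0\,\min\!\big(0,\; 5(R_0/R)^{12} - 6(R_0/R)^{10}\big)\,
\cos^2\theta,$$

with well depth $D_0 = 8$ kcal/mol, optimal donor–acceptor distance
$R_0 = 2.8$ Å, and $\theta$ the D–H–A angle. The energy is zero at the 90°
gate, decreases monotonically with better alignment, and reaches its global
minimum $-D_0$ at $(R_0, 180^\circ)$. The radial factor is clamped at zero
so unphysically short separations never contribute a *stabilising* positive
term. All constants live in `interaction_params()` so the form can be
swapped; rigidity results are known to be sensitive to hydrogen-bond
placement, which is why the form is explicit and replaceable rather than
hard-wired. Bonds weaker than the energy cutoff `E_cut` (default −1.0
kcal/mol) are pruned; this cutoff is the principal tunable knob of the
whole analysis.

**Mechanical framework.** Atoms with covalent degree ≥ 2 become *bodies*
containing themselves and their covalent neighbours, so bonded hub atoms
yield bodies overlapping on the two bond atoms. Bonds between hubs become
*hinges* (sharing a rotation axis, removing 5 of the 6 relative DoF);
non-rotatable bonds (peptide, double) are locked with 6 bars; hydrogen
bonds are hinges; hydrophobic contacts contribute 3 bars. Bar counts are
user-adjustable in `[1, 6]` per bond class via `modeling_options()`.

**Pebble game.** The framework maps to a multigraph — one vertex per body,
5 parallel edges per hinge, $b$ edges per $b$-bar connection — and the
(6,6)-pebble game computes a maximum independent edge set of the
(6,6)-sparsity matroid: every vertex subset $S$ ($|S|\ge 2$) spans at most
$6|S|-6$ independent edges. Rigid components are the maximal vertex sets
spanning exactly $6|S|-6$ independent edges; redundant edges indicate
over-constraint. For body-bar-hinge frameworks this combinatorial answer
equals the generic mechanical rigidity (the molecular conjecture, now a
theorem), which is what licenses replacing linear algebra with a pebble
game.

**Clusters.** Components convert back to atom-level clusters (union of
their bodies' atoms); bodies in no component are reported as their own
clusters. Clusters may overlap on the two atoms of a shared hinge axis —
overlap is a feature of the body-bar-hinge formulation, not an error.
Labels are assigned by decreasing size, ties by smallest atom serial and
then lexicographic atom set, so outputs are deterministic.

## Derivative analyses

*Dilution* removes hydrogen bonds one at a time — by default weakest first,
i.e. energy closest to zero first — recomputing the decomposition from
scratch after each removal. Snapshots refine monotonically: clusters only
ever split. The removal direction deserves a note: "increasing order of
energy" with negative energies is ambiguous, so both `weakest_first` and
`strongest_first` are provided, plus a geometric `depth` order (shallowest
first, by distance from the bond midpoint to the nearest convex-hull
facet). *Alanine scanning* removes all hydrogen bonds **and hydrophobic
contacts** touching a residue's side chain beyond Cβ — a deliberate
extension beyond hydrogen bonds alone, since alanine substitution also
deletes side-chain packing — and ranks residues by the shrinkage of the
largest cluster (ties: increase in cluster count, then residue order; the
score is this package's declared metric, not a literature-calibrated one).
*Redundancy classification* applies the definition directly: a bond is
redundant if removing it leaves the decomposition unchanged, critical
otherwise.

Decomposition equality here includes the flexible connections between
clusters, not only the cluster atom sets. The distinction matters exactly
once: a bond that is the sole link between two flexible clusters leaves the
cluster atom sets unchanged when removed, yet it constrains the framework
(its removal adds degrees of freedom), so it must classify as critical.
With connections included, criticality coincides with "removal changes the
flexible framework", which is the mechanically meaningful reading.

*Consistent coloring* makes related decompositions visually comparable.
Within a dilution, each parent cluster's colour is inherited by its largest
child (ties by smallest atom serial); other children above the size
threshold (default 5 atoms) get fresh colours, smaller ones a neutral grey.
Between two arbitrary decompositions, clusters are matched by Gale–Shapley
stable matching with preferences by raw shared-atom count (ties by label;
zero overlap = mutually unacceptable). Stable matchings are side-dependent,
so the proposer is fixed to the first argument for determinism. Raw counts
rather than Jaccard similarity keep the preference order transparent; both
choices are defensible and this one is the simplest to state.

## Numerical and algorithmic choices

- **Determinism.** Edges are inserted in a fixed order (connection id, then
  endpoints), making the *identity* of redundant edges reproducible. Rank,
  free DoF and components are provably insertion-order invariant — the test
  suite checks this over random permutations — but which specific edges are
  called redundant is order-dependent, as in any matroid greedy.
- **Component detection.** For the $k = l$ games, two adjacent vertices lie
  in a common tight set exactly when $l+1$ pebbles cannot be gathered on
  them, and tight sets sharing a vertex have a tight union; components are
  therefore computed as the union-find closure of failing adjacent pairs,
  and are pairwise vertex-disjoint at graph level. (Two rigid pairs sharing
  a body are jointly rigid — locking against a shared body is transitive —
  so merging is correct, and overlap reappears only at atom level through
  hinge axes.) For $l \neq k$ the engine still computes rank and redundant
  edges; component reporting is restricted to $k = l$, the only case the
  molecular model uses.
- **Oracles.** The pebble game is certified against an independent
  brute-force oracle: greedy matroid augmentation with exhaustive sparsity
  verification over all vertex subsets, and component enumeration over all
  subsets, feasible for $|V| \le 8$. The generalized $(k,l)$ engine exists
  mainly so this cross-check is cheap to trust.
- **Convex hull depth.** Burial depth uses supporting-plane enumeration
  over all point triples — $O(n^3)$ but exact, and robust to the coplanar
  degeneracies that ideal-geometry fixtures produce (peptide planes). It is
  intended for desk-scale molecules (capped at 400 points).
- **Degenerate inputs.** Loops are rejected (inadmissible for $l \ge k$);
  empty graphs have rank 0 and no DoF defined; an interaction lying inside
  a single body produces no connection but is logged; a bonded pair of
  degree-1 atoms (a diatomic) becomes one two-atom body.

## The synthetic fixtures

`make_fixture()` builds deterministic ideal-geometry molecules: water,
ethane, ethylene, an ALA–ALA dipeptide, and `toy_helix(n_res)` — an
alanine helix built by natural-extension from φ = −70°, ψ = −45°, ω = 180°.
These torsions sit in the α region and were chosen once so that the
*i → i+4* backbone geometry (D–A 2.74 Å, D–H–A 144°, ≈ −5.0 kcal/mol)
passes the default gates while *i → i+3* falls outside the 3.5 Å distance
gate (3.77 Å): the helix's detectable hydrogen bonds are exactly its
four-bond ladder for `n_res = 8`, making every downstream count
hand-verifiable.

The fixtures emulate the *topology* that drives rigidity analysis — hub
bodies, hinge chains, a hydrogen-bond ladder, methyl packing contacts —
with perfectly clean geometry. They do not emulate real structures'
heterogeneity: missing atoms, alternate conformations, protonation
ambiguity, waters, ligands, or energy spread among hydrogen bonds (all
helix bonds are symmetry-equivalent). Passing tests on fixtures therefore
certifies the machinery (detection gates, modeling constants, matroid
computation, refinement and coloring rules), not the biological accuracy of
any particular cutoff on real proteins, which remains the user's tunable
experiment.

Validation problem sizes, chosen to keep every oracle exhaustive: 200
random multigraphs with $|V| \le 6$, $|E| \le 40$ for pebble/oracle
equivalence; 20 insertion-order permutations per graph; helices of 6–8
residues (≈ 60–80 atoms, ≈ 24–32 bodies) for dilution, mutagenesis,
redundancy and coloring; stable matchings verified exhaustively up to 5×5.

## Known limitations

- Hydrogens must be present; the package reports a clear error rather than
  placing them (protonation is delegated to dedicated tools upstream).
- PDB only (no mmCIF); no bio-assembly or crystal-symmetry expansion;
  structural defects are reported (chain gaps) but not repaired.
- All non-water HETATM groups are treated uniformly by the ligand-pruning
  flag; distinguishing cofactors from crystallization additives is left to
  the user's chain/ligand selection.
- Atoms in no body (isolated HETATM atoms) are reported as trivial
  single-atom clusters and excluded from coloring by the size threshold.
- The peptide-unit body grouping mentioned in the modeling literature is
  not used by default; hub bodies give an equivalent decomposition for
  generic frameworks and keep the model fully specified.
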