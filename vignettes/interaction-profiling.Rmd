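---
title: "Geometric rules and engineering choices in nciprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric rules and engineering choices in nciprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nciprofiler)
```

## The model

`nciprofiler` treats non-covalent interaction detection as a purely
geometric classification problem. A macromolecular complex is reduced to a
set of chemical features — hydrogen-bond donors and acceptors, charged-group
centroids, aromatic ring planes, hydrophobic carbons, carbon-bound halogens,
metals and water oxygens — and each of the eight interaction classes is a
predicate over distances and unsigned angles between features on the ligand
side and features on the receptor side. There is no energy model and no
statistical potential: a contact either satisfies its geometric rule under
the active thresholds or it does not. This makes every result exactly
reproducible, auditable atom by atom, and sensitive only to coordinates and
to the thresholds, which are all user-facing configuration
(`default_config()`).

The receptor may be protein, DNA, RNA or any mixture. Nucleic residues are
recognised purely by residue name (`U`, `A`, `C`, `G` for RNA; `DT`, `DA`,
`DC`, `DG` for DNA). In the default mode each contiguous nucleic chain is a
ligand entity, profiled against the rest of the structure; in the
nucleic-receptor mode those residues join the receptor and only hetero
content remains ligand. A single run uses one global mode: a chain cannot be
receptor for one ligand and ligand for another within the same analysis.
This keeps the receptor/ligand partition a function of the input plus flags,
never of per-site context.

### Assumptions

* **Single conformer.** Alternate locations are pruned at parse time to the
  highest-occupancy altloc (ties prefer `A`, then first encountered), so all
  geometry is unambiguous.
* **pH 7 protonation.** Asp/Glu are deprotonated, Arg/Lys protonated.
  Histidine is both a potential donor and acceptor, and counts as a cationic
  centre only when the input carries hydrogens on both ring nitrogens; the
  package's own hydrogenation produces the neutral NE2-H tautomer.
* **Hydrogens are positional, not inferential.** Missing polar hydrogens on
  standard residues and waters are placed with idealised sp2/sp3 geometry
  (N–H 1.01 Å, O–H 0.96 Å, S–H 1.34 Å; water 0.9572 Å / 104.52°). Hydrogens
  already present are kept unmodified — even if misplaced — because the
  input's hydrogen positions may carry information (e.g. from a docking or
  MD snapshot) that an idealiser would destroy. Arbitrary hetero ligands are
  never hydrogenated; a ligand donor without an explicit hydrogen is
  evaluated distance-only and its bonds are flagged `geometry-unverified`
  rather than dropped.

## Thresholds

All bounds are inclusive (a contact exactly at a `*_max` is reported) and
live in one flat configuration, serialisable as `key = value` text:

```{r}
unlist(default_config())
```

The defaults match the values commonly used by geometric profilers in this
field, so results on shared structures are comparable; every one of them is
an input, not a constant. Two non-obvious entries: `binding_site_dist`
(7.5 Å) is deliberately larger than any interaction cutoff plus a group
radius, so the site shell can never truncate a detectable contact; and the
halogen angles are targets with tolerances (165° ± 30° at the halogen — the
σ-hole direction — and 120° ± 30° at the acceptor).

## Refinement

Raw per-type matches are refined deterministically; the ordering of the
rules is part of the package contract:

(a) hydrophobic contacts are reduced twice — the closest pair per (ligand
atom, receptor residue), then fully connected clusters collapse to their
single closest contact, ties broken by distance, then lowest receptor and
ligand serials; (b) a water bridge is suppressed when the same
ligand-atom/receptor-atom pair forms a direct hydrogen bond; (c) a salt
bridge subsumes the hydrogen bonds between member atoms of its two charged
groups; (d) the purine multi-ring representation (5-ring, 6-ring and fused
centroid are all stacking candidates) keeps only the best-offset stack — and
the closest π-cation contact — per ring-group pair; (e) a pair reported as
π-cation is not additionally a salt bridge for the same centroids; (f) a
donor atom donates at most one hydrogen bond, keeping the candidate with the
largest donor angle.

Rule (f) deserves its justification: without it, an ideal Watson–Crick G:C
pair reports five "bonds" instead of three, because each donor hydrogen also
clears the 100° angle floor toward the *neighbouring* acceptor of the paired
base at ~3.7 Å. Physically a donor hydrogen engages one acceptor; the
best-angle candidate is that one.

## The synthetic-data generator

`generate_fixture()` writes PDB files containing minimal chemical groups —
formamide donors, benzene and phenylalanine rings, guanidinium, acetate,
ammonium, nucleobases built as idealised planar ring systems, phosphates,
waters, metals with coordination spheres — arranged at exactly requested
geometry, plus decoy atoms, and a tab-separated manifest of ground truth.
The standard suite (`standard_fixture_specs()`) plants, for every
interaction class, one arrangement inside the default thresholds, one
exactly at a threshold and one outside: 30 arrangements in all.

Two numerical details matter here:

* **PDB precision.** Coordinates are rounded to 3 decimals *before* the
  manifest geometry is measured, so re-measuring the written file reproduces
  the manifest identically (worst-case distance noise from rounding is below
  0.001 Å).
* **Boundary snapping.** Rounding can push an at-threshold arrangement a
  fraction of a milli-Ångström past its inclusive bound. The generator
  therefore iteratively nudges the critical atom (or rigid group) back onto
  the safe side of the requested value after rounding, with a 0.002 Å /
  0.05° margin — so "at the boundary" means *at the boundary to PDB
  precision*, on the reportable side.

What the fixtures emulate is the geometry of real contacts; what they do not
emulate is everything else about experimental structures — coordinate error
beyond the optional seeded jitter (≤ 0.05 Å), crystallographic disorder,
missing atoms mid-residue, chemistry outside the template/generic rule
vocabulary, and crowded sites where many marginal contacts compete. A green
fixture suite demonstrates that the rules are implemented exactly as stated,
not that the rule set itself captures every interaction a structural
biologist would annotate in a messy real structure.

Two larger hand-built complexes extend this to integration scale, and are
named synthetic because they are constructed, not downloaded:
`synthetic_rna_protein_complex()` (an RNA 5-mer UGGUG bound by a minimal
recognition pocket: an aromatic ring intercalated between the two central
guanines, a face-on arginine, a lysine at a backbone phosphate,
hydrogen-bond and hydrophobic partners for the uracils) and
`synthetic_elongation_complex()` (a nucleoside-triphosphate ligand whose
guanine pairs with a DNA cytosine via three Watson–Crick bonds, stacks on an
RNA guanine and donates one Hoogsteen-edge bond to an RNA adenine, while the
triphosphate salt-bridges a lysine next to an octahedrally coordinated
magnesium). The Watson–Crick placement is a rigid 2D fit of the cytosine
onto the three canonical bond distances (2.91 / 2.95 / 2.86 Å) with a
clash penalty, tried from several starting rotations and both base faces.

## Numerical choices

* Ring planarity: RMSD from the best-fit (SVD) plane ≤ 0.25 Å — tolerant of
  coordinate noise, excluding saturated rings. Ring normals are defined up
  to sign; every consumer folds plane angles into [0°, 90°].
* Generic bond perception: covalent radii sum + 0.45 Å, metals never bonded
  by distance; CONECT records are taken verbatim. Hydrogens attach to a
  heavy atom within 1.3 Å.
* A guanidinium centre requires an *acyclic* carbon with three nitrogen
  neighbours — an aromatic amidine carbon (nucleobase C2) is not a cation.
* Element inference without columns 77–78 strips digits from the atom name
  and prefers two-letter metal symbols only when the residue name matches
  (so `CA` in `ALA` is a carbon, `CA` in residue `CA` is calcium).
* Metal geometry labels minimise the RMSD between sorted observed pairwise
  ligand–metal–ligand angles and sorted template angles, among templates of
  matching coordination number; a single-partner sphere is
  `other/underdetermined`.
* Degenerate inputs: empty structures and structures with no parsable
  coordinate records are structured errors naming the offending line; a
  ligand with an empty binding site, or a structure with no ligand at all,
  is a valid run (advisory, empty report).
* Determinism: sites are ordered by ligand chain then sequence number;
  interactions by type (fixed catalogue order), receptor residue, distance,
  serials. Two runs on the same input are byte-identical.

## Scope of the validation runs

The test suite and the acceptance script size their simulations to run in
seconds-to-minutes on one CPU: 30 planted arrangements in the fixture suite,
200 seeded random micro-geometries per detector (each ≤ ~60 atoms) for the
brute-force oracle comparison, three-point threshold sweeps per class, and
the two synthetic complexes (~100 atoms each). These sizes were chosen
because the rules are local, pairwise predicates: a detector that agrees
with exhaustive evaluation on thousands of small random configurations has
no scale-dependent behaviour left to probe.

## Known limitations

* Feature templates cover the 20 standard amino acids and the 8 standard
  nucleotides; modified residues (phosphorylated amino acids, modified
  bases such as pseudouridine) fall back to generic element/valence
  perception, which is a fallback, not a claim of chemical equivalence.
* No formal-charge or pKa computation: charge assignment is rule-based
  (carboxylate, phosphate, sulfonate, guanidinium, amine/quaternary
  nitrogen, halide).
* Interactions between two ligand entities (e.g. a metal ion bridging a
  nucleotide ligand and the protein) are not profiled within either
  entity's site — each site is strictly ligand against receptor.
* mmCIF input, symmetry-mate generation, covalent-bond reporting, energy
  scoring and visualisation are out of scope.
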