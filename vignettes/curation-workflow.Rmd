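---
title: "Curating non-covalent protein-ligand complexes with plcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating non-covalent protein-ligand complexes with plcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plcurate)
```

## The problem

Scoring functions for protein-ligand binding are trained on deposited
crystal structures, and those structures are imperfect in systematic ways:
hydrogens are absent, side chains and whole loops are unresolved, ligand
bond orders and aromaticity are not part of the PDB coordinate format and
must be re-derived, protonation states are unassigned, and a minority of
entries contain covalent ligands, exotic elements, or physically
impossible protein-ligand contacts. `plcurate` implements a reproducible
curation pipeline that takes a deposited entry apart, rejects what cannot
be certified non-covalent and well-formed, repairs what can, and produces
a relaxed, chemistry-complete complex plus normalized binding-affinity
annotations.

The pipeline runs per ligand occurrence ("bundle"): split into ligand /
protein / additives, four rejection filters, ligand chemistry repair,
protein completion, constrained relaxation. Each stage either passes the
bundle on or terminates it with a machine-readable diagnostic; bundles of
the same entry are independent, because one deposited entry legitimately
contributes several protein-ligand complexes (copies in homomultimers,
multiple pockets, multiple ligands).

## Splitting and the four filters

A ligand is named either by its Chemical Component Dictionary (CCD)
residue code or, for short polymers (peptides, oligosaccharides,
oligonucleotides), as a whole chain of at least 2 and fewer than 20
residues. For every ligand occurrence, any biopolymer chain with a heavy
atom within 10 Å is associated whole — chains, not residue shells, are
the unit of association. HETATM residues within 4 Å of that protein
(ions, solvents, cofactors) are kept aside as additives and deposited as
a separate PDB file. Waters count as additives by default
(`drop_waters = FALSE`).

The four filters, all evaluated so reports are complete:

* **Covalent binder** — any CONECT record joining a ligand atom to a
  protein atom.
* **Rare element** — any ligand element outside {H, C, N, O, F, P, S,
  Cl, Br, I}.
* **Small ligand** — fewer than 4 heavy atoms (O2, CO2, azide and the
  like).
* **Steric clash** — any protein-ligand heavy-atom pair closer than
  2 Å. "Closer than" is read strictly: a pair at exactly 2.000 Å passes.
  This filter also catches covalent binders whose bond was never recorded
  in CONECT.

Additives are excluded from the clash scan; the filter certifies the
protein-ligand pair itself. All thresholds live in one validated
configuration object (`plc_config()`), overridable from a flat YAML file,
so no rule constant is buried in code.

```{r config}
cfg <- plc_config()
cfg$clash_cutoff
```

## Ligand repair: trust the coordinates, not the deposited chemistry

Crystallographic ligand coordinates are the ground truth being curated;
the chemistry annotations around them often are not. The repair pipeline
therefore:

1. **Perceives** a bonding graph purely from geometry: two heavy atoms
   are bonded when their distance is under 1.3 times the sum of their
   covalent radii (the factor is configurable). Orders are provisional.
2. **Resolves a reference** SMILES: a user override table takes
   precedence (for the known-corrupt deposited references), then a
   CCD/BIRD lookup function, then — for polymer ligands made only of
   standard alpha-amino acids — a generated linear-peptide SMILES with
   amide-bond chaining and free neutral termini. Counter-ion fragments
   are stripped to the largest organic fragment.
3. **Validates the reference against the geometry**: deposited references
   are occasionally saturated (every bond single). A planar 5/6-ring or a
   planar three-substituent carbon in the crystal with no matching
   unsaturation in the reference fails the reference, not the structure.
   Planarity is an improper dihedral within 10° (ring closure within
   0.1 Å RMS of the best-fit plane); both tolerances are configuration
   fields.
4. **Transfers bond orders** by element-labelled graph isomorphism
   (orders are deliberately ignored during matching since the perceived
   orders are untrusted). Isomorphism failure means missing atoms or
   distorted geometry — the entry is excluded with a diagnostic naming
   the difference, because a reference cannot certify a structure it
   does not match. Automorphic mappings are chemically equivalent and
   any one is taken.
5. **Protonates** by fixed-order rules (below) and adds explicit
   hydrogens at standard geometry. Heavy atoms never move: the fixed
   ligand's heavy-atom RMSD to the crystal is exactly zero.

### Protonation rules at pH 7.4

Applied in fixed order as molecular-graph predicates; each rule only
touches atoms with zero formal charge, which makes the whole assignment
idempotent:

1. deprotonate carboxylic/sulfonic/phosphonic acids, the nitro OH form,
   thiophenols, azides and N-oxides;
2. deprotonate enols in the O=C-C=C-OH motif;
3. protonate aliphatic amines and guanidine/imine nitrogens — but not
   anilines, not amide nitrogens, and not amines whose nitrogen touches
   any atom other than C or H;
4. on diamines and piperazines (basic nitrogens within three bonds of
   each other) protonate exactly one: the nitrogen with fewer heavy
   substituents, ties to the lowest atom index. A nitrogen that is
   already cationic claims its neighborhood the same way.

On the ambiguity of "imines": amidine/guanidine-like nitrogens and
isolated non-aromatic C=N nitrogens are protonated; aromatic ring
nitrogens are not. For amidines and guanidinium groups the proton is
placed on the least-substituted nitrogen of the group; the resulting
cation is a resonance form with the correct net charge and hydrogen
count.

## Protein repair

Missing content is detected against the complete deposited sequence from
the mmCIF header — not SEQRES, which in some entries omits the missing
residues, so that naive rebuilding would seal the gap with a spurious
peptide bond. Missing atoms within modeled residues are always rebuilt;
internal missing segments of at most 10 residues are rebuilt; terminal
segments and longer gaps (typically disordered regions or purification
tags) are left absent, with the chain break preserved in numbering. All
rebuilding superposes idealized residue templates (Chemical Component
Dictionary ideal geometry, shipped as plain text in `extdata`) onto the
present atoms; every added atom is flagged `is_experimental = FALSE` and
declared in `REMARK 99` lines of the output PDB, so downstream users can
separate crystal atoms from modeled ones.

Protonation uses fixed titration states: LYS/ARG cationic, ASP/GLU
anionic, CYS neutral unless its Sγ is within 2.3 Å of another Sγ
(disulfide), histidine neutral. The HID/HIE tautomer is chosen per
histidine by the better hydrogen bond: the proton whose placement yields
more polar contacts within 3.5 Å at a donor angle above 120°; ties and
isolated histidines default to HIE.

## Constrained relaxation

The repaired protein and fixed ligand are recombined and relaxed under a
hard constraint: experimentally resolved atoms are not optimization
variables at all, so their displacement is exactly zero rather than
small. Only hydrogens and fixer-added atoms move. The potential is a
lightweight geometric one — harmonic restraints on bonds involving
movable atoms (X–H bonds to ideal lengths, others to their input
lengths) plus a soft-core quadratic repulsion between non-bonded pairs
below 85% of their van der Waals contact distance, with bonds gated by
distance so a preserved chain break never acquires a phantom peptide
bond. This potential is everywhere finite (no singular cores), so
relaxation always starts from a defined energy, and L-BFGS with a
10,000-iteration cap decreases it monotonically and deterministically.
It is a steric-relief scheme, not a molecular-mechanics force field: its
job is to resolve collisions among added atoms and tidy hydrogen
placement, and its contract — zero experimental displacement, energy
never increasing — is what the tests certify. Additives are excluded
from the relaxed system.

## Affinity normalization

Annotation strings in the BioLiP and Binding MOAD dialects are parsed
into (measurement, qualifier, molar value): Kd, Ki, IC50, EC50 with
qualifiers `=`, `~`, `<`, `>`, `<=`, `>=` and units fM through M. Exact
(`=`) Kd/Ki records get a standard free energy ΔG = RT ln K, at
T = 298.15 K with R = 8.31446×10⁻³ kJ/(mol·K); the temperature is a
package default (assay temperatures are rarely annotated) and is
configurable. IC50/EC50 are carried through untranslated — they depend
on assay conditions and inhibition mechanism — as are range-qualified
values, which downstream users may treat as censored data. Records are
merged across sources by (entry, ligand, measurement) with precedence
biolip > moad > other; Ki/Kd above 10³ M are dropped as invalid; every
drop and every quarantined unparseable row is logged, never silent.

## The synthetic-fixture generator

Real deposited entries cannot ship with the package, so the generator
builds the smallest structures that exercise every code path: an
ideal-geometry α-helix receptor (φ = −57°, ψ = −47°, standard backbone
lengths and angles; default 20 residues of polyalanine with one LYS,
ASP, HIS and CYS for titration coverage) and a benzamidine-like ligand
embedded in 3D, hydrogens stripped and bond orders absent exactly as a
deposited PDB would present it, placed at a seeded direction with a
target minimum contact distance of 3.5 Å. Nine injectable defects map
one-to-one onto the filter and fixer failure modes, and each fixture
carries a machine-readable manifest of the stage outcome it must
trigger, so the integration tests are data-driven.

What the fixtures do not emulate: real protein folds, crystallographic
noise, alternate conformations, waters in the binding site, or large
ligands with rotatable-bond-rich conformers. Passing the fixture suite
therefore certifies the *logic* of every stage — thresholds, rule
ordering, bookkeeping, constraint contracts — not the empirical success
rate of the workflow on archive-scale data, which requires the bulk
inputs the package deliberately does not bundle. Conformer embedding for
fixture ligands goes through a stochastic search whose generator state
advances across calls; embeddings are memoized per SMILES within a
session so identical fixture specs yield identical files.

## Numerical choices and problem sizes

* Distance cutoffs are strict inequalities; boundary cases are covered by
  tests at exact coordinates.
* Alt-locs keep the highest-occupancy conformer (ties: file order);
  multi-model files keep model 1 unless told otherwise; deposited
  hydrogens are dropped on input so protonation is uniform.
* The rotamer metric uses the periodic difference on (−180°, 180°], with
  180°-symmetric terminal torsions (ASP χ2, GLU χ3, PHE/TYR χ2) folded,
  and ARG χ5 excluded entirely; "near the binding site" defaults to the
  10 Å association cutoff, a documented choice the archive comparison
  depends on.
* QED is computed from the published desirability parameterization over
  the eight standard descriptors; logP and TPSA come from OpenBabel's
  implementations of the fragment methods, donor/acceptor/rotatable
  counts from explicit graph rules (N+O acceptors, N/O/S-H donors,
  non-ring single bonds between non-terminal heavy atoms excluding
  amides). The structural-alerts descriptor is taken as zero matches —
  a known limitation for molecules carrying reactive groups, where the
  reported QED is an upper bound.
* Default suite sizes — 20-residue receptors, a 50-molecule round-trip
  panel, 100 random clash poses, a 48×48 angle grid — were chosen as the
  smallest sets that exercise every rule and symmetry; they complete in
  a few minutes on one CPU.

## Known limitations

* The relaxation potential does not model electrostatics or torsional
  preferences; refined hydrogen positions are sterically reasonable, not
  force-field optimal.
* Cyclic peptides and disulfide-containing polymer ligands fail the
  peptide reference by construction and are excluded, mirroring the
  workflow's scope.
* Rebuilt loop conformations are placeholders relieved of steric strain,
  not modeled loops.
* Live-archive operation (fetching by accession) requires network access;
  everything else runs offline.
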