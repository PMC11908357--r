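# plcurate

Curation of non-covalent protein–ligand complex structures and their
binding-affinity annotations, in R.

Deposited crystal structures are imperfect inputs for training and
validating binding scoring functions: hydrogens are absent, side chains
and loops go unresolved, the PDB coordinate format carries no bond orders
or formal charges, and a minority of entries hide covalent ligands, rare
elements, or sub-2 Å protein–ligand clashes that are artifacts of density
fitting. `plcurate` implements the full curation pipeline as composable,
tested functions:

* **split** — identify each ligand occurrence (CCD-coded small molecule,
  or short polymer chain of 2–19 residues), associate every biopolymer
  chain within 10 Å as its protein, and set aside HETATM residues within
  4 Å as additives;
* **filter** — reject covalent binders (CONECT evidence), ligands with
  elements outside {H, C, N, O, F, P, S, Cl, Br, I}, ligands under
  4 heavy atoms, and complexes with protein–ligand heavy-atom pairs
  closer than 2 Å;
* **fix the ligand** — perceive bonds from geometry, obtain a reference
  SMILES (override table → CCD/BIRD lookup → generated peptide), verify
  the reference against the crystal geometry, transfer bond
  orders/aromaticity/charges through element-labelled graph isomorphism,
  then apply rule-based protonation at pH 7.4 (ΔG-relevant groups:
  acids, nitro, thiophenol, azide, N-oxide and enol motifs deprotonated;
  aliphatic amines and guanidines/imines protonated, anilines and
  hetero-substituted amines not; one proton per diamine/piperazine);
* **fix the protein** — detect missing atoms/residues against the mmCIF
  header sequence, rebuild missing atoms and internal gaps of ≤ 10
  residues from idealized residue templates, leave terminal and long
  gaps as annotated chain breaks, protonate (LYS/ARG⁺, ASP/GLU⁻, HIS
  neutral with the tautomer chosen by the better hydrogen bond,
  disulfide CYS bare);
* **refine** — relax the recombined complex under a hard constraint:
  experimentally resolved atoms are not optimization variables, so only
  hydrogens and fixer-added atoms move, and the final energy never
  exceeds the initial one (ΔG = RT ln K annotation conversion included:
  exact Kd/Ki records get free energies at 298.15 K).

A deterministic synthetic-complex generator (ideal α-helix receptor +
embedded small-molecule ligand + nine injectable defects) makes every
stage verifiable offline, with no archive downloads.

## Worked example

```r
library(plcurate)

fx <- make_fixture(fixture_spec(seed = 1))          # synthetic entry
res <- run_entry(fixture_entry(fx), out_dir = "curated")
res
#> <plc_curation_result> 9XYZ: succeeded (1 bundle(s))
#>   L|1|: succeeded

b <- res$bundles[["L|1|"]]
b$refinement
#> <plc_refinement> energy 11188.58 -> 962.55 kJ/mol (converged); constrained displacement 0.0 A

mol <- b$refinement$ligand_mol                      # fixed benzamidine-like ligand
mol_net_charge(mol)
#> [1] 1
ligand_properties(mol)
#> <plc_property_profile> MW 121.16 Da, clogP 2.20, TPSA 27.1 A^2, 1 rotatable, 9 heavy, HBD 2, HBA 2, QED 0.596
```

The entry directory now holds `protein_refined.pdb` (with `REMARK 99`
lines declaring every fixer-added atom), `ligand_fixed.sdf` (Kekulé
orders, formal charges in the charge block, explicit hydrogens) and
`additives.pdb`, side by side.

Affinity annotations normalize the same way:

```r
rec <- parse_affinity("Kd=2nM", entry_id = "1ABC", ligand_key = "ATP",
                      source = "biolip")
rec$delta_g
#> [1] -49.65379
```

A defective entry is rejected with evidence, not dropped silently:

```r
bad <- make_fixture(fixture_spec(seed = 2, defects = "create_clash"))
run_entry(fixture_entry(bad))
#> <plc_curation_result> 9XYZ: filter-rejected (1 bundle(s))
#>   L|1|: filter-rejected at filter [clash]
```

A thin CLI wrapping these functions ships in `inst/cli/plcurate`
(`curate`, `batch`, `fixture`, `affinity` subcommands).

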