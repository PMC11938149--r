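# nmrdock

NMR-guided assessment of protein–protein complex models.

Transient protein complexes — such as the one formed by the bacterial
cell-division inhibitor MinC and the tubulin homolog FtsZ — often
resist crystallography and cryo-EM, while solution NMR titrations
still report which residues feel the partner. `nmrdock` implements the
workflow that turns such titration data into a quantitative judge of
candidate complex structures (docking poses, AlphaFold-Multimer
predictions, MD snapshots):

1. **Chemical shift perturbations.** For each amide, the weighted
   distance in (¹H, ¹⁵N) shift space between apo and bound states,

   Δδ = √( (ΔδH)² + (ΔδN / 10)² )   [ppm]

   Peaks that vanish on titration are flagged *broadened beyond
   detectability* — evidence of intermediate-exchange binding that
   carries no measurable Δδ.
2. **Perturbed set.** Residues with Δδ ≥ σ (σ from an iterative
   3·SD-trimmed estimate or a fixed value, e.g. the 0.021 / 0.012 ppm
   used in published MinC/FtsZ work), plus broadened residues, form
   I_NMR.
3. **Model interface.** Residues of one partner with any atom
   (hydrogens included) within 5 Å of the other partner form I_pred.
4. **Scoring.** Interface coverage and error,

   C% = 100 · |I_pred ∩ I_NMR| / |I_pred|,
   E% = 100 · |I_pred \ I_NMR| / |I_pred|  (C + E = 100),

   and models are ranked by the C/E ratio (E = 0 ranks best, by C).
5. **Stability checks on trajectories.** Residue-pair contact
   frequencies (5 Å, any atom), hydrogen bonds (D–A ≤ 3 Å, deviation
   from linearity ≤ 20°), receptor-aligned ligand RMSD excluding
   disordered tails, and hierarchical clustering with the
   representative frame closest to the mean of the most populated
   cluster.

Supporting tools: Shrake–Rupley solvent-accessible and buried surface
area, polar/nonpolar contact classification, NOE restraint
categorization by sequence separation, mono-exponential relaxation
fits (R₁/R₂) with hetNOE ratios, mutation-concordance counting, and
seed-deterministic synthetic-data generators with known ground truth.

## Worked example

```r
library(nmrdock)

# a synthetic two-chain complex with 8 designed interface residues,
# and a titration in which those residues carry planted CSPs
cx  <- make_complex(n_res_a = 30, n_res_b = 30, n_contacts = 8, seed = 42)
tt  <- make_titration(cx$truth, effect = 0.06, noise = 0.00667,
                      broadened_fraction = 0.25, seed = 42)
csp <- compute_csp(tt$apo, tt$holo)          # Eq. above, alpha = 10
ps  <- perturbed_set(csp, sigma = 0.02, label = "partnerA")
ps
#> <perturbed_set> partnerA: 8 residues (sigma = 0.02 ppm)

# score the true pose and a decoy against the NMR-perturbed set
card  <- score_model(cx$structure, "A", "B", ps, ps, id = "true_pose")
decoy <- score_model(make_complex(30, 30, 8, seed = 99)$structure,
                     "A", "B", ps, ps, id = "decoy")
card
#> <score_card> true_pose: C = 100.0%, E = 0.0% (ratio Inf); A: 100.0/0.0, B: 100.0/0.0
decoy
#> <score_card> decoy: C = 25.0%, E = 75.0% (ratio 0.33); A: 25.0/75.0, B: 25.0/75.0
rank_models(list(decoy, card))[[1]]$id
#> [1] "true_pose"
```

The coverage of 100% says every interface residue of the true pose is
NMR-perturbed; the decoy places 75% of its interface on unperturbed
residues, so its C/E ratio collapses.

```r
# stability of the pose in a jittered trajectory that loses the
# interface at frame 9 of 10
tr <- make_trajectory(cx, n_frames = 10, jitter_sigma = 0.05,
                      escape_at = 9, seed = 1)
head(contact_frequency(tr$trajectory, "A", "B"), 3)
#>   resA resB frequency
#> 1    1    1        80
#> 2    4    4        80
#> 3    5    5        80
head(hbonds(tr$trajectory, "A", "B")[, c("donor", "acceptor", "frequency")], 2)
#>   donor acceptor frequency
#> 1 B:1:N    A:1:O        80
#> 2 B:4:N    A:4:O        80
round(ligand_rmsd_series(tr$trajectory, "chain A and backbone",
                         "chain B and backbone")$series, 2)
#>  [1]  0.00  0.09  0.10  0.09  0.09  0.09  0.09  0.09 25.00 25.00
cluster_frames(tr$trajectory, "chain B and backbone", threshold = 2,
               align_sel = "chain A and backbone")
#> <cluster_result> 2 cluster(s), sizes 8/2; representative frame 1
buried_area(cx$structure, "A", "B")
#> [1] 596.4518
```

Contacts and hydrogen bonds persist in 8 of 10 frames (80%), the
ligand RMSD jumps to 25 Å when the pose escapes, and clustering
recovers the bound conformation (8 frames) as the dominant state.

## Command line

Every step is scriptable; subcommands: `csp`, `perturbed`,
`interface`, `score`, `rank`, `concordance`, `sasa`, `contacts`,
`hbonds`, `rmsd`, `cluster`, `restraints`, `relax`, `simulate`,
`report`.

```sh
Rscript -e 'quit(status = nmrdock::nd_main())' --args \
  score --model modelA.pdb --chains-a A --chains-b B \
        --perturbed-a minc.json --perturbed-b ftsz.json --out score.json
```

(or use the launcher installed at `inst/cli/nmrdock`). Exit codes: 0
ok, 1 usage error, 2 data error. Each run writes a provenance sidecar
(`<out>.prov.json`) with input hashes and parameters; reruns on
identical inputs are byte-identical.

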