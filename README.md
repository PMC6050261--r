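# glycopose

Antibody–carbohydrate complexes are rarely crystallizable: anti-glycan
monoclonal antibodies bind weakly, glycans are flexible, and docking
alone produces thousands of plausible binding poses with no way to tell
which one is real. `glycopose` implements the computational half of a
combined strategy for this problem, using the anti-sialyl-Tn (STn,
Neu5Acα2–6GalNAcα) antibody system as its model: enumerate candidate
poses at scale, then let orthogonal experimental observables — ligand
stability in molecular-dynamics trajectories, saturation-transfer-
difference (STD) NMR enhancements, and glycan-microarray affinities —
select the single pose consistent with all of them, and finally screen
the validated complex against a glycome for off-target glycans.

It is aimed at structural glycobiologists and antibody engineers who
have docking output, trajectory snapshots, STD integrals and array
titrations in hand (or want to rehearse the full analysis on synthetic
data with known ground truth before committing to wet-lab inputs).

## What it computes

**Pose funnel.** A two-protocol docking campaign is bookkept in closed
form: 6 glycosidic rotamers of the α2–6 sialyl linkage (φ ∈ {−60°,
180°}, ω ∈ {−60°, 60°, 180°}) × 25 receptor snapshots × 20 poses =
3,000 rigid poses per receptor model, plus 3,000 flexible-ligand poses
per model — 12,000 screened in total. Poses are clustered at 2 Å ligand
RMSD with a density-based scan (minpoints = 1, which is exactly the
partition into connected components of the RMSD ≤ 2 Å graph); the
best-scoring member of the 20 most populated clusters per rotamer
(rigid) and the 50 top scorers (flexible) survive: 340 candidates.

**Stability filter.** For each candidate, the mean ligand heavy-atom
RMSF over the last 10 ns of simulation — each atom's root-mean-square
deviation from its time-averaged position, averaged over atoms — must
not exceed 1.0 Å; poses repositioning in the site are discarded.

**STD agreement.** Predicted STD enhancement of ligand proton *j* is a
frame-averaged proximity sum S_j = Σ_i r_ij⁻⁶ over receptor protons
within 8 Å, normalized to max = 100; agreement with the experimental
dataset is the Pearson correlation over shared proton labels. Survivors
are ranked by agreement, ties broken by docking rescore.

**Microarray quantification.** Apparent K_D by one-site specific
binding, B(C) = B_max·C/(K_D + C), fitted to 16-point titrations
(400–0.00256 nM); relative binding free energy ΔΔG = RT·ln(K_D/K_D,ref)
with R = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹ at 298.15 K; mutants classified as
minimal / destabilizing / stabilizing / undetectable.

**Carbohydrate grafting.** Glycome entries containing the antigen as a
subtree (exact residue, anomer and linkage-position matching — Neu5Gc
never matches a Neu5Ac core) are grown outward from the bound core with
a grid search over the new glycosidic torsions; entries whose every
embedding clashes with the receptor at all torsions are sterically
excluded, the rest are putative off-targets.

All of it runs on synthetic inputs from the package's generators, which
plant a true pose, stability labels, K_D values, fold changes and
core/extension labels, so every stage can be scored against ground
truth.

## Worked example

```r
library(glycopose)

stn <- parse_glycan("Neu5Ac(a2-6)GalNAc(a1-")
stn
#> <glycan_tree: 2 residues, root GalNAc> Neu5Ac(a2-6)GalNAc(a1-

length(enumerate_rotamers(stn))
#> [1] 6

expected_counts()
#>                          stage count
#> 1                     rotamers     6
#> 2    rigid_generated_per_model  3000
#> 3 flexible_generated_per_model  3000
#> 4          generated_per_model  6000
#> 5               total_screened 12000
#> 6     rigid_retained_per_model   120
#> 7  flexible_retained_per_model    50
#> 8               retained_total   340

# free-energy cost of swapping the terminal Neu5Ac for Neu5Gc,
# from the two apparent KDs (0.13 nM vs 132 nM)
round(ddG(132, 0.13), 2)
#> [1] 4.1

# recover a planted sub-nanomolar KD from a noisy synthetic titration
fit_one_site(make_titration(true_kd = 0.13, bmax = 3000, cv = 0.1, seed = 1))
#> <titration G1 (glycan): 64 points, KD = 0.131 nM>

# which attachment positions of the bound antigen does the pocket bury?
pp <- make_pocket_and_poses(seed = 1, n_decoy = 0)
occlusion_map(pp$receptor, pp$planted$structure, pp$core_tree)
#> [1] "Neu5Ac#1:O7" "Neu5Ac#1:O8" "Neu5Ac#1:O9" "GalNAc#2:O3" "GalNAc#2:O4"
```

The first output says the six α2–6 rotamers produce a 12,000-pose
campaign narrowed to 340 candidates; the ΔΔG of +4.1 kcal/mol
quantifies a ~1000-fold affinity loss; the fitted K_D lands on the
planted 0.13 nM; and the occlusion map shows the pocket burying the
sialic-acid glycerol arm and the GalNAc O3/O4 — so any glycome entry
extending the core at those positions cannot be an off-target.

`run_pipeline(pipeline_config(seed = 1))` chains everything end to end
on synthetic data (enumerate → cluster → select → stability → STD →
final ranking) and reports whether the planted pose was recovered.

## Documentation

The methods vignette (`vignettes/glycopose-methods.Rmd`) describes the
models, their assumptions, the synthetic-data design and the package's
numerical choices in detail.
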