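---
title: "Methods: pose selection and specificity analysis for antibody-glycan complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pose selection and specificity analysis for antibody-glycan complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopose)
```

# The problem

Anti-carbohydrate antibodies resist co-crystallization, so the 3-D
structure of an antibody-glycan complex is usually approached by
docking — which yields thousands of energetically plausible poses rather
than one answer. `glycopose` implements a funnel that lets orthogonal
observables do the selecting: molecular-dynamics stability, STD-NMR
proximity patterns, and microarray affinities each eliminate poses that
are inconsistent with them, until a single experimentally consistent
model remains. The validated complex is then used generatively, by
grafting larger glycome entries onto the bound antigen core to predict
off-target binding. The package's reference antigen is sialyl-Tn
(Neu5Acα2–6GalNAcα), a tumour-associated O-glycan, but every component
is parameterized by glycan trees and works for other antigens.

# Glycan model and 3-D building

Glycans are rooted labelled trees: residues carry a monosaccharide name,
anomeric configuration, anomeric-carbon position (C2 for sialic acids,
C1 otherwise) and optional modifications such as 9-O-acetylation; edges
carry the child anomeric carbon and parent attachment oxygen. The text
form (`"Neu5Ac(a2-6)GalNAc(a1-"`) is written non-reducing end first,
with branches bracketed. The canonical writer orders branches by
attachment position, descending, so parse-write-parse is the identity —
a property the test suite checks on branched cases.

3-D structures are assembled from idealized templates: a closed chair
ring (1.54 Å bonds, alternating pucker) with substituents on the
remaining tetrahedral directions and exocyclic chains placed by
natural-extension geometry. Bond lengths and angles are fixed; only the
glycosidic torsions vary. This is a deliberate simplification: the
downstream metrics (pose RMSD, RMSF, proton proximity sums, steric
overlap) depend on torsion semantics and coarse shape, not on
force-field-quality geometry, and the package never computes energies.
Stereochemistry is carried in residue and atom labels rather than exact
coordinates.

Torsion conventions follow the α2–6 sialyl definitions: φ over
C1–C2–O6′–C6′ (anomeric reference C1 for sialic acids, ring O5 for
aldoses) and ω over O6–C6–C5–O5 of the aglycon residue. The rotamer
library enumerates φ ∈ {−60°, 180°} × ω ∈ {−60°, 60°, 180°} for α2–6 —
the six solution rotamers of the sialyl-Tn linkage — and the
exo-anomeric φ well for other linkage classes. ψ is not part of the
library (the α2–6 rotamer description specifies only φ and ω); the
builder fixes it at −120° unless a torsion set names it explicitly. The
builder sets φ by rotation about the glycosidic bond after placement
and ω by rotation about the parent C5–C6 bond, so requested torsions
are reproduced exactly (the round-trip tolerance of 1° in the contracts
is loose). Non-bonded heavy-atom pairs closer than 1.0 Å abort a build
with the offending pair named; all six library rotamers of the
disaccharide build with every non-bonded pair beyond 1.5 Å.

# The pose funnel

`expected_counts()` keeps the campaign arithmetic honest: per receptor
model the rigid protocol generates rotamers × snapshots × poses-per-run
poses (6 × 25 × 20 = 3,000) and the flexible protocol 1 × 150 × 20 =
3,000 more; with two homology models, 12,000 poses are screened and
(6 × 20) + 50 = 170 per model, 340 in total, are retained.

Pose-pose distance is plain ligand heavy-atom RMSD in the common
receptor frame, with no re-superposition — docked poses share a frame by
construction, and hydrogens are excluded because their placement is
inferred. Clustering uses a density-based scan with eps = 2 Å and
minpoints = 1; with minpoints = 1 no point is noise and the DBSCAN
partition is provably the set of connected components of the
RMSD ≤ eps graph, which is how it is implemented (and how it is
verified, against a brute-force single-linkage oracle). Cluster order is
population descending, ties broken by better best member score and then
by id, so results are deterministic; the contracts say nothing about tie
order, and this choice is the package's own.

# Trajectory stability

The stability filter analyses the final window (default: last 10 ns) of
each pose's trajectory. Ligand RMSF is the per-atom root-mean-square
deviation from that atom's window-mean position, averaged without
weighting over ligand heavy atoms; poses with mean RMSF above 1.0 Å are
discarded. Two readings were open here: whether the cutoff applies to
the mean or the maximum per-atom RMSF, and whether frames should be
re-superposed first. The package adopts the mean (the quantity its
reports call "average RMSF") and assumes frames are pre-aligned, while
`rmsd_series()` and `ligand_rmsf()` both accept a receptor-atom `fit`
subset for inputs that are not; the ligand never enters the fit, since
the quantity of interest is motion relative to the binding site.

# STD prediction and agreement

The predicted STD enhancement of ligand proton *j* is
S_j = Σ_i r_ij⁻⁶ over receptor protons *i* within a cutoff (default
8 Å), averaged over trajectory frames when a window is supplied, then
normalized to a maximum of 100. This is a minimal proximity model — no
relaxation-matrix treatment, no saturation-time dependence — chosen
because the selection step only needs a monotone proxy for "how close is
this proton to the protein surface". Its two exact consequences anchor
the tests: a proton at distance r receives 2⁶ = 64 times the raw
enhancement of one at 2r, and predictions are invariant under rigid
motion of the whole complex. Hydrogens absent from the input are placed
with idealized tetrahedral geometry on carbons only (in D₂O experiments
exchangeable OH/NH protons are not observed). A pose with no receptor
proton within the cutoff of any ligand proton predicts all zeros; its
agreement is flagged undefined rather than raised as an error, so
screens over decoy ensembles proceed.

Agreement is the Pearson correlation between normalized predicted and
experimental intensities over shared proton labels (at least three
required), with normalized RMSD reported as a secondary diagnostic.
The final ranking excludes poses failing the RMSF or rescore
thresholds, sorts survivors by agreement descending with rescore as the
tie-break, and reports an explicit empty selection when nothing
survives.

# Microarray quantification

Apparent K_D comes from a least-squares fit of the one-site binding
model B(C) = B_max·C/(K_D + C) to replicate-averaged RFU over at least
four concentrations (the reference ladder is 16 geometric points from
400 to 0.00256 nM). Replicates are averaged before fitting, matching
how such arrays are printed (four spots per glycan); per-spot weighting
is not attempted. Initialization is deterministic: B_max₀ is the
maximum mean RFU and K_D₀ the concentration nearest half-maximum, with
a fallback grid over decades (10⁻³–10⁴ nM) if the first attempt fails.
A fit is flagged *undetectable* when it does not converge, when the
fitted K_D exceeds the top tested concentration more than 100-fold, or
when an F-test cannot distinguish the fitted curve from a flat response
at p ≤ 0.01 — the regime where an apparent K_D is simply not calculable
from the data. The F-test criterion is the package's answer to a real
failure mode: flat noise can converge numerically to a spurious small
K_D with a tiny B_max, and a pure convergence check does not catch it.

ΔΔG = RT·ln(K_D/K_D,ref) with R = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹ at
298.15 K (the assay temperature is not part of the data; room
temperature is assumed). Classification uses a ±0.5 kcal/mol band for
"minimal"; undetectable propagates without a number. The relative-RFU
ranking computes, per antibody concentration, each glycan's mean RFU as
a percentage of that concentration's maximum, ranks the percentages
(1 = strongest), and averages ranks across concentrations with their
SEM. Whether the original analysis averaged ranks or percentages is
ambiguous; ranks are the primary output and the mean percentages are
reported alongside.

# Carbohydrate grafting

`match_core()` finds every embedding of the antigen core in a glycome
entry under exact residue-name, anomer and linkage-position equality —
strictness that matters because the binding data itself distinguishes
Neu5Ac from Neu5Gc. Extensions are the subtrees hanging off matched
residues at positions the core leaves free, including the reducing-end
continuation below the core root (attachment position 1, the aglycon
direction).

`graft()` never moves the core. Each extension subtree is built from
templates at library-default internal torsions and attached at its
core position; the attaching linkage's φ and ψ are grid-searched within
±30° of the library values in 20° steps ("normal ranges" made
concrete), and the verdict uses the minimal clash score found. A
heavy-atom pair clashes when its distance falls below 0.6 × the sum of
van der Waals radii; the clash score is the summed overlap depth and
"fits" means the minimum over the grid is ≤ 0. Extensions are scored
independently against receptor plus core — they are disjoint subtrees,
and ignoring extension-extension contacts makes the per-extension
minimum exact while keeping the grid small. Because extension atoms only
ever add non-negative overlap terms, adding an extension can never
decrease the minimal clash score, a monotonicity the tests assert.

`occlusion_map()` asks the converse question — which attachment oxygens
could accept *any* extension: a carbon-sized probe is placed one bond
length from the oxygen along the chemically accessible cone of
next-atom directions (180° − 117° tilt, twelve azimuths), and the
position is occluded when every direction clashes. Receptor side chains
are held rigid throughout; whether the original grafting allowed
receptor relaxation is unstated, and rigid is the conservative choice
(it can only over-predict exclusion, never invent an off-target).

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of (seed, parameters) and define the
study conditions the tests run under:

* **Pocket and poses** — a pseudo-atom pocket is built around the
  antigen at one library rotamer: blocker atoms seal the designated
  occluded positions (glycerol-arm O7/O8/O9, GalNAc O3/O4 — the
  occlusion pattern of the sialyl-Tn complex, with the aglycon
  direction and Neu5Ac O4 left open), and carbon–proton contact pairs
  sit against the acetamido methyls and glycerol arm so the planted
  pose's predicted STD is dominated by those protons, as in the real
  epitope. Decoys are rigid copies rotated about their centroid and
  translated by at least the requested displacement; rotation about the
  centroid makes the translation length a lower bound on coordinate
  RMSD, so the "decoys ≥ displacement" guarantee is geometric, not
  sampled.
* **Trajectories** — stable poses jitter with per-coordinate Gaussian
  noise (σ = 0.231 Å by default, giving mean RMSF ≈ σ√3 ≈ 0.4 Å,
  matching the RMSF scale of retained poses); unstable poses add a
  linear drift of 0.8 Å/ns along a random direction, emulating a ligand
  walking out of the site. Default length 20 ns at 1 ns spacing — long
  enough to contain the 10 ns analysis window while keeping the full
  12,000-pose pipeline around a quarter of a minute of trajectory work;
  the filter statistics do not depend on the pre-window length.
* **Titrations** — mean-one multiplicative lognormal noise on the exact
  one-site curve (intensity data are positive and
  heteroscedastic-multiplicative); undetectable mutants emit flat
  lognormal noise near zero instead of a curve.
* **Glycomes** — entries with the core carry single-residue extensions
  at chosen position labels; core-free entries are drawn from related
  sialoglycans (Neu5Gc variants, α2–3 isomers) that exercise the
  strict-matching rules.

What the generators do **not** emulate: force-field physics (no
energies, no solvent), realistic NMR noise structure (no baseline or
overlap artefacts), receptor flexibility, and the composition statistics
of a real glycome. Tests passing on these conditions show the
*selection machinery* is correct — that planted signal of the stated
size is recovered — not that real MD/NMR/array data have that
signal-to-noise.

# Pipeline and problem sizes

`run_pipeline()` chains the stages on synthetic data: the campaign-shaped
ensemble (12,000 poses, with the true pose planted a handful of times in
one model's rigid run, the way docking re-finds a genuine minimum),
per-rotamer clustering and representative selection to 340, trajectories
with 80 planted-stable poses, the 1.0 Å RMSF filter, STD agreement
against a reference dataset generated from the planted pose's own
trajectory window (10% noise), and the final ranking. Everything derives
from one seed, and reruns are identical including report ordering. The
full campaign shape completes in well under a minute on one CPU; the
test suite runs the same configuration with 20 ns trajectories, and the
acceptance script repeats the label-recovery experiments over 20 seeds
(80 trajectories each), a 200-fit K_D recovery study, and a 100-entry
glycome screen.

# Known limitations

* Idealized templates mean built coordinates are cartoons: correct
  topology, torsions and coarse sterics, but not bond-level accuracy;
  grafting verdicts near the clash threshold inherit that coarseness.
* The STD proximity model ignores spin diffusion and saturation-time
  effects; it ranks poses, it does not predict quantitative
  enhancements.
* DBSCAN is implemented only for minpoints = 1 (the no-noise regime the
  funnel uses); other settings raise an informative error rather than
  silently approximating.
* The one-site fit averages replicates and so underuses per-spot
  variance; standard errors are asymptotic from the nonlinear fit.
* Multi-residue extensions are grafted with library-default internal
  torsions, grid-searching only the attaching linkage; deeply branched
  extensions could in principle relieve clashes through internal
  torsions the grid does not visit (the verdict is then conservative in
  the "blocked" direction).
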