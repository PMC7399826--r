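---
title: "Shape analysis of disordered-protein conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape analysis of disordered-protein conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confshape)
```

## The problem

Intrinsically disordered peptides do not fold into a single structure: in
solution they sample a broad ensemble of conformations ranging from
collapsed globules to highly elongated chains. Characterising such an
ensemble with a single observable is treacherous. The solvent-accessible
surface (SAS) area, a popular proxy for compactness, measures how much of
the molecule water can touch — a quantity that cavities and surface
roughness inflate, so conformations of very different shape can share a
SAS value. `confshape` instead characterises each conformation
*geometrically*, through the WHIM (Weighted Holistic Invariant Molecular)
descriptors, and builds the downstream ensemble analyses — distribution
deconvolution, free-energy landscapes, clustering against a bound-like
reference — on top of them.

## The WHIM descriptors

For a conformation with backbone coordinates $x_i \in \mathbb{R}^3$
(unit weights by default), the principal-component analysis of the
centred coordinates gives eigenvalues
$\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0$ (axis variances, nm²) and
per-atom scores $s_{im}$ (projections on axis $m$). The 13 descriptors
are:

* size: $\lambda_1, \lambda_2, \lambda_3$ and the global sizes
  $T = \sum_m \lambda_m$,
  $A = \lambda_1\lambda_2 + \lambda_1\lambda_3 + \lambda_2\lambda_3$,
  $V = \prod_m(1+\lambda_m) - 1 = T + A + \lambda_1\lambda_2\lambda_3$;
* shape: $\vartheta_m = \lambda_m / \sum_m \lambda_m$ for $m = 1, 2$, and
  the global shape index
  $$K = \frac{\sum_{m=1}^{3} \left|\lambda_m/\textstyle\sum_m\lambda_m - 1/3\right|}{4/3} \in [0, 1],$$
  which is 0 for a spherically isotropic cloud and 1 for a straight line;
* density: $\eta_m = 1/\kappa_m$ with
  $\kappa_m = (\sum_i s_{im}^4 / n)/\lambda_m^2$ the kurtosis of the axis-
  $m$ score distribution, and $D = (\eta_1+\eta_2+\eta_3)/3$.

$K$, $\vartheta$, $\eta$ and $D$ are scale-invariant; $\lambda$, $T$, $A$,
$V$ carry the nm² coordinate scale. All 13 are invariant under rigid
motion. Two numerical conventions are fixed for exact testability: the
covariance is normalised by $n$ (population convention — the descriptors
are statistical indices of the atomic score distribution, not estimators
of an underlying population), and eigenvector signs are fixed by making
each axis's largest-magnitude component positive. On rank-deficient
configurations (e.g. a strictly collinear chain) the $\eta_m$ of
zero-variance axes are undefined and reported as `NA` rather than
invented; the standalone `density_descriptors()` treats that case as an
error naming the axis.

The typography of the $K$ formula is read as the sum of the three absolute
deviations divided by $4/3$ — the only reading that maps a sphere to 0 and
a line to 1 with range $[0,1]$.

```{r}
whim_vector(make_collinear_chain(50)$xyz)["K"]       # straight line -> 1
whim_vector(make_isotropic_cloud(8, symmetrize = TRUE)$xyz)["K"]  # cube -> 0
```

## Units and input handling

Coordinates live in nanometres internally; PDB files (Ångström) are
converted at the I/O boundary (`read_multimodel_pdb()` /
`write_multimodel_pdb()`, one frame per `MODEL`). Van der Waals radii are
assigned per element (C 0.170, N 0.155, O 0.152, H 0.120, S 0.180 nm) and
can be overridden per call, since input files carry none. Backbone amide
hydrogens missing from the input are reconstructed at 0.10 nm from N,
opposing the bisector of the N→CA and N→C(prev) directions — a
deterministic standard placement; the first residue gets none.

## Solvent-accessible surface area

`sasa_total()` implements the Shrake–Rupley method: each atom's sphere,
expanded by the probe radius (default 0.14 nm, the standard water probe),
is sampled with a deterministic golden-spiral point set (default 960
points, accurate to well under 1 % at peptide scale and exactly
reproducible, unlike random sampling). A surface point is buried when it
falls strictly inside another expanded sphere; exact duplicate atoms are
tie-broken by index so they do not double-count area. The neighbour
search is a direct pairwise cutoff — at a few hundred backbone atoms per
conformation, asymptotically cleverer structures buy nothing. The kernel
is compiled (Rcpp) for per-frame throughput on 1000-frame ensembles.
Absolute SAS values depend on the radii set and algorithm, so published
means from other toolchains are comparable only up to a systematic
offset.

## Secondary structure

`assign_secondary_structure()` is a faithful-but-simplified
implementation of the Kabsch–Sander hydrogen-bond rules: the backbone
N–H···O=C bond is scored with the electrostatic model
$E = 0.084 \cdot 332 \cdot (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol (distances in Å, bond if $E < -0.5$; distances below 0.05 nm
are clamped and flagged). Turns at offsets 3/4/5 give G/H/I helices (two
consecutive turns), parallel/antiparallel bridge patterns give strand
(E, isolated bridges B), turn-bracketed residues are T, a change of
chain direction above 70° over Cα(i−2)→Cα(i)→Cα(i+2) is a bend S, and
the rest is coil, with priority H > E > B > G > I > T > S > C. Chirality
and π-helix refinements of later DSSP revisions are deliberately out of
scope. The eight classes reduce to the five reported categories
(H/G/I → Helix, E/B → Strand, T → Turn, S → Bend, C → Coil), and
`ss_fractions()` averages them over residues × frames (summing to 1 by
construction) plus per-residue profiles.

## Deconvolution of descriptor distributions

`fit_minimum_gaussians()` histograms the values and fits sums of
$k = 1, 2, \ldots$ Gaussian curves to the bin *densities* by
Levenberg–Marquardt least squares, returning the smallest $k$ whose
$R^2$ exceeds the threshold (default 0.990). This is deliberately a
curve fit, not likelihood-based mixture modelling: the $R^2$ criterion is
defined on the fitted curve. Initial means are quantile-spaced with ten
jittered restarts under an internal fixed seed (the caller's RNG stream
is untouched), components are reported sorted by mean, and fractions are
component areas over the total area — invariant to duplicating the
sample.

Binning matters. The Freedman–Diaconis rule is the default, but on
moderately sized samples (around $10^3$) of a bounded index it can yield
so few bins that no sum of Gaussians can reach the threshold, while many
more bins push multinomial noise into the fit. The pipeline therefore
bins the shape index K at a fixed 0.05 resolution — a natural granularity
for a [0, 1] index — via the `binwidth` option; $R^2$ is computed on
densities (counts would weight tall bins more; either is defensible, one
had to be fixed).

With finite samples the minimum-components rule may legitimately need
more than two Gaussians to clear the threshold on a bimodal but skewed
distribution. To read such a fit as a two-state population split,
`two_state_split()` integrates the fitted mixture on either side of its
antimode (or a supplied threshold) — the same interpretive step as
grouping fitted populations into compact and extended states, and robust
to how many components the rule selected.

## PCA spaces and projection

Two spaces are supported. *Essential dynamics* (`fit_pca_cartesian()`):
all frames are iteratively superposed to the ensemble mean structure
(Kabsch, two refinement rounds — the fitting reference is a free choice
and the mean is self-consistent), then PCA is applied to the flattened
Cα coordinates, unweighted, with the $n-1$ covariance convention.
*WHIM space* (`fit_pca_whim()`): the 13-descriptor matrix is autoscaled
(centred, divided by the sample sd) so descriptors of different magnitude
contribute equally, then PCA. PC signs follow the
largest-magnitude-loading-positive convention. `project_pca()` places
external items — a bound-like reference conformation, an independent
ensemble, a descriptor vector — into a fitted space, reproducing training
scores for training items; models serialise to JSON.

## Free-energy landscapes

`fel_from_points()` bins two collective variables (K/SAS, ED PC1/PC2,
WHIM PC1/PC2, …) into a 2D histogram (default 60 × 60) and sets
$G = -k_B T \ln P$ on occupied bins, shifted so the global minimum is
exactly 0 ($k_B = 0.0083144621$ kJ mol⁻¹ K⁻¹). Unoccupied bins stay
masked: imputing pseudo-counts would fabricate barriers. With a histogram
estimate, $\Delta G$ between occupied bins is exactly $-k_B T$ times the
log count ratio, which the tests exploit. Minima are strict local minima
over occupied 8-neighbours on the raw grid (no smoothing by default —
reproducibility over aesthetics).

The "pathway of minimal gradients" between two minima is operationalised
as the shortest path over occupied 8-connected cells minimising the
accumulated absolute energy change $\sum |\Delta G|$ (Dijkstra with a
deterministic lowest-index tie-break). This is one defensible reading of
a minimal-gradient pathway; steepest-descent or minimax-barrier variants
would be alternative operationalisations and the criterion is
intentionally isolated in one function. `basin_representatives()` pools
the frames within a Chebyshev bin radius of each minimum, clusters them
(GROMOS), and returns the largest cluster's centrotype.

## Superposition and clustering

`kabsch_rmsd()` computes the minimal RMSD over proper rotations and
translations via SVD (reflections excluded); the tests cross-check it
against an independent quaternion-method oracle. `gromos_cluster()`
implements the neighbour-counting algorithm: the frame with most
neighbours at RMSD strictly below the cutoff seeds a cluster, the cluster
is removed, and the count repeats — ties broken by lowest frame index
(the original leaves ties open; determinism is required here), clusters
numbered by decreasing size. `rmsd_filter()` retains frames strictly
below a cutoff from a reference (default 1.0 nm in the pipeline), the
usual prefilter before clustering against a bound-like structure. Whether
a published backbone RMSD uses N, CA, C, O with or without H is rarely
stated; the default selection here is the 5-atom backbone with a config
override.

## The synthetic ensemble generator

Real disordered-peptide trajectories are rarely deposited, so every stage
is validated against generated ensembles with known ground truth. The
generators are pure functions of their arguments including the seed.

* `make_collinear_chain()` / `make_isotropic_cloud(symmetrize = TRUE)`
  probe the exact K limits (line → 1; cube/octahedron vertex sets have
  exactly equal eigenvalues → 0).
* `make_ideal_helix()` builds a full backbone at φ = −57°, ψ = −47° with
  standard bond geometry, producing the canonical i → i+4 bond ladder;
  `make_extended_chain()` gives torsion-uniform chains (default fully
  extended, no internal bonds).
* `make_chain()` grows a self-avoiding Cα walk (step 0.38 nm, hard core
  0.30 nm) with step weights
  $\exp(p \cos\theta - b\,d_{\mathrm{centroid}})$: collapse bias $b$
  pulls toward the running centroid (globule), persistence $p$ favours
  locally straight continuation (worm-like-chain stiffness, elongated
  shapes). The trace is completed to an N, CA, C, O backbone by schematic
  standard geometry — shape-faithful, not hydrogen-bond-faithful, which
  is why secondary-structure tests use the torsion-built fixtures
  instead.
* `make_two_state_ensemble()` mixes an extended class (persistence 2.5,
  no bias) and a compact class (bias 8) at a tunable fraction (default
  0.7 extended / 0.3 compact, the two-state picture reported for
  disordered inhibitor domains by mass-spectrometry studies). The
  persistence makes the extended class genuinely elongated: a plain
  bias-0 random coil has a left-skewed K distribution overlapping the
  compact class, and a mixture of the two is not cleanly bimodal — it
  would misrepresent what the analysis is supposed to detect. With the
  defaults the class K distributions are separated by well over 2 pooled
  standard deviations (near-disjoint central 90 % ranges), which the
  test suite verifies.

What the generator does **not** emulate: sequence effects, realistic
secondary-structure propensities inside `make_chain()` output, solvent
physics, or temporal correlation between frames. Passing tests therefore
demonstrate the correctness of the descriptors and of the recovery
machinery on ensembles with planted structure — not force-field accuracy
on real peptides.

## The pipeline

`run_pipeline()` drives the full analysis from one declarative config
(`run_config()` in R or `read_run_config()` from YAML; every default is
recorded in the output `MANIFEST.json`): load → per-frame WHIM + SASA
table (+ optional secondary structure) → K and SAS deconvolution → FELs
in K/SAS, ED and WHIM spaces with minima and basin representatives →
minimal-gradient path between the two lowest WHIM-space minima →
reference projection into both PC spaces → RMSD filter + GROMOS
clustering of the bound-like pool. Numeric outputs are written at full
precision and are byte-identical across re-runs with the same config;
single-frame inputs stop after the descriptor table with the skips
logged. Default temperature is 400 K (the high-temperature sampling
regime the analysis targets); the FEL energy scale is the only place
temperature enters.

## Numerical choices and limitations

* Eigenvalue ties are broken by descending order; all tie-breaks
  (clustering, Dijkstra) prefer the lowest index, making every reported
  structure deterministic.
* Deconvolution is a histogram curve fit; for rigorous density estimation
  under label uncertainty an EM mixture model would be the tool — out of
  scope by design.
* The SASA numbers are totals; per-atom areas are available
  (`per_atom = TRUE`) but not validated against external per-residue
  references.
* Problem sizes used in the validation suite — 70-residue chains,
  1000-frame ensembles, $10^4$-sample deconvolutions, 100-trial oracle
  comparisons — were chosen so the full suite runs comfortably on a
  single CPU while leaving the statistical checks well powered.
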