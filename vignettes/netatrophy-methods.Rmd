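---
title: "Models and methods behind netatrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind netatrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netatrophy)
```

netatrophy analyses the *progression* of brain atrophy in a longitudinal
patient cohort and asks what shapes its spatial pattern: the brain's
structural and functional connectivity, the regional prevalence of cell
types, and regional gene expression. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions where
the methodology was genuinely open. It states no empirical result beyond
what the package's test suite and acceptance script themselves compute.

## W-score normative modelling

Deformation-based morphometry (DBM) summarizes, per brain parcel, the
volume ratio by which a subject's anatomy must expand or contract to
match a template (unitless, near 1). To separate disease effects from
normal ageing, deformation is standardized against healthy controls.
For each region, ordinary least squares on control baselines gives

$$W_i = \frac{\mathrm{DBM}_i - (\beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} + \beta_3)}{\mathrm{SD\ of\ control\ residuals}_i},$$

so `W = 0` means "exactly as expected for this age and sex", negative W
means atrophy. Choices to be aware of:

* **Controls at baseline only.** Only baseline control scans train the
  model; longitudinal control trajectories are out of scope.
* **Degrees of freedom.** The residual SD uses denominator $n-3$, the
  unbiased choice under the three-parameter model.
* **Sex coding.** Sex is coded 0 = female, 1 = male, recorded in the
  output metadata. W *differences* between sessions are invariant to
  this choice, as they are to any common affine rescaling of the
  deformation unit.
* **Finite-control bias.** With a finite control sample the estimated
  age slope carries error; because patients age between sessions, that
  error reappears as a small *shared longitudinal trend* in patient
  W-scores. The package's familywise-error simulations therefore fit
  the normative model at the full reference size (157 controls), where
  the induced trend is negligible; with very small control samples the
  progression test inherits a mild liberal bias that no permutation
  scheme downstream can remove.

Parcel-level rather than voxel-level W-scores are used throughout: every
statistic in scope operates on parcellated maps, and for a linear model
the two commute.

## Atrophy progression and regional inference

The progression score between baseline and a follow-up is
$-(W_{\text{follow-up}} - W_{\text{baseline}})$: positive = atrophy
accrued. Regional inference uses a one-way repeated-measures ANOVA
across sessions (subjects as blocks) after residualizing W on sex and
acquisition site — covariates are constant within subject, so the
residualization is fit once per region on the stacked data and the same
fitted value removed from every session, preserving within-subject
contrasts. Sites contributing a single subject are dropped from the
residualization with a warning.

"Time as a covariate" is ambiguous between a session factor and a
linear trend; the omnibus session-factor F is the default and a
linear-in-years trend contrast is available (`trend = TRUE`).

Familywise error across regions is controlled by **max-statistic
permutation**: session labels are permuted within subject, the maximum
F across regions recomputed per permutation, and each region's F
compared to that null (add-one convention). This is the regional
analogue of voxelwise FWE cluster inference, which is out of scope;
there is no regional analogue of a minimum-cluster-extent rule.
Benjamini–Hochberg FDR on the parametric p-values is reported
alongside, as are one-tailed paired post-hoc contrasts of baseline
against each follow-up.

Cortical-type comparisons use a one-way ANOVA over regions grouped into
the four cytoarchitectonic classes (idiotypic, unimodal, heteromodal,
paralimbic) with pairwise Welch t-tests, Bonferroni-adjusted over the
six pairs. Clinical change scores are related to progression summaries
by partial Spearman correlations (rank everything, residualize the
ranks of x and y on the covariate ranks, Pearson on the residuals,
t-approximation with $n-2-k$ df) with BH adjustment across the battery.

## Spin permutation nulls

Brain maps are spatially autocorrelated, so naive permutation nulls
overstate significance. The spin test preserves autocorrelation by
rigidly rotating the parcel centroids on the sphere: per spin a uniform
random rotation is applied to the left hemisphere and its sagittal
mirror image to the right, and each parcel is reassigned the value of
the nearest rotated parcel. Conventions:

* **p-value**: $p = (1 + k)/(1 + N)$ with $k$ the number of nulls at
  least as extreme; guarantees $p > 0$ and never undercounts the
  observed statistic. The plain $k/N$ convention is available
  (`convention = "raw"`); with 1000 spins the add-one minimum is
  ≈ 0.001.
* **Assignment**: `nearest` (duplicates allowed) is the default.
  `bijective` produces a strict permutation by greedy one-to-one
  matching in order of increasing distance; a globally optimal
  assignment would need a linear-assignment solver and changes nothing
  the package's tests measure, since every stated invariant (rows are
  permutations, rotations are isometries) holds for the greedy match.
* **Label-mean tests** (network means) permute the *labels*. Here the
  bijective method is the right tool: with nearest assignment small
  labels vanish under many spins, those spins are skipped, and the
  test becomes conservative. The package's calibration experiments
  (acceptance suite) use bijective spins for label means and the
  default for value reassignment, both of which reject at close to the
  nominal 5% on independent autocorrelated maps.
* Spin nulls are *approximately* calibrated, not exactly exchangeable;
  the suite tests type-I control rather than exact p-uniformity.
* Ties in nearest-centroid distance break to the lowest region index,
  making spins reproducible bit-for-bit given the seed.

## Connectome neighbourhood statistics

The network-spread hypothesis predicts that a region's atrophy
progression tracks that of its connected neighbours. Four neighbourhood
estimators are computed per region (self always excluded):

| estimator | neighbourhood | weights |
|---|---|---|
| `dSc` | structurally connected | equal |
| `dFcSc` | structurally connected | functional connectivity |
| `dFcNonSc` | structurally *unconnected* | functional connectivity |
| `dFcAll` | all other regions | functional connectivity |

Negative functional weights are kept by default (`clipped_fc` clips at
zero); weighted means with near-zero weight sums (magnitude < 1e-8) or
empty neighbourhoods are flagged missing rather than zeroed. The
node–neighbour Pearson correlation is tested against spins of the
atrophy map — the network stays fixed, and both node values and
neighbourhood estimates are recomputed from the spun map.

Pairs of these dependent, overlapping correlations (same atrophy vector,
two different predictors) are compared with Zou's confidence interval
for $r_1 - r_2$, built from back-transformed Fisher-z limits and the
estimated correlation between the two sample correlations; the
predictor-predictor correlation $r_{12}$ is computed from the data.
Degree-preserving (double-edge-swap) rewiring provides a negative
control network that keeps the degree sequence but destroys topology.
Whether structural neighbourhoods should use binary or weighted edges is
unstated in the methodology this follows; binary is the default and
weighted matrices are accepted.

## Virtual histology and gene screening

Cell-class scores are the mean z-scored expression of each class's
marker genes per region (seven classes: astrocytes, endothelial cells,
microglia, excitatory and inhibitory neurons, oligodendrocytes, OPCs);
the class score is correlated with progression and tested against spins
of the progression map. The gene-wise screen correlates every gene with
progression (Pearson by default, Spearman by flag), applies BH-FDR
across genes, computes a per-gene spin p from one shared set of spun
progression maps, and keeps genes passing *both* (FDR < α AND spin
p < 0.05, the joint reading of the selection rule), split by sign.

Overrepresentation of the surviving list against an annotation uses the
hypergeometric upper tail and the one-sided Fisher exact test — the same
tail, both reported and agreeing to numerical precision — with fold
enrichment = observed / expected overlap and Bonferroni adjustment over
the tested terms. The background is all screened genes; terms with
fewer than 5 background genes are skipped (degenerate folds).

## The synthetic-data generator

No patient imaging, reference connectome or donor expression data ship
with the package; a generator emulates the *structure* the analysis
assumes, with planted effects for recovery tests.

* **Atlas**: Fibonacci lattices on each unit hemisphere (mirror
  symmetric), Voronoi network patches around random seed directions,
  four cortical-type bands along a latitude gradient. Default 110
  parcels per hemisphere.
* **Connectome**: edges sampled with probability ∝ exp(−d/decay) on
  great-circle distance, calibrated to a target density of 0.10 with
  decay length 1.0 rad and resampled until connected. Tractography
  consensus networks at comparable resolution are sparse (on the order
  of 10% density) and retain genuine long-range projections; a short
  decay at higher density makes the graph a proximity lattice whose
  neighbourhood structure is indistinguishable from spatial smoothing,
  defeating the generator's purpose of producing *connectivity*-shaped
  (not merely distance-shaped) atrophy. FC is the normalized
  communicability of the structural graph plus symmetric noise,
  rescaled to [−1, 1].
* **Spread**: linear accumulation — per step each region gains
  `eta * vulnerability * (degree-normalized adjacency) %*% load`,
  seeded with unit load on a few regions. This is deliberately the
  simplest process guaranteed to couple atrophy to connectivity;
  it is not an epidemic/agent-based model. Defaults: eta 0.3, 2 steps
  per follow-up year, 3 random seed regions.
* **Cohort**: 157 controls (baseline only) and 74 patients over
  baseline/1/2/4 years; ages ~ N(60, 9.4²) truncated to [30, 85],
  70% male, four sites; deformation = 1.0 − 0.003·age + 0.02·sex +
  N(0, 0.05); patient follow-ups subtract
  `disease_effect_scale (1.5) × noise SD × spread pattern` normalized
  to its year-4 peak. Setting the effect scale to 0 yields an exact
  null cohort used by the calibration experiments.
* **Expression**: each gene a Gaussian random field on the sphere
  (squared-exponential kernel, length scale 0.3 rad) plus white noise,
  z-scored per gene; 1000 genes stand in for a ~15k-gene atlas at
  desk scale. Seven 25-gene classes share latent spatial patterns
  (loading 0.6). The regional vulnerability of the spread process is
  `exp(−γ · endothelial latent)` with γ = 1, planting the protective
  endothelial gradient the cell-type decoding should recover; 50
  signal genes track the resulting disease map (loading 0.7), and the
  annotation contains a positive-control term drawn from them plus a
  matched random negative-control term.

What the generator does *not* emulate: realistic tractography or BOLD
dynamics, voxel geometry, scanner/site effect structure beyond a label,
dropout/attrition, or empirical effect sizes. Passing recovery tests on
these data shows the estimators detect the structures they target at
realistic scale — not that real data contain them.

## Numerical and reproducibility choices

* One master seed; every stage derives a child seed from a stage tag,
  so stages are independently reproducible and the full pipeline is
  byte-identical across reruns (`runPipeline` is tested for this).
* Matrix symmetry is accepted within 1e-8 and symmetrized by
  averaging; centroids are renormalized within 1e-6 of unit length and
  rejected beyond; zero centroids are degenerate.
* Degenerate inputs error early and loudly: zero residual SD in
  controls, single-sex control cohorts, constant maps in correlations,
  empty neighbourhoods everywhere, annotation targets outside the
  background.
* Problem sizes in the shipped experiments — 220-region atlases,
  500–1000 spins, 200 calibration replicates, 500 permutations — were
  chosen as the smallest sizes at which the calibration bands and
  recovery rates under study are stable from seed to seed.

## Known limitations

* The spin test assumes parcels are well represented by spherical
  centroids; elongated parcels and the medial wall are not modelled.
* The greedy bijective matching is not the optimal assignment (it can
  differ for a few parcels per spin).
* The repeated-measures test assumes complete cases across sessions;
  subjects missing a session are excluded by construction.
* With very small control samples, W-score trends inherit normative
  estimation error (see above).
* The generator's planted effects are linear-Gaussian; heavy-tailed or
  nonlinear disease effects are untested territory.
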