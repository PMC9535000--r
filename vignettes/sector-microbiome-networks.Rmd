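---
title: "Methods: sector-resolved microbiome diversity and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sector-resolved microbiome diversity and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelnet)
```

`pelnet` analyses the spatial structure of paired water-column and sediment
microbiomes from a small coastal area: alpha-diversity sectors, phylogenetic
beta diversity against environmental gradients, co-abundance groups, and
sector-specific co-occurrence networks.  This vignette is the package's own
account of the methods: the models and their assumptions, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the methodology left room.

## Alpha diversity, quartiles, sectors, TIN

Shannon diversity is computed in nats (natural logarithm) from relative
abundances; only the quartile *ranks* of H feed the sector definitions, and
ranks are invariant to the logarithm base, so this choice cannot affect any
downstream conclusion.  No rarefaction is applied by default — the
`rarefy_depth` argument of `alpha_diversity()` makes the choice explicit
and seeded when depth standardisation is wanted.

Quartiles are assigned by rank, not by value cut-offs: samples are ordered
by H with ties broken by sample id, and split into four consecutive groups
whose sizes differ by at most one (19 samples give 5/5/5/4).  This makes
the assignment deterministic and invariant under monotone transforms of H.

Sectors are *user input*, not discovered: in practice they are drawn by
inspecting the interpolated diversity map, and automating that would invent
a method.  `validate_sectors()` instead checks a sector assignment against
quartile-composition rules (`sector_rule(sector, quartiles, min_fraction)`).
The conventional rule for the North-West sediment sector spans "the 2nd and
4th quartiles", which is ambiguous between {2,4} and {2,3,4};
`default_sector_rules("sediment")` uses the inclusive reading {2,3,4}, and
any other reading is one `sector_rule()` call away.

The diversity surface is interpolated with a TIN: Delaunay triangulation of
the station coordinates (Bowyer–Watson insertion, implemented in-package)
and barycentric-linear interpolation within each triangle, with no-data
outside the convex hull.  Coordinates are treated as planar; over a
~0.2° × 0.2° extent the projection error is far below the inter-station
spacing.  Interpolation is exact at the stations and reproduces affine
surfaces to 1e-9, which the tests assert.  Degenerate inputs (collinear
stations, duplicate points) are rejected rather than silently perturbed.

## Beta diversity and environmental screens

Unweighted UniFrac between two samples is the branch length leading
exclusively to taxa present in one of them, divided by the branch length
leading to taxa present in either (normalisation over *observed* lineages,
the classical formulation).  Presence means relative abundance strictly
greater than zero; no detection floor is imposed.  Taxa missing from the
tree are an error unless pruning is requested explicitly, because silent
pruning changes the distance.  The implementation (edge–tip incidence via
one postorder pass) is checked exactly against a brute-force per-branch
enumeration oracle on random trees.  Unweighted UniFrac is a semimetric;
`pcoa()` therefore reports negative eigenvalues, excludes them from the
returned axes, and computes variance fractions over the positive spectrum
only.  Axis signs follow a deterministic convention (largest-magnitude
coordinate positive).

PERMANOVA uses the one-factor pseudo-F computed directly from squared
distances, free permutation of sample labels (the design has no strata),
and the +1-corrected p-value p = (1 + #{F* ≥ F}) / (1 + n_perm), whose
floor at 999 permutations is 0.001.  Defaults: 999 permutations for
PERMANOVA, 9999 for Mantel tests; every permutation routine takes an
explicit seed.  Mantel tests correlate the vectorised upper triangles
(Spearman by default for community-vs-biochemistry comparisons) and permute
one matrix's rows and columns jointly.

The axis–environment screen reports both Pearson and Spearman correlations
per (axis, covariate) pair — the correlation flavour behind a reported "R"
is often unstated in field studies, so both are emitted — plus the linear
regression R², flagged against a biological-relevance threshold of 0.25.
Constant covariates yield an `undefined` flag, not an error.

Sediment trophic descriptors: total phytopigments are Chl-a plus
phaeopigments (µg/g); biopolymeric carbon converts proteins, carbohydrates
and lipids to carbon equivalents with 0.49, 0.40 and 0.75 mgC/mg and sums
them (mg/g).  Derived columns are always recomputed on load so a stored
table cannot contradict the defining identities.

## Co-abundance groups and over-abundance

Co-abundance is measured by Kendall tau-b (tie-corrected) with asymptotic
p-values and Benjamini–Hochberg q-values over the taxon pairs.  CAGs come
from Ward clustering (ward.D2) on a Spearman correlation distance.  Two
readings of that recipe exist: clustering taxa by the Spearman distance of
their abundance profiles (default, `cluster_input = "profiles"`), or
converting the Kendall matrix itself to distances 1 − τ
(`cluster_input = "kendall"`).  Both are implemented.  The distance is
1 − ρ (not √(1 − ρ), not 1 − |ρ|): anti-correlated taxa belong in different
groups, so sign must matter.  The number of groups defaults to the mean
silhouette maximum over k = 2..6, but `k = 3` reproduces the three-CAG
structure typical of this kind of order-level survey; CAGs are named by
their most abundant member, with pooled `Unassigned-*` bins kept in the
clustering but never lending their name.

Over-abundance of taxon j in sector s is O = meanArea/meanTot, the mean
relative abundance over the sector's samples divided by the mean over all
samples.  The sector-size weighted mean of O over sectors is identically 1
for every taxon, which the tests assert to 1e-12.  Display tiers follow the
Wiggum-plot convention: below 1 hidden, at or above 1.3 bold.  Network
exports (GraphML or edge-list TSV plus a node table) carry mean abundance,
over-abundance, CAG membership and edge signs, so any viewer can render
them; no plotting is built in.  Edges of the CAG-stage networks are the
Kendall correlations at q ≤ 0.05, the same false-discovery level used for
every other multiplicity-controlled decision in the pipeline.

## Sector co-occurrence networks

`infer_network()` is a *documented methodological substitute* for
conditional-independence tools (FlashWeave): centered-log-ratio transform
(pseudocount = half the minimum positive relative abundance), pairwise
Pearson association on CLR values, permutation p-values (each round permutes
the sample order once and evaluates all pairs), BH control at q ≤ 0.05,
then order-1 partial-correlation pruning — an edge is dropped if
conditioning on any single third taxon sends |partial r| below a threshold
(default 0.1).  Because the CLR transform is scale-invariant per sample,
the inferred edge set is exactly invariant to per-sample depth rescaling,
which the tests check.  The heterogeneous-data and meta-variable features
of the published tool are out of scope, and network provenance fields name
the method (`"sector-inference"`).

Hubs combine the highest degree, betweenness and closeness: nodes at or
above the 0.90 quantile of all three, computed on the unsigned skeleton of
the largest connected component (betweenness and closeness are ill-defined
across components).  If no node clears all three — or if *every* node does,
as in a perfectly symmetric ring — the single best node by summed
centrality ranks is returned with a `degenerate` flag.  Modules come from
seeded Louvain on unsigned weights; modularity of k equal disconnected
cliques is 1 − 1/k, which the tests use as a closed-form anchor.  "Total
connectivity" is reported as edges per node (a summary table's units cannot
be disambiguated without node counts, so density and mean degree are
emitted alongside).

Cohesion follows the taxon-shuffle null-model procedure: each taxon's
connectedness is the mean of its positive (respectively negative) pairwise
correlations with all other taxa, minus the mean of the same quantity under
shuffles of every taxon's abundances across samples; per-sample cohesion is
the abundance-weighted sum of connectedness, and the sector-level N:P ratio
is |mean negative cohesion| / mean positive cohesion.  Two contracts
deserve note.  First, the null-corrected side-wise connectedness can dip
slightly below zero — the package keeps it unclamped so that independent
data centre at zero (the calibration the tests assert); the uncorrected
sides do satisfy the sign constraints.  Second, when the corrected positive
cohesion is not positive the ratio is reported as `NA` with an
`np_infinite` flag instead of a misleading number.  Cohesion is computed
from the correlation matrix of relative abundances (the null-model
procedure's own definition), not from the inferred network;
compositional closure contributes a negative bias of order −1/(p−1) per
pair, which is negligible at realistic taxon counts but visible below ~10
taxa.

## The synthetic generator

`generate_dataset()` draws counts from a logistic-normal-multinomial: a
latent Gaussian log-abundance vector with block covariance is
softmax-transformed and sampled at a lognormal depth.  A Dirichlet would
not admit a plantable correlation structure, which the CAG stage needs.
Its components:

* **Baseline composition.** Per-realm taxon means are normal with standard
  deviation 2.5 on the log scale, wide enough that rare orders drop in and
  out of detection — unweighted UniFrac is driven entirely by
  presence/absence, so a generator without detection-boundary taxa would
  make every UniFrac distance collapse toward zero.
* **Blocks.** A factor model gives correlation ρ_within inside each of 3
  blocks and ρ_between across blocks (defaults 0.8 and 0).
* **Sectors.** Water sectors are three latitude bands
  (North/Central/South); sediment has a southern band plus a
  North-West/North-East split — axis-aligned partitions of the default
  bounding box (latitude 44.0687–44.2524, longitude 12.7229–12.9065),
  the simplest contiguous geometry for such an area.  Station
  coordinates are drawn uniformly inside their sector so every sector is
  populated with near-equal counts (19 water stations split 7/6/6).
  Sector s adds a log-fold shift (default 1.0) to block s.
* **Gradient.** A continuous north–south component multiplies per-taxon
  standard-normal loadings by the centred "northness" of each station;
  water depth, distance from coast and all five biochemical concentrations
  are increasing functions of the same northness plus noise, so composition
  and environment are genuinely coupled, as in the field data.
* **Hubs.** One hub per sector, placed on its block's most abundant members
  (water on odd abundance ranks, sediment on even ranks, so the realms use
  disjoint but comparably abundant taxa): inside the hub's sector, each of
  the (default 4) satellite taxa's latent *residuals* are replaced by
  `a·hub + sqrt(1−a²)·own` with coupling a (default 0.9).  Coupling acts on
  zero-mean residuals only, so planting a hub never shifts a satellite's
  marginal abundance — a coupling applied to the means would masquerade as
  a sector effect.  Hubs sit on abundant taxa deliberately: a "hub" whose
  counts are mostly zero is unrecoverable by any method and does not occur
  in practice, where reported hub orders are prominent community members.
* **Biochemistry.** Sediment concentrations are linear in northness with
  Gaussian noise, calibrated so that their means sit near values typical
  of north-western Adriatic shelf sediments (PRT ≈ 4.2, CHO ≈ 0.65,
  LIP ≈ 0.75 mg/g, Chl-a ≈ 1.2, phaeopigments ≈ 14.5 µg/g).
* **Phylogeny.** A random coalescent over the taxa; it carries no signal
  about the blocks, so UniFrac structure arises from presence patterns
  only.

One master seed feeds per-component substreams (`derive_seed`), making
every table bitwise reproducible and the components individually stable.

What the generator does **not** emulate: read-level error and chimera
processes, taxonomic mis-assignment, spatial autocorrelation beyond the
sector/gradient structure, non-Gaussian latent tails, and any realistic
phylogenetic conservation of ecological niche.  Passing recovery tests
therefore demonstrate that the estimators recover the structure they are
designed for under their own model class — not that field data of this size
would yield equally clean answers.

## Test and recovery conditions

The suite's problem sizes are chosen so each check isolates one planted
feature at a scale where the method is expected to work:

* **CAG recovery** uses the stated block conditions (3 blocks,
  ρ_within = 0.8, ρ_between = 0, n = 100 samples) and requires adjusted
  Rand index ≥ 0.9 against the planted partition.
* **Hub recovery** uses sectors of 100 samples (n_sediment = 300), 48 taxa,
  7 satellites, coupling 0.9, weak background (ρ_within = 0.15), no
  gradient, 2000 permutations and pruning threshold 0.35.  The reasoning:
  satellite–satellite correlations equal a² under the factor model, so the
  collider algebra makes their order-1 partials vanish while direct
  hub–satellite partials stay high — but CLR attenuation and finite-sample
  noise blur this, and the Benjamini–Hochberg step combined with the
  permutation-p floor (1/(B+1)) behaves as an all-or-nothing cliff when
  too few pairs can reach the floor.  One hundred samples per sector and
  B = 2000 put the star safely on the detectable side; the planted hub must
  be called in ≥ 90% of 100 seeded replicates.
* **Gradient recovery** uses gradient_effect = 2 with 30 water samples and
  screens a PCoA of Euclidean distances on CLR abundances: unweighted
  UniFrac reduces a quantitative gradient to presence shifts and is the
  wrong lens for this check, while the screen itself is
  ordination-agnostic.
* **Calibration** uses 1000 null PERMANOVA simulations (n = 12, 99
  permutations), 50 replicates of a 1000-feature two-group null screen,
  and 10 cohesion calibrations at 30 taxa × 40 samples.

These sizes keep the default suite around two minutes on one CPU while
leaving each check statistically meaningful.

## Numerical choices and limitations

Tables are serialised with 17 significant digits (`%.17g`), which
round-trips doubles bitwise; 12 digits would not.  Rank-based tests are
two-sided with mid-rank tie handling; the rank-sum test enumerates the
exact null when the pooled size is at most 12 and tie-free, matching the
behaviour of the standard R implementation it wraps.  Permutation p-values
always use the +1 correction.  Hierarchical clustering, quartile
assignment, hub tie-breaks and axis signs all break ties deterministically
(lexicographic ids), so reruns are identical.

Known limitations: the co-occurrence inference is a stand-in whose edge
sets should not be compared numerically with published FlashWeave networks;
unweighted UniFrac discards abundance information by design, so gradients
expressed in abundances (not presence) need a quantitative distance;
sector-level analyses with fewer than ~10 samples per sector frequently
produce empty networks under FDR control (reported honestly as zero-edge
summaries with degenerate-hub flags rather than being relaxed); and
modularity/cohesion of signed networks are computed on unsigned weights,
as the field's summary tables do.
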