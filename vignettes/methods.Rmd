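---
title: "Models and methods behind caulotraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caulotraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caulotraits)
```

caulotraits bundles the quantitative machinery of a comparative study of
dimorphic Caulobacterales bacteria into reusable, tested functions: a
single-cell lineage analysis of replicative asymmetry, a phylogeny-aware
screen for convergently lost gene modules, and a rule-based caller for
phototrophic genetic potential with photosynthesis gene-cluster (PGC)
detection. Because the original data (hundreds of genomes, manual
timelapse tracking) are not reproducible at desk scale, every analysis is
paired with a synthetic-data generator whose ground truth is known by
construction; all empirical claims in this vignette are the ones the test
suite and `scripts/acceptance.R` themselves compute.

## The dimorphic lifecycle simulator

Caulobacter-like cells alternate between a motile, non-reproductive
swarmer stage and a sessile, reproducing stalked stage. Each division of a
stalked cell yields one stalked-like daughter, immediately competent to
divide again, and one swarmer-like daughter that must first differentiate.
`simulate_lineage()` encodes exactly this: at every division event one
base generation time $T$ is drawn from the stalked distribution, the
stalked daughter divides after $T$, and the swarmer daughter after
$T + D$, where $D$ is the differentiation delay.

Two modeling choices deserve comment.

* **Gamma generation times.** Both $T$ and $D$ are gamma distributed with
  a given mean and coefficient of variation (CV). The gamma has strictly
  positive support, so no truncation is needed at small times, and its
  CV parameterization makes the deterministic limit (`cv = 0`) exact.
* **A shared base draw per division, plus small sibling jitter.**
  Sibling daughters share their mother, birth instant, and
  micro-environment, so their base timing is modeled as a single shared
  draw per division event; the differentiation delay is the systematic
  source of timing asymmetry. A small independent per-daughter jitter
  (`sibling_jitter_cv`, default 3% of the stalked mean) keeps sibling
  correlation high (~0.92) but imperfect, as real tracking shows — a
  fully shared draw would emit exact duplicate generation times per
  pair, which double-count evidence in downstream distribution fits. In
  the monomorphic limit (`swarmer_delay_mean = 0`) daughter pairs divide
  near-synchronously (median degree ≈ 0.03 at the defaults, exactly 0
  with the jitter at zero), the defining behavior of monomorphic strains
  in this analysis.

Observation effects are modeled explicitly: all event times are quantized
to the imaging interval (a division is first seen at the first frame at
or after it occurs), and cells that have not divided when tracking ends
are emitted with a censored flag rather than dropped, so downstream
pairing must handle censoring. Division-site placement is displaced by
`division_offset` toward the swarmer pole plus Gaussian noise; each cell
records which frame side its swarmer pole is, so the offset direction is
well defined across generations.

Defaults (all overridable): stalked mean 60 min, delay mean 30 min, both
CVs 0.1, division offset 0.07, position noise SD 0.02, imaging interval
5 min, duration 300 min, 50 founders. These are realistic magnitudes for
Caulobacter-like growth (total swarmer cycle ≈ 90 min, division site
displaced a few percent toward the swarmer pole, 5-min frames as used for
slow-growing strains); the constraint
`division_offset + 3 * position_noise_sd < 0.5` keeps positions inside
the cell.

## Degree of asymmetry and its summaries

For a mother whose daughters both divide at observed generation times
$t_1 \le t_2$, the degree of asymmetry is

$$\mathrm{degree} = \frac{\Delta t}{t_2}, \qquad \Delta t = t_2 - t_1,$$

i.e. how much extra time the late-dividing daughter spends to divide as a
fraction of its generation time — a growth-rate-independent measure.
`pair_asymmetry()` emits one record per mother with two non-censored
daughters; mothers with a censored daughter or a malformed daughter count
are excluded with explicit counters, never errors, because manually
tracked data always contain such cases. In the deterministic limit the
degree has the closed form $D/(T_s + D)$; with $T_s = 60$ and $D = 30$
every complete pair gives exactly $1/3$, which the tests verify, and the
sample median of $\Delta t$ recovers $D$ under noise.

Histograms follow the field's display conventions: half-open bins with a
right-most overflow bin pooling degrees above 50%, and generation times
above 150 min (fast growers) or 20 h (slow growers). Counts, overflow,
and exclusions always sum to the input size.

**Modality.** Whether a strain's pooled generation times are unimodal or
bimodal (the stalked/swarmer signature) is decided by fitting 1- and
2-component Gaussian location mixtures by EM (via mclust, which
initializes EM from model-based hierarchical clustering — a deterministic
and restart-robust scheme) and selecting by BIC. A mixture-based decision
was chosen over a dip test because the 2-component fit directly yields
the displayed peak separation estimate. Degenerate (zero-variance) input
short-circuits to a unimodal call; fewer than `min_n = 50` values is an
error rather than a silent call. The classifier is calibrated for the
hundreds-of-cells scale of tracking experiments; with many thousands of
values, BIC gains the power to resolve the mild skew of a single gamma
as a second Gaussian component, so modality should be assessed on
experiment-sized samples, not on arbitrarily large simulations. On the simulator's own dimorphic output
the classifier reports two components separated by ≈ the planted 30-min
delay.

**Constriction positions.** Snapshot displays of relative division-site
position are not sorted by cell polarity, so `constriction_summary()`
randomizes polarity (each $x$ becomes $x$ or $1-x$ with equal
probability, under a caller-supplied seed — never global state) before
binning into 100 bins. The mid-cell fraction is computed from the raw
positions as the share with $\min(x, 1-x) \ge 0.45$ (mid-cell ± 5%), and
a two-sample Kolmogorov–Smirnov test of the randomized positions against
their mirror image quantifies display symmetry (asymptotic p-values,
since quantized positions tie heavily).

## Presence/absence matrices and clade summaries

`build_matrix()` combines two evidence channels — KEGG-ortholog (KO)
annotations and reciprocal best hits (RBH) against a reference proteome —
as a union for presence while preserving the channel in a per-cell code
(absent / ko_only / rbh_only / both), matching heatmap displays that
overlay both annotations. Multi-copy genes collapse to presence. RBH
selection (`rbh_pairs()`) filters hits to `evalue <= 1e-3` first, then
requires mutual unique best hits, with ties broken by bitscore, then
e-value, then lexicographic subject id, so the output is deterministic
and a partial matching. Clade aggregation is the per-clade presence
fraction; genome size of incomplete assemblies is estimated as assembly
size divided by completeness (with percent/fraction auto-detection,
because upstream QC tools emit percents); environment summaries tally
category fractions over a controlled vocabulary with unknowns mapped to
"unclassified" so fractions sum to one.

## Convergent-loss screening

The screen formalizes "a module of genes specifically absent from
independent reduced lineages while conserved in their relatives":

1. **Focal lineages** are found by `discover_focal_sets()` as maximal
   monophyletic tip sets in which every genome lacks every marker family
   (e.g. all flagellar genes); singletons are allowed, since one absent
   genome nested inside a present clade is a legitimate candidate.
2. **Per family**, `co_loss_screen()` requires (a) background
   conservation — presence in at least `conservation_min` of non-focal
   genomes, (b) absence from every focal genome, and (c) at least as many
   phylogenetically independent loss events as focal lineages.
3. **Loss events** come from Dollo parsimony (`dollo_losses()`): a single
   gain fixed at the MRCA of present tips, below which losses are the
   stems of maximal absent subtrees — a unique minimal set, each event
   maximal so no event nests under another. Dollo is the default because
   ancestral presence is the biologically supported scenario for deeply
   conserved machinery; an unconstrained Fitch engine (`fitch_score()`)
   is retained for diagnostics. Both engines handle multifurcations
   (Fitch via intersection/union over all children). Families absent
   everywhere are flagged never-gained and skipped.

`conservation_min = 0.75` is a package default, not an empirical value:
it tolerates incomplete assemblies and sporadic loss in the background
while rejecting patchily distributed families. The tests verify exact
recovery of a planted 26-family module among 2000 background families on
200-tip trees in the noise-free case, and precision/recall above 0.9
with 5% background non-conservation plus 1% sporadic loss — conditions
chosen to resemble high-quality genome sets (completeness ≥ 90%).
The absence-category classifier (`classify_absence()`) separates
families absent only from the focal lineages from those also absent from
their close relatives (by default the remaining members of each focal
genus), mirroring the red/yellow display convention.

The planted-loss generator draws uniform coalescent trees (`ape::rcoal`);
the screens are topology-agnostic, so the tree distribution is a
simplicity choice. Focal clades are drawn disjoint with 3 tips up to ~5%
of the tree, keeping reduced lineages a minority as in real data.
Sporadic noise applies only to background families by default so the
planted truth stays exact; `noise_on_module = TRUE` enables robustness
experiments.

## Phototrophy calling and gene clusters

A genome is called a **phototroph** when its type II reaction-center core
(`pufL` AND `pufM`) is present and at least 4 of 15 bacteriochlorophyll
biosynthesis families (`bchB/C/D/E(acsF)/F/G/H/I/L/M/N/P/X/Y/Z`) are
found; it has **photoautotrophic potential** when the Calvin–Benson–
Bassham cycle is additionally complete, including the required RuBisCO
step. A genome with every CBB step except RuBisCO stays a phototroph with
a `near_complete_cbb_missing_rubisco` flag — the expected signature when
`cbbLS` falls on an unassembled contig edge. LH2 (`pucAB`) and
carotenoid (`crtCDF`) genes are recorded as evidence but do not gate the
call, since they co-occur with, rather than define, the photosystem. The
whole rule set ships as editable JSON (`inst/extdata/phototrophy_rules.json`);
no field-standard numeric rule exists, so these thresholds are package
decisions validated on synthetic truth only. Pathway completeness counts
steps, not genes: each step is a set of alternatives, each alternative an
AND-set of ids, so multi-subunit enzymes (cbbL + cbbS) cannot be
double-counted.

**Cluster detection** works in gene-index space: maximal runs of category
genes with at most `max_gap = 5` intervening non-category genes,
reported at `min_members = 5`. Gene-count distance (not bp) is robust to
intergenic length variation and matches the granularity of synteny maps.
Edge flags mark runs whose first/last member lies within `max_gap` genes
of a contig end — how an assembly-truncated cluster presents.
**Synteny** between regions is scored by shared family count, the
fraction of adjacent shared-family pairs of one region that remain
adjacent (either orientation) in the other, and strand agreement relative
to each region's majority frame (so a whole-cluster inversion scores 1).

The PGC generator plants a 40-gene cluster (25 photosynthesis genes,
plus LH2 and 15 CBB-block genes when `with_cbb = TRUE`) contiguously in
a background of 3800 housekeeping genes — the gene count of a typical
~4 Mb Caulobacterales genome at ~1 kb spacing. That density matters: the
null property that scattering the cluster's genes leaves nothing
detectable is a direct function of category-gene density, and at
realistic density chance clustering is negligible (the tests measure
≥ 95% zero-cluster rate over 100 shuffles). `split_at` moves the cluster
across two contig ends with internal order preserved, reproducing the
contig-edge case.

## Numerical and reproducibility conventions

* All times in minutes, coordinates 0-based half-open, TSV everywhere
  with mandatory headers; Newick is the only tree format (via ape, with
  duplicate tip labels rejected and basal multifurcations accepted with
  a warning).
* Every stochastic function takes an explicit seed and runs under a
  private RNG stream, restoring the caller's RNG state. The pipeline
  (`run_pipeline()`) derives one seed per stage from the root seed as
  `(seed * 13 + offset) mod (2^31 - 1)` and records it in the manifest;
  re-running an identical configuration reproduces identical output
  checksums, which the tests assert.
* File writes are atomic (temp file + rename), so a crashed run never
  leaves a partial file under a final name.
* Histogram bins are half-open `[lo, hi)` with values exactly at the
  overflow threshold kept in the last regular bin; ties in RBH selection
  break deterministically; `degree`'s denominator cannot vanish because
  division strictly after birth is enforced at validation.

## Problem sizes and limitations

The shipped tests and acceptance script run at deliberately chosen desk
scales: 200-tip trees with 2026 families (20 replicates for the noisy
screen), 100 random ≤ 8-tip trees with all binary patterns checked
against exhaustive enumeration, ≥ 500 daughter pairs for parameter
recovery, 100 seeded replicates for modality rates and scatter nulls.
These sizes make every property measurable in minutes while matching the
magnitudes of the motivating study (hundreds of species, hundreds of
tracked pairs).

What passing tests do **not** show: the generators emulate censoring,
quantization, sporadic loss, and assembly breaks, but not segmentation
errors, correlated loss of functionally linked background families,
annotation transfer errors between KO and RBH channels, or
contamination-driven false presences. Results on real data inherit the
quality of the upstream annotations and species tree, which this package
consumes but does not produce. The Dollo model excludes regain and
horizontal transfer by construction; families plausibly re-acquired
horizontally should be interpreted through the Fitch diagnostics instead.
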