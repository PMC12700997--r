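# caulotraits

Analytics for comparative studies of dimorphic *Caulobacterales*
bacteria. *Caulobacter crescentus* and its relatives divide
asymmetrically: a sessile stalked cell produces a motile swarmer daughter
that must differentiate before it can reproduce. Some lineages have
convergently lost this dimorphic lifecycle together with flagellar,
holdfast, and regulatory genes, and a surprising minority of the order
carries photosynthesis gene clusters. caulotraits packages the
quantitative methods such a study needs, each testable end-to-end on
synthetic data with known planted truth:

* **Replicative asymmetry from tracked lineages.** For daughter pairs
  with generation times t₁ ≤ t₂, the degree of asymmetry is
  Δt/t₂ with Δt = t₂ − t₁ — the extra time the late daughter spends to
  divide, as a fraction of its generation time. Plus overflow-binned
  histograms, Gaussian-mixture (EM + BIC) modality classification of
  generation times, and polarity-randomized constriction-position
  summaries (`pair_asymmetry`, `classify_modality`,
  `constriction_summary`).
* **Presence/absence matrices.** Genome × gene-family matrices from KEGG
  ortholog sets and reciprocal-best-hit evidence, with per-cell evidence
  codes, clade averaging, completeness-corrected genome-size estimation,
  and environment summaries (`build_matrix`, `rbh_pairs`,
  `aggregate_by_clade`, `estimated_genome_size`).
* **Convergent-loss screening.** Dollo parsimony loss inference on a
  species tree (single gain at the MRCA of present tips; losses = stems
  of maximal absent subtrees), Fitch diagnostics, discovery of
  marker-free focal clades, and a screen for modules absent from every
  focal lineage while conserved in the background with independently
  countable losses (`dollo_losses`, `fitch_score`,
  `discover_focal_sets`, `co_loss_screen`).
* **Phototrophy calling.** Rule-based calls (reaction-center core
  `pufL`+`pufM`, bacteriochlorophyll gene count, CBB-cycle completeness
  with RuBisCO required) with photosynthesis gene-cluster detection in
  gene-index space, contig-edge flags, and synteny scoring
  (`call_phototroph`, `detect_gene_cluster`, `cluster_synteny`).
* **Synthetic generators.** Dimorphic/monomorphic lineage forests with
  imaging quantization and censoring, random trees with planted
  clade-restricted loss modules, and annotated genomes with planted
  (optionally contig-split or scattered) photosynthesis gene clusters
  (`simulate_lineage`, `simulate_loss_matrix`,
  `simulate_annotated_genomes`).

## Worked example

Simulate a dimorphic strain tracked at 30-second frames for 7 hours,
then quantify its asymmetry:

```r
library(caulotraits)

tab <- simulate_lineage(dimorphic_params(
  stalked_gen_mean = 60, swarmer_delay_mean = 30,
  imaging_interval = 0.5, duration = 420, n_founders = 25,
  seed = 20260926))
pa <- pair_asymmetry(tab)
nrow(pa$records)                 # 429 complete daughter pairs
median(pa$records$degree)        # 0.335
median(pa$records$delta_t)       # 30 (min) -- the planted delay

gens <- na.omit(tab$division_time_min - tab$birth_time_min)
mc <- classify_modality(gens)
mc$n_components                  # 2
mc$peak_separation               # 29.8 (min)

constriction_summary(tab, seed = 99)$midcell_fraction   # 0.17
```

The median degree of asymmetry recovers the closed form
D/(T_s + D) = 30/90 ≈ 1/3; the pooled generation times are bimodal with
the two modes separated by the differentiation delay; and the off-center
division site (offset 0.07 from mid-cell) keeps most constrictions
outside the mid-cell ± 5% band. Running the same pipeline with
`swarmer_delay_mean = 0, division_offset = 0` gives the monomorphic
contrast: median degree 0.029, monomodal generation times, mid-cell
fraction 0.99.

The numbered scripts under `analysis/` run the full study on synthetic
data — `01_simulate.R` (generate lineages, a 200-tip tree with a planted
26-family loss module among 2000 background families, and a 20-genome
cohort with 2 planted photosynthesis gene clusters), `02_asymmetry.R`,
`03_convergent_loss.R` (the screen recovers the planted module with
precision and recall 1.0), and `04_phototrophy.R` (2/20 genomes called
photoautotrophic, split clusters edge-flagged) — writing tables under
`results/`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the simulator's
model and its assumptions, the screening rules and their defaults, the
numerical conventions, and the limitations of synthetic validation.
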