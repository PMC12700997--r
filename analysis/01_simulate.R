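#!/usr/bin/env Rscript
# Generate all synthetic inputs for the downstream analyses: dimorphic and
# monomorphic lineage tables, a species tree with a planted convergently
# lost gene module, and annotated genomes with planted photosynthesis gene
# clusters. Everything is seeded, so results/ is fully reproducible.

suppressPackageStartupMessages(library(caulotraits))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)
seed <- 20260926

# dimorphic (Caulobacter-like) and monomorphic (E. coli-like) timelapse
# tracking on 7 h pads; 30-s frames, the convention for strains with
# ~1 h generation times (5-min frames are for much slower growers, where
# quantization is negligible relative to the generation time)
# founder counts picked so the number of complete daughter pairs lands in
# the few-hundred range typical of manual tracking experiments
dim_tab <- simulate_lineage(dimorphic_params(
  imaging_interval = 0.5, duration = 420, n_founders = 25, seed = seed))
mono_tab <- simulate_lineage(dimorphic_params(
  swarmer_delay_mean = 0, division_offset = 0,
  imaging_interval = 0.5, duration = 300, n_founders = 25, seed = seed + 1))
write_lineage_tsv(dim_tab, "results/simulated/lineage_dimorphic.tsv")
write_lineage_tsv(mono_tab, "results/simulated/lineage_monomorphic.tsv")
message(sprintf("lineages: dimorphic %d cells (%d censored), monomorphic %d cells",
                nrow(dim_tab), sum(dim_tab$censored), nrow(mono_tab)))

# species tree with a 26-family module deleted from two independent clades
# over 2000 background families with mild sporadic loss
loss <- simulate_loss_matrix(planted_loss_spec(
  n_tips = 200, n_background_families = 2000, module_size = 26,
  focal_clades = 2, background_conservation = 0.95,
  sporadic_loss_rate = 0.01, seed = seed + 2))
write_newick(loss$tree, "results/simulated/species_tree.nwk")
write_matrix_tsv(loss$matrix, "results/simulated/presence_matrix.tsv")
writeLines(unlist(lapply(loss$truth$focal_tips, paste, collapse = "\t")),
           "results/simulated/focal_clades.txt")
writeLines(loss$truth$module_families,
           "results/simulated/planted_module.txt")
message(sprintf("planted-loss matrix: %d genomes x %d families, focal clades of %s tips",
                nrow(loss$matrix), ncol(loss$matrix),
                paste(lengths(loss$truth$focal_tips), collapse = " and ")))

# 20-genome cohort, 2 with a full PGC (incl. LH2 + CBB), one of them split
# across a contig edge
cohort <- simulate_annotated_genomes(planted_pgc_spec(
  n_genomes = 20, n_with_pgc = 2, seed = seed + 3))
write_annotation_tsv(cohort$annotations,
                     "results/simulated/annotations_cohort.tsv")
edge_case <- simulate_annotated_genomes(planted_pgc_spec(
  n_genomes = 1, split_at = 15, seed = seed + 4))
write_annotation_tsv(edge_case$annotations,
                     "results/simulated/annotations_contig_edge.tsv")
message(sprintf("genomes: cohort of %d (%d with PGC) plus 1 contig-edge case",
                20, 2))
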