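#!/usr/bin/env Rscript
# Phototrophy screen of the simulated genome cohort: per-genome calls,
# photosynthesis gene-cluster detection (including the contig-edge case),
# and synteny scoring between detected clusters. Run
# analysis/01_simulate.R first.

suppressPackageStartupMessages(library(caulotraits))
dir.create("results/phototrophy", recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation_tsv("results/simulated/annotations_cohort.tsv")
edge <- read_annotation_tsv("results/simulated/annotations_contig_edge.tsv")
rules <- load_phototrophy_rules()
pgc_fams <- c(default_pgc_order(), cbb_block())

scr <- screen_genomes(ann, rules)
write.table(scr$calls, "results/phototrophy/calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("cohort: %d/%d genomes with phototrophic potential (%.0f%%); levels: %s",
                sum(scr$calls$level != "none"), scr$n_genomes,
                100 * scr$fraction_phototrophic,
                paste(names(table(scr$calls$level)),
                      table(scr$calls$level), collapse = ", ", sep = "=")))

regions <- c(detect_gene_cluster(ann, pgc_fams),
             detect_gene_cluster(edge, pgc_fams))
reg_df <- do.call(rbind, lapply(regions, function(r)
  data.frame(genome_id = r$genome_id, contig_id = r$contig_id,
             first_index = r$first_index, last_index = r$last_index,
             n_members = r$n_members,
             left_at_contig_end = r$left_at_contig_end,
             right_at_contig_end = r$right_at_contig_end)))
write.table(reg_df, "results/phototrophy/pgc_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
n_edge <- sum(reg_df$left_at_contig_end | reg_df$right_at_contig_end)
message(sprintf("clusters: %d regions detected, %d truncated at a contig edge",
                nrow(reg_df), n_edge))

# pairwise synteny between all detected clusters
syn <- list()
for (i in seq_along(regions)) for (j in seq_along(regions)) {
  if (i >= j) next
  s <- cluster_synteny(regions[[i]], regions[[j]])
  syn[[length(syn) + 1]] <- data.frame(
    a = regions[[i]]$genome_id, b = regions[[j]]$genome_id,
    shared_families = s$shared_families,
    adjacency_conservation = s$adjacency_conservation,
    orientation_agreement = s$orientation_agreement)
}
if (length(syn)) {
  syn_df <- do.call(rbind, syn)
  write.table(syn_df, "results/phototrophy/synteny.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("synteny: mean adjacency conservation %.2f over %d pairs",
                  mean(syn_df$adjacency_conservation), nrow(syn_df)))
}
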