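#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the selected stages in dependency order — simulate lineages,
#' asymmetry statistics, simulate and screen a planted-loss matrix,
#' simulate genomes and run the phototrophy/cluster screen — writing each
#' stage's outputs (TSV/JSON) atomically under `out_dir` and a run
#' manifest recording the package version, a hash of the configuration,
#' the per-stage derived seeds, input checksums, and per-output row
#' counts and checksums. Re-running with an identical configuration and
#' seed reproduces identical output checksums.
#'
#' Every stochastic stage consumes exactly one seed derived from the root
#' seed as `(seed * 13 + stage_offset) mod (2^31 - 1)`, with offsets 1
#' (lineage), 2 (loss matrix), 3 (genomes), 4 (constriction polarity).
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `out_dir`; `seed`; `stages` (subset of `"lineage"`, `"asymmetry"`,
#'   `"loss"`, `"phototrophy"`); optional per-stage parameter lists
#'   `lineage`, `asymmetry`, `loss`, `phototrophy` (passed to
#'   [dimorphic_params()], the histogram functions,
#'   [planted_loss_spec()] / [co_loss_screen()], and
#'   [planted_pgc_spec()] / [detect_gene_cluster()] respectively);
#'   optional `inputs` list with a pre-existing `lineage` TSV path when
#'   the asymmetry stage runs without the simulation stage.
#' @return The run manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  out_dir <- config$out_dir %||% stop_param("config$out_dir is required")
  seed <- config$seed %||% stop_param("config$seed is required")
  stages <- config$stages %||% c("lineage", "asymmetry", "loss",
                                 "phototrophy")
  known <- c("lineage", "asymmetry", "loss", "phototrophy")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_param("unknown stages: %s", paste(bad, collapse = ", "))

  # validate referenced input paths before any stage runs
  inputs <- config$inputs %||% list()
  for (p in unlist(inputs))
    if (!file.exists(p)) stop_param("input path does not exist: %s", p)
  if ("asymmetry" %in% stages && !("lineage" %in% stages) &&
      is.null(inputs$lineage))
    stop_param("asymmetry stage needs the lineage stage or inputs$lineage")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_tmp, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)

  manifest <- list(
    tool = "caulotraits",
    version = as.character(utils::packageVersion("caulotraits")),
    config_hash = cfg_hash,
    seed = seed,
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    stages = list())
  log_msg <- function(...) message(sprintf(...))
  record <- function(stage, stage_seed, files, rows) {
    manifest$stages[[stage]] <<- list(
      seed = stage_seed,
      outputs = stats::setNames(
        lapply(files, function(f) unname(tools::md5sum(f))), basename(files)),
      rows = rows)
  }

  lineage_tab <- NULL
  if ("lineage" %in% stages) {
    s <- derive_seed(seed, 1)
    log_msg("stage lineage (seed %s)", s)
    lp <- do.call(dimorphic_params, c(config$lineage %||% list(),
                                      list(seed = s)))
    lineage_tab <- simulate_lineage(lp)
    f <- file.path(out_dir, "lineage.tsv")
    write_lineage_tsv(lineage_tab, f)
    record("lineage", s, f, nrow(lineage_tab))
  }

  if ("asymmetry" %in% stages) {
    log_msg("stage asymmetry")
    if (is.null(lineage_tab))
      lineage_tab <- read_lineage_tsv(inputs$lineage)
    ap <- config$asymmetry %||% list()
    pa <- pair_asymmetry(lineage_tab)
    f_rec <- file.path(out_dir, "asymmetry_records.tsv")
    write_tsv_atomic(pa$records, f_rec)
    h <- asymmetry_histogram(pa$records,
                             bin_width = ap$bin_width %||% 0.05,
                             overflow_threshold = ap$overflow_threshold %||% 0.5)
    gh <- generation_time_histogram(lineage_tab,
                                    bin_width = ap$gt_bin_width %||% 5,
                                    overflow_threshold = ap$gt_overflow %||% 150)
    f_h <- file.path(out_dir, "asymmetry_histogram.tsv")
    write_tsv_atomic(histogram_df(h), f_h)
    f_gh <- file.path(out_dir, "generation_time_histogram.tsv")
    write_tsv_atomic(histogram_df(gh), f_gh)
    cs <- constriction_summary(lineage_tab, seed = derive_seed(seed, 4))
    summary <- list(n_pairs = nrow(pa$records),
                    exclusions = as.list(pa$exclusions),
                    median_delta_t = stats::median(pa$records$delta_t),
                    median_degree = stats::median(pa$records$degree),
                    midcell_fraction = cs$midcell_fraction,
                    symmetry_p = cs$symmetry_p)
    gt <- lineage_tab$division_time_min - lineage_tab$birth_time_min
    gt <- gt[!is.na(gt)]
    if (length(gt) >= 50) {
      mc <- classify_modality(gt)
      summary$modality <- list(n_components = mc$n_components,
                               peak_separation = mc$peak_separation)
    }
    f_sum <- file.path(out_dir, "asymmetry_summary.json")
    write_json_atomic(summary, f_sum)
    record("asymmetry", NA, c(f_rec, f_h, f_gh, f_sum), nrow(pa$records))
  }

  if ("loss" %in% stages) {
    s <- derive_seed(seed, 2)
    log_msg("stage loss (seed %s)", s)
    lo <- config$loss %||% list()
    cons_min <- lo$conservation_min %||% 0.75
    lo$conservation_min <- NULL
    spec <- do.call(planted_loss_spec, c(lo, list(seed = s)))
    sim <- simulate_loss_matrix(spec)
    f_tree <- file.path(out_dir, "species_tree.nwk")
    write_newick(sim$tree, f_tree)
    f_mat <- file.path(out_dir, "presence_matrix.tsv")
    write_matrix_tsv(sim$matrix, f_mat)
    mod <- co_loss_screen(sim$matrix, sim$tree, sim$truth$focal_tips,
                          conservation_min = cons_min)
    f_mod <- file.path(out_dir, "convergent_module.tsv")
    write_tsv_atomic(mod$report, f_mod)
    record("loss", s, c(f_tree, f_mat, f_mod), nrow(mod$report))
  }

  if ("phototrophy" %in% stages) {
    s <- derive_seed(seed, 3)
    log_msg("stage phototrophy (seed %s)", s)
    ph <- config$phototrophy %||% list()
    max_gap <- ph$max_gap %||% 5
    min_members <- ph$min_members %||% 5
    ph$max_gap <- NULL; ph$min_members <- NULL
    spec <- do.call(planted_pgc_spec, c(ph, list(seed = s)))
    sim <- simulate_annotated_genomes(spec)
    f_ann <- file.path(out_dir, "annotations.tsv")
    write_annotation_tsv(sim$annotations, f_ann)
    scr <- screen_genomes(sim$annotations)
    f_calls <- file.path(out_dir, "phototrophy_calls.tsv")
    write_tsv_atomic(scr$calls, f_calls)
    regs <- detect_gene_cluster(sim$annotations, sim$cluster_families,
                                max_gap = max_gap,
                                min_members = min_members)
    reg_df <- if (length(regs)) do.call(rbind, lapply(regs, function(r)
      data.frame(genome_id = r$genome_id, contig_id = r$contig_id,
                 first_index = r$first_index, last_index = r$last_index,
                 n_members = r$n_members,
                 families = paste(r$families, collapse = ","),
                 left_at_contig_end = r$left_at_contig_end,
                 right_at_contig_end = r$right_at_contig_end,
                 stringsAsFactors = FALSE)))
      else data.frame(genome_id = character(0), contig_id = character(0),
                      first_index = integer(0), last_index = integer(0),
                      n_members = integer(0), families = character(0),
                      left_at_contig_end = logical(0),
                      right_at_contig_end = logical(0))
    f_reg <- file.path(out_dir, "pgc_regions.tsv")
    write_tsv_atomic(reg_df, f_reg)
    record("phototrophy", s, c(f_ann, f_calls, f_reg), nrow(reg_df))
  }

  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# histogram object -> TSV-ready data.frame (bin_lo, bin_hi, count), with
# the overflow pool as a final open-ended row
histogram_df <- function(h) {
  edges <- h$bin_edges
  df <- data.frame(bin_lo = edges[-length(edges)],
                   bin_hi = edges[-1],
                   count = h$counts)
  if (!is.null(h$overflow_threshold))
    df <- rbind(df, data.frame(bin_lo = h$overflow_threshold,
                               bin_hi = Inf,
                               count = h$overflow_count))
  df
}
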