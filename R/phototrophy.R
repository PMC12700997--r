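#' Define a stepwise pathway for completeness scoring
#'
#' A pathway is an ordered list of steps; each step is satisfied when any
#' one of its alternatives is fully present, where an alternative is a set
#' of family ids that are all required together (so multi-subunit enzymes
#' like RuBisCO `cbbL` + `cbbS` form one step, preventing subunit
#' double-counting). Steps marked required gate "complete" calls.
#'
#' @param name Pathway name.
#' @param steps List of steps; each step a list with `name`,
#'   `alternatives` (list of character vectors), and optional `required`
#'   flag.
#' @return A validated list of class `pathway_def`.
#' @export
pathway_def <- function(name, steps) {
  if (!length(steps)) stop_param("pathway '%s' has no steps", name)
  steps <- lapply(steps, function(s) {
    alts <- lapply(s$alternatives, as.character)
    if (!length(alts) || any(!lengths(alts)))
      stop_param("step '%s' needs non-empty alternatives", s$name %||% "?")
    list(name = as.character(s$name %||% "step"),
         alternatives = alts,
         required = isTRUE(s$required))
  })
  structure(list(name = name, steps = steps), class = "pathway_def")
}

#' Pathway completeness of a KO set
#'
#' @param ko_set Character vector of family/KO ids present in a genome.
#' @param pathway A [pathway_def()].
#' @return A list: `completeness` (satisfied steps / total steps),
#'   `step_present` (named logical per step), `required_ok` (all required
#'   steps satisfied).
#' @export
pathway_completeness <- function(ko_set, pathway) {
  stopifnot(inherits(pathway, "pathway_def"))
  sat <- vapply(pathway$steps, function(s)
    any(vapply(s$alternatives, function(a) all(a %in% ko_set), logical(1))),
    logical(1))
  names(sat) <- vapply(pathway$steps, `[[`, character(1), "name")
  req <- vapply(pathway$steps, `[[`, logical(1), "required")
  list(completeness = mean(sat),
       step_present = sat,
       required_ok = all(sat[req]))
}

#' Load the phototrophy rule configuration
#'
#' Reads the editable JSON rule set gating phototrophy calls: the
#' reaction-center core requirement (`pufL` AND `pufM`), the
#' bacteriochlorophyll-synthesis family list with its minimum count, the
#' LH2 and carotenoid families recorded as evidence, and the CBB-cycle
#' pathway definition with RuBisCO as the required step.
#'
#' @param path Path to a rules JSON; default: the configuration shipped
#'   with the package.
#' @return A list of class `phototrophy_rules`.
#' @export
load_phototrophy_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "phototrophy_rules.json",
                                package = "caulotraits")
  r <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("rc_core", "bch_entries", "bch_min", "cbb")
  miss <- setdiff(need, names(r))
  if (length(miss))
    stop_param("malformed rules: missing %s", paste(miss, collapse = ", "))
  rules <- list(
    rc_core = vapply(r$rc_core, as.character, character(1)),
    bch_entries = lapply(r$bch_entries, function(e)
      vapply(e, as.character, character(1))),
    bch_min = as.integer(r$bch_min),
    lh2_families = vapply(r$lh2_families %||% list(), as.character,
                          character(1)),
    carotenoid_families = vapply(r$carotenoid_families %||% list(),
                                 as.character, character(1)),
    cbb = pathway_def(r$cbb$name %||% "CBB", r$cbb$steps)
  )
  class(rules) <- "phototrophy_rules"
  rules
}

#' Call phototrophic and photoautotrophic genetic potential
#'
#' A genome is called a phototroph when its reaction-center core (`pufL`
#' AND `pufM`) is present and it carries at least `bch_min`
#' bacteriochlorophyll-synthesis families; it is upgraded to
#' photoautotrophic potential when the CBB cycle is additionally complete,
#' including the required RuBisCO step. A genome satisfying every CBB step
#' except RuBisCO stays a phototroph with the
#' `near_complete_cbb_missing_rubisco` flag raised (the pattern expected
#' when `cbbLS` falls on an unassembled contig edge). LH2 (`pucAB`) and
#' carotenoid (`crtCDF`) families are recorded as evidence but do not
#' gate the call.
#'
#' @param ko_set Character vector of family/KO ids present in the genome.
#' @param rules A `phototrophy_rules` object
#'   (default: [load_phototrophy_rules()]).
#' @return A list of class `phototrophy_call`: `level` (`"none"`,
#'   `"phototroph"`, `"photoautotroph_potential"`), `evidence`,
#'   `cbb_completeness`, `flags`.
#' @export
call_phototroph <- function(ko_set, rules = load_phototrophy_rules()) {
  stopifnot(inherits(rules, "phototrophy_rules"))
  rc <- stats::setNames(rules$rc_core %in% ko_set, rules$rc_core)
  bch_hit <- vapply(rules$bch_entries, function(e) any(e %in% ko_set),
                    logical(1))
  cbb <- pathway_completeness(ko_set, rules$cbb)
  req <- vapply(rules$cbb$steps, `[[`, logical(1), "required")
  non_req_complete <- all(cbb$step_present[!req])
  phototroph <- all(rc) && sum(bch_hit) >= rules$bch_min
  flags <- character(0)
  if (phototroph && non_req_complete && !cbb$required_ok)
    flags <- c(flags, "near_complete_cbb_missing_rubisco")
  level <- if (!phototroph) "none"
           else if (cbb$completeness == 1 && cbb$required_ok)
             "photoautotroph_potential"
           else "phototroph"
  structure(list(
    level = level,
    evidence = list(rc_core = rc,
                    bch_count = sum(bch_hit),
                    bch_present = bch_hit,
                    lh2 = stats::setNames(rules$lh2_families %in% ko_set,
                                          rules$lh2_families),
                    carotenoid = stats::setNames(
                      rules$carotenoid_families %in% ko_set,
                      rules$carotenoid_families)),
    cbb_completeness = cbb$completeness,
    flags = flags), class = "phototrophy_call")
}

#' Screen a genome cohort for phototrophic potential
#'
#' Applies [call_phototroph()] per genome and reports cohort counts and
#' the fraction of genomes with phototrophic potential, optionally broken
#' down by clade.
#'
#' @param ko_sets Named list (by genome id) of family/KO id vectors, or an
#'   annotation data.frame with `genome_id` and `family_id` columns (KO
#'   sets are then the distinct families per genome).
#' @param rules A `phototrophy_rules` object.
#' @param taxon_map Optional named vector genome id -> clade label for
#'   per-clade fractions.
#' @return A list: `calls` (data.frame: `genome_id`, `level`,
#'   `cbb_completeness`, `flags`), `fraction_phototrophic`, `n_genomes`,
#'   and `by_clade` (or `NULL`).
#' @export
screen_genomes <- function(ko_sets, rules = load_phototrophy_rules(),
                           taxon_map = NULL) {
  if (is.data.frame(ko_sets)) {
    stopifnot(all(c("genome_id", "family_id") %in% names(ko_sets)))
    ko_sets <- lapply(split(ko_sets$family_id, ko_sets$genome_id), unique)
  }
  ids <- names(ko_sets)
  if (is.null(ids) || anyDuplicated(ids))
    stop_param("duplicate or missing genome ids")
  calls <- lapply(ko_sets, call_phototroph, rules = rules)
  df <- data.frame(
    genome_id = ids,
    level = vapply(calls, `[[`, character(1), "level"),
    cbb_completeness = vapply(calls, `[[`, numeric(1), "cbb_completeness"),
    flags = vapply(calls, function(cl)
      paste(cl$flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  pho <- df$level != "none"
  by_clade <- NULL
  if (!is.null(taxon_map)) {
    cl <- taxon_map[df$genome_id]
    by_clade <- do.call(rbind, lapply(split(pho, cl), function(v)
      data.frame(n = length(v), n_phototrophic = sum(v),
                 fraction = mean(v))))
    by_clade <- cbind(clade = rownames(by_clade), by_clade)
    rownames(by_clade) <- NULL
  }
  list(calls = df,
       fraction_phototrophic = mean(pho),
       n_genomes = length(ids),
       by_clade = by_clade)
}
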