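#' Read a rooted tree from a Newick file
#'
#' Thin wrapper over \pkg{ape} with the package's contracts: duplicate tip
#' labels are rejected; a trifurcating (unrooted-style) root is accepted
#' as a multifurcation with a warning; branch lengths are preserved but
#' unused downstream.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_param("could not parse Newick file: %s", path)
  if (anyDuplicated(tree$tip.label))
    stop_param("duplicate tip labels in %s", path)
  if (!ape::is.rooted(tree))
    warning("tree has a basal multifurcation; treating as rooted with ",
            "a multifurcating root", call. = FALSE)
  tree
}

#' Write a tree as Newick
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ape::write.tree(tree, file = tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write / read a lineage table as TSV
#'
#' Tab-separated, UTF-8, '.' decimal separator, mandatory header; the
#' censored division time is written as an empty field.
#' @param table A lineage table.
#' @param path File path.
#' @return `write_lineage_tsv`: the path, invisibly; `read_lineage_tsv`:
#'   a validated `lineage_table`.
#' @export
write_lineage_tsv <- function(table, path) {
  write_tsv_atomic(as.data.frame(table), path)
}

#' @rdname write_lineage_tsv
#' @export
read_lineage_tsv <- function(path) {
  tab <- read_tsv(path, colClasses = c(cell_id = "character",
                                       parent_id = "character"))
  tab$parent_id[tab$parent_id == ""] <- NA_character_
  validate_lineage(tab)
  class(tab) <- c("lineage_table", "data.frame")
  tab
}

#' Write / read a presence matrix as TSV
#'
#' Rows are genomes (first column `genome_id`), columns are families;
#' values are evidence codes 0-3 or plain 0/1.
#' @param matrix Presence matrix.
#' @param path File path.
#' @return `write_matrix_tsv`: the path, invisibly; `read_matrix_tsv`:
#'   an integer matrix of class `presence_matrix`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(genome_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE,
                 colClasses = c(genome_id = "character"))
  if (anyDuplicated(df$genome_id))
    stop_param("duplicate genome ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$genome_id
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Write / read a genome annotation table as TSV
#'
#' Columns: `genome_id`, `contig_id`, `gene_index`, `start`, `end`
#' (0-based, half-open), `strand`, `family_id`.
#' @param annotation Annotation data.frame.
#' @param path File path.
#' @return `write_annotation_tsv`: the path, invisibly;
#'   `read_annotation_tsv`: the annotation data.frame.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write_tsv_atomic(annotation, path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  read_tsv(path, colClasses = c(genome_id = "character",
                                contig_id = "character",
                                family_id = "character"))
}

#' Validate interchange tables against their schemas
#'
#' Checks headers, types, and row-level invariants of TSV inputs without
#' raising on data errors; all violations are aggregated with line
#' numbers (line 1 is the header, so data line `k` is file line `k + 1`).
#'
#' @param paths Character vector of file paths.
#' @param schemas Character vector (recycled) naming each file's schema:
#'   `"lineage"`, `"matrix"`, or `"annotation"`.
#' @return A data.frame report: `path`, `line`, `message`; zero rows if
#'   everything is well-formed.
#' @export
validate_tables <- function(paths, schemas) {
  schemas <- rep_len(schemas, length(paths))
  out <- list()
  note <- function(path, line, msg)
    out[[length(out) + 1L]] <<- data.frame(path = path, line = line,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) { note(p, NA, "file does not exist"); next }
    sch <- schemas[i]
    tab <- tryCatch(read_tsv(p, check.names = FALSE),
                    error = function(e) NULL)
    if (is.null(tab)) { note(p, NA, "unparseable TSV"); next }
    if (sch == "lineage") {
      req <- c("cell_id", "parent_id", "birth_time_min",
               "division_time_min", "censored")
      miss <- setdiff(req, names(tab))
      if (length(miss)) {
        note(p, 1, paste("missing columns:", paste(miss, collapse = ", ")))
        next
      }
      dup <- which(duplicated(tab$cell_id))
      for (k in dup) note(p, k + 1, "duplicate cell_id")
      known <- tab$cell_id
      bad_par <- which(!is.na(tab$parent_id) & tab$parent_id != "" &
                         !(tab$parent_id %in% known))
      for (k in bad_par) note(p, k + 1, "parent_id not found")
      bad_t <- which(!is.na(tab$division_time_min) &
                       tab$division_time_min <= tab$birth_time_min)
      for (k in bad_t) note(p, k + 1,
                            "division_time_min <= birth_time_min")
    } else if (sch == "matrix") {
      if (names(tab)[1] != "genome_id") {
        note(p, 1, "first column must be genome_id")
        next
      }
      dup <- which(duplicated(tab$genome_id))
      for (k in dup) note(p, k + 1, "duplicate genome_id")
      vals <- as.matrix(tab[, -1, drop = FALSE])
      bad <- which(!(vals %in% c(0, 1, 2, 3)))
      if (length(bad))
        note(p, (bad[1] - 1) %% nrow(vals) + 2,
             "matrix values must be evidence codes 0-3")
    } else if (sch == "annotation") {
      req <- c("genome_id", "contig_id", "gene_index", "start", "end",
               "strand", "family_id")
      miss <- setdiff(req, names(tab))
      if (length(miss)) {
        note(p, 1, paste("missing columns:", paste(miss, collapse = ", ")))
        next
      }
      bad <- which(tab$start >= tab$end)
      for (k in bad) note(p, k + 1, "start must be < end")
    } else {
      note(p, NA, paste("unknown schema:", sch))
    }
  }
  if (!length(out))
    return(data.frame(path = character(0), line = numeric(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
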