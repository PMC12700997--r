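#' Pair daughter cells and compute degrees of replicative asymmetry
#'
#' For every mother whose two daughters both have observed (non-censored)
#' division times, computes the daughters' generation times `t1 <= t2`
#' (each measured from their shared birth at the mother's division), the
#' time difference `delta_t = t2 - t1`, and the degree of asymmetry
#' `delta_t / t2` — how much extra time the late-dividing daughter spends
#' to divide, as a fraction of its generation time. The result is
#' invariant to daughter labeling and to input row order.
#'
#' Mothers with at least one censored daughter are excluded (counted in
#' `exclusions$censored_daughter`); mothers with a number of daughters
#' other than two are flagged malformed and excluded
#' (`exclusions$malformed_mother`), not raised as errors.
#'
#' @param table A lineage table (see [simulate_lineage()]); validated with
#'   [validate_lineage()].
#' @return A list with `records` (data.frame: `mother_id`, `t1`, `t2`,
#'   `delta_t`, `degree`) and `exclusions` (named counts).
#' @examples
#' tab <- simulate_lineage(dimorphic_params(n_founders = 10, seed = 1))
#' pa <- pair_asymmetry(tab)
#' summary(pa$records$degree)
#' @export
pair_asymmetry <- function(table) {
  validate_lineage(table)
  kids <- table[!is.na(table$parent_id), , drop = FALSE]
  if (nrow(kids) == 0)
    return(list(records = empty_asym_records(),
                exclusions = c(censored_daughter = 0L,
                               malformed_mother = 0L)))
  split_kids <- split(kids, kids$parent_id)
  excl_cens <- 0L
  excl_malformed <- 0L
  recs <- lapply(split_kids, function(d) {
    if (nrow(d) != 2L) {
      excl_malformed <<- excl_malformed + 1L
      return(NULL)
    }
    if (any(d$censored == 1L) || anyNA(d$division_time_min)) {
      excl_cens <<- excl_cens + 1L
      return(NULL)
    }
    gt <- sort(d$division_time_min - d$birth_time_min)
    data.frame(mother_id = d$parent_id[1], t1 = gt[1], t2 = gt[2],
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(recs)) recs <- empty_asym_records()[1:3]
  recs <- recs[order(recs$mother_id), , drop = FALSE]
  rownames(recs) <- NULL
  recs$delta_t <- recs$t2 - recs$t1
  recs$degree <- ifelse(recs$t2 > 0, recs$delta_t / recs$t2, 0)
  list(records = recs,
       exclusions = c(censored_daughter = excl_cens,
                      malformed_mother = excl_malformed))
}

empty_asym_records <- function() {
  data.frame(mother_id = character(0), t1 = numeric(0), t2 = numeric(0),
             delta_t = numeric(0), degree = numeric(0),
             stringsAsFactors = FALSE)
}

# Shared binning engine: half-open bins [lo, hi) from 0 up to the overflow
# threshold; values > threshold pool into the right-most overflow bin.
bin_with_overflow <- function(values, bin_width, overflow_threshold) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_param("bin_width must be > 0")
  if (!is.null(overflow_threshold) && overflow_threshold <= 0)
    stop_param("overflow_threshold must be > 0")
  hi <- overflow_threshold %||% (if (length(values)) max(values) else bin_width)
  edges <- seq(0, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  over <- !is.null(overflow_threshold) & values > hi
  inside <- values[!over & values <= hi]
  counts <- if (length(edges) > 1) {
    # half-open [lo, hi): shift the top edge so a value exactly at the
    # threshold falls in the last regular bin
    tabulate(pmin(findInterval(inside, edges), length(edges) - 1L),
             nbins = length(edges) - 1L)
  } else integer(0)
  structure(list(bin_edges = edges,
                 counts = as.integer(counts),
                 overflow_count = as.integer(sum(over)),
                 overflow_threshold = overflow_threshold),
            class = "trait_histogram")
}

#' Histogram of degrees of asymmetry with an overflow bin
#'
#' Bins degrees of asymmetry into half-open bins `[lo, hi)`; degrees above
#' `overflow_threshold` (display convention: 50%) are pooled into a single
#' right-most overflow bin.
#'
#' @param records The `records` data.frame from [pair_asymmetry()], or a
#'   numeric vector of degrees.
#' @param bin_width Bin width on the degree scale (default 0.05).
#' @param overflow_threshold Degrees above this pool into the overflow bin
#'   (default 0.5).
#' @return A `trait_histogram`: `bin_edges`, `counts`, `overflow_count`,
#'   `overflow_threshold`.
#' @export
asymmetry_histogram <- function(records, bin_width = 0.05,
                                overflow_threshold = 0.5) {
  degrees <- if (is.data.frame(records)) records$degree else records
  stopifnot(is.numeric(degrees) || length(degrees) == 0)
  h <- bin_with_overflow(as.numeric(degrees), bin_width, overflow_threshold)
  h$n_values <- length(degrees)
  h
}

#' Histogram of single-cell generation times with an overflow bin
#'
#' Generation time is `division_time - birth_time` for each non-censored
#' cell; censored cells are excluded and counted. Values above
#' `overflow_threshold` pool into the right-most overflow bin (display
#' conventions: 150 min for fast growers, 1200 min = 20 h for slow ones).
#'
#' @param table A lineage table.
#' @param bin_width Bin width in minutes.
#' @param overflow_threshold Overflow threshold in minutes.
#' @return A `trait_histogram` with an added `exclusions` count (censored
#'   cells).
#' @export
generation_time_histogram <- function(table, bin_width = 5,
                                      overflow_threshold = 150) {
  validate_lineage(table)
  ok <- table$censored == 0L & !is.na(table$division_time_min)
  gt <- table$division_time_min[ok] - table$birth_time_min[ok]
  h <- bin_with_overflow(gt, bin_width, overflow_threshold)
  h$exclusions <- as.integer(sum(!ok))
  h$n_values <- as.integer(sum(ok))
  h
}
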