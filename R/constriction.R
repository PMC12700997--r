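#' Summarize relative constriction-site positions
#'
#' Emulates snapshot displays of relative division-site position in which
#' cells are not sorted by polarity: each position `x` is replaced by `x`
#' or `1 - x` with equal probability under the given seed, so the display
#' is symmetric about mid-cell for any true offset. The histogram uses
#' `n_bins` equal bins on `(0, 1)`. Two convention summaries accompany it:
#'
#' * `midcell_fraction` — the share of raw (pre-randomization) positions
#'   whose distance-from-the-nearer-pole `min(x, 1 - x)` is at least
#'   `0.5 - midcell_halfwidth`, i.e. cells constricting within the
#'   mid-cell band (default band: mid-cell +/- 5%).
#' * `symmetry_p` — p-value of a two-sample Kolmogorov-Smirnov test of the
#'   randomized positions against their mirror image; non-significant for
#'   polarity-randomized data.
#'
#' @param table A lineage table with `division_position_fraction`, or a
#'   numeric vector of positions in `(0, 1)`.
#' @param n_bins Number of histogram bins (default 100, the display
#'   convention).
#' @param midcell_halfwidth Half-width of the mid-cell band (default 0.05).
#' @param seed Seed for the polarity randomization (function argument, not
#'   global state).
#' @return A list: `histogram` (a `trait_histogram` over `[0, 1]`),
#'   `midcell_fraction`, `symmetry_p`, `n`.
#' @examples
#' constriction_summary(rep(0.5, 20))$midcell_fraction
#' @export
constriction_summary <- function(table, n_bins = 100,
                                 midcell_halfwidth = 0.05, seed = 1L) {
  x <- if (is.data.frame(table)) table$division_position_fraction else table
  x <- x[!is.na(x)]
  if (!length(x)) stop_param("no division positions available")
  bad <- x <= 0 | x >= 1
  if (any(bad))
    stop_param("division positions outside (0, 1) at indices: %s",
               paste(utils::head(which(bad), 5), collapse = ", "))
  if (n_bins < 1) stop_param("n_bins must be >= 1")

  rand <- with_seed(seed, {
    flip <- sample(c(TRUE, FALSE), length(x), replace = TRUE)
    ifelse(flip, 1 - x, x)
  })

  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(rand, edges), n_bins), nbins = n_bins)
  hist <- structure(list(bin_edges = edges, counts = as.integer(counts),
                         overflow_count = 0L, overflow_threshold = NULL,
                         n_values = length(rand)),
                    class = "trait_histogram")

  midcell <- mean(pmin(x, 1 - x) >= 0.5 - midcell_halfwidth)
  p <- suppressWarnings(
    stats::ks.test(rand, 1 - rand, exact = FALSE)$p.value)
  list(histogram = hist,
       midcell_fraction = midcell,
       symmetry_p = p,
       n = length(x))
}
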