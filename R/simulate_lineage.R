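#' Parameters for the dimorphic lifecycle simulator
#'
#' Bundles and validates the parameters of [simulate_lineage()]. The
#' simulator emulates agarose-pad timelapse tracking of bacteria with a
#' Caulobacter-like dimorphic cell cycle: every division yields one
#' stalked-like daughter, which can divide again after a generation time
#' drawn from the stalked distribution, and one swarmer-like daughter,
#' whose generation time additionally includes a swarmer-to-stalked
#' differentiation delay. The base stalked generation time is drawn once
#' per division event and shared by the daughter pair (sibling cells share
#' their division context), so the delay is the sole source of timing
#' asymmetry in the monomorphic limit apart from a small independent
#' per-daughter jitter (`sibling_jitter_cv`, default 3% of the stalked
#' mean), which keeps sibling generation-time correlation high but
#' imperfect, as in real tracking data. With all CVs and the jitter at
#' zero, `swarmer_delay_mean = 0` gives exactly symmetric, monomorphic
#' (E. coli-like) timing.
#'
#' Generation times are gamma distributed with the given mean and
#' coefficient of variation (strictly positive support; `cv = 0` is the
#' deterministic limit). Event times are quantized to the imaging interval:
#' a division is first observed at the first frame at or after it occurs.
#'
#' @param stalked_gen_mean Mean stalked-cell generation time (min).
#' @param stalked_gen_cv Coefficient of variation of the stalked generation
#'   time (dimensionless, >= 0).
#' @param swarmer_delay_mean Mean differentiation delay added to swarmer
#'   daughters (min, >= 0; 0 means monomorphic timing).
#' @param swarmer_delay_cv CV of the differentiation delay.
#' @param sibling_jitter_cv SD of the zero-mean independent per-daughter
#'   timing jitter, as a fraction of `stalked_gen_mean` (>= 0).
#' @param division_offset Displacement of the division site toward the
#'   swarmer pole, as a fraction of cell length in `[0, 0.5)`; 0 is
#'   mid-cell.
#' @param position_noise_sd Gaussian noise SD on the division position
#'   (fraction of length). Must satisfy
#'   `division_offset + 3 * position_noise_sd < 0.5`.
#' @param imaging_interval Imaging frame interval (min, > 0).
#' @param duration Total tracking duration (min, > 0); cells that have not
#'   divided by then are emitted censored.
#' @param n_founders Number of founder cells (>= 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A validated list of class `dimorphic_params`.
#' @seealso [simulate_lineage()]
#' @export
dimorphic_params <- function(stalked_gen_mean = 60,
                             stalked_gen_cv = 0.1,
                             swarmer_delay_mean = 30,
                             swarmer_delay_cv = 0.1,
                             sibling_jitter_cv = 0.03,
                             division_offset = 0.07,
                             position_noise_sd = 0.02,
                             imaging_interval = 5,
                             duration = 300,
                             n_founders = 50,
                             seed = 1L) {
  p <- list(stalked_gen_mean = stalked_gen_mean,
            stalked_gen_cv = stalked_gen_cv,
            swarmer_delay_mean = swarmer_delay_mean,
            swarmer_delay_cv = swarmer_delay_cv,
            sibling_jitter_cv = sibling_jitter_cv,
            division_offset = division_offset,
            position_noise_sd = position_noise_sd,
            imaging_interval = imaging_interval,
            duration = duration,
            n_founders = n_founders,
            seed = seed)
  if (!is.numeric(stalked_gen_mean) || stalked_gen_mean <= 0)
    stop_param("stalked_gen_mean must be > 0")
  if (stalked_gen_cv < 0 || swarmer_delay_cv < 0 || sibling_jitter_cv < 0)
    stop_param("coefficients of variation must be >= 0")
  if (swarmer_delay_mean < 0)
    stop_param("swarmer_delay_mean must be >= 0")
  if (division_offset < 0 || division_offset >= 0.5)
    stop_param("division_offset must lie in [0, 0.5)")
  if (position_noise_sd < 0)
    stop_param("position_noise_sd must be >= 0")
  if (division_offset + 3 * position_noise_sd >= 0.5)
    stop_param("division_offset + 3*position_noise_sd must be < 0.5 so that division positions stay inside (0, 1)")
  if (imaging_interval <= 0) stop_param("imaging_interval must be > 0")
  if (!is.numeric(duration) || duration <= 0)
    stop_param("duration must be > 0")
  if (!is.numeric(n_founders) || n_founders < 1)
    stop_param("n_founders must be >= 1")
  class(p) <- "dimorphic_params"
  p
}

#' Simulate a tracked single-cell division forest
#'
#' Generates a lineage table like those produced by manual tracking of
#' timelapse microscopy: a forest of cells with parentage, birth and
#' division times (quantized to the imaging interval), a censored flag for
#' cells still undivided at the end of tracking, the relative division-site
#' position, cell length, and new-pole bookkeeping.
#'
#' Pole bookkeeping: each cell records the frame side of its swarmer
#' (flagellated) pole. The division site is displaced by `division_offset`
#' toward that pole, so the swarmer compartment is the smaller one. The
#' stalked daughter keeps the mother's old pole and gains its new
#' (swarmer) pole at the division site; the swarmer daughter inherits the
#' mother's swarmer pole.
#'
#' @param params A [dimorphic_params()] object.
#' @return A `data.frame` of class `lineage_table` with columns `cell_id`,
#'   `parent_id`, `birth_time_min`, `division_time_min` (`NA` if censored),
#'   `censored` (0/1), `division_position_fraction`, `cell_length_um`, and
#'   `new_pole_side`.
#' @examples
#' tab <- simulate_lineage(dimorphic_params(n_founders = 5, seed = 42))
#' head(tab)
#' @export
simulate_lineage <- function(params) {
  stopifnot(inherits(params, "dimorphic_params"))
  p <- params
  with_seed(p$seed, {
    # cells processed in creation order; vectors grow as daughters are
    # appended (forest sizes here are a few thousand cells at most)
    cell_id <- character(0); parent_id <- character(0)
    birth_true <- numeric(0); birth_obs <- numeric(0)
    pole <- character(0)
    div_true <- numeric(0); div_obs <- numeric(0)
    censored <- integer(0); pos <- numeric(0); len <- numeric(0)

    gen_time <- numeric(0)
    n <- 0L
    add_cell <- function(pid, bt, bo, gen, po) {
      n <<- n + 1L
      cell_id[n] <<- paste0("c", n)
      parent_id[n] <<- pid
      birth_true[n] <<- bt; birth_obs[n] <<- bo
      gen_time[n] <<- gen; pole[n] <<- po
      div_true[n] <<- NA_real_; div_obs[n] <<- NA_real_
      censored[n] <<- 0L; pos[n] <<- NA_real_; len[n] <<- NA_real_
      n
    }

    for (f in seq_len(p$n_founders))
      add_cell(NA_character_, 0, 0,
               rgamma_mean_cv(1, p$stalked_gen_mean, p$stalked_gen_cv),
               if (f %% 2L == 0L) "left" else "right")

    i <- 1L
    while (i <= n) {
      dt <- birth_true[i] + gen_time[i]
      len[i] <- rgamma_mean_cv(1, 3, 0.05)
      if (dt > p$duration) {
        censored[i] <- 1L
      } else {
        censored[i] <- 0L
        div_true[i] <- dt
        div_obs[i] <- quantize_time(dt, p$imaging_interval)
        # a division is always observed at least one frame after birth
        if (div_obs[i] <= birth_obs[i])
          div_obs[i] <- birth_obs[i] + p$imaging_interval
        offset <- p$division_offset +
          if (p$position_noise_sd > 0) rnorm(1, 0, p$position_noise_sd) else 0
        # position measured from the left frame edge of the cell
        pos[i] <- if (pole[i] == "right") 0.5 + offset else 0.5 - offset
        # daughters: stalked keeps the old pole, swarmer keeps the
        # mother's swarmer pole; both are born at the mother's division.
        # One stalked base time is drawn per division event and shared by
        # the pair; the swarmer daughter adds the differentiation delay
        # on top, so monomorphic timing (delay 0) is exactly symmetric.
        base <- rgamma_mean_cv(1, p$stalked_gen_mean, p$stalked_gen_cv)
        delay <- if (p$swarmer_delay_mean > 0)
          rgamma_mean_cv(1, p$swarmer_delay_mean, p$swarmer_delay_cv)
          else 0
        jit <- if (p$sibling_jitter_cv > 0)
          rnorm(2, 0, p$sibling_jitter_cv * p$stalked_gen_mean) else c(0, 0)
        site_side <- pole[i]
        old_side <- if (site_side == "right") "left" else "right"
        add_cell(cell_id[i], dt, div_obs[i],
                 max(base + jit[1], 0.1 * p$imaging_interval), site_side)
        add_cell(cell_id[i], dt, div_obs[i],
                 max(base + delay + jit[2], 0.1 * p$imaging_interval),
                 old_side)
      }
      i <- i + 1L
    }

    out <- data.frame(
      cell_id = cell_id[seq_len(n)],
      parent_id = parent_id[seq_len(n)],
      birth_time_min = birth_obs[seq_len(n)],
      division_time_min = div_obs[seq_len(n)],
      censored = censored[seq_len(n)],
      division_position_fraction = pos[seq_len(n)],
      cell_length_um = len[seq_len(n)],
      new_pole_side = pole[seq_len(n)],
      stringsAsFactors = FALSE
    )
    class(out) <- c("lineage_table", "data.frame")
    out
  })
}

#' Validate a lineage table
#'
#' Checks the structural invariants of a tracked-cell table: unique cell
#' ids, parent references that resolve, and division strictly after birth
#' for every divided cell.
#'
#' @param table A data.frame with lineage-table columns.
#' @return The table, invisibly, with class `lineage_table`; errors on
#'   violation.
#' @export
validate_lineage <- function(table) {
  req <- c("cell_id", "parent_id", "birth_time_min", "division_time_min",
           "censored")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop_param("lineage table is missing columns: %s",
               paste(miss, collapse = ", "))
  if (anyDuplicated(table$cell_id))
    stop_param("duplicate cell_id values in lineage table")
  bad_parent <- !is.na(table$parent_id) &
    !(table$parent_id %in% table$cell_id)
  if (any(bad_parent))
    stop_param("parent_id does not reference an existing cell: %s",
               paste(utils::head(table$cell_id[bad_parent], 5),
                     collapse = ", "))
  divided <- !is.na(table$division_time_min)
  if (any(divided & table$division_time_min <= table$birth_time_min))
    stop_param("division_time_min must exceed birth_time_min")
  class(table) <- unique(c("lineage_table", class(table)))
  invisible(table)
}
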