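#' @keywords internal
#' @importFrom stats rbinom rgamma rnorm runif median quantile sd setNames
#'   ks.test
"_PACKAGE"

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic entry points funnel through
# here so that a seed argument never leaks into (or depends on) global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Stable per-stage seed derivation from a root seed: root * 13 + offset,
# folded into [0, 2^31 - 1]. Documented contract of run_pipeline().
derive_seed <- function(root_seed, stage_offset) {
  (as.numeric(root_seed) * 13 + stage_offset) %% 2147483647
}

# Gamma draws parameterized by mean and coefficient of variation.
# cv = 0 degenerates to a point mass at `mean`.
rgamma_mean_cv <- function(n, mean, cv) {
  stopifnot(mean >= 0, cv >= 0)
  if (mean == 0 || cv == 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# Observation-time quantization: an event is first seen at the first imaging
# frame at or after it occurs.
quantize_time <- function(t, interval) {
  ceiling(t / interval - 1e-9) * interval
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Atomic TSV/JSON writers: write to a temp file in the target directory,
# then rename. A partial file never appears under the final name.
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  file.rename(tmp, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
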