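#' @keywords internal
"_PACKAGE"

## Shared argument checks. All user-facing errors name the offending field so
## failures in long pipeline runs are attributable.

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(x)
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

## Fixed per-module offsets added to the global seed so that partial re-runs
## of individual generators reproduce the full-run streams.
.seed_offsets <- c(
  genes      = 0L,
  counts     = 1L,
  compendium = 2L,
  deg        = 3L,
  meta       = 4L,
  pipeline   = 5L
)

.module_seed <- function(seed, module) {
  off <- .seed_offsets[[module]]
  (as.integer(seed) + off) %% .Machine$integer.max
}
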