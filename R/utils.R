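#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules. Nothing here is exported.

# Derive a set of reproducible child seeds from one master seed.
# Draws are taken from a local RNG state so callers' streams are untouched.
derive_seeds <- function(seed, n, labels = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(labels)) names(s) <- labels
  s
}

# Evaluate an expression under a temporary RNG seed, restoring state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# md5 of an R object via its serialization (text files only; used for run manifests)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stop_if_not_increasing <- function(x, what) {
  if (length(x) < 2L || any(diff(x) <= 0))
    stop(sprintf("%s must be a strictly increasing vector of length >= 2", what), call. = FALSE)
  invisible(x)
}

# linear interpolation clamped to the source range (rule = 2)
interp_onto <- function(x, y, xout) stats::approx(x, y, xout = xout, rule = 2)$y
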