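# Internal helpers: RNG substreams, voxel indexing, input checks.

# Deterministic 32-bit sub-seed derived from (seed, year, phase).
# One shared stream per simulation would make draw order fragile across
# submodel changes; instead each (year, submodel) pair reseeds from this.
sub_seed <- function(seed, year, phase) {
  x <- (as.numeric(seed) %% 2147483647) * 31 + as.numeric(year) * 1000003 +
    as.numeric(phase) * 10007
  as.integer(x %% 2147483647)
}

# phases used across the package (fixed; ledger semantics depend on order)
PHASE <- c(
  forest = 1L, init = 2L, recruit = 3L, growth = 4L,
  mort_light = 5L, mort_space = 6L, mort_fall = 7L, mort_metab = 8L,
  traits = 9L, screen = 10L
)

# 1-based linear voxel index from 0-based integer voxel coordinates
voxel_index <- function(x, y, z, dims) {
  x + dims[1L] * (y + dims[2L] * z) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("'%s' must be a single finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
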