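# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps stochastic routines free of global
# side effects.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                  strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name))
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %s", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %s", name, format(lower)))
  }
  if (x > upper) stop(sprintf("'%s' must be <= %s", name, format(upper)))
  invisible(x)
}

# Overlap wrappers: querying across disjoint chromosome sets is legitimate
# everywhere in this package (an empty result, not a user error), so the
# "no sequence levels in common" warning is silenced.
.find_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject, ...))
}

.overlaps_any <- function(query, subject, ...) {
  suppressWarnings(IRanges::overlapsAny(query, subject, ...))
}

.count_overlaps <- function(query, subject, ...) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject, ...))
}
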