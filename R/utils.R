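#' @keywords internal
#' @useDynLib pointid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed_preserved <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child-seed derivation. All inputs are small integers; the
# arithmetic stays well inside the exact-double range and the result inside
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, ...) {
  offs <- c(...)
  val <- (abs(seed) %% 1e6) * 999983 + 17
  if (length(offs)) {
    mult <- c(7919, 104729, 1299709, 15485863)[seq_along(offs) %% 4 + 1]
    val <- val + sum((abs(offs) %% 1e6) * mult)
  }
  as.integer(val %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Order-based lexicographic argmin over rows of a 3-column matrix,
# restricted to candidate row indices.
lex_min_index <- function(cloud, candidates) {
  if (length(candidates) == 1L) return(candidates)
  sub <- cloud[candidates, , drop = FALSE]
  candidates[order(sub[, 1L], sub[, 2L], sub[, 3L], candidates)[1L]]
}
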