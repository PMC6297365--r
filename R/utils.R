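`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never disturb a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive per-stage seeds from one master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Apportion integer counts by largest remainder
#'
#' Splits `n` units among classes proportionally to `weights` so the counts
#' are integers summing exactly to `n` (Hamilton apportionment; ties broken
#' by class order).
#'
#' @param weights nonnegative numeric vector.
#' @param n total count to apportion.
#' @return integer vector of the same length as `weights`, summing to `n`.
#' @export
largest_remainder <- function(weights, n) {
  if (any(weights < 0) || !isTRUE(all.equal(sum(weights), 1, tolerance = 1e-8)))
    stopf("weights must be nonnegative and sum to 1")
  exact <- weights * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    frac <- exact - base
    add <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

## Stable hash of an arbitrary R object for provenance blocks (md5 of its
## serialized form via tools::md5sum on a temp file; base R only).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
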