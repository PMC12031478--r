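#' @keywords internal
#' @useDynLib silentspeech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict
"_PACKAGE"

# Letters of the silent-typing protocol, in fixed order.
#' Protocol letter classes
#'
#' The eight most frequent English letters used as the classification targets,
#' in canonical order.
#' @return Character vector of length 8.
#' @export
ssr_classes <- function() c("E", "T", "A", "O", "I", "N", "R", "S")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a reproducible substream seed from a base seed and integer keys.
# Kept below 2^31 - 1; all arithmetic stays within double precision.
substream_seed <- function(seed, ...) {
  keys <- c(...)
  s <- (as.numeric(seed) %% 2147483647)
  for (k in keys) {
    s <- (s * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}
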