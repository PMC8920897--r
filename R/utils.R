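#' @import methods
#' @importFrom stats cor rnorm rpois runif rexp setNames
#' @importFrom utils read.delim write.table head tail
NULL

#' Round half away from zero
#'
#' Commercial rounding for non-negative values: 169.5 rounds to 170 (base
#' \code{round()} uses round-half-even and would give 170 too, but 0.5 -> 0;
#' depth bounds and genotypes require the half-up convention throughout).
#'
#' @param x numeric vector, assumed non-negative.
#' @return integer-valued numeric vector.
#' @export
roundHalfUp <- function(x) {
  floor(x + 0.5)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded simulator calls do not perturb the
#' session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# derive a stage-specific sub-seed from a master seed; kept < 2^31
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

# deterministic per-string hash in [0, 2^31); polynomial rolling hash.
# Used to give each read its own reproducible random draw.
hashStrings <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (ci in utf8ToInt(s)) h <- (h * 131 + ci) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# presence indicator on genotype values
binarizePap <- function(x) {
  as.integer(x > 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
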