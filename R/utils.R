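#' @useDynLib raschform, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats approx cor plogis qlogis rbinom rnorm runif uniroot var
#'   complete.cases setNames
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

#' Developmental subdomain taxonomy
#'
#' The fixed taxonomy used throughout the package: five primary domains
#' (motor, language, cognition, socioemotional, adaptive) with nine
#' subdomains.  Domain votes, profiles and item metadata are validated against
#' it.
#'
#' @format Character vector of `primary.subdomain` names.
#' @export
SUBDOMAINS <- c(
  "motor.gross", "motor.fine",
  "language.receptive", "language.expressive",
  "cognition.reasoning", "cognition.executive", "cognition.preacademic",
  "socioemotional",
  "adaptive.life_skills"
)

MATCH_LEVELS <- c("none", "partial", "strong", "very_strong")

#' Default ordinal level mapping for matching ratings
#'
#' Maps the four matching levels to equally spaced values on \[0, 1\]; only the
#' endpoints (no match = 0, very strong match = 1) are substantive, the interior
#' spacing is a convention and can be overridden wherever a `mapping` argument
#' is accepted.
#'
#' @return Named numeric vector over `none`, `partial`, `strong`, `very_strong`.
#' @export
defaultLevelMapping <- function() {
  setNames(c(0, 1 / 3, 2 / 3, 1), MATCH_LEVELS)
}

primaryDomain <- function(subdomain) sub("\\..*$", "", subdomain)

# Evaluate a block with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards so generators are deterministic without clobbering
# the session RNG.
withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed, so pipeline
# stages draw from independent, reproducible streams.
subSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stream) %% 1000L
}

stopIfNot <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# Gauss-Hermite nodes/weights rescaled for expectations under N(mu, sigma^2).
gaussHermiteNormal <- function(n = 31L) {
  gh <- pracma::gaussHermite(n)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Polynomial rolling hash (mod 2^31 - 1) of a character scalar, returned as 8
# hex digits.  Used to stamp output files with a configuration fingerprint;
# collision resistance beyond accidental edits is not required.
stableHash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}
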