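#' Round half away from zero
#'
#' Deterministic rounding used wherever printed percentages or counts are
#' reconstructed: ties are rounded away from zero rather than to even, so
#' that e.g. `round_half_up(0.5) == 1`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulation calls do not
#' perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Collapse a 0/1 haplotype vector to a pattern string
#' @param h integer vector of 0/1 alleles.
#' @return a single string such as "01101".
#' @keywords internal
pattern_string <- function(h) paste(h, collapse = "")

#' Expand a pattern string back to an integer vector
#' @param s pattern string of 0/1 characters.
#' @return integer vector.
#' @keywords internal
pattern_vector <- function(s) as.integer(strsplit(s, "", fixed = TRUE)[[1]])

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
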