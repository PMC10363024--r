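#' Round half away from zero
#'
#' Deterministic rounding used everywhere a real-valued copy number is
#' converted to an integer state. `round()` in R rounds half to even, which
#' is platform-stable but surprising for copy numbers (2.5 -> 2); rounding
#' half away from zero keeps e.g. a bin straddling a 2/3 segment boundary at
#' the higher state.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Branch-length formatter for newick output: up to 12 significant digits,
# always with a decimal point so integer lengths print as "1.0".
format_branch_length <- function(x) {
  s <- sprintf("%.12g", x)
  needs_dot <- !grepl("[.e]", s)
  s[needs_dot] <- paste0(s[needs_dot], ".0")
  s
}

#' Derive a module seed from a master seed
#'
#' One master seed deterministically fans out to per-stage seeds so that,
#' e.g., turning read generation on does not perturb the simulated tree.
#' Uses a Lehmer-style mix and stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param tag character stage tag (e.g. "lineage", "events").
#' @return integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(master)) * 48271 + h * 2654435) %% 2147483646 + 1)
}

# stopifnot-with-message helper for parameter validation
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
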