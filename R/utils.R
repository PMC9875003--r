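#' Round half away from zero
#'
#' Rounding used everywhere a count is described as "nearest integer":
#' halves round up (away from zero for positive input), independent of the
#' platform's banker's rounding in [base::round()].
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Split a total into k near-equal integer parts
#'
#' Every part gets `floor(total / k)`; the remaining `total %% k` units are
#' assigned one each to parts chosen uniformly at random without
#' replacement.  Used for plots over phenotyping generations, progeny over
#' crosses, and plots over individuals.
#'
#' @param total non-negative integer to split.
#' @param k number of parts (>= 1).
#' @return integer vector of length `k` summing to `total`.
#' @keywords internal
split_evenly <- function(total, k) {
  stopifnot(k >= 1, total >= 0)
  base <- as.integer(total %/% k)
  rem <- as.integer(total %% k)
  out <- rep.int(base, k)
  if (rem > 0) {
    extra <- sample.int(k, rem)
    out[extra] <- out[extra] + 1L
  }
  out
}

# Draw a pool of evaluation seeds from the current RNG stream, each a valid
# 32-bit seed for set.seed().
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}
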