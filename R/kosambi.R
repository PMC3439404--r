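#' Kosambi map distance
#'
#' Convert a recombination fraction to centiMorgans under the Kosambi mapping
#' function, d = 25 * ln((1 + 2r) / (1 - 2r)), which allows for moderate
#' crossover interference.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centiMorgans.
#' @seealso [kosambi_r()] for the inverse, [haldane_cm()] for the
#'   no-interference mapping function.
#' @examples
#' kosambi_cm(0.25)  # 25 * log(3) = 27.465 cM
#' @export
kosambi_cm <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' @param d Map distance(s) in centiMorgans, `d >= 0`.
#' @return Recombination fraction(s); `kosambi_r(kosambi_cm(r))` round-trips.
#' @export
kosambi_r <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be non-negative")
  0.5 * tanh(d / 50)
}

#' Haldane mapping function and inverse
#'
#' No-interference (Poisson crossover) mapping function,
#' d = -50 * ln(1 - 2r). The synthetic gamete simulator draws crossovers
#' from this model; see the methods vignette for why estimation still uses
#' Kosambi distances.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return `haldane_cm`: distance in cM; `haldane_r`: recombination fraction.
#' @export
haldane_cm <- function(r) {
  stopifnot(is.numeric(r))
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @param d Map distance(s) in centiMorgans.
#' @export
haldane_r <- function(d) {
  stopifnot(is.numeric(d))
  if (any(d < 0, na.rm = TRUE)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}
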