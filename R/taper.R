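# Seventh-order polynomial taper switching nonbonded interactions (and their
# first three derivatives) smoothly to zero at the cutoff radius.

#' Taper switching function
#'
#' Seventh-order polynomial used to switch nonbonded energy contributions off
#' at the cutoff: value 1 at `r = 0`, and value plus first three derivatives
#' zero at `r = r_cut`.
#'
#' @param r Distance(s), Angstrom (`r >= 0`).
#' @param r_cut Cutoff radius, Angstrom (`> 0`).
#' @return Dimensionless taper value(s) in `[0, 1]`; 0 beyond the cutoff.
#' @export
#' @examples
#' taper_value(0, 10)  # 1
#' taper_value(10, 10) # 0
taper_value <- function(r, r_cut) {
  if (!is.numeric(r_cut) || length(r_cut) != 1 || r_cut <= 0) {
    stop("`r_cut` must be a positive scalar", call. = FALSE)
  }
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  u <- pmin(r / r_cut, 1)
  # factored form of 20u^7 - 70u^6 + 84u^5 - 35u^4 + 1: free of catastrophic
  # cancellation near the cutoff
  (1 - u)^4 * (1 + 4 * u + 10 * u^2 + 20 * u^3)
}

# d(taper)/dr, same domain handling as taper_value()
taper_deriv <- function(r, r_cut) {
  u <- pmin(r / r_cut, 1)
  inside <- r < r_cut
  out <- 140 * u^3 * (u - 1)^3 / r_cut
  out[!inside] <- 0
  out
}
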