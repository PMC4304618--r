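#' CRP-cAMP activity implied by a growth rate
#'
#' CRP-cAMP reporter activity increases linearly with generation time:
#' \eqn{C(\mu) = c_0 + c_1 \cdot \ln 2 / \mu}.
#'
#' @param mu growth rate (1/h), strictly positive
#' @param c0,c1 coefficients of the affine dependence on generation time
#' @return CRP activity (same units as `c0`); vectorized over `mu`
#' @examples
#' crp_activity_of_growth(log(2), 0, 1)  # generation time 1 h -> 1
#' @export
crp_activity_of_growth <- function(mu, c0, c1) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("invalid growth rate: mu must be finite and > 0")
  }
  c0 + c1 * log(2) / mu
}

#' Normalized CRP activity at a growth rate, under a constants table
#'
#' Convenience wrapper: CRP activity divided by the table's normalization
#' reference (the activity at the slowest anchor sugar), so the ribose-alone
#' level is 1 under the defaults.
#'
#' @param mu growth rate (1/h)
#' @param ct a `constants_table`
#' @return normalized CRP activity
#' @export
crp_norm_of_growth <- function(mu, ct) {
  crp_activity_of_growth(mu, ct$crp_c0, ct$crp_c1) / ct$crp_max_ref
}

#' True promoter activity of a reporter at a given CRP level
#'
#' The generator's ground truth. When the promoter's cognate sugar is
#' present (`induced = TRUE`) activity follows the promoter's affine CRP
#' input function, clamped at zero, scaled to absolute units by `pa_scale`.
#' When the cognate sugar is absent the promoter runs at its
#' cross-activation fraction of the cognate maximum. The promoter-specific
#' `baseline` leak is added in both cases.
#'
#' @param promoter one row of `constants$promoters` (data frame or list)
#' @param crp normalized CRP activity (>= 0); vectorized
#' @param induced logical: is the cognate sugar present?
#' @return absolute promoter activity (au per OD per h)
#' @export
true_promoter_activity <- function(promoter, crp, induced) {
  stopifnot(all(crp >= 0))
  if (isTRUE(induced)) {
    act <- pmax(0, promoter$crp_slope * crp + promoter$crp_intercept) *
      promoter$pa_scale
  } else {
    act <- rep(promoter$cross_activation * promoter$pa_scale, length(crp))
  }
  act + promoter$baseline
}
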