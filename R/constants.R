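#' Packaged calibration constants for the synthetic plate-reader generator
#'
#' The generator is calibrated so that the full analysis pipeline, run on a
#' noiseless default dataset, reproduces the study's printed constants:
#' maximal growth rates of 0.53 h^-1 (lactose) and 0.29 h^-1 (ribose), a
#' repressed band of 0.1-0.5 in the pairwise hierarchy matrix, a median
#' cross-activation of 20%, a 3-fold higher CRP requirement for maximal
#' activation of the ribose system relative to lactose, and a 30% higher
#' input-function slope for the CRP-site-mutant rhaB variant.
#'
#' @details
#' CRP-cAMP reporter activity is modeled as an affine function of generation
#' time, \eqn{C(\mu) = c_0 + c_1 \ln 2/\mu}. The intercept \eqn{c_0} is
#' derived (not tuned) from the two anchor growth rates so that the
#' normalized CRP level at the ribose-alone growth rate is exactly 3 times
#' the level at the lactose-alone rate. Promoter input functions are affine
#' in normalized CRP activity, anchored so each promoter reaches its defined
#' maximum (normalized activity 1) at the CRP level of growth on its own
#' cognate sugar. Intermediate growth rates are calibration anchors chosen
#' so that every repressed entry of the noiseless pair matrix falls inside
#' the 0.1-0.5 band while input functions stay affine (see the methods
#' vignette for the feasibility argument).
#'
#' @return A list of class `constants_table` with elements
#'   \describe{
#'     \item{sugars}{tibble: name, max_growth_rate (1/h), saturating_conc
#'       (fraction w/v), yield (OD per unit concentration), rank.}
#'     \item{promoters}{tibble: name, cognate_sugar, crp_slope,
#'       crp_intercept (normalized units), cross_activation, baseline,
#'       pa_scale (au/OD/h at maximal activation).}
#'     \item{crp_c0, crp_c1}{coefficients of CRP activity vs generation time.}
#'     \item{crp_max_ref}{CRP activity at the slowest anchor (ribose alone);
#'       normalization reference so normalized CRP is 1 there.}
#'     \item{crp_scale}{absolute CRP-reporter activity per unit CRP activity.}
#'     \item{autofluor_rate}{autofluorescence accumulation rate (au/OD/h),
#'       shared by all strains including the promoterless background.}
#'     \item{mixture_rule}{growth-rate rule in mixtures ("max").}
#'     \item{ribose_boost}{optional multiplicative speedup for
#'       ribose-containing mixtures (1 = off).}
#'     \item{mutant_slope_factor}{slope multiplier of the CRP-site-mutant
#'       rhaB variant.}
#'     \item{background_strain, crp_reporter_strain}{strain identifiers.}
#'   }
#' @examples
#' ct <- default_constants()
#' ct$sugars$max_growth_rate[ct$sugars$name == "lactose"]  # 0.53
#' @export
default_constants <- function() {
  sugars <- tibble::tibble(
    name = c("lactose", "arabinose", "xylose", "sorbitol", "rhamnose", "ribose"),
    # anchors 0.53 / 0.29 are the printed extremes; intermediates are
    # calibration choices constrained by the repressed-band feasibility
    max_growth_rate = c(0.53, 0.524, 0.514, 0.49, 0.406, 0.29),
    saturating_conc = 0.2,
    yield = 2.5,
    rank = 1:6
  )

  ln2 <- log(2)
  t_lac <- ln2 / 0.53
  t_rib <- ln2 / 0.29
  # C(mu) = c0 + c1 * ln2/mu with c0 fixed so C(ribose) = 3 * C(lactose)
  crp_c1 <- 1
  crp_c0 <- (t_rib - 3 * t_lac) / 2
  crp_max_ref <- crp_c0 + crp_c1 * t_rib

  cn <- (crp_c0 + crp_c1 * ln2 / sugars$max_growth_rate) / crp_max_ref

  # normalized input-function slopes, steeper for higher-ranked systems;
  # chosen so repressed pair-matrix entries land in [0.1, 0.5] and the
  # mutant (1.3x rhaB slope) never clamps at zero in any pair condition
  slope <- c(100, 70, 34, 13, 3.0, 1.28)
  intercept <- 1 - slope * cn

  promoters <- tibble::tibble(
    name = c("lacZ", "araB", "xylA", "srlA", "rhaB", "rbsD"),
    cognate_sugar = sugars$name,
    crp_slope = slope,
    crp_intercept = intercept,
    cross_activation = c(0.15, 0.18, 0.20, 0.20, 0.22, 0.25),
    baseline = 0,
    pa_scale = c(1000, 900, 800, 700, 600, 500)
  )

  ct <- list(
    sugars = sugars,
    promoters = promoters,
    crp_c0 = crp_c0,
    crp_c1 = crp_c1,
    crp_max_ref = crp_max_ref,
    crp_scale = 300,
    autofluor_rate = 30,
    mixture_rule = "max",
    ribose_boost = 1,
    mutant_slope_factor = 1.3,
    background_strain = "background",
    crp_reporter_strain = "crp"
  )
  class(ct) <- "constants_table"
  validate_constants(ct)
  ct
}

#' Validate a constants table
#'
#' Checks the structural invariants: positive rates and yields, ranks a
#' permutation of 1..N, one promoter per sugar, positive slopes, cross
#' activation in [0, 1), the two printed anchor growth rates, and the 3-fold
#' CRP requirement ratio between the ribose and lactose systems.
#'
#' @param ct a `constants_table`
#' @return `ct`, invisibly, or an error describing the violated invariant.
#' @export
validate_constants <- function(ct) {
  s <- ct$sugars
  p <- ct$promoters
  stopifnot(
    all(s$max_growth_rate > 0),
    all(s$yield > 0),
    setequal(s$rank, seq_len(nrow(s))),
    !anyDuplicated(s$name),
    all(p$crp_slope > 0),
    all(p$cross_activation >= 0 & p$cross_activation < 1),
    setequal(p$cognate_sugar, s$name),
    !anyDuplicated(p$cognate_sugar)
  )
  if (identical(sort(ct$sugars$name), sort(c(
    "lactose", "arabinose", "xylose", "sorbitol", "rhamnose", "ribose"
  )))) {
    mu <- stats::setNames(s$max_growth_rate, s$name)
    if (abs(mu[["lactose"]] - 0.53) > 1e-9 || abs(mu[["ribose"]] - 0.29) > 1e-9) {
      stop("anchor growth rates must be 0.53 (lactose) and 0.29 (ribose)")
    }
    ratio <- crp_activity_of_growth(mu[["ribose"]], ct$crp_c0, ct$crp_c1) /
      crp_activity_of_growth(mu[["lactose"]], ct$crp_c0, ct$crp_c1)
    if (abs(ratio - 3) > 1e-9) {
      stop("CRP requirement ratio ribose:lactose must be 3 under the defaults")
    }
  }
  invisible(ct)
}

#' Day-to-day and read-noise model for the plate renderer
#'
#' Day effects are multiplicative lognormal factors (one draw per day per
#' well-condition) with the stated coefficients of variation; read noise is
#' additive Gaussian, truncated at zero for OD. The default CVs reproduce
#' the reported day-day relative errors of 5% (growth rate) and 11%
#' (promoter activity).
#'
#' @param day_cv_growth relative sd of the per-day growth-rate factor
#' @param day_cv_pa relative sd of the per-day promoter-activity factor
#' @param od_read_sd additive OD read noise (OD units)
#' @param gfp_read_sd additive fluorescence read noise (au)
#' @param seed integer seed; identical seed + configuration gives
#'   bit-identical rendered plates
#' @return a list of class `noise_model`
#' @export
noise_model <- function(day_cv_growth = 0.05, day_cv_pa = 0.11,
                        od_read_sd = 0.001, gfp_read_sd = 1, seed = 1L) {
  stopifnot(
    day_cv_growth >= 0, day_cv_pa >= 0,
    od_read_sd >= 0, gfp_read_sd >= 0,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      day_cv_growth = day_cv_growth, day_cv_pa = day_cv_pa,
      od_read_sd = od_read_sd, gfp_read_sd = gfp_read_sd,
      seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

#' Zero-noise model (truth rendering)
#' @return a `noise_model` with all variances zero
#' @export
no_noise <- function() {
  noise_model(day_cv_growth = 0, day_cv_pa = 0, od_read_sd = 0,
              gfp_read_sd = 0, seed = 0L)
}
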