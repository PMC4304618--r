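#' Define a growth scenario (one culture condition)
#'
#' A scenario describes one well-condition: which reporter strains are
#' grown, the sugar mixture, inoculum, duration and sampling, the
#' consumption mode in mixtures, and how many replicate days are run.
#'
#' @param strains character vector of reporter identifiers. The promoterless
#'   background strain is always added if absent.
#' @param sugar_mix named numeric vector of concentrations (fraction w/v),
#'   names are sugar identifiers; may be empty (no growth).
#' @param inoculum_od starting OD600
#' @param duration culture duration (h)
#' @param sampling_interval sampling interval (min)
#' @param consumption_mode "sequential" (higher-ranked sugar consumed first)
#'   or "co" (co-consumption, proportional to remaining stock)
#' @param n_replicate_days number of replicate days
#' @param camp optional normalized CRP setpoint; when set, external cAMP is
#'   taken to pin CRP activity at this level regardless of growth rate
#' @return a list of class `scenario`
#' @export
scenario <- function(strains, sugar_mix = numeric(0), inoculum_od = 0.008,
                     duration = 20, sampling_interval = 6,
                     consumption_mode = c("sequential", "co"),
                     n_replicate_days = 1, camp = NA_real_) {
  consumption_mode <- match.arg(consumption_mode)
  stopifnot(
    length(strains) >= 1,
    all(sugar_mix >= 0),
    inoculum_od > 0,
    duration > 0,
    sampling_interval > 0,
    n_replicate_days >= 1
  )
  if (length(sugar_mix) > 0 && is.null(names(sugar_mix))) {
    stop("sugar_mix must be a named vector of concentrations")
  }
  sugar_mix <- sugar_mix[sugar_mix > 0]
  structure(
    list(
      strains = unique(strains),
      sugar_mix = sugar_mix,
      inoculum_od = inoculum_od,
      duration = duration,
      sampling_interval = sampling_interval,
      consumption_mode = consumption_mode,
      n_replicate_days = as.integer(n_replicate_days),
      camp = camp
    ),
    class = "scenario"
  )
}

#' Condition identifier string for a scenario
#'
#' Deterministic encoding: sugars sorted alphabetically as
#' `"name:conc+name:conc"`, with `"|camp=x"` appended for external-cAMP
#' conditions and `"none"` for sugar-free media.
#' @param sc a `scenario`
#' @return a single string
#' @export
condition_id <- function(sc) {
  mix <- sc$sugar_mix
  if (length(mix) == 0) {
    base <- "none"
  } else {
    mix <- mix[order(names(mix))]
    base <- paste(sprintf("%s:%g", names(mix), unname(mix)), collapse = "+")
  }
  if (!is.na(sc$camp)) base <- sprintf("%s|camp=%g", base, sc$camp)
  base
}

#' Parse a condition identifier back into its components
#' @param id condition string as produced by [condition_id()]
#' @return list with `sugars` (named numeric) and `camp` (numeric or NA)
#' @export
parse_condition <- function(id) {
  camp <- NA_real_
  if (grepl("|camp=", id, fixed = TRUE)) {
    parts <- strsplit(id, "|camp=", fixed = TRUE)[[1]]
    id <- parts[1]
    camp <- as.numeric(parts[2])
  }
  if (identical(id, "none")) {
    return(list(sugars = numeric(0), camp = camp))
  }
  kv <- strsplit(strsplit(id, "+", fixed = TRUE)[[1]], ":", fixed = TRUE)
  sugars <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
  names(sugars) <- vapply(kv, `[`, character(1), 1)
  list(sugars = sugars, camp = camp)
}

strains_for_sugars <- function(sugars, ct, all_reporters = FALSE,
                               include_mutant = FALSE) {
  p <- ct$promoters
  rep_strains <- if (all_reporters) p$name else p$name[p$cognate_sugar %in% sugars]
  if (include_mutant && "rhamnose" %in% sugars) {
    rep_strains <- c(rep_strains, "rhaB_mut")
  }
  c(rep_strains, ct$crp_reporter_strain, ct$background_strain)
}

#' Sole-sugar scenario with every reporter strain
#'
#' One saturating sugar with all six reporters, the CRP reporter and the
#' promoterless background. These conditions feed the cross-activation
#' matrix and (on the cognate reporter) the growth-rate anchors.
#' @param sugar sugar identifier
#' @param ct constants table
#' @param conc concentration (default saturating)
#' @param include_mutant add the CRP-site-mutant rhaB variant when the
#'   sugar is rhamnose
#' @param ... passed to [scenario()]
#' @export
scenario_sole <- function(sugar, ct = default_constants(),
                          conc = NULL, include_mutant = TRUE, ...) {
  if (is.null(conc)) conc <- ct$sugars$saturating_conc[ct$sugars$name == sugar]
  scenario(
    strains = strains_for_sugars(sugar, ct, all_reporters = TRUE,
                                 include_mutant = include_mutant),
    sugar_mix = stats::setNames(conc, sugar),
    ...
  )
}

#' Saturating sugar-pair scenario
#'
#' Both cognate reporters (plus the mutant rhaB variant in
#' rhamnose-containing pairs), the CRP reporter and the background strain.
#' @param s1,s2 sugar identifiers
#' @param ct constants table
#' @param conc1,conc2 concentrations (default saturating)
#' @param ... passed to [scenario()]
#' @export
scenario_pair <- function(s1, s2, ct = default_constants(),
                          conc1 = NULL, conc2 = NULL, ...) {
  sat <- function(s) ct$sugars$saturating_conc[ct$sugars$name == s]
  if (is.null(conc1)) conc1 <- sat(s1)
  if (is.null(conc2)) conc2 <- sat(s2)
  scenario(
    strains = strains_for_sugars(c(s1, s2), ct, include_mutant = TRUE),
    sugar_mix = stats::setNames(c(conc1, conc2), c(s1, s2)),
    ...
  )
}

#' External-cAMP titration series for one mixture
#'
#' Returns one scenario per CRP setpoint. External cAMP is modeled as
#' pinning normalized CRP activity at the setpoint. The default setpoints
#' start at the mixture's own CRP level and rise in small increments, which
#' is what a sub-saturating cAMP titration produces for fast-growing
#' mixtures.
#'
#' @param sugars named concentrations of the mixture
#' @param reporters reporter strains measured in the series
#' @param ct constants table
#' @param setpoints normalized CRP values; defaults to 7 points from the
#'   mixture's resting level upward
#' @param ... passed to [scenario()]
#' @return list of `scenario`s
#' @export
scenario_camp_series <- function(sugars, reporters, ct = default_constants(),
                                 setpoints = NULL, ...) {
  if (is.null(setpoints)) {
    mu <- max(ct$sugars$max_growth_rate[ct$sugars$name %in% names(sugars)])
    base <- crp_norm_of_growth(mu, ct)
    setpoints <- base + c(0, 0.001, 0.002, 0.004, 0.008, 0.012, 0.016)
  }
  lapply(setpoints, function(cp) {
    scenario(
      strains = c(reporters, ct$crp_reporter_strain, ct$background_strain),
      sugar_mix = sugars,
      camp = cp,
      ...
    )
  })
}

#' The packaged reference scenario set
#'
#' All conditions the main analysis consumes: every sugar alone at
#' saturation with all reporters (cross-activation and growth anchors), all
#' unordered sugar pairs at saturation (hierarchy matrix), and external-cAMP
#' titrations of the lactose+ribose and arabinose+rhamnose mixtures for the
#' lacZ/rbsD and araB/rhaB reporters (input-function identifiability for
#' promoters whose pair conditions share a single growth rate).
#'
#' @param ct constants table
#' @param n_replicate_days replicate days for every condition
#' @param include_camp include the cAMP titration series
#' @param include_mutant include the CRP-site-mutant rhaB variant
#' @return named list of `scenario`s
#' @export
reference_scenarios <- function(ct = default_constants(), n_replicate_days = 1,
                                include_camp = TRUE, include_mutant = TRUE) {
  sugars <- ct$sugars$name[order(ct$sugars$rank)]
  out <- list()
  for (s in sugars) {
    out[[paste0("sole_", s)]] <- scenario_sole(
      s, ct, include_mutant = include_mutant,
      n_replicate_days = n_replicate_days
    )
  }
  prs <- enumerate_pairs(sugars)
  for (k in seq_len(nrow(prs))) {
    s1 <- prs$sugar_1[k]; s2 <- prs$sugar_2[k]
    out[[paste0("pair_", s1, "_", s2)]] <-
      scenario_pair(s1, s2, ct, n_replicate_days = n_replicate_days)
  }
  if (include_camp) {
    sat <- ct$sugars$saturating_conc[1]
    ser1 <- scenario_camp_series(
      stats::setNames(c(sat, sat), c("lactose", "ribose")),
      c("lacZ", "rbsD"), ct, n_replicate_days = n_replicate_days
    )
    ser2 <- scenario_camp_series(
      stats::setNames(c(sat, sat), c("arabinose", "rhamnose")),
      c("araB", "rhaB"), ct, n_replicate_days = n_replicate_days
    )
    names(ser1) <- paste0("camp_lac_rib_", seq_along(ser1))
    names(ser2) <- paste0("camp_ara_rha_", seq_along(ser2))
    out <- c(out, ser1, ser2)
  }
  out
}

#' Sub-saturating arabinose dynamics scenarios
#'
#' Five mixtures of low arabinose (0.005%) with a saturating second sugar,
#' following the design used to probe activation dynamics. Mixtures with
#' partners above rhamnose in the hierarchy (lactose, xylose, sorbitol) are
#' generated in co-consumption mode; rhamnose and ribose partners in
#' sequential mode. Each scenario carries the arabinose reporter, the
#' partner's cognate reporter, the CRP reporter and the background strain.
#'
#' @param ct constants table
#' @param ara_conc sub-saturating arabinose concentration (fraction w/v)
#' @param ... passed to [scenario()]
#' @return named list of `scenario`s (one per partner sugar)
#' @export
dynamics_scenarios <- function(ct = default_constants(), ara_conc = 0.005, ...) {
  partners <- setdiff(ct$sugars$name[order(ct$sugars$rank)], "arabinose")
  co_partners <- c("lactose", "xylose", "sorbitol")
  p <- ct$promoters
  out <- lapply(partners, function(s) {
    sat <- ct$sugars$saturating_conc[ct$sugars$name == s]
    scenario(
      strains = c("araB", p$name[p$cognate_sugar == s],
                  ct$crp_reporter_strain, ct$background_strain),
      sugar_mix = stats::setNames(c(ara_conc, sat), c("arabinose", s)),
      consumption_mode = if (s %in% co_partners) "co" else "sequential",
      ...
    )
  })
  stats::setNames(out, paste0("dyn_ara_", partners))
}
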