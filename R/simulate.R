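#' Resolve a strain identifier to its promoter parameters
#'
#' Reporter strains map to rows of `ct$promoters`. The CRP-site-mutant rhaB
#' variant (`"rhaB_mut"`) is derived from the wild-type rhaB row: its input
#' function has `mutant_slope_factor` times the slope, re-anchored so the
#' variant also reaches its own maximum (normalized activity 1) at the CRP
#' level of growth on rhamnose alone. The background and CRP reporter
#' strains are handled specially by the simulator.
#'
#' @param strain strain identifier
#' @param ct constants table
#' @return a one-row list of promoter parameters, or `NULL` for the
#'   background / CRP reporter strains
#' @export
promoter_for_strain <- function(strain, ct) {
  if (strain %in% c(ct$background_strain, ct$crp_reporter_strain)) {
    return(NULL)
  }
  p <- ct$promoters
  if (strain %in% p$name) {
    return(as.list(p[p$name == strain, ]))
  }
  if (identical(strain, "rhaB_mut")) {
    wt <- as.list(p[p$name == "rhaB", ])
    mu_rha <- ct$sugars$max_growth_rate[ct$sugars$name == wt$cognate_sugar]
    cn_rha <- crp_norm_of_growth(mu_rha, ct)
    mut <- wt
    mut$name <- "rhaB_mut"
    mut$crp_slope <- wt$crp_slope * ct$mutant_slope_factor
    mut$crp_intercept <- 1 - mut$crp_slope * cn_rha
    return(mut)
  }
  stop("unknown strain: ", strain)
}

# Piecewise-exponential phase decomposition of a batch culture.
# Growth is exponential at the mixture rule's rate while sugar remains;
# each phase ends when its consumable pool is exhausted, with the depletion
# time solved in closed form, so trajectories are exact at sample times.
build_phases <- function(sc, ct, growth_factor = 1) {
  rates <- stats::setNames(ct$sugars$max_growth_rate, ct$sugars$name)
  yields <- stats::setNames(ct$sugars$yield, ct$sugars$name)
  ranks <- stats::setNames(ct$sugars$rank, ct$sugars$name)
  mix <- sc$sugar_mix
  unknown <- setdiff(names(mix), names(rates))
  if (length(unknown) > 0) stop("unknown sugar: ", paste(unknown, collapse = ", "))

  eps <- 1e-12
  t <- 0
  od <- sc$inoculum_od
  S <- mix
  phases <- list()
  while (t < sc$duration - 1e-12 && length(phases) < 100L) {
    avail <- names(S)[S > eps]
    if (length(avail) == 0) {
      phases[[length(phases) + 1L]] <- list(
        t0 = t, t1 = sc$duration, mu_eff = 0, mu_reg = 0,
        od0 = od, S0 = S, active = character(0), mode = "stationary"
      )
      break
    }
    mu_nom <- max(rates[avail])
    if ("ribose" %in% avail && length(avail) >= 2 && ct$ribose_boost != 1) {
      mu_nom <- mu_nom * ct$ribose_boost
    }
    mu_eff <- mu_nom * growth_factor
    if (identical(sc$consumption_mode, "sequential")) {
      active <- avail[which.min(ranks[avail])]
      od_dep <- od + yields[[active]] * S[[active]]
    } else {
      active <- avail
      if (length(unique(yields[avail])) > 1) {
        stop("co-consumption requires equal yields across sugars")
      }
      od_dep <- od + sum(yields[avail] * S[avail])
    }
    t_dep <- t + log(od_dep / od) / mu_eff
    t1 <- min(t_dep, sc$duration)
    phases[[length(phases) + 1L]] <- list(
      t0 = t, t1 = t1, mu_eff = mu_eff, mu_reg = mu_nom,
      od0 = od, S0 = S, active = active, mode = sc$consumption_mode
    )
    od_new <- od * exp(mu_eff * (t1 - t))
    if (identical(sc$consumption_mode, "sequential")) {
      S[[active]] <- max(0, S[[active]] - (od_new - od) / yields[[active]])
    } else {
      pool0 <- sum(yields[avail] * S[avail])
      S[avail] <- S[avail] * max(0, (pool0 - (od_new - od)) / pool0)
    }
    S[S < eps] <- 0  # snap float residue at depletion events
    od <- od_new
    t <- t1
  }
  phases
}

phase_at <- function(phases, tt) {
  for (ph in phases) if (tt <= ph$t1 + 1e-12) return(ph)
  phases[[length(phases)]]
}

#' Simulate the true trajectories of one scenario
#'
#' Mechanistic ground truth for one culture: OD grows exponentially at the
#' mixture rule's rate (maximum of the rates of the sugars present) while
#' sugar remains; consumed sugars deplete by mass balance
#' \eqn{dS_i/dt = -(\mu/Y_i)\,OD}; the growth rate drops to the next
#' sugar's rate, then to zero, as sugars run out. Reporter GFP accumulates
#' as \eqn{dG/dt = (P(t) + b_{auto})\,OD(t)} with the promoter activity
#' \eqn{P} given by [true_promoter_activity()] at the CRP level implied by
#' the current regulatory growth rate (or pinned by external cAMP), plus a
#' shared autofluorescence term. In stationary phase all promoter
#' activities are zero. Integration is event-driven and piecewise-exact:
#' within a phase all rates are constant, so trajectories at the sampling
#' grid carry no discretization error.
#'
#' @param sc a [scenario()]
#' @param ct a constants table
#' @param growth_factor multiplicative day factor applied to the growth
#'   dynamics (not to the regulatory growth rate that sets CRP; day effects
#'   emulate assay-level variability, not shifts of the input functions)
#' @param pa_factor multiplicative day factor on promoter-driven
#'   fluorescence accumulation (not on autofluorescence)
#' @return list with `times` (h), `od`, `sugars` (matrix time x sugar),
#'   `mu` (realized growth rate), `crp` (normalized CRP activity),
#'   `pa` and `gfp` (matrices time x strain), `strains`, `scenario`.
#' @export
simulate_batch <- function(sc, ct = default_constants(), growth_factor = 1,
                           pa_factor = 1) {
  stopifnot(inherits(sc, "scenario"))
  phases <- build_phases(sc, ct, growth_factor)
  times <- seq(0, sc$duration, by = sc$sampling_interval / 60)
  n <- length(times)

  strains <- sc$strains
  proms <- lapply(strains, promoter_for_strain, ct = ct)
  names(proms) <- strains

  # per-phase promoter activity (constant within a phase)
  phase_pa <- lapply(phases, function(ph) {
    cn <- if (!is.na(sc$camp)) {
      sc$camp
    } else if (ph$mu_reg > 0) {
      crp_norm_of_growth(ph$mu_reg, ct)
    } else {
      0
    }
    vapply(strains, function(st) {
      if (identical(st, ct$background_strain)) return(0)
      if (ph$mu_reg <= 0 && is.na(sc$camp)) return(0)  # stationary shutdown
      if (ph$mu_reg <= 0) return(0)
      if (identical(st, ct$crp_reporter_strain)) return(ct$crp_scale * cn)
      prom <- proms[[st]]
      induced <- prom$cognate_sugar %in% names(ph$S0) &&
        ph$S0[[prom$cognate_sugar]] > 1e-12
      true_promoter_activity(prom, cn, induced)
    }, numeric(1))
  })
  phase_crp <- vapply(phases, function(ph) {
    if (!is.na(sc$camp)) sc$camp
    else if (ph$mu_reg > 0) crp_norm_of_growth(ph$mu_reg, ct)
    else 0
  }, numeric(1))

  # accumulate GFP across phase boundaries
  gfp_start <- matrix(0, nrow = length(phases), ncol = length(strains))
  g0 <- rep(0, length(strains))
  for (k in seq_along(phases)) {
    gfp_start[k, ] <- g0
    ph <- phases[[k]]
    dt <- ph$t1 - ph$t0
    odint <- if (ph$mu_eff > 0) {
      ph$od0 * (exp(ph$mu_eff * dt) - 1) / ph$mu_eff
    } else {
      ph$od0 * dt
    }
    g0 <- g0 + (phase_pa[[k]] * pa_factor + ct$autofluor_rate) * odint
  }

  od <- numeric(n)
  mu <- numeric(n)
  crp <- numeric(n)
  sugars_m <- matrix(0, nrow = n, ncol = length(sc$sugar_mix),
                     dimnames = list(NULL, names(sc$sugar_mix)))
  pa_m <- matrix(0, nrow = n, ncol = length(strains),
                 dimnames = list(NULL, strains))
  gfp_m <- matrix(0, nrow = n, ncol = length(strains),
                  dimnames = list(NULL, strains))
  yields <- stats::setNames(ct$sugars$yield, ct$sugars$name)

  for (i in seq_len(n)) {
    tt <- times[i]
    k <- which(vapply(phases, function(ph) tt <= ph$t1 + 1e-12, logical(1)))[1]
    if (is.na(k)) k <- length(phases)
    ph <- phases[[k]]
    dtt <- tt - ph$t0
    od_t <- ph$od0 * exp(ph$mu_eff * dtt)
    od[i] <- od_t
    mu[i] <- ph$mu_eff
    crp[i] <- phase_crp[k]
    pa_m[i, ] <- phase_pa[[k]]
    if (length(sc$sugar_mix) > 0) {
      S_t <- ph$S0
      if (length(ph$active) > 0) {
        if (identical(ph$mode, "sequential")) {
          a <- ph$active
          S_t[[a]] <- max(0, S_t[[a]] - (od_t - ph$od0) / yields[[a]])
        } else {
          pool0 <- sum(yields[ph$active] * S_t[ph$active])
          S_t[ph$active] <- S_t[ph$active] *
            max(0, (pool0 - (od_t - ph$od0)) / pool0)
        }
      }
      sugars_m[i, names(S_t)] <- S_t
    }
    odint <- if (ph$mu_eff > 0) {
      ph$od0 * (exp(ph$mu_eff * dtt) - 1) / ph$mu_eff
    } else {
      ph$od0 * dtt
    }
    gfp_m[i, ] <- gfp_start[k, ] +
      (phase_pa[[k]] * pa_factor + ct$autofluor_rate) * odint
  }

  list(
    times = times, od = od, sugars = sugars_m, mu = mu, crp = crp,
    pa = pa_m, gfp = gfp_m, strains = strains, scenario = sc,
    phases = phases
  )
}
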