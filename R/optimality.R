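#' Define a sugar-system allocation (cost/benefit) model
#'
#' Expressing \eqn{E_i} proteins of sugar system i costs \eqn{a_i E_i}
#' growth-rate units; the benefit is the growth rate
#' \eqn{\mu = \sum_i S_i E_i b_i} (or with a Michaelis-Menten dependence on
#' sugar level). The total cost is constrained to the budget along the
#' curve \eqn{\sum_i a_i E_i^p = C}: p = 1 is the straight constraint line
#' of the simplest model, p > 1 bulges outward and can make co-expression
#' optimal.
#'
#' @param a cost per protein per system (> 0)
#' @param b growth contribution per protein per unit sugar (> 0)
#' @param S sugar concentrations (>= 0)
#' @param C total cost budget (> 0)
#' @param p constraint exponent (> 0)
#' @param benefit "linear" (benefit proportional to S) or "mm"
#'   (Michaelis-Menten, S/(K+S))
#' @param K half-saturation constant for the "mm" benefit
#' @return list of class `allocation_model`
#' @export
allocation_model <- function(a, b, S, C = 1, p = 1,
                             benefit = c("linear", "mm"), K = 0.1) {
  benefit <- match.arg(benefit)
  stopifnot(
    length(a) == length(b), length(b) == length(S),
    all(a > 0), all(b > 0), all(S >= 0), C > 0, p > 0, K > 0
  )
  structure(
    list(a = a, b = b, S = S, C = C, p = p, benefit = benefit, K = K,
         n_systems = length(a)),
    class = "allocation_model"
  )
}

# per-protein growth contribution of each system at current sugar levels
benefit_coef <- function(model, S = model$S) {
  switch(model$benefit,
    linear = model$b * S,
    mm = model$b * S / (model$K + S)
  )
}

#' Growth-optimal expression allocation under the cost constraint
#'
#' For p = 1 the optimum is analytic and all-or-none (bang-bang): the full
#' budget goes to the system maximizing \eqn{S_i b_i / a_i}, giving
#' \eqn{E_i = C/a_i} and \eqn{\mu = C S_i b_i / a_i}; exact ties are
#' resolved to the lowest index and flagged degenerate. For p != 1 the
#' constraint curve is parameterized by the budget share and the benefit
#' maximized numerically (objective tolerance ~1e-8); with p > 1 and two
#' productive systems the optimum co-expresses both.
#'
#' @param model an `allocation_model`
#' @return list of class `allocation`: E, mu, corner (single-system
#'   solution), degenerate (tie between corners)
#' @export
optimal_allocation <- function(model) {
  s <- benefit_coef(model)
  if (all(s == 0)) stop("no sugar provides any benefit (all S_i b_i = 0)")
  n <- model$n_systems

  if (model$p == 1) {
    gain <- s / model$a  # mu per unit budget in each corner
    best <- max(gain)
    winners <- which(abs(gain - best) <= 1e-12 * max(best, 1))
    i <- min(winners)
    E <- rep(0, n)
    E[i] <- model$C / model$a[i]
    return(structure(
      list(E = E, mu = best * model$C, corner = TRUE,
           degenerate = length(winners) > 1),
      class = "allocation"
    ))
  }

  E_of_share <- function(u) {
    # u: budget shares (sum 1); a_i E_i^p = u_i C
    (u * model$C / model$a)^(1 / model$p)
  }
  if (n == 2) {
    f <- function(u1) sum(s * E_of_share(c(u1, 1 - u1)))
    # compare interior optimum against both corners explicitly
    opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-10)
    cand_u <- c(opt$maximum, 0, 1)
    vals <- vapply(cand_u, f, numeric(1))
    u1 <- cand_u[which.max(vals)]
    E <- E_of_share(c(u1, 1 - u1))
  } else {
    soft <- function(z) {
      e <- exp(z - max(z))
      e / sum(e)
    }
    obj <- function(z) -sum(s * E_of_share(soft(c(0, z))))
    fit <- stats::optim(rep(0, n - 1), obj, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    E <- E_of_share(soft(c(0, fit$par)))
  }
  mu <- sum(s * E)
  corner <- sum(E > 1e-8 * max(E)) == 1
  structure(
    list(E = E, mu = mu, corner = corner, degenerate = FALSE),
    class = "allocation"
  )
}

#' Critical sugar level at which the optimal corner switches
#'
#' For the two-system linear-constraint model (p = 1), the bang-bang
#' optimum jumps between corners where the corner values are equal:
#' \eqn{S_1 b_1 / a_1 = S_2 b_2 / a_2}. For system 1 the threshold is
#' \eqn{S_1^* = S_2 b_2 a_1 / (a_2 b_1)}.
#'
#' @param model a two-system `allocation_model` with p = 1, linear benefit
#' @param varying_system index (1 or 2) of the sugar whose critical level
#'   is sought
#' @return critical sugar concentration
#' @export
switch_threshold <- function(model, varying_system = 1) {
  if (model$p != 1) stop("switch threshold undefined for p != 1")
  if (model$n_systems != 2) stop("switch threshold needs exactly 2 systems")
  if (model$benefit != "linear") {
    stop("switch threshold implemented for the linear benefit")
  }
  i <- varying_system
  j <- setdiff(1:2, i)
  model$S[j] * model$b[j] * model$a[i] / (model$a[j] * model$b[i])
}

#' Two-sugar batch culture under instantaneous optimal control
#'
#' At every step the expression allocation is re-optimized for the current
#' sugar levels (p = 1: bang-bang), the culture grows at the resulting
#' rate, and only the expressed system's sugar is consumed by mass balance
#' \eqn{dS_i/dt = -(\mu/Y_i)\,OD\,E_i/\sum E}. Times at which the optimal
#' corner changes are recorded as switch events. Once consumption has
#' driven the per-budget gains \eqn{S_i b_i / a_i} onto the tie surface,
#' the discrete-time policy chatters between corners (the continuous-time
#' singular arc), so corner changes within a one-step tie band are not
#' counted as further switches. The run ends when all sugars are
#' (numerically) exhausted, growth stops, or `t_max` is reached.
#'
#' @param model an `allocation_model` with p = 1
#' @param S0 initial sugar concentrations
#' @param od0 initial OD (> 0)
#' @param yields OD produced per unit sugar, per system
#' @param dt time step (h)
#' @param t_max maximum simulated time (h)
#' @param mu_tol growth rate below which the culture is considered stopped
#' @return list of class `batch_trajectory`: `trajectory` (tibble with
#'   time, od, mu, S and E columns) and `switch_events` (times)
#' @export
simulate_optimal_batch <- function(model, S0 = model$S, od0 = 0.01,
                                   yields = rep(1, model$n_systems),
                                   dt = 0.01, t_max = 200, mu_tol = 1e-8) {
  if (dt <= 0) stop("non-positive dt")
  if (model$p != 1) stop("optimal-control batch implemented for p = 1")
  n <- model$n_systems
  S <- S0
  od <- od0
  t <- 0
  prev_regime <- NA_integer_
  switch_events <- numeric(0)
  rows <- list()
  repeat {
    m_now <- model
    m_now$S <- S
    gains <- benefit_coef(m_now) / model$a
    if (all(gains == 0)) break
    alloc <- optimal_allocation(m_now)
    if (alloc$mu < mu_tol) break
    winner <- which.max(alloc$E)
    od_step <- od * (exp(alloc$mu * dt) - 1)
    # largest gain change a single step can cause: the tie (sliding) band
    band <- 2 * max(model$b / (yields * model$a)) * od_step
    top2 <- sort(gains, decreasing = TRUE)[1:min(2, n)]
    regime <- if (n >= 2 && top2[1] - top2[2] <= band) {
      0L  # on the tie surface: chattering, not a new decision
    } else {
      winner
    }
    # an event is a change away from a clear winner (to another winner,
    # or onto the tie surface — the moment of the switch)
    if (!is.na(prev_regime) && prev_regime != 0L && regime != prev_regime) {
      switch_events <- c(switch_events, t)
    }
    prev_regime <- regime
    rows[[length(rows) + 1L]] <- c(time = t, od = od, mu = alloc$mu, S, alloc$E)
    S[winner] <- max(0, S[winner] - od_step / yields[winner])
    od <- od + od_step
    t <- t + dt
    if (t > t_max) break
  }
  traj <- as.data.frame(do.call(rbind, rows))
  names(traj) <- c("time", "od", "mu",
                   paste0("S", seq_len(n)), paste0("E", seq_len(n)))
  structure(
    list(trajectory = tibble::as_tibble(traj), switch_events = switch_events),
    class = "batch_trajectory"
  )
}

#' Pareto front of growth now versus preparedness
#'
#' Sweeps allocations along the two-system constraint curve and returns
#' the set not dominated in the two objectives: current growth rate
#' \eqn{\mu} and preparedness for a future sugar, taken as the expression
#' level of the designated (poorer) system. Endpoints of the sweep are the
#' two corners. With p = 1 and both sugars beneficial the objectives trade
#' off linearly and the entire constraint segment is non-dominated.
#'
#' @param model a two-system `allocation_model`
#' @param preparedness_index which system's expression is the second
#'   objective (default: the system with the smaller current benefit)
#' @param grid_size number of allocations swept along the constraint
#' @return tibble of class `pareto_front`: E1, E2, mu, preparedness;
#'   non-dominated points only, ordered along the constraint
#' @export
pareto_front <- function(model, preparedness_index = NULL, grid_size = 101) {
  if (model$n_systems != 2) stop("pareto front implemented for 2 systems")
  s <- benefit_coef(model)
  if (is.null(preparedness_index)) preparedness_index <- which.min(s)
  u <- seq(0, 1, length.out = grid_size)
  E1 <- (u * model$C / model$a[1])^(1 / model$p)
  E2 <- ((1 - u) * model$C / model$a[2])^(1 / model$p)
  mu <- s[1] * E1 + s[2] * E2
  prep <- if (preparedness_index == 1) E1 else E2
  pts <- tibble::tibble(E1 = E1, E2 = E2, mu = mu, preparedness = prep)
  dominated <- vapply(seq_len(nrow(pts)), function(i) {
    any(pts$mu >= pts$mu[i] & pts$preparedness >= pts$preparedness[i] &
          (pts$mu > pts$mu[i] | pts$preparedness > pts$preparedness[i]))
  }, logical(1))
  out <- pts[!dominated, ]
  class(out) <- c("pareto_front", class(out))
  out
}
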