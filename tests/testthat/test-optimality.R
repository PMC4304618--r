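grid_search_mu <- function(model, n_grid = 1001) {
  # exhaustive search over the feasible triangle's boundary segment
  # a1 E1 + a2 E2 = C (the maximum always sits on the constraint)
  e1 <- seq(0, model$C / model$a[1], length.out = n_grid)
  e2 <- (model$C - model$a[1] * e1) / model$a[2]
  s <- model$b * model$S
  max(s[1] * e1 + s[2] * e2)
}

test_that("bang-bang optimum puts the whole budget in the best system", {
  m <- allocation_model(a = c(1, 1), b = c(2, 1), S = c(1, 1), C = 1, p = 1)
  al <- optimal_allocation(m)
  expect_equal(al$E, c(1, 0))
  expect_equal(al$mu, 2)
  expect_true(al$corner)
  expect_false(al$degenerate)
  expect_equal(al$mu, grid_search_mu(m), tolerance = 1e-9)

  # absent sugar contributes nothing regardless of its b
  m0 <- allocation_model(a = c(2, 1), b = c(1, 100), S = c(1, 0), C = 3, p = 1)
  al0 <- optimal_allocation(m0)
  expect_equal(al0$E, c(3 / 2, 0))

  expect_error(
    optimal_allocation(allocation_model(a = c(1, 1), b = c(1, 1), S = c(0, 0))),
    "no sugar"
  )
})

test_that("analytic corner matches exhaustive grid search on random models", {
  set.seed(20)
  for (k in 1:100) {
    m <- allocation_model(
      a = runif(2, 0.2, 3), b = runif(2, 0.2, 3),
      S = runif(2, 0, 2), C = runif(1, 0.5, 2), p = 1
    )
    if (all(m$S * m$b == 0)) next
    al <- optimal_allocation(m)
    expect_equal(al$mu, grid_search_mu(m), tolerance = 1e-6)
    # constraint met with equality
    expect_equal(sum(m$a * al$E), m$C, tolerance = 1e-9)
  }
})

test_that("convex constraint (p = 2) yields the closed-form co-expression", {
  m <- allocation_model(a = c(1, 1), b = c(1, 1), S = c(1, 1), C = 1, p = 2)
  al <- optimal_allocation(m)
  expect_equal(al$E, rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(al$mu, sqrt(2), tolerance = 1e-7)
  expect_false(al$corner)

  # general closed form mu* = sqrt(C * sum(s_i^2 / a_i)) for p = 2
  m2 <- allocation_model(a = c(2, 0.5), b = c(1.5, 1), S = c(0.8, 1.2),
                         C = 1.7, p = 2)
  s <- m2$b * m2$S
  expect_equal(optimal_allocation(m2)$mu,
               sqrt(m2$C * sum(s^2 / m2$a)), tolerance = 1e-6)
})

test_that("co-expression arises for p > 1 and never for p = 1", {
  set.seed(31)
  for (k in 1:25) {
    a <- runif(2, 0.3, 2); b <- runif(2, 0.3, 2); S <- runif(2, 0.2, 2)
    al1 <- optimal_allocation(allocation_model(a, b, S, C = 1, p = 1))
    expect_true(al1$corner || al1$degenerate)
    al2 <- optimal_allocation(allocation_model(a, b, S, C = 1, p = 2))
    expect_true(all(al2$E > 0))
  }
})

test_that("switch threshold equates the two corner values", {
  m <- allocation_model(a = c(1, 1), b = c(2, 1), S = c(1, 1), C = 1, p = 1)
  expect_equal(switch_threshold(m, varying_system = 1), 0.5)
  # symmetric model: threshold equals the other sugar's level
  ms <- allocation_model(a = c(1, 1), b = c(1, 1), S = c(0.7, 0.7), C = 1, p = 1)
  expect_equal(switch_threshold(ms, 1), 0.7)
  # exactly at the threshold the allocation is degenerate, lowest index wins
  m$S[1] <- switch_threshold(m, 1)
  al <- optimal_allocation(m)
  expect_true(al$degenerate)
  expect_equal(al$E[1], m$C / m$a[1])
  expect_error(
    switch_threshold(allocation_model(c(1, 1), c(1, 1), c(1, 1), p = 2)),
    "p != 1"
  )
})

test_that("optimal-control batch: single sugar depletes at the closed form", {
  # saturating (Michaelis-Menten, S >> K) benefit keeps mu ~ constant so
  # the fixed-rate depletion time t = ln(1 + Y S0 / OD0) / mu applies
  m <- allocation_model(a = 1, b = 2, S = 0.5, C = 1, p = 1,
                        benefit = "mm", K = 1e-5)
  tr <- simulate_optimal_batch(m, S0 = 0.5, od0 = 0.01, yields = 1,
                               dt = 0.002)
  mu0 <- 2 * 1  # b * E with E = C/a, S saturated
  t_exp <- log(1 + 1 * 0.5 / 0.01) / mu0
  # the run ends one step after the sugar is exhausted
  t_dep <- max(tr$trajectory$time) + 0.002
  expect_equal(t_dep, t_exp, tolerance = 0.02)
  expect_length(tr$switch_events, 0)
})

test_that("two-sugar batch switches exactly once, at the threshold crossing", {
  m <- allocation_model(a = c(1, 1), b = c(1, 1), S = c(0.4, 0.2), C = 1, p = 1)
  tr <- simulate_optimal_batch(m, od0 = 0.05, yields = c(1, 1), dt = 0.002)
  expect_length(tr$switch_events, 1)
  # at the recorded switch, S1 has just crossed S2 b2 a1 / (a2 b1) = S2
  traj <- tr$trajectory
  at <- traj[which.min(abs(traj$time - tr$switch_events)), ]
  expect_equal(at$S1, at$S2, tolerance = 0.01)
  # bang-bang: E piecewise constant, changing only at the switch
  expect_equal(sort(unique(round(traj$E1, 9))), c(0, 1))
  pre <- traj$E1[traj$time < tr$switch_events]
  expect_true(all(pre == 1))
  # growth rate never increases across the switch
  mu_pre <- traj$mu[max(which(traj$time < tr$switch_events))]
  mu_post <- traj$mu[min(which(traj$time > tr$switch_events))]
  expect_lte(mu_post, mu_pre + 1e-9)
  expect_error(simulate_optimal_batch(m, dt = 0), "non-positive dt")
})

test_that("pareto front endpoints are corners and no point is dominated", {
  m <- allocation_model(a = c(1, 1), b = c(2, 1), S = c(1, 1), C = 1, p = 1)
  pf <- pareto_front(m, preparedness_index = 2, grid_size = 51)
  # linear trade-off: the whole constraint segment is non-dominated
  expect_equal(nrow(pf), 51)
  expect_equal(max(pf$mu), optimal_allocation(m)$mu)
  # the mu-maximizing corner is always on the front
  expect_true(any(pf$E1 == 1 & pf$E2 == 0))
  # grid of two: exactly the corners
  pf2 <- pareto_front(m, grid_size = 2)
  expect_equal(nrow(pf2), 2)
  expect_equal(sort(pf2$E1), c(0, 1))
  # non-domination property under a convex constraint
  pf3 <- pareto_front(allocation_model(c(1, 1), c(2, 1), c(1, 1), p = 2),
                      preparedness_index = 2, grid_size = 41)
  for (i in seq_len(nrow(pf3))) {
    dominated <- any(pf3$mu >= pf3$mu[i] & pf3$preparedness >= pf3$preparedness[i] &
                       (pf3$mu > pf3$mu[i] | pf3$preparedness > pf3$preparedness[i]))
    expect_false(dominated)
  }
})
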