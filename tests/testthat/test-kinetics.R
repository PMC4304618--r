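test_that("local polynomial derivative is exact on low-order signals", {
  tt <- seq(0, 10, by = 0.1)
  # linear signal: derivative 3 everywhere, any order
  d <- smooth_derivative(tt, 3 * tt, half_width = 4, order = 1)
  expect_equal(d$values[d$valid], rep(3, sum(d$valid)))
  # quadratic signal, order 2: derivative exactly 2t
  d2 <- smooth_derivative(tt, tt^2, half_width = 3, order = 2)
  expect_equal(d2$values[d2$valid], 2 * tt[d2$valid], tolerance = 1e-10)
  # edges are masked
  expect_false(any(d2$valid[1:3]))
  expect_false(any(d2$valid[(length(tt) - 2):length(tt)]))
  expect_error(smooth_derivative(1:3, 1:3, half_width = 3), "window larger")
})

test_that("derivative noise shrinks with the smoothing window", {
  set.seed(5)
  tt <- seq(0, 50, by = 0.1)
  y <- 2 * tt + rnorm(length(tt), 0, 0.5)
  v_narrow <- var(smooth_derivative(tt, y, half_width = 2, order = 1)$values,
                  na.rm = TRUE)
  v_wide <- var(smooth_derivative(tt, y, half_width = 8, order = 1)$values,
                na.rm = TRUE)
  expect_lt(v_wide, v_narrow)
})

test_that("growth-rate curve recovers exponential and flat regimes", {
  tt <- seq(0, 12, by = 0.1)
  w <- tibble::tibble(time_h = tt, od600 = 0.01 * exp(0.4 * tt))
  a <- growth_rate_curve(w)
  expect_equal(a$values[a$valid], rep(0.4, sum(a$valid)), tolerance = 1e-10)
  w0 <- tibble::tibble(time_h = tt, od600 = rep(0.2, length(tt)))
  a0 <- growth_rate_curve(w0)
  expect_equal(a0$values[a0$valid], rep(0, sum(a0$valid)))
  expect_error(growth_rate_curve(tibble::tibble(time_h = tt, od600 = -tt)),
               "non-positive OD")
})

test_that("growth-rate curve tracks a logistic slowdown", {
  tt <- seq(0, 30, by = 0.1)
  K <- 1; od0 <- 0.01; r <- 0.5
  od <- K * od0 * exp(r * tt) / (K + od0 * (exp(r * tt) - 1))
  a <- growth_rate_curve(tibble::tibble(time_h = tt, od600 = od))
  truth <- r * (1 - od / K)  # analytic d ln(od)/dt for logistic growth
  expect_equal(a$values[a$valid], truth[a$valid], tolerance = 5e-3)
  expect_lt(a$values[which(a$times == 25)], 0.05)
})

test_that("background subtraction averages matched background wells", {
  tt <- seq(0, 5, by = 0.1)
  well <- tibble::tibble(time_h = tt, od600 = 0.1, gfp_au = 500 + 10 * tt)
  bg <- dplyr::bind_rows(
    tibble::tibble(well = "B1", time_h = tt, od600 = 0.1, gfp_au = 90),
    tibble::tibble(well = "B2", time_h = tt, od600 = 0.1, gfp_au = 110)
  )
  out <- subtract_background(well, bg)
  expect_equal(out$gfp_au, 500 + 10 * tt - 100)
  # identical to background -> zero
  self <- subtract_background(
    tibble::tibble(time_h = tt, od600 = 0.1, gfp_au = 100),
    tibble::tibble(well = "B1", time_h = tt, od600 = 0.1, gfp_au = 100)
  )
  expect_equal(self$gfp_au, rep(0, length(tt)))
  expect_error(subtract_background(well, NULL), "no background")
})

test_that("promoter activity is the GFP derivative over OD", {
  tt <- seq(0, 8, by = 0.1)
  w <- tibble::tibble(time_h = tt, od600 = 0.1, gfp_au = 5 * tt)
  p <- promoter_activity_curve(w)
  expect_equal(p$values[p$valid], rep(50, sum(p$valid)), tolerance = 1e-10)
  wc <- tibble::tibble(time_h = tt, od600 = 0.1, gfp_au = rep(7, length(tt)))
  pc <- promoter_activity_curve(wc)
  expect_equal(pc$values[pc$valid], rep(0, sum(pc$valid)))
})

test_that("mid-log window is two generations centered on the peak", {
  tt <- seq(0, 10, by = 0.1)
  a <- rate_curve(tt, 0.693 * exp(-(tt - 5)^2))
  win <- midlog_window(a)
  expect_equal(win$t_peak, 5)
  expect_equal(win$t_start, 5 - log(2) / 0.693, tolerance = 1e-6)
  expect_equal(win$t_end, 5 + log(2) / 0.693, tolerance = 1e-6)
  expect_lte(win$t_end - win$t_start, 2 * log(2) / win$alpha_max + 1e-9)

  # constant rate: earliest-point tie-break, clipped at the data start
  ac <- rate_curve(tt, rep(0.5, length(tt)))
  wc <- midlog_window(ac)
  expect_equal(wc$t_peak, 0)
  expect_equal(wc$t_start, 0)

  # peak at the end: clipped at the data end
  ae <- rate_curve(tt, tt / 10)
  we <- midlog_window(ae)
  expect_equal(we$t_peak, 10)
  expect_equal(we$t_end, 10)

  expect_error(midlog_window(rate_curve(tt, rep(-1, length(tt)))),
               "no positive growth")
})

test_that("condition summaries average days and report day-day spread", {
  ts <- synthetic_two_day_plate(pa_days = c(90, 110))
  sm <- summarize_condition(ts, "rep", "manual")
  expect_equal(sm$mean_promoter_activity, 100, tolerance = 1e-6)
  expect_equal(sm$day_rel_error_pa, sd(c(90, 110)) / 100, tolerance = 1e-6)
  expect_equal(sm$mean_growth_rate, 0.3, tolerance = 1e-9)
  expect_equal(sm$n_replicates, 2)

  # single noiseless day: zero errors
  ts1 <- synthetic_two_day_plate(pa_days = 120)
  sm1 <- summarize_condition(ts1, "rep", "manual")
  expect_equal(sm1$mean_promoter_activity, 120, tolerance = 1e-6)
  expect_equal(sm1$day_rel_error_pa, 0)
})

test_that("background wells read as zero activity after subtraction", {
  ct <- default_constants()
  sc <- scenario_sole("lactose", ct, include_mutant = FALSE)
  ts <- render_plate(sc, ct, no_noise())
  bg <- ts$data[ts$data$strain == ct$background_strain, ]
  st <- well_midlog_stats(bg, bg)
  expect_equal(st$promoter_activity, 0, tolerance = 1e-9)
})

test_that("overlap score separates disjoint, identical and staggered pulses", {
  tt <- seq(0, 3, by = 0.005)
  box <- function(a, b) as.numeric(tt >= a & tt < b)
  # disjoint pulses
  r <- classify_dynamics(rate_curve(tt, box(0, 1)), rate_curve(tt, box(2, 3)))
  expect_equal(r$overlap, 0, tolerance = 1e-9)
  expect_identical(r$classification, "sequential")
  # identical curves
  r2 <- classify_dynamics(rate_curve(tt, box(0, 2)), rate_curve(tt, box(0, 2)))
  expect_equal(r2$overlap, 1)
  expect_identical(r2$classification, "simultaneous")
  # half-overlapping equal boxcars: min area 1, max area 3
  r3 <- classify_dynamics(rate_curve(tt, box(0, 2)), rate_curve(tt, box(1, 3)))
  expect_equal(r3$overlap, 1 / 3, tolerance = 0.02)
  expect_error(
    classify_dynamics(rate_curve(tt, box(0, 1)), rate_curve(tt, 0 * tt)),
    "all-zero"
  )
})
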