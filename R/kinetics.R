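`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subtract promoterless-background fluorescence from a well
#'
#' The mean GFP of the matched background wells (same plate, day and
#' condition, hence the same growth trajectory) is subtracted at each time
#' point. Background wells on a different grid are linearly interpolated.
#' Negative corrected values are retained, not clipped, so downstream
#' errors stay unbiased. OD is unchanged.
#'
#' @param well tibble with columns time_h, od600, gfp_au (one well)
#' @param background_wells tibble of one or more background wells (long
#'   format, column `well` distinguishing them)
#' @return `well` with gfp_au replaced by the background-corrected signal
#' @export
subtract_background <- function(well, background_wells) {
  if (is.null(background_wells) || nrow(background_wells) == 0) {
    stop("no background well available")
  }
  bg_by_well <- split(background_wells, background_wells$well %||%
                        seq_len(nrow(background_wells)))
  bg_mat <- vapply(bg_by_well, function(b) {
    if (length(b$time_h) == length(well$time_h) &&
        isTRUE(all.equal(b$time_h, well$time_h))) {
      b$gfp_au
    } else {
      stats::approx(b$time_h, b$gfp_au, xout = well$time_h, rule = 2)$y
    }
  }, numeric(nrow(well)))
  well$gfp_au <- well$gfp_au - rowMeans(bg_mat)
  well
}

#' Smoothed temporal derivative by local polynomial regression
#'
#' In each sliding window of `2 * half_width + 1` points a least-squares
#' polynomial of the given order is fitted and its derivative evaluated at
#' the window center (a Savitzky-Golay derivative on uniform grids). Edge
#' points, where no centered window fits, are masked. The default order 3
#' makes the estimator exact through fourth-degree polynomials, which keeps
#' the curvature bias on exponentially growing signals far below the
#' pipeline's 1e-3 calibration tolerance at 6-min sampling.
#'
#' @param times sampling times (h), strictly increasing
#' @param values signal values, same length
#' @param half_width window half-width in points (>= 1)
#' @param order polynomial order (>= 1, < window size)
#' @return a `rate_curve`: list(times, values, valid) where masked points
#'   carry NA values
#' @export
smooth_derivative <- function(times, values, half_width = 3, order = 3) {
  n <- length(times)
  stopifnot(length(values) == n, half_width >= 1, order >= 1)
  w <- 2 * half_width + 1
  if (n < w) stop("window larger than series (need >= ", w, " points)")
  if (order >= w) stop("polynomial order must be below the window size")

  h <- diff(times)
  uniform <- max(h) - min(h) < 1e-9 * max(h)
  deriv <- rep(NA_real_, n)
  idx <- (half_width + 1):(n - half_width)

  if (uniform) {
    x <- (-half_width:half_width) * h[1]
    V <- outer(x, 0:order, "^")
    wts <- solve(crossprod(V), t(V))[2, ]  # derivative-at-center weights
    for (i in idx) {
      deriv[i] <- sum(wts * values[(i - half_width):(i + half_width)])
    }
  } else {
    for (i in idx) {
      sel <- (i - half_width):(i + half_width)
      x <- times[sel] - times[i]
      V <- outer(x, 0:order, "^")
      cf <- stats::lm.fit(V, values[sel])$coefficients
      deriv[i] <- cf[2]
    }
  }
  structure(
    list(times = times, values = deriv,
         valid = !is.na(deriv)),
    class = "rate_curve"
  )
}

#' Instantaneous growth-rate curve of a well
#'
#' \eqn{\alpha(t) = d\,\ln(OD)/dt}, computed by [smooth_derivative()] on
#' the natural logarithm of the OD trace. The default order is 2 (a
#' linear-weight derivative): ln(OD) is piecewise linear during balanced
#' growth, for which this estimator is exact, and at the concave kinks of
#' diauxic or stationary transitions its estimate is a convex combination
#' of the neighbouring slopes, so the maximum-growth-rate point can never
#' be pushed onto a transition by smoothing overshoot (higher orders
#' ring at kinks).
#'
#' @param well tibble with time_h and od600
#' @param half_width,order passed to [smooth_derivative()]
#' @return a `rate_curve` (1/h)
#' @export
growth_rate_curve <- function(well, half_width = 3, order = 2) {
  if (any(well$od600 <= 0)) {
    stop("non-positive OD; cannot take log of the growth curve")
  }
  smooth_derivative(well$time_h, log(well$od600), half_width, order)
}

#' Promoter-activity curve of a well
#'
#' \eqn{P(t) = (dG/dt) / OD(t)}: the smoothed temporal derivative of
#' (background-subtracted) reporter fluorescence divided by the OD.
#'
#' @param well tibble with time_h, od600 and background-subtracted gfp_au
#' @param half_width,order passed to [smooth_derivative()]
#' @return a `rate_curve` (au per OD per h)
#' @export
promoter_activity_curve <- function(well, half_width = 3, order = 3) {
  if (any(well$od600 <= 0)) {
    stop("non-positive OD in promoter activity calculation")
  }
  d <- smooth_derivative(well$time_h, well$gfp_au, half_width, order)
  d$values <- d$values / well$od600
  d
}

#' Mid-exponential window of a growth-rate curve
#'
#' Two generations centered on the point of maximal growth rate:
#' `t_peak` is the first global argmax of \eqn{\alpha} over valid points
#' (ties broken by earliest time), the generation time is
#' \eqn{\tau = \ln 2 / \alpha_{max}}, and the window
#' \eqn{[t_{peak} - \tau,\; t_{peak} + \tau]} is clipped to the data range.
#'
#' @param alpha a `rate_curve` from [growth_rate_curve()]
#' @param tol relative tolerance for the argmax: the peak is the first
#'   point within `tol * alpha_max` of the maximum, so on an exactly flat
#'   exponential plateau floating-point jitter cannot move the window
#' @return list(t_peak, alpha_max, t_start, t_end) of class `midlog_window`
#' @export
midlog_window <- function(alpha, tol = 1e-6) {
  v <- alpha$values
  v[!alpha$valid] <- -Inf
  if (!any(is.finite(v)) || max(v, na.rm = TRUE) <= 0) {
    stop("no positive growth detected")
  }
  alpha_max <- max(v)
  i <- which(v >= alpha_max - tol * abs(alpha_max))[1]  # earliest near-max
  t_peak <- alpha$times[i]
  tau <- log(2) / alpha_max
  structure(
    list(
      t_peak = t_peak,
      alpha_max = alpha_max,
      t_start = max(t_peak - tau, min(alpha$times)),
      t_end = min(t_peak + tau, max(alpha$times))
    ),
    class = "midlog_window"
  )
}

window_mean <- function(curve, win) {
  sel <- curve$valid & curve$times >= win$t_start - 1e-9 &
    curve$times <= win$t_end + 1e-9
  if (!any(sel)) stop("empty mid-log window after masking")
  mean(curve$values[sel])
}

#' Mid-log statistics of one well
#'
#' Background subtraction, growth-rate and promoter-activity curves, the
#' two-generation mid-exponential window, and the windowed means.
#'
#' @param well one well's measurements (tibble: time_h, od600, gfp_au)
#' @param background_wells matched background wells for subtraction
#' @param half_width derivative window half-width
#' @param order_growth,order_pa polynomial orders for the growth-rate and
#'   promoter-activity derivatives (see [growth_rate_curve()] for why they
#'   differ)
#' @param od_floor detection floor (OD units): points below it are masked
#'   before the maximal growth rate is located, since the relative read
#'   noise of near-inoculum ODs makes the log-derivative there spurious
#' @return list(growth_rate, promoter_activity, window)
#' @export
well_midlog_stats <- function(well, background_wells, half_width = 3,
                              order_growth = 2, order_pa = 3,
                              od_floor = 0.05) {
  well <- well[order(well$time_h), ]
  corrected <- subtract_background(well, background_wells)
  alpha <- growth_rate_curve(corrected, half_width, order_growth)
  pa <- promoter_activity_curve(corrected, half_width, order_pa)
  low <- corrected$od600 < od_floor
  alpha$valid <- alpha$valid & !low
  pa$valid <- pa$valid & !low
  win <- midlog_window(alpha)
  list(
    growth_rate = window_mean(alpha, win),
    promoter_activity = window_mean(pa, win),
    window = win
  )
}

#' Summarize one (strain, condition) across replicate days
#'
#' Per-well mid-log means are computed first, wells are averaged within a
#' day, and the day values averaged; the day-to-day relative error is the
#' standard deviation across days (n-1 denominator) divided by the mean.
#'
#' @param ts a `plate_ts`
#' @param strain reporter strain identifier
#' @param condition condition identifier
#' @param ct constants table (names the background strain)
#' @param half_width,order_growth,order_pa derivative settings (see
#'   [well_midlog_stats()])
#' @return one-row tibble: strain, condition, mean_growth_rate,
#'   mean_promoter_activity, day_rel_error_growth, day_rel_error_pa,
#'   n_replicates
#' @export
summarize_condition <- function(ts, strain, condition,
                                ct = default_constants(), half_width = 3,
                                order_growth = 2, order_pa = 3) {
  d <- ts$data[ts$data$strain == strain & ts$data$condition == condition, ]
  if (nrow(d) == 0) stop("no wells for ", strain, " in ", condition)
  bg_all <- ts$data[ts$data$strain == ct$background_strain &
                      ts$data$condition == condition, ]
  day_stats <- d |>
    dplyr::group_by(.data$plate, .data$day, .data$well) |>
    dplyr::group_map(function(w, key) {
      bg <- bg_all[bg_all$plate == key$plate & bg_all$day == key$day, ]
      st <- well_midlog_stats(w, bg, half_width, order_growth, order_pa)
      tibble::tibble(day = key$day, growth = st$growth_rate,
                     pa = st$promoter_activity)
    }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(growth = mean(.data$growth), pa = mean(.data$pa))

  rel_err <- function(x) if (length(x) < 2) 0 else stats::sd(x) / mean(x)
  tibble::tibble(
    strain = strain,
    condition = condition,
    mean_growth_rate = mean(day_stats$growth),
    mean_promoter_activity = mean(day_stats$pa),
    day_rel_error_growth = rel_err(day_stats$growth),
    day_rel_error_pa = rel_err(day_stats$pa),
    n_replicates = nrow(day_stats)
  )
}

#' Summarize every reporter well-condition in a dataset
#'
#' @param ts a `plate_ts`
#' @param ct constants table
#' @param half_width,order_growth,order_pa derivative settings (see
#'   [well_midlog_stats()])
#' @return tibble of condition summaries (one row per strain x condition),
#'   background wells excluded
#' @export
summarize_all <- function(ts, ct = default_constants(), half_width = 3,
                          order_growth = 2, order_pa = 3) {
  combos <- dplyr::distinct(
    ts$map[!ts$map$is_background, c("strain", "condition")]
  )
  purrr::pmap_dfr(combos, function(strain, condition) {
    summarize_condition(ts, strain, condition, ct, half_width,
                        order_growth, order_pa)
  })
}

#' Classify two promoter-activity curves as sequential or simultaneous
#'
#' Both curves are normalized to their own maxima over the assessed region
#' and compared by the overlap score
#' \deqn{score = \int \min(p_1, p_2)\,dt \; / \; \int \max(p_1, p_2)\,dt,}
#' integrated (trapezoid rule) over the growth phase. Disjoint activation
#' gives 0, identical curves give 1; scores below the threshold are called
#' sequential, otherwise simultaneous.
#'
#' @param p1,p2 `rate_curve`s on a common time grid
#' @param threshold overlap score below which dynamics are sequential
#' @param mask optional logical vector (same grid) restricting the
#'   integration to the growth phase
#' @return list(classification, overlap, threshold)
#' @export
classify_dynamics <- function(p1, p2, threshold = 0.25, mask = NULL) {
  stopifnot(length(p1$times) == length(p2$times))
  sel <- p1$valid & p2$valid
  if (!is.null(mask)) sel <- sel & mask
  tt <- p1$times[sel]
  if (length(tt) < 2) stop("no overlapping valid region to compare")
  a <- p1$values[sel]
  b <- p2$values[sel]
  if (max(abs(a)) == 0 || max(abs(b)) == 0) {
    stop("all-zero promoter activity curve")
  }
  a <- pmax(a, 0) / max(a)
  b <- pmax(b, 0) / max(b)
  trapz <- function(y) sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  overlap <- trapz(pmin(a, b)) / trapz(pmax(a, b))
  list(
    classification = if (overlap < threshold) "sequential" else "simultaneous",
    overlap = overlap,
    threshold = threshold
  )
}

#' Growth-phase mask from a growth-rate curve
#'
#' The contiguous span from the first to the last time the growth rate
#' exceeds the given fraction of its maximum.
#' @param alpha a `rate_curve`
#' @param frac fraction of the maximal growth rate (default 0.1)
#' @return logical vector over the curve's grid
#' @export
growth_phase_mask <- function(alpha, frac = 0.1) {
  v <- ifelse(alpha$valid, alpha$values, NA_real_)
  thr <- frac * max(v, na.rm = TRUE)
  on <- which(!is.na(v) & v > thr)
  mask <- rep(FALSE, length(v))
  if (length(on) > 0) mask[min(on):max(on)] <- TRUE
  mask
}

#' Classify the activation dynamics of a two-reporter condition
#'
#' Extracts the two reporters' background-subtracted promoter-activity
#' curves from a dataset, restricts to the growth phase (from the first
#' reporter well's OD trace), and applies [classify_dynamics()].
#'
#' @param ts a `plate_ts`
#' @param condition condition identifier
#' @param strain1,strain2 the two reporter strains to compare
#' @param ct constants table
#' @param threshold overlap threshold
#' @param day replicate day to use (default 1)
#' @return list(classification, overlap, threshold)
#' @export
condition_dynamics <- function(ts, condition, strain1, strain2,
                               ct = default_constants(), threshold = 0.25,
                               day = 1) {
  get_well <- function(strain) {
    d <- ts$data[ts$data$strain == strain & ts$data$condition == condition &
                   ts$data$day == day, ]
    if (nrow(d) == 0) stop("no well for ", strain, " in ", condition)
    d[order(d$time_h), ]
  }
  bg <- ts$data[ts$data$strain == ct$background_strain &
                  ts$data$condition == condition & ts$data$day == day, ]
  w1 <- subtract_background(get_well(strain1), bg)
  w2 <- subtract_background(get_well(strain2), bg)
  p1 <- promoter_activity_curve(w1)
  p2 <- promoter_activity_curve(w2)
  alpha <- growth_rate_curve(w1)
  classify_dynamics(p1, p2, threshold, mask = growth_phase_mask(alpha))
}
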