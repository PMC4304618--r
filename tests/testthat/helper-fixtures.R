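# Shared fixtures, computed once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# Noiseless reference dataset pushed through the whole pipeline.
ref_analysis <- function() {
  if (is.null(.fixtures$ref)) {
    ct <- default_constants()
    ts <- make_dataset(reference_scenarios(ct), ct, no_noise())
    summaries <- summarize_all(ts, ct)
    ranking <- rank_sugars(summaries, ct)
    dataset <- build_crp_dataset(summaries, ct)
    .fixtures$ref <- list(
      ct = ct,
      ts = ts,
      summaries = summaries,
      ranking = ranking,
      pair_matrix = pair_matrix(summaries, ranking, ct),
      cross_matrix = cross_matrix(summaries, ranking, ct),
      dataset = dataset,
      loo = loo_predict(dataset, ranking, ct)
    )
  }
  .fixtures$ref
}

# A CRP dataset whose points lie exactly on the generator's input-function
# lines (truth level, no plate rendering).
truth_crp_dataset <- function(ct = default_constants()) {
  cn <- crp_norm_of_growth(ct$sugars$max_growth_rate, ct)
  names(cn) <- ct$sugars$name
  pts <- list()
  for (k in seq_len(nrow(ct$promoters))) {
    prom <- as.list(ct$promoters[k, ])
    # pair conditions: the faster sugar sets the growth rate, hence the
    # lower CRP level of the two
    for (s in ct$sugars$name) {
      crp_here <- min(cn[[s]], cn[[prom$cognate_sugar]])
      pts[[length(pts) + 1L]] <- tibble::tibble(
        promoter = prom$name,
        condition = paste0("pairlike_", s),
        pa_norm = prom$crp_slope * crp_here + prom$crp_intercept,
        crp_norm = crp_here,
        cognate = prom$cognate_sugar,
        partner = s,
        is_pair = TRUE
      )
    }
    # small cAMP-like titration above the cognate level
    for (d in c(0.004, 0.008, 0.016)) {
      x <- cn[[prom$cognate_sugar]] + d
      pts[[length(pts) + 1L]] <- tibble::tibble(
        promoter = prom$name,
        condition = paste0("camplike_", d),
        pa_norm = prom$crp_slope * x + prom$crp_intercept,
        crp_norm = x,
        cognate = prom$cognate_sugar,
        partner = NA_character_,
        is_pair = FALSE
      )
    }
  }
  out <- dplyr::bind_rows(pts)
  class(out) <- c("crp_dataset", class(out))
  out
}

# Manual two-day plate for estimator checks: exponential growth at a known
# rate with promoter activity held constant per day.
synthetic_two_day_plate <- function(pa_days = c(90, 110), mu = 0.3,
                                    od0 = 0.06, duration = 10,
                                    ct = default_constants()) {
  tt <- seq(0, duration, by = 0.1)
  od <- od0 * exp(mu * tt)
  rows <- list()
  for (d in seq_along(pa_days)) {
    gfp <- (pa_days[d] + ct$autofluor_rate) * od0 * (exp(mu * tt) - 1) / mu
    gfp_bg <- ct$autofluor_rate * od0 * (exp(mu * tt) - 1) / mu
    rows[[length(rows) + 1L]] <- tibble::tibble(
      plate = "T", day = d, well = "A1", strain = "rep",
      condition = "manual", time_h = tt, od600 = od, gfp_au = gfp
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      plate = "T", day = d, well = "A2", strain = ct$background_strain,
      condition = "manual", time_h = tt, od600 = od, gfp_au = gfp_bg
    )
  }
  # no CRP reporter on this miniature plate, by construction
  suppressWarnings(plate_ts(dplyr::bind_rows(rows), ct))
}

rate_curve <- function(times, values, valid = rep(TRUE, length(times))) {
  structure(list(times = times, values = values, valid = valid),
            class = "rate_curve")
}
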