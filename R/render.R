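well_coord <- function(i) {
  paste0(LETTERS[(i - 1) %/% 12 + 1], (i - 1) %% 12 + 1)
}

# deterministic per-condition seed derived from the noise seed (kept < 2^31)
condition_seed <- function(seed, condition) {
  h <- sum(utf8ToInt(condition) * seq_along(utf8ToInt(condition)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Render a scenario into measured plate-reader wells
#'
#' Samples the true trajectories on the regular sampling grid and applies
#' the measurement model: per-day multiplicative lognormal factors on
#' growth dynamics and on promoter-driven fluorescence (one draw per day
#' per condition, mean 1 at the stated CVs), and additive Gaussian read
#' noise (OD truncated just above zero). Each day's culture is re-simulated
#' under its day factors, so growth and fluorescence stay mutually
#' consistent. A promoterless background well is always rendered; its GFP
#' is the autofluorescence accumulation plus read noise. Output is
#' bit-identical for identical seed and configuration.
#'
#' @param sc a [scenario()]
#' @param ct constants table
#' @param noise a [noise_model()]; use [no_noise()] for truth rendering
#' @param plate plate label recorded with every well
#' @return a `plate_ts` object (see [plate_ts()])
#' @export
render_plate <- function(sc, ct = default_constants(), noise = no_noise(),
                         plate = "P1") {
  stopifnot(inherits(sc, "scenario"), inherits(noise, "noise_model"))
  # every rendered plate carries a promoterless background well
  sc$strains <- union(sc$strains, ct$background_strain)
  cond <- condition_id(sc)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(condition_seed(noise$seed, cond))

  sdlog_mu <- sqrt(log(1 + noise$day_cv_growth^2))
  sdlog_pa <- sqrt(log(1 + noise$day_cv_pa^2))

  rows <- vector("list", sc$n_replicate_days)
  for (day in seq_len(sc$n_replicate_days)) {
    f_mu <- exp(stats::rnorm(1, -sdlog_mu^2 / 2, sdlog_mu))
    f_pa <- exp(stats::rnorm(1, -sdlog_pa^2 / 2, sdlog_pa))
    tr <- simulate_batch(sc, ct, growth_factor = f_mu, pa_factor = f_pa)
    n <- length(tr$times)
    day_rows <- vector("list", length(tr$strains))
    for (j in seq_along(tr$strains)) {
      od_meas <- tr$od
      gfp_meas <- tr$gfp[, j]
      if (noise$od_read_sd > 0) {
        od_meas <- pmax(od_meas + stats::rnorm(n, 0, noise$od_read_sd), 1e-6)
      }
      if (noise$gfp_read_sd > 0) {
        gfp_meas <- gfp_meas + stats::rnorm(n, 0, noise$gfp_read_sd)
      }
      day_rows[[j]] <- tibble::tibble(
        plate = plate,
        day = day,
        well = well_coord(j),
        strain = tr$strains[j],
        condition = cond,
        time_h = tr$times,
        od600 = od_meas,
        gfp_au = gfp_meas
      )
    }
    rows[[day]] <- dplyr::bind_rows(day_rows)
  }
  data <- dplyr::bind_rows(rows)
  plate_ts(data, ct,
           metadata = list(seed = noise$seed, condition = cond))
}

#' Construct a plate time-series container
#'
#' The interchange object between the generator, the IO layer and the
#' kinetics pipeline: long-format measurements plus a plate map derived
#' from them, with background and CRP-reporter strains flagged.
#'
#' @param data tibble with columns plate, day, well, strain, condition,
#'   time_h, od600, gfp_au
#' @param ct constants table (names the background and CRP reporter strains)
#' @param metadata free-form provenance list (seed, constants version, ...)
#' @return list of class `plate_ts` with elements `data`, `map`, `metadata`
#' @export
plate_ts <- function(data, ct = default_constants(), metadata = list()) {
  req <- c("plate", "day", "well", "strain", "condition", "time_h",
           "od600", "gfp_au")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  map <- dplyr::distinct(
    data, .data$plate, .data$day, .data$well, .data$strain, .data$condition
  )
  map$is_background <- map$strain == ct$background_strain
  map$is_crp <- map$strain == ct$crp_reporter_strain
  dup <- map[duplicated(map[, c("plate", "day", "well")]), ]
  if (nrow(dup) > 0) {
    stop("duplicate well assignment: ",
         paste(unique(paste(dup$plate, dup$day, dup$well)), collapse = "; "))
  }
  obj <- list(data = tibble::as_tibble(data), map = map, metadata = metadata)
  class(obj) <- "plate_ts"
  validate_plate_ts(obj)
  obj
}

#' Validate a plate time series
#'
#' Checks that times are strictly increasing within every well and that at
#' least one background well is present per plate; warns when no
#' CRP-reporter strain is present (the CRP-model stage will refuse to run).
#' @param x a `plate_ts`
#' @return `x` invisibly
#' @export
validate_plate_ts <- function(x) {
  bad <- x$data |>
    dplyr::group_by(.data$plate, .data$day, .data$well) |>
    dplyr::summarise(ok = all(diff(.data$time_h) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("non-monotone times in well ",
         paste(paste(bad$plate, bad$day, bad$well), collapse = "; "))
  }
  no_bg <- setdiff(unique(x$map$plate), unique(x$map$plate[x$map$is_background]))
  if (length(no_bg) > 0) {
    stop("no background well on plate ", paste(no_bg, collapse = ", "))
  }
  if (!any(x$map$is_crp)) {
    warning("no CRP reporter strain present; CRP-model stages will not run")
  }
  invisible(x)
}

#' Combine plate time series
#' @param ... `plate_ts` objects
#' @return a single `plate_ts`
#' @export
bind_plate_ts <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "plate_ts")) {
    parts <- parts[[1]]
  }
  data <- dplyr::bind_rows(lapply(parts, function(p) p$data))
  meta <- parts[[1]]$metadata
  obj <- list(
    data = data,
    map = dplyr::bind_rows(lapply(parts, function(p) p$map)),
    metadata = meta
  )
  class(obj) <- "plate_ts"
  obj
}

#' Generate a full dataset from a list of scenarios
#'
#' Renders every scenario with the given noise model into one combined
#' `plate_ts`; plate labels come from the scenario names.
#'
#' @param scenarios named list of [scenario()]s
#' @param ct constants table
#' @param noise a [noise_model()]
#' @return a `plate_ts`
#' @export
make_dataset <- function(scenarios, ct = default_constants(),
                         noise = no_noise()) {
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("P", seq_along(scenarios))
  }
  parts <- lapply(names(scenarios), function(nm) {
    render_plate(scenarios[[nm]], ct, noise, plate = nm)
  })
  out <- bind_plate_ts(parts)
  out$metadata <- list(seed = noise$seed, n_scenarios = length(scenarios))
  out
}
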