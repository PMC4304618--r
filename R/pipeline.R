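#' Run configuration for the full analysis
#'
#' @param seed integer seed controlling every stochastic element
#' @param noise logical: apply the default day/read noise model, or a
#'   [noise_model()] for full control
#' @param n_replicate_days replicate days per condition
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output
#' @param stages subset of c("simulate", "extract", "hierarchy", "crp",
#'   "dynamics", "optimality")
#' @param ct constants table
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1L, noise = FALSE, n_replicate_days = 1,
                       out_dir = NULL,
                       stages = c("simulate", "extract", "hierarchy",
                                  "crp", "dynamics", "optimality"),
                       ct = default_constants()) {
  nm <- if (inherits(noise, "noise_model")) {
    noise
  } else if (isTRUE(noise)) {
    noise_model(seed = seed)
  } else {
    no_noise()
  }
  structure(
    list(seed = as.integer(seed), noise = nm,
         n_replicate_days = n_replicate_days, out_dir = out_dir,
         stages = stages, ct = ct),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Generates the reference dataset, extracts condition summaries, builds
#' the ranking and the hierarchy/cross-activation matrices, fits the CRP
#' input functions with leave-one-out prediction, classifies the
#' sub-saturating dynamics scenarios, and solves the allocation optimality
#' demonstrations. Intermediate tables are written under `out_dir` when
#' set; the returned report collects every headline statistic. Identical
#' configurations give identical outputs.
#'
#' @param config a [run_config()]
#' @return list (the run report)
#' @export
run_full_analysis <- function(config = run_config()) {
  ct <- config$ct
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out)) writer(file.path(out, name))
  }
  report <- list(seed = config$seed)
  stage <- function(s) s %in% config$stages

  ts <- NULL
  if (stage("simulate") || stage("extract") || stage("hierarchy") ||
      stage("crp")) {
    scen <- reference_scenarios(ct, n_replicate_days = config$n_replicate_days)
    ts <- make_dataset(scen, ct, config$noise)
    emit("timeseries.csv", function(p) write_timeseries(ts, p))
    emit("platemap.json", function(p) write_platemap(ts, p, ct))
    report$n_wells <- nrow(ts$map)
  }

  summaries <- NULL
  if (stage("extract") || stage("hierarchy") || stage("crp")) {
    summaries <- summarize_all(ts, ct)
    emit("summaries.tsv", function(p) readr::write_tsv(summaries, p))
    report$mean_day_rel_error_pa <- mean(
      summaries$day_rel_error_pa[summaries$n_replicates > 1]
    )
    report$mean_day_rel_error_growth <- mean(
      summaries$day_rel_error_growth[summaries$n_replicates > 1]
    )
  }

  ranking <- NULL
  if (stage("hierarchy") || stage("crp")) {
    ranking <- rank_sugars(summaries, ct)
    report$ranking <- ranking$sugars
    pm <- pair_matrix(summaries, ranking, ct)
    cm <- cross_matrix(summaries, ranking, ct)
    emit("pair_matrix.tsv", function(p) write_matrix_tsv(pm, p))
    emit("cross_matrix.tsv", function(p) write_matrix_tsv(cm, p))
    report$pair_matrix <- pm
    report$cross_matrix <- cm
    report$dominance_score <- dominance_score(pm)
    report$cross_median <- stats::median(cm[row(cm) != col(cm)])
  }

  if (stage("crp")) {
    dataset <- build_crp_dataset(summaries, ct)
    loo <- loo_predict(dataset, ranking, ct)
    emit("loo_predicted_matrix.tsv",
         function(p) write_matrix_tsv(loo$predicted_matrix, p))
    emit("input_function_fits.tsv", function(p) {
      readr::write_tsv(
        dplyr::bind_rows(lapply(loo$fits, function(f) {
          tibble::tibble(promoter = f$promoter, slope = f$slope,
                         intercept = f$intercept, n_points = f$n_points)
        })), p)
    })
    report$r2_loo <- loo$r2
    report$r2_loo_pearson <- loo$r2_pearson
    req <- vapply(loo$fits, crp_required_for_max, numeric(1))
    report$crp_required <- req
    report$crp_ratio_ribose_lactose <- req[["rbsD"]] / req[["lacZ"]]
    if (all(c("rhaB", "rhaB_mut") %in% names(loo$fits))) {
      report$mutant_slope_pct <- compare_variant_slopes(
        loo$fits[["rhaB"]], loo$fits[["rhaB_mut"]]
      )
    }
  }

  if (stage("dynamics")) {
    dyn_scen <- dynamics_scenarios(ct)
    dyn_ts <- make_dataset(dyn_scen, ct, config$noise)
    p <- ct$promoters
    partners <- sub("^dyn_ara_", "", names(dyn_scen))
    cls <- lapply(partners, function(s) {
      condition_dynamics(
        dyn_ts, condition_id(dyn_scen[[paste0("dyn_ara_", s)]]),
        "araB", p$name[p$cognate_sugar == s], ct
      )
    })
    names(cls) <- partners
    report$dynamics <- tibble::tibble(
      partner = partners,
      classification = vapply(cls, `[[`, character(1), "classification"),
      overlap = vapply(cls, `[[`, numeric(1), "overlap")
    )
    emit("dynamics.tsv", function(pth) readr::write_tsv(report$dynamics, pth))
  }

  if (stage("optimality")) {
    m1 <- allocation_model(a = c(1, 1), b = c(2, 1), S = c(1, 1), C = 1, p = 1)
    m2 <- allocation_model(a = c(1, 1), b = c(1, 1), S = c(1, 1), C = 1, p = 2)
    report$optimality <- list(
      bang_bang = optimal_allocation(m1),
      convex = optimal_allocation(m2),
      threshold = switch_threshold(m1, varying_system = 1),
      pareto_points = nrow(pareto_front(m1, grid_size = 21))
    )
  }

  report
}
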