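#' Build the CRP input-function dataset from condition summaries
#'
#' For every reporter promoter, collects the conditions in which its
#' cognate sugar is present (cognate alone, all pairs containing it, and
#' any external-cAMP titrations of such mixtures). Promoter activity is
#' normalized to the promoter's cognate-alone activity; CRP-reporter
#' activity is normalized to its highest value across all conditions in
#' the dataset.
#'
#' @param summaries condition summaries from [summarize_all()], including
#'   CRP-reporter rows
#' @param ct constants table
#' @param promoters promoter strains to include (default: all packaged
#'   promoters plus the mutant rhaB variant when present in the summaries)
#' @return tibble of class `crp_dataset`: promoter, condition, pa_norm,
#'   crp_norm, cognate, partner (the second sugar, or the cognate itself
#'   for the cognate-alone condition, or NA for cAMP titration points),
#'   is_pair (logical: belongs to the pairwise hierarchy matrix)
#' @export
build_crp_dataset <- function(summaries, ct = default_constants(),
                              promoters = NULL) {
  crp_rows <- summaries[summaries$strain == ct$crp_reporter_strain, ]
  if (nrow(crp_rows) == 0) {
    stop("no CRP reporter measurements; cannot build the CRP dataset")
  }
  crp_max <- max(crp_rows$mean_promoter_activity)
  crp_of <- function(cond) {
    r <- crp_rows[crp_rows$condition == cond, ]
    if (nrow(r) == 0) stop("no CRP reporter well in condition ", cond)
    r$mean_promoter_activity[1] / crp_max
  }

  if (is.null(promoters)) {
    promoters <- intersect(
      c(ct$promoters$name, "rhaB_mut"), unique(summaries$strain)
    )
  }

  pts <- list()
  for (pr in promoters) {
    prom <- promoter_for_strain(pr, ct)
    cognate <- prom$cognate_sugar
    own <- lookup_summary(summaries, pr, cognate)
    rows <- summaries[summaries$strain == pr, ]
    for (k in seq_len(nrow(rows))) {
      pc <- parse_condition(rows$condition[k])
      if (!cognate %in% names(pc$sugars)) next
      n_sugars <- length(pc$sugars)
      if (n_sugars > 2) next
      is_camp <- !is.na(pc$camp)
      partner <- if (is_camp) {
        NA_character_
      } else if (n_sugars == 1) {
        cognate
      } else {
        setdiff(names(pc$sugars), cognate)
      }
      pts[[length(pts) + 1L]] <- tibble::tibble(
        promoter = pr,
        condition = rows$condition[k],
        pa_norm = rows$mean_promoter_activity[k] / own$mean_promoter_activity,
        crp_norm = crp_of(rows$condition[k]),
        cognate = cognate,
        partner = partner,
        is_pair = !is_camp
      )
    }
  }
  out <- dplyr::bind_rows(pts)
  class(out) <- c("crp_dataset", class(out))
  out
}

#' Fit one promoter's linear CRP input function
#'
#' Ordinary least squares of normalized promoter activity on normalized
#' CRP-reporter activity, with intercept.
#'
#' @param points tibble with columns crp_norm and pa_norm (one promoter)
#' @param promoter optional promoter name recorded in the fit
#' @return list of class `input_function_fit`: promoter, slope, intercept,
#'   rss, n_points, plus the design moments needed for prediction
#'   intervals (x_bar, sxx)
#' @export
fit_input_function <- function(points, promoter = NA_character_) {
  x <- points$crp_norm
  y <- points$pa_norm
  if (length(x) < 2) stop("need at least 2 points to fit a line")
  if (diff(range(x)) < 1e-12) {
    stop("all CRP values identical for promoter ",
         promoter %||% "<unnamed>")
  }
  x_bar <- mean(x)
  sxx <- sum((x - x_bar)^2)
  slope <- sum((x - x_bar) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * x_bar
  resid <- y - (intercept + slope * x)
  structure(
    list(
      promoter = promoter, slope = slope, intercept = intercept,
      rss = sum(resid^2), n_points = length(x), x_bar = x_bar, sxx = sxx
    ),
    class = "input_function_fit"
  )
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the observed mean. Can be negative for predictions worse than the
#' mean; never exceeds 1.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2)
#' @return R-squared value
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("zero total variance in observed values")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Leave-one-out prediction of promoter activity from CRP activity
#'
#' For every point of the dataset, the point's promoter line is refitted
#' without that point and the point's activity predicted from its measured
#' CRP level, so no prediction uses its own observation. Returns the
#' per-point predictions with 95% prediction intervals, the predicted
#' hierarchy matrix (pair points, in rank order), and the global R-squared
#' pooled over all predicted points (both 1 - SSres/SStot and the squared
#' Pearson correlation of the scatter are reported).
#'
#' @param dataset a `crp_dataset`
#' @param ranking optional `sugar_ranking` for matrix assembly
#' @param ct constants table
#' @return list of class `loo_prediction`: `predictions` (tibble),
#'   `predicted_matrix`, `r2`, `r2_pearson`, `fits` (full-data fits per
#'   promoter)
#' @export
loo_predict <- function(dataset, ranking = NULL, ct = default_constants()) {
  counts <- table(dataset$promoter)
  too_few <- names(counts)[counts < 3]
  if (length(too_few) > 0) {
    stop("insufficient points for leave-one-out fits: ",
         paste(too_few, collapse = ", "))
  }
  preds <- dataset
  preds$predicted <- NA_real_
  preds$ci_lo <- NA_real_
  preds$ci_hi <- NA_real_
  for (i in seq_len(nrow(dataset))) {
    pr <- dataset$promoter[i]
    train <- dataset[dataset$promoter == pr, ]
    train <- train[!(train$condition == dataset$condition[i]), ]
    fit <- fit_input_function(train, promoter = pr)
    x0 <- dataset$crp_norm[i]
    yhat <- fit$intercept + fit$slope * x0
    dfree <- fit$n_points - 2
    se <- if (dfree > 0) {
      s2 <- fit$rss / dfree
      sqrt(s2 * (1 + 1 / fit$n_points + (x0 - fit$x_bar)^2 / fit$sxx))
    } else {
      0
    }
    tq <- if (dfree > 0) stats::qt(0.975, dfree) else 0
    preds$predicted[i] <- yhat
    preds$ci_lo[i] <- yhat - tq * se
    preds$ci_hi[i] <- yhat + tq * se
  }

  predicted_matrix <- NULL
  if (!is.null(ranking)) {
    sugars <- ranking$sugars
    p <- ct$promoters
    predicted_matrix <- matrix(
      NA_real_, length(sugars), length(sugars),
      dimnames = list(sugars, sugars)
    )
    pair_pts <- preds[preds$is_pair & preds$promoter %in% p$name, ]
    for (k in seq_len(nrow(pair_pts))) {
      i <- match(pair_pts$cognate[k], sugars)
      j <- match(pair_pts$partner[k], sugars)
      predicted_matrix[i, j] <- pair_pts$predicted[k]
    }
  }

  fits <- lapply(split(dataset, dataset$promoter), function(d) {
    fit_input_function(d, promoter = d$promoter[1])
  })

  structure(
    list(
      predictions = preds,
      predicted_matrix = predicted_matrix,
      r2 = r_squared(preds$pa_norm, preds$predicted),
      r2_pearson = stats::cor(preds$pa_norm, preds$predicted)^2,
      fits = fits
    ),
    class = "loo_prediction"
  )
}

#' CRP level required for maximal promoter activity
#'
#' The normalized CRP-reporter activity at which a promoter's fitted input
#' function reaches its maximal (normalized 1) activity:
#' \eqn{(1 - intercept)/slope}.
#'
#' @param fit an `input_function_fit` with positive slope
#' @return normalized CRP level
#' @export
crp_required_for_max <- function(fit) {
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop("CRP requirement undefined for non-positive slope")
  }
  (1 - fit$intercept) / fit$slope
}

#' Percent slope change of a variant promoter relative to wild type
#'
#' @param fit_wt,fit_variant `input_function_fit`s
#' @return percent change, 100 * (slope_variant - slope_wt) / slope_wt
#' @export
compare_variant_slopes <- function(fit_wt, fit_variant) {
  if (!is.finite(fit_wt$slope) || fit_wt$slope == 0) {
    stop("wild-type slope must be nonzero")
  }
  100 * (fit_variant$slope - fit_wt$slope) / fit_wt$slope
}
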