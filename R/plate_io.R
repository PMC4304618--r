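#' Write a plate time series to CSV
#'
#' Long format with fixed column order
#' `plate, day, well, strain, condition, time_h, od600, gfp_au`, numbers at
#' 6 significant digits, rows sorted by (plate, day, well, time); stable
#' across runs, so identical series produce byte-identical files.
#'
#' @param series a `plate_ts`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "plate_ts"))
  d <- series$data |>
    dplyr::arrange(.data$plate, .data$day, .data$well, .data$time_h) |>
    dplyr::mutate(
      time_h = signif(.data$time_h, 6),
      od600 = signif(.data$od600, 6),
      gfp_au = signif(.data$gfp_au, 6)
    )
  d <- d[, c("plate", "day", "well", "strain", "condition",
             "time_h", "od600", "gfp_au")]
  readr::write_csv(d, path)
  invisible(path)
}

#' Read a plate time series from CSV
#'
#' Inverse of [write_timeseries()]. Malformed rows (missing fields,
#' non-numeric measurements) are reported with their line numbers; wells
#' with non-monotone times are rejected by name. Parse problems never drop
#' wells silently.
#'
#' @param path CSV file written by [write_timeseries()] (or conforming)
#' @param ct constants table used to flag background / CRP reporter strains
#' @return a `plate_ts`
#' @export
read_timeseries <- function(path, ct = default_constants()) {
  if (!file.exists(path)) stop("file not found: ", path)
  # parse issues are collected from readr::problems() and reported as
  # errors with line numbers below; silence the transient warning
  d <- withCallingHandlers(
    readr::read_csv(
    path,
    col_types = readr::cols(
      plate = readr::col_character(),
      day = readr::col_integer(),
      well = readr::col_character(),
      strain = readr::col_character(),
      condition = readr::col_character(),
      time_h = readr::col_double(),
      od600 = readr::col_double(),
      gfp_au = readr::col_double()
    ),
    progress = FALSE,
    show_col_types = FALSE
    ),
    warning = function(w) {
      if (grepl("parsing issues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  missing_cols <- setdiff(
    c("plate", "day", "well", "strain", "condition", "time_h", "od600",
      "gfp_au"),
    names(d)
  )
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    stop("malformed rows at lines ",
         paste(utils::head(probs$row, 10), collapse = ", "))
  }
  bad <- !stats::complete.cases(d[, c("time_h", "od600")])
  if (any(bad)) {
    stop("malformed rows at lines ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
  }
  plate_ts(d, ct, metadata = list(source = path))
}

#' Write a plate map as JSON
#'
#' @param series a `plate_ts` (its map component is written), or a tibble
#'   with columns plate, day, well, strain, condition
#' @param path output file
#' @param ct constants table naming the background / CRP reporter strains
#' @return `path`, invisibly
#' @export
write_platemap <- function(series, path, ct = default_constants()) {
  map <- if (inherits(series, "plate_ts")) series$map else series
  obj <- list(
    background_strain = ct$background_strain,
    crp_reporter_strain = ct$crp_reporter_strain,
    wells = map[, c("plate", "day", "well", "strain", "condition")]
  )
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a plate map from JSON
#'
#' @param path JSON file written by [write_platemap()] (or conforming)
#' @return list with `wells` (tibble), `background_strain`,
#'   `crp_reporter_strain`; errors on duplicate well assignments or a
#'   missing background strain, warns when no CRP reporter strain is named.
#' @export
read_platemap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  wells <- tibble::as_tibble(obj$wells)
  if (anyDuplicated(wells[, c("plate", "day", "well")])) {
    stop("duplicate well assignment in plate map")
  }
  if (is.null(obj$background_strain) ||
      !obj$background_strain %in% wells$strain) {
    stop("plate map lacks a background (promoterless) strain")
  }
  if (is.null(obj$crp_reporter_strain) ||
      !obj$crp_reporter_strain %in% wells$strain) {
    warning("plate map lacks a CRP reporter strain; ",
            "CRP-model stages will refuse to run")
  }
  list(
    wells = wells,
    background_strain = obj$background_strain,
    crp_reporter_strain = obj$crp_reporter_strain %||% NA_character_
  )
}

#' Write a labeled matrix as TSV
#'
#' Row/column labels are preserved; a header comment records the label
#' order (rank order for hierarchy matrices).
#' @param m matrix with dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# order: ", paste(rownames(m), collapse = ",")), con)
  writeLines(paste(c("row", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], signif(m[i, ], 6)), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a labeled matrix from TSV written by [write_matrix_tsv()]
#' @param path TSV file
#' @return matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
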