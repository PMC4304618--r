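test_that("time series round-trip through CSV preserves values", {
  ct <- default_constants()
  ts <- render_plate(scenario_sole("rhamnose", ct), ct, no_noise())
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts, f)
  back <- read_timeseries(f, ct)
  expect_equal(nrow(back$data), nrow(ts$data))
  expect_equal(back$data$od600,
               signif(ts$data[order(ts$data$plate, ts$data$day,
                                    ts$data$well, ts$data$time_h), ]$od600, 6))
  expect_setequal(unique(back$data$strain), unique(ts$data$strain))
})

test_that("writing twice is byte-identical; 6-min 20-h wells have 201 rows", {
  ct <- default_constants()
  ts <- render_plate(scenario_sole("xylose", ct), ct, no_noise())
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts, f1)
  write_timeseries(ts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rows_per_well <- table(ts$data$well)
  expect_true(all(rows_per_well == floor(20 * 60 / 6) + 1))  # 201
})

test_that("malformed series are rejected with location information", {
  ct <- default_constants()
  ts <- render_plate(scenario_sole("lactose", ct), ct, no_noise())
  d <- ts$data
  # time going backwards in one well
  d$time_h[d$strain == "lacZ"][5] <- 100
  expect_error(plate_ts(d, ct), "non-monotone times")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate,day,well,strain,condition,time_h,od600,gfp_au",
               "P1,1,A1,lacZ,x,0,0.01,5",
               "P1,1,A1,lacZ,x,oops,0.02,6"), f)
  expect_error(read_timeseries(f, ct), "line")
})

test_that("plate maps round-trip and enforce their contract", {
  ct <- default_constants()
  ts <- render_plate(scenario_sole("sorbitol", ct), ct, no_noise())
  f <- withr::local_tempfile(fileext = ".json")
  write_platemap(ts, f, ct)
  pm <- read_platemap(f)
  expect_equal(nrow(pm$wells), nrow(ts$map))
  expect_identical(pm$background_strain, ct$background_strain)

  # duplicate well assignment
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$wells <- rbind(obj$wells, obj$wells[1, ])
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, dataframe = "rows", auto_unbox = TRUE)
  expect_error(read_platemap(f2), "duplicate")

  # missing CRP reporter: warn now, fail later in the CRP stage
  obj2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj2$wells <- obj2$wells[obj2$wells$strain != ct$crp_reporter_strain, ]
  obj2$crp_reporter_strain <- NULL
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f3, dataframe = "rows", auto_unbox = TRUE)
  expect_warning(read_platemap(f3), "CRP")
})

test_that("matrices round-trip through labeled TSV", {
  m <- matrix(c(1, 0.3, 0.8, 1), 2, 2,
              dimnames = list(c("lactose", "ribose"), c("lactose", "ribose")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m)
  expect_match(readLines(f, n = 1), "order: lactose,ribose")
})
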