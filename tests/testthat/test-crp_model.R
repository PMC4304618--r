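test_that("least-squares line fits match hand-computed coefficients", {
  f <- fit_input_function(tibble::tibble(crp_norm = c(0, 1), pa_norm = c(0, 1)))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  # normal equations by hand for (0,0), (1,1), (2,1)
  f2 <- fit_input_function(
    tibble::tibble(crp_norm = c(0, 1, 2), pa_norm = c(0, 1, 1))
  )
  expect_equal(f2$slope, 0.5)
  expect_equal(f2$intercept, 1 / 6, tolerance = 1e-12)

  # collinear points leave no residual
  f3 <- fit_input_function(
    tibble::tibble(crp_norm = c(0, 0.5, 1), pa_norm = 2 + 3 * c(0, 0.5, 1))
  )
  expect_equal(f3$rss, 0, tolerance = 1e-12)

  expect_error(
    fit_input_function(tibble::tibble(crp_norm = c(1, 1), pa_norm = c(0, 1)),
                       promoter = "lacZ"),
    "identical.*lacZ"
  )
})

test_that("r_squared matches its definition and edge cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero total variance")
})

test_that("CRP requirement and variant-slope comparisons are algebraic", {
  f <- function(s, i) structure(list(slope = s, intercept = i),
                                class = "input_function_fit")
  expect_equal(crp_required_for_max(f(1, 0)), 1)
  expect_equal(crp_required_for_max(f(0.5, 0)), 2)
  expect_error(crp_required_for_max(f(-1, 0)), "non-positive slope")
  expect_equal(compare_variant_slopes(f(1, 0), f(1, 0)), 0)
  expect_equal(compare_variant_slopes(f(1, 0), f(1.3, 0)), 30)
  expect_error(compare_variant_slopes(f(0, 0), f(1, 0)), "nonzero")
})

test_that("noiseless fits recover the generator input functions exactly", {
  ct <- default_constants()
  ds <- truth_crp_dataset(ct)
  for (k in seq_len(nrow(ct$promoters))) {
    prom <- ct$promoters[k, ]
    f <- fit_input_function(ds[ds$promoter == prom$name, ], prom$name)
    expect_equal(f$slope, prom$crp_slope, tolerance = 1e-6)
    expect_equal(f$intercept, prom$crp_intercept, tolerance = 1e-6)
  }
})

test_that("leave-one-out reproduces exact linear data and degrades with noise", {
  ct <- default_constants()
  ds <- truth_crp_dataset(ct)
  loo <- loo_predict(ds, ct = ct)
  expect_equal(loo$predictions$predicted, loo$predictions$pa_norm,
               tolerance = 1e-9)
  expect_equal(loo$r2, 1, tolerance = 1e-9)
  expect_lte(loo$r2, 1)

  # symmetric noise cannot improve on the noiseless fit
  set.seed(42)
  noisy <- ds
  noisy$pa_norm <- noisy$pa_norm + rnorm(nrow(noisy), 0, 0.05)
  loo_n <- loo_predict(noisy, ct = ct)
  expect_lt(loo_n$r2, 1)

  # full fits explain at least as much as leave-one-out predictions
  full_pred <- vapply(seq_len(nrow(noisy)), function(i) {
    f <- fit_input_function(noisy[noisy$promoter == noisy$promoter[i], ])
    f$intercept + f$slope * noisy$crp_norm[i]
  }, numeric(1))
  expect_gte(r_squared(noisy$pa_norm, full_pred), loo_n$r2)
})

test_that("leave-one-out refuses promoters with too few points", {
  ct <- default_constants()
  ds <- truth_crp_dataset(ct)
  ds2 <- ds[!(ds$promoter == "srlA" &
                seq_len(nrow(ds)) %in% which(ds$promoter == "srlA")[-(1:2)]), ]
  expect_error(loo_predict(ds2, ct = ct), "srlA")
})

test_that("every leave-one-out fit excludes the predicted point", {
  # two promoters with one deliberate outlier each: if the outlier were
  # included in its own fit, its prediction would chase it
  ds <- tibble::tibble(
    promoter = rep("p1", 5),
    condition = paste0("c", 1:5),
    pa_norm = c(0, 1, 2, 3, 10),   # last point far off the line
    crp_norm = c(0, 1, 2, 3, 4),
    cognate = "s1", partner = NA_character_, is_pair = FALSE
  )
  class(ds) <- c("crp_dataset", class(ds))
  loo <- loo_predict(ds)
  # prediction for the outlier comes from the clean line through the rest
  expect_equal(loo$predictions$predicted[5], 4, tolerance = 1e-9)
})
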