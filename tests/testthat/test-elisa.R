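test_that("endpoint titers interpolate in log2-dilution space", {
  s <- make_series(c(1.8, 1.4, 1.2, 0.8))
  out <- endpoint_titer(s, mode = "interpolated")
  # crossing between 8000 (1.2) and 16000 (0.8): fraction 0.5 of a 2-fold step
  expect_equal(out$titer, 8000 * 2^0.5, tolerance = 1e-12)
  expect_equal(out$censored, "not_censored")
  expect_false(out$noisy)

  disc <- endpoint_titer(s, mode = "discrete")
  expect_equal(disc$titer, 8000)
})

test_that("censoring at the range edges follows the boundary rules", {
  high <- endpoint_titer(make_series(c(2.0, 1.8, 1.5, 1.1)))
  expect_equal(high$censored, "above_range")
  expect_equal(high$titer, 16000)

  low <- endpoint_titer(make_series(c(0.9, 0.6, 0.3, 0.1)))
  expect_equal(low$censored, "below_range")
  expect_true(is.na(low$titer))
})

test_that("interpolated and discrete titers agree when an OD hits the target exactly", {
  s <- make_series(c(1.6, 1.0, 0.5, 0.2))
  expect_equal(endpoint_titer(s, mode = "interpolated")$titer,
               endpoint_titer(s, mode = "discrete")$titer)
  expect_equal(endpoint_titer(s, mode = "interpolated")$titer, 4000)
})

test_that("raising every OD never decreases the titer and the result stays bracketed", {
  withr::local_seed(15)
  for (i in 1:25) {
    od <- sort(runif(8, 0.1, 2.2), decreasing = TRUE)
    s <- make_series(od, dil = 2000 * 2^(0:7))
    t1 <- endpoint_titer(s)$titer
    t2 <- endpoint_titer(dplyr::mutate(s, od = od + 0.15))$titer
    if (!is.na(t1)) {
      expect_true(is.na(t2) || t2 >= t1 - 1e-9)
      expect_gte(t1, 2000)
      expect_lte(t1, 256000)
      # bracketing: the interpolated titer lies between the crossing pair
      below <- max(s$reciprocal_dilution[s$od >= 1])
      expect_gte(t1, below)
    }
  }
})

test_that("non-monotone series are flagged noisy, duplicates and short series error", {
  noisy <- endpoint_titer(make_series(c(1.8, 1.2, 1.5, 0.6)))
  expect_true(noisy$noisy)
  smooth <- endpoint_titer(make_series(c(1.8, 1.5, 1.2, 0.6)))
  expect_false(smooth$noisy)

  dup <- make_series(c(1.8, 1.2), dil = c(2000, 2000))
  expect_error(endpoint_titer(dup), class = "peptiter_validation_error")
  expect_error(endpoint_titer(make_series(1.5, dil = 2000)),
               class = "peptiter_validation_error")
})

test_that("the Frey cutoff is mean + sd x t-based prediction multiplier", {
  # n = 10 at 99.9%: multiplier = t_{0.999,9} * sqrt(1 + 1/10) ~= 4.507
  blanks <- c(0.040, 0.045, 0.048, 0.050, 0.052, 0.055, 0.058, 0.060,
              0.044, 0.048)
  fc <- frey_cutoff(blanks, confidence = 0.999)
  expect_equal(fc$multiplier, 4.5065, tolerance = 1e-4)
  expect_equal(fc$cutoff, mean(blanks) + sd(blanks) * 4.50653,
               tolerance = 1e-4)
  expect_equal(fc$n_blanks, 10L)
  expect_false(fc$degenerate)
  # frozen worked case: mean 0.050, sd 0.010 -> cutoff ~= 0.0951
  expect_equal(0.050 + 0.010 * fc$multiplier, 0.0951, tolerance = 5e-4)
})

test_that("Frey cutoff edge cases: zero sd, monotone confidence, n < 2", {
  fc0 <- frey_cutoff(rep(0.05, 8))
  expect_true(fc0$degenerate)
  expect_equal(fc0$cutoff, 0.05)

  blanks <- c(0.04, 0.05, 0.06, 0.05, 0.045)
  expect_gt(frey_cutoff(blanks, 0.999)$cutoff,
            frey_cutoff(blanks, 0.99)$cutoff)
  expect_error(frey_cutoff(0.05), class = "peptiter_validation_error")
  expect_error(frey_cutoff(blanks, confidence = 0.4),
               class = "peptiter_config_error")
})

test_that("fresh blanks exceed the 99.9% cutoff at about the nominal rate", {
  withr::local_seed(9)
  k <- 400L
  per <- 50L
  exceed <- vapply(seq_len(k), function(i) {
    fc <- frey_cutoff(rnorm(24, 0.05, 0.01), confidence = 0.999)
    sum(rnorm(per, 0.05, 0.01) > fc$cutoff)
  }, numeric(1))
  rate <- sum(exceed) / (k * per)
  se <- sqrt(0.001 * 0.999 / (k * per))
  expect_lt(abs(rate - 0.001), 4 * se + 1e-6)
})

test_that("serum retention reproduces both threshold rules", {
  titers <- tibble::tibble(
    serum_id = c("r1", "r2", "r3"), antigen_id = "p",
    titer = c(4000, 8000, NA_real_), mode = "interpolated",
    censored = c("not_censored", "not_censored", "below_range"),
    noisy = FALSE
  )
  strict <- retain_sera(titers, 4000, "strict_greater")
  expect_equal(strict$retained, c(FALSE, TRUE, FALSE))
  ge <- retain_sera(titers, 4000, "greater_equal")
  expect_equal(ge$retained, c(TRUE, TRUE, FALSE))
  expect_equal(unique(strict$rule), "strict_greater")
})

test_that("reactivity banding matches the published thresholds", {
  out <- reactivity_band(od = c(1.5, 0.045, 0.02), serum_max_od = 1.6,
                         cutoff = 0.03)
  expect_equal(as.character(out$band), c("+++", "+/-", "-"))
  expect_equal(out$pct_of_max[1], 1.5 / 1.6)

  # decision order: below cutoff wins even if <= 0.050
  expect_equal(as.character(
    reactivity_band(0.02, 1.6, cutoff = 0.03)$band), "-")
  # the undefined corner (od > 0.050 but < 5% of max) is "+" and flagged
  corner <- reactivity_band(0.06, 2.0, cutoff = 0.03)
  expect_equal(as.character(corner$band), "+")
  expect_true(corner$flagged)
  expect_error(reactivity_band(0.5, 0, 0.03),
               class = "peptiter_validation_error")
})

test_that("banding is total and exclusive over a spanning OD grid", {
  cutoff <- 0.03
  max_od <- 2.0
  grid <- c(0, 0.029, 0.03, 0.049, 0.050, 0.0501, 0.099, 0.1, 0.4999,
            0.5, 1.49, 1.5, 1.9, 2.0)
  bands <- reactivity_band(grid, max_od, cutoff)$band
  expect_false(anyNA(bands))
  expect_equal(
    as.character(bands),
    c("-", "-", "+/-", "+/-", "+/-", "+", "+", "+", "+",
      "++", "++", "+++", "+++", "+++")
  )
})

test_that("specificity matrices are rectangular with n/a for untested cells", {
  calls <- tibble::tibble(
    serum_id = c("r1", "r1", "r1", "r2", "r2"),
    antigen_id = c("a", "b", "c", "a", "b"),
    band = factor(c("+++", "+", "-", "++", "-"),
                  levels = c("-", "+/-", "+", "++", "+++"))
  )
  m <- specificity_matrix(calls)
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(m$c, c("-", "n/a"))

  expect_equal(nrow(specificity_matrix(calls[0, ])), 0L)
  expect_error(specificity_matrix(dplyr::bind_rows(calls, calls[1, ])),
               class = "peptiter_validation_error")
})

test_that("call_reactivity derives per-serum maxima and accepts a frey_cutoff", {
  data <- tibble::tibble(
    serum_id = c("r1", "r1", "r2", "r2"),
    antigen_id = c("a", "b", "a", "b"),
    od = c(1.6, 0.4, 0.8, 0.02)
  )
  fc <- frey_cutoff(c(0.05, 0.04, 0.06, 0.05, 0.045))
  calls <- call_reactivity(data, fc)
  expect_equal(as.character(calls$band), c("+++", "++", "+++", "-"))
  expect_equal(calls$pct_of_max, c(1, 0.25, 1, 0.025))
})
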