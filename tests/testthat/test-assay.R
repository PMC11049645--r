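test_that("inhibition percentage follows the plate equation", {
  expect_equal(inhibition_percent(0.5, 0.5, 1.0, 0.2), 100)  # A_S = A_SC
  expect_equal(inhibition_percent(1.0, 0.2, 1.0, 0.2), 0)    # full activity
  expect_equal(inhibition_percent(0.8, 0.2, 1.0, 0.2), 25)
  expect_error(inhibition_percent(0.5, 0.2, 0.7, 0.7), "A_NC")
  expect_warning(inhibition_percent(0.1, 0.5, 1.0, 0.2), "as-is")
  expect_warning(out <- inhibition_percent(1.2, 0.2, 1.0, 0.5), "as-is")
  expect_equal(out, -100)  # retained, not clipped
})

test_that("inhibition is invariant to shifting and scaling all readings", {
  set.seed(409)
  for (i in 1:25) {
    r <- sort(runif(4, 0.1, 2))
    # out-of-range percentages warn by design; irrelevant to the invariance
    base <- suppressWarnings(inhibition_percent(r[2], r[1], r[4], r[3]))
    shift <- runif(1, -1, 1)
    scale <- runif(1, 0.2, 5)
    expect_equal(suppressWarnings(
      inhibition_percent(r[2] + shift, r[1] + shift,
                         r[4] + shift, r[3] + shift)), base)
    expect_equal(suppressWarnings(
      inhibition_percent(r[2] * scale, r[1] * scale,
                         r[4] * scale, r[3] * scale)), base)
  }
})

test_that("viability percentage follows the MTT equation", {
  expect_equal(viability_percent(0.9, 0.1, 0.9), 100)  # test = control
  expect_equal(viability_percent(0.1, 0.1, 0.9), 0)    # test = blank
  expect_equal(viability_percent(0.6, 0.1, 0.9), 62.5)
  expect_error(viability_percent(0.5, 0.3, 0.3), "undefined")
})

test_that("4PL fit recovers noiseless truth and honours preconditions", {
  doses <- 10^seq(0, 3.5, length.out = 8)
  d <- gen_dose_response(ic50 = 200, hill = 1.3, bottom = 5, top = 95,
                         doses = doses, reps = 2, noise_sd = 0, seed = 2)
  fit <- fit_ic50(d$concentration, d$response)
  expect_equal(coef(fit)[["ic50"]], 200, tolerance = 1e-3)
  expect_equal(coef(fit)[["hill"]], 1.3, tolerance = 1e-3)
  expect_lte(coef(fit)[["bottom"]], coef(fit)[["top"]])
  expect_lt(fit$rss, 1e-6)

  # inflection definition: 0/100 extremes with 50 at the IC50 dose
  cc <- c(1, 10, 100, 1000, 1e4)
  resp <- c(0, 0, 50, 100, 100)
  fit2 <- fit_ic50(cc, resp, fix_bottom = 0, fix_top = 100)
  expect_equal(coef(fit2)[["ic50"]], 100, tolerance = 0.05)

  expect_error(fit_ic50(c(1, 10, 100), c(0, 50, 100)), "4 distinct")
  expect_error(fit_ic50(c(-1, 1, 10, 100), c(0, 10, 50, 100)), "positive")
  expect_error(fit_ic50(c(1, 10, 100, 1000), rep(40, 4)), "unidentifiable")
})

test_that("fits are deterministic and unit-consistent", {
  d <- gen_dose_response(ic50 = 150, doses = 10^seq(0, 3, length.out = 6),
                         noise_sd = 3, seed = 11)
  f1 <- fit_ic50(d$concentration, d$response)
  f2 <- fit_ic50(d$concentration, d$response)
  expect_identical(coef(f1), coef(f2))
  # rescaling the concentration axis rescales the IC50 identically
  f10 <- fit_ic50(d$concentration * 10, d$response)
  expect_equal(coef(f10)[["ic50"]] / coef(f1)[["ic50"]], 10,
               tolerance = 1e-6)
  # mg/mL mode converts through the peptide mass
  mass <- monoisotopic_mass("YPF")
  fmg <- fit_ic50(d$concentration * mass / 1e6, d$response,
                  unit = "mg_ml", mass_da = mass)
  expect_equal(fmg$ic50_um, coef(f1)[["ic50"]], tolerance = 1e-6)
  expect_equal(convert_ic50_units(1, 500), 2000)
})

test_that("ic50_fit methods expose the fitted curve", {
  d <- gen_dose_response(ic50 = 200, noise_sd = 0, seed = 5)
  fit <- fit_ic50(d$concentration, d$response)
  p <- coef(fit)
  expect_equal(predict(fit, p[["ic50"]]),
               (p[["bottom"]] + p[["top"]]) / 2, tolerance = 1e-6)
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$response)
  expect_output(print(fit), "IC50")
})

test_that("replicate IC50 summaries use the sample SD", {
  expect_equal(summarize_ic50(c(10, 10, 10)), c(mean = 10, sd = 0))
  expect_equal(summarize_ic50(c(8, 10, 12)), c(mean = 10, sd = 2))
  expect_error(summarize_ic50(10), "at least 2")
})
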