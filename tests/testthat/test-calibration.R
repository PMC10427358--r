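test_that("steady-state averaging uses the trailing window", {
  t <- 0:599  # 10 min at 1 Hz
  run <- standard_run("FMN", 0.1, t, rep(750, 600))
  res <- steady_state_average(run)
  expect_equal(res$mean, 750)
  expect_true(res$steady)

  # ramp then constant 500 for the final 5 min
  y <- c(seq(0, 500, length.out = 300), rep(500, 300))
  res2 <- steady_state_average(standard_run("FMN", 0.1, t, y))
  expect_equal(res2$mean, 500)
  expect_true(res2$steady)

  # still ramping: flagged not steady
  res3 <- steady_state_average(standard_run("FMN", 0.1, t, seq(0, 1000, length.out = 600)))
  expect_false(res3$steady)

  # noisy constant: mean within 3 sd/sqrt(n)
  set.seed(21)
  yn <- rnorm(600, 750, 10)
  res4 <- steady_state_average(standard_run("FMN", 0.1, t, yn))
  expect_lt(abs(res4$mean - 750), 3 * 10 / sqrt(300))

  expect_error(steady_state_average(standard_run("FMN", 0.1, 0:10, rep(1, 11))),
               "shorter")
})

test_that("calibration fitting matches the normal-equations oracle", {
  # exact line
  conc <- c(0, 0.05, 0.1, 0.2, 0.5)
  pts <- data.frame(concentration = conc, intensity = 2000 * conc + 150)
  cv <- fit_calibration(pts)
  expect_equal(cv$slope, 2000, tolerance = 1e-9)
  expect_equal(cv$intercept, 150, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)

  # two points
  cv2 <- fit_calibration(data.frame(concentration = c(0, 1),
                                    intensity = c(100, 1100)))
  expect_equal(cv2$slope, 1000, tolerance = 1e-12)
  expect_equal(cv2$intercept, 100, tolerance = 1e-12)

  # noisy standards: equals oracle to 1e-9 relative; CI covers truth
  set.seed(33)
  conc6 <- c(0, 0.02, 0.05, 0.1, 0.2, 0.4)
  y6 <- 2000 * conc6 + 150 + rnorm(6, 0, 20)
  cv3 <- fit_calibration(data.frame(concentration = conc6, intensity = y6))
  or <- oracle_ols(conc6, y6)
  expect_equal(cv3$slope, unname(or["slope"]), tolerance = 1e-9)
  expect_equal(cv3$intercept, unname(or["intercept"]), tolerance = 1e-9)
  fit <- stats::lm(y6 ~ conc6)
  ci <- confint(fit)["conc6", ]
  expect_true(ci[1] <= 2000 && 2000 <= ci[2])

  # random small designs vs the oracle
  for (s in 1:20) {
    set.seed(s)
    x <- sort(runif(5, 0, 1))
    y <- 3 + 800 * x + rnorm(5, 0, 5)
    cvr <- fit_calibration(data.frame(concentration = x, intensity = y))
    orr <- oracle_ols(x, y)
    expect_equal(cvr$slope, unname(orr["slope"]), tolerance = 1e-9)
    expect_equal(cvr$intercept, unname(orr["intercept"]), tolerance = 1e-9)
  }

  expect_error(fit_calibration(data.frame(concentration = c(1, 1),
                                          intensity = c(5, 6))), "degenerate")
  expect_error(fit_calibration(data.frame(concentration = c(0, 1),
                                          intensity = c(100, 50))), "slope")
})

test_that("blank sigma comes from blank replicates when available", {
  set.seed(4)
  conc <- c(0, 0, 0, 0.1, 0.2, 0.4)
  y <- 2000 * conc + 100 + rnorm(6, 0, 10)
  cv <- fit_calibration(data.frame(concentration = conc, intensity = y))
  expect_equal(cv$sigma_blank, sd(y[1:3]))
  # fewer than 3 blanks: RMS residual fallback
  cv2 <- fit_calibration(data.frame(concentration = conc[3:6], intensity = y[3:6]))
  fit <- stats::lm(y[3:6] ~ conc[3:6])
  expect_equal(cv2$sigma_blank, sqrt(mean(residuals(fit)^2)))
})

test_that("blank offset averages the first n blanks and shrinks as 1/sqrt(n)", {
  expect_equal(blank_offset(rep(0, 10)), 0)
  expect_equal(blank_offset(rep(0.005, 12)), 0.005)
  expect_error(blank_offset(rep(0, 5)), "blank")

  sd10 <- sd(vapply(1:500, function(s) {
    set.seed(s); blank_offset(rnorm(10, 0, 1), 10)
  }, numeric(1)))
  sd40 <- sd(vapply(1:500, function(s) {
    set.seed(1000 + s); blank_offset(rnorm(40, 0, 1), 40)
  }, numeric(1)))
  expect_equal(sd10 / sd40, 2, tolerance = 0.2)
})

test_that("limit of detection follows the 3-sigma convention", {
  expect_equal(limit_of_detection(0, 2), 0)
  expect_equal(limit_of_detection(1, 2), 1.5)
  # homogeneity: scaling sigma and slope together leaves LOD unchanged
  for (f in c(0.1, 3, 1e4)) {
    expect_equal(limit_of_detection(7 * f, 1234 * f), limit_of_detection(7, 1234))
  }
  # algebraic round trip through the 4.4 nM anchor
  ch <- fix_channel_fmn()
  lod_conc <- convert_units(4.4, "nM_to_ug_per_ml", ch)
  slope <- 48571
  sigma <- slope * lod_conc / 3
  expect_equal(convert_units(limit_of_detection(sigma, slope), "ug_per_ml_to_nM", ch),
               4.4, tolerance = 1e-9)
  expect_error(limit_of_detection(1, 0), "slope")
})

test_that("cross-talk matrix flags contaminated channels", {
  chs <- default_channels(c("FMN", "NADH"))
  fl <- default_fluorophores()
  nm <- noiseless_model()
  measure <- function(chn, an, conc) {
    dk <- emit_frame(numeric(), chs[[chn]], fl, nm, dark = TRUE)
    lt <- emit_frame(stats::setNames(conc, an), chs[[chn]], fl, nm)
    band_intensity(dark_subtract(lt, dk), chs[[chn]])
  }
  design <- expand.grid(channel = names(chs), analyte = c("FMN", "NADH"),
                        concentration = c(0, 0.05, 0.1),
                        stringsAsFactors = FALSE)
  design$intensity <- mapply(measure, design$channel, design$analyte,
                             design$concentration)
  ct <- crosstalk_matrix(design)
  expect_equal(unname(diag(ct$matrix[c("FMN", "NADH"), c("FMN", "NADH")])), c(1, 1))
  expect_lt(abs(ct$matrix["FMN", "NADH"]), 0.05)
  expect_lt(abs(ct$matrix["NADH", "FMN"]), 0.05)
  expect_equal(ct$verdict, "PASS")

  # identical fluorophores on two channels: off-diagonal ~ 1, FAIL
  fl2 <- fl
  fl2$NADH <- fl$FMN
  fl2$NADH$analyte <- "NADH"
  measure2 <- function(chn, an, conc) {
    dk <- emit_frame(numeric(), chs[[chn]], fl2, nm, dark = TRUE)
    lt <- emit_frame(stats::setNames(conc, an), chs[[chn]], fl2, nm)
    band_intensity(dark_subtract(lt, dk), chs[[chn]])
  }
  design2 <- design
  design2$intensity <- mapply(measure2, design2$channel, design2$analyte,
                              design2$concentration)
  ct2 <- crosstalk_matrix(design2)
  expect_equal(ct2$verdict, "FAIL")
  expect_gt(abs(ct2$matrix["FMN", "NADH"]), 0.5)

  # zero-concentration-only column is reported missing (NA), not invented
  design3 <- design[!(design$analyte == "NADH" & design$concentration > 0), ]
  ct3 <- crosstalk_matrix(design3)
  expect_true(all(is.na(ct3$matrix[, "NADH"])))

  # missing diagonal run: NADH channel never sees its own analyte
  design4 <- design[design$analyte == "FMN", ]
  expect_error(crosstalk_matrix(design4), "diagonal")
})

test_that("adduct masses use integer nominal atomic weights", {
  expect_equal(expected_adduct_mz("H2O"), 19)
  expect_equal(expected_adduct_mz("C17H21N4O9P"), 457)
  expect_equal(expected_adduct_mz("C4H7N3O"), 114)
  # additive over formula concatenation (up to the double proton)
  expect_equal(expected_adduct_mz("C2H6") + expected_adduct_mz("O2"),
               expected_adduct_mz("C2H6O2") + 1)
  expect_error(expected_adduct_mz("C2Xx3"), "unknown element")
  expect_error(expected_adduct_mz("C2H6", adduct = "+Na"), "adduct")
})

test_that("sensor estimates agree with an orthogonal reference", {
  x <- c(0.1, 0.2, 0.4)
  r <- validate_against_reference(x, x)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$bias, 0)

  r2 <- validate_against_reference(x, 2 * x)
  expect_equal(r2$slope, 0.5, tolerance = 1e-12)

  # simulator truth vs pipeline estimates over 20 paired samples
  ch <- fix_channel_fmn()
  nm <- anchored_noise_model()
  cv <- analytic_curve()
  set.seed(17)
  truth <- seq(0.005, 0.1, length.out = 20)
  est <- vapply(truth, function(conc) {
    dk <- emit_frame(numeric(), ch, noise = nm, dark = TRUE)
    lt <- emit_frame(c(FMN = conc), ch, noise = nm)
    net <- band_intensity(dark_subtract(lt, dk), ch)
    concentration_from_intensity(net, cv)$concentration
  }, numeric(1))
  r3 <- validate_against_reference(est, truth)
  expect_gt(r3$r, 0.99)

  expect_error(validate_against_reference(1:2, 1:2), "paired")
})

test_that("simulated calibrations recover the optics and stay in spec", {
  cv <- calibrate_simulated("FMN", seed = 1)
  slope_true <- expected_band_response(default_fluorophores()$FMN,
                                       fix_channel_fmn(), fix_grid())
  expect_equal(cv$slope, slope_true, tolerance = 0.02)
  expect_gt(cv$r_squared, 0.999)
  expect_lt(abs(cv$blank_offset), 0.02)
  # LOD lands near the 4.4 nM design anchor
  lod_nM <- convert_units(cv$lod, "ug_per_ml_to_nM", fix_channel_fmn())
  expect_equal(lod_nM, 4.4, tolerance = 0.15)

  # curves round-trip through JSON
  p <- withr::local_tempfile(fileext = ".json")
  write_curves(list(FMN = cv), p)
  back <- read_curves(p)
  expect_equal(back$FMN$slope, cv$slope)
  expect_equal(back$FMN$lod, cv$lod)
  expect_equal(back$FMN$blank_offset, cv$blank_offset)
})
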