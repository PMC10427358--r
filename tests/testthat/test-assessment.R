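test_that("trapezoidal AUC handles endpoints, geometry and additivity", {
  # constant INR of 1 over 24 h integrates to 24
  expect_identical(auc_trapezoid(c(0, 24), c(1, 1)), 24)
  expect_equal(auc_trapezoid(0:24, rep(1, 25), 0, 24), 24)

  # all-zero series
  expect_equal(auc_trapezoid(0:60, rep(0, 61)), 0)

  # triangle 0 -> 2 -> 0 over [0, 60]: area 1/2 * 60 * 2
  expect_equal(auc_trapezoid(c(0, 30, 60), c(0, 2, 0)), 60)

  # interpolated endpoints: integral of y = t over [10, 20] sampled at 0/15/30
  expect_equal(auc_trapezoid(c(0, 15, 30), c(0, 15, 30), 10, 20), 150)

  # additivity to 1e-9
  set.seed(13)
  tt <- sort(runif(40, 0, 100))
  yy <- abs(rnorm(40))
  full <- auc_trapezoid(tt, yy, 5, 95)
  expect_equal(auc_trapezoid(tt, yy, 5, 40) + auc_trapezoid(tt, yy, 40, 95),
               full, tolerance = 1e-9)

  # constant c over span T equals c T exactly
  expect_equal(auc_trapezoid(seq(0, 7, 0.5), rep(3.2, 15)), 3.2 * 7)

  # matches the brute-force knot-walk oracle on full spans
  expect_equal(auc_trapezoid(tt, yy), oracle_trapz(tt, yy), tolerance = 1e-12)

  expect_error(auc_trapezoid(0:10, rep(1, 11), 20, 30), "cover")
  expect_error(auc_trapezoid(0:10, rep(1, 11), -5, 10), "extrapolation")
})

test_that("grid resampling is piecewise linear without extrapolation", {
  tr <- trajectory("g", c(0, 10, 20), c(0, 10, 5))
  expect_equal(resample_to_grid(tr, c(0, 10, 20)), c(0, 10, 5))
  expect_equal(resample_to_grid(trajectory("g", c(0, 10), c(0, 10)), 5), 5)
  expect_true(is.na(resample_to_grid(tr, 25)))

  set.seed(19)
  tt <- sort(runif(15, 0, 60))
  yy <- abs(rnorm(15))
  tr2 <- trajectory("r", tt, yy)
  for (q in runif(10, min(tt), max(tt))) {
    expect_equal(resample_to_grid(tr2, q), oracle_pwlinear(tt, yy, q),
                 tolerance = 1e-12)
  }
})

test_that("reference bands pool cohorts pointwise", {
  g <- seq(0, 60, 5)
  tr <- function(id, v) trajectory(id, g, rep(v, length(g)))
  # identical trajectories give a zero-width band equal to them
  b0 <- reference_band(list(tr("a", 2), tr("b", 2)), g)
  expect_equal(b0$mean, rep(2, length(g)))
  expect_equal(b0$lower, b0$upper)

  # constants 1 and 3 average to 2
  b1 <- reference_band(list(tr("a", 1), tr("b", 3)), g)
  expect_equal(b1$mean, rep(2, length(g)))
  expect_true(all(b1$lower <= b1$mean & b1$mean <= b1$upper))

  # permutation invariance
  co <- make_graft_cohort(6, 0, seed = 4)
  b_fwd <- reference_band(co, g)
  b_rev <- reference_band(rev(co), g)
  expect_equal(b_fwd$mean, b_rev$mean)
  expect_equal(b_fwd$upper, b_rev$upper)

  # affine equivariance under scaling of all trajectories
  co_scaled <- lapply(co, function(x) trajectory(x$graft_id, x$timestamps_min,
                                                 2 * x$concentrations))
  b_sc <- reference_band(co_scaled, g)
  expect_equal(b_sc$mean, 2 * b_fwd$mean, tolerance = 1e-12)
  expect_equal(b_sc$upper, 2 * b_fwd$upper, tolerance = 1e-12)

  expect_error(reference_band(list(tr("a", 1)), g), "trajectories")

  # JSON round trip
  p <- withr::local_tempfile(fileext = ".json")
  write_band(b_fwd, p)
  back <- read_band(p)
  expect_equal(back$mean, b_fwd$mean)
  expect_equal(back$upper, b_fwd$upper)
})

test_that("band coverage is near nominal for Gaussian cohorts", {
  set.seed(7)
  g <- seq(0, 60, by = 2)
  base <- 0.02 * (1 - exp(-g / 10))
  mk <- function(i) trajectory(paste0("g", i), g,
                               pmax(base + rnorm(length(g), 0, 0.004), 0))
  band <- reference_band(lapply(1:200, mk), g)
  inside <- unlist(lapply(201:300, function(i) {
    v <- resample_to_grid(mk(i), g)
    v >= band$lower & v <= band$upper
  }))
  expect_gte(mean(inside), 0.93)
  expect_lte(mean(inside), 0.97)
})

test_that("trajectory classification separates rising grafts from the band", {
  band_cohort <- make_graft_cohort(10, 0, seed = 2)
  band <- reference_band(band_cohort)

  # the band mean itself is WITHIN
  mean_tr <- trajectory("mean", band$grid_min, band$mean)
  expect_equal(classify_trajectory(mean_tr, band)$status, "WITHIN")

  # twice the upper envelope everywhere: DEVIATING by the band rule
  high_tr <- trajectory("high", band$grid_min, band$upper * 2 + 1e-6)
  cls_high <- classify_trajectory(high_tr, band)
  expect_equal(cls_high$status, "DEVIATING")
  expect_match(cls_high$reasons, "above_band", all = FALSE)

  # monotonicity: raising a trajectory never converts DEVIATING to WITHIN
  for (s in 1:5) {
    set.seed(100 + s)
    tr <- make_graft_cohort(2, 1, seed = 100 + s)[[3]]
    before <- classify_trajectory(tr, band)$status
    raised <- trajectory(tr$graft_id, tr$timestamps_min,
                         tr$concentrations + 0.01)
    after <- classify_trajectory(raised, band)$status
    if (before == "DEVIATING") expect_equal(after, "DEVIATING")
  }

  # sparse coverage yields the explicit third state
  short_tr <- trajectory("s", c(50, 55, 60), c(0.01, 0.01, 0.01))
  expect_equal(classify_trajectory(short_tr, band)$status, "INSUFFICIENT_DATA")
})

test_that("cohort classification reaches the expected separation", {
  band <- reference_band(make_graft_cohort(10, 0, seed = 2))
  bad <- make_graft_cohort(2, 5, seed = 1)
  labs <- attr(bad, "labels")
  bad_status <- vapply(bad[labs == "DISCARDED"],
                       function(tr) classify_trajectory(tr, band)$status,
                       character(1))
  expect_true(all(bad_status == "DEVIATING"))

  held_good <- make_graft_cohort(20, 0, seed = 3)
  good_status <- vapply(held_good,
                        function(tr) classify_trajectory(tr, band)$status,
                        character(1))
  expect_gte(mean(good_status == "WITHIN"), 0.9)
})

test_that("the discrete protocol discards on high late readings", {
  keep <- discrete_protocol(c(`5` = 500, `10` = 500, `15` = 500, `30` = 500,
                              `60` = 500))
  expect_equal(keep$verdict, "KEEP")

  hit30 <- discrete_protocol(c(`5` = 100, `10` = 300, `15` = 800, `30` = 3500,
                               `60` = 2000))
  expect_equal(hit30$verdict, "DISCARD_CANDIDATE")
  expect_true(30 %in% hit30$triggered_at_min)

  # boundary: 2999 at 30 min passes, 3001 at 60 min triggers
  edge <- discrete_protocol(c(`5` = 100, `10` = 200, `15` = 400, `30` = 2999,
                              `60` = 3001))
  expect_equal(edge$verdict, "DISCARD_CANDIDATE")
  expect_equal(edge$triggered_at_min, 60)

  expect_error(discrete_protocol(c(`5` = 1, `10` = 1)), "30-min")
})

test_that("exponential decay fits recover parameters", {
  t <- 0:7
  # noiseless identity for a rate grid
  for (k in c(0.05, 0.2, 0.5, 1, 2)) {
    y <- 1000 * exp(-k * t) + 50
    f <- fit_exponential_decay(t, y)
    expect_false(f$degenerate)
    expect_equal(f$amplitude, 1000, tolerance = 1e-6)
    expect_equal(f$rate, k, tolerance = 1e-6)
    expect_equal(f$baseline, 50, tolerance = 1e-4)
  }

  # constant series: degenerate, rate 0
  fc <- fit_exponential_decay(t, rep(100, 8))
  expect_true(fc$degenerate)
  expect_equal(fc$rate, 0)

  # 5% multiplicative noise, 100 seeds: median relative rate error < 10%
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- (1000 * exp(-0.5 * t) + 50) * exp(rnorm(8, 0, 0.05))
    abs(fit_exponential_decay(t, y)$rate - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(errs), 0.10)

  expect_error(fit_exponential_decay(0:2, c(3, 2, 1)), "points")
  expect_error(fit_exponential_decay(0:4, c(3, 2, 1, 0, -1)), "positive")
})

test_that("interpolation refuses extrapolation and hits samples exactly", {
  # factor V at 24 h = 40%, 72 h = 80%: midpoint 48 h = 60%
  expect_equal(interpolate_at(c(24, 72), c(40, 80), 48), 60)
  expect_equal(interpolate_at(c(24, 72), c(40, 80), 72), 80)
  set.seed(23)
  tt <- sort(runif(12, 0, 10))
  yy <- rnorm(12)
  for (q in runif(8, min(tt), max(tt))) {
    expect_equal(interpolate_at(tt, yy, q), oracle_pwlinear(tt, yy, q),
                 tolerance = 1e-12)
  }
  expect_error(interpolate_at(c(24, 72), c(40, 80), 100), "extrapolation")
})

test_that("correlation reports recover known couplings", {
  x <- 1:10
  expect_equal(correlation_report(x, 2 * x + 1, "pearson")$r, 1)
  expect_equal(correlation_report(x, exp(x / 3), "spearman")$r, 1)
  expect_error(correlation_report(1:2, 1:2), "paired")

  # outcome = alpha * AUC + noise over a 19-graft cohort: r in the central
  # 95% sampling interval around the design correlation
  set.seed(6)
  co <- make_graft_cohort(19, 0, seed = 6)
  auc <- vapply(co, function(tr) auc_trapezoid(tr$timestamps_min,
                                               tr$concentrations, 0, 60),
                numeric(1))
  alpha <- 4000
  sigma_out <- 0.5 * stats::sd(alpha * auc)
  outcome <- alpha * auc + rnorm(19, 0, sigma_out)
  rho <- 1 / sqrt(1 + (sigma_out / (alpha * stats::sd(auc)))^2)
  r <- correlation_report(auc, outcome, "pearson")$r
  # Fisher-z central 95% interval of a sample r at n = 19
  z <- atanh(rho) + c(-1, 1) * 1.96 / sqrt(19 - 3)
  expect_gte(r, tanh(z[1]))
  expect_lte(r, tanh(z[2]))
})

test_that("graft reports bundle the assessment deterministically", {
  band <- reference_band(make_graft_cohort(10, 0, seed = 2))
  g <- seq(0, 60, 2)

  # zero trajectory: AUC 0, WITHIN, KEEP
  zero <- trajectory("zero", g, rep(0, length(g)))
  rep0 <- graft_report(zero, band,
                       discrete_samples_au = c(`5` = 10, `10` = 10, `15` = 10,
                                               `30` = 10, `60` = 10))
  expect_equal(rep0$auc_0_60_ug_min_per_ml, 0)
  expect_equal(rep0$classification, "WITHIN")
  expect_equal(rep0$discrete_verdict, "KEEP")

  # constant 1 ug/mL over 60 min: AUC 60
  const <- trajectory("const", g, rep(1, length(g)))
  expect_equal(graft_report(const)$auc_0_60_ug_min_per_ml, 60)

  # default poor graft, seed 1: DEVIATING with the slope rule recorded
  bad <- make_graft_cohort(2, 1, seed = 1)[[3]]
  repb <- graft_report(bad, band)
  expect_equal(repb$classification, "DEVIATING")
  expect_match(repb$classification_reasons, "rising_slope", all = FALSE)

  # a run shorter than 30 min is an explicit non-result
  short <- trajectory("short", c(0, 10, 20), c(0, 0.01, 0.012))
  expect_equal(graft_report(short)$status, "INSUFFICIENT_DATA")

  # serialisation
  tmp <- withr::local_tempdir()
  jp <- file.path(tmp, "r.json")
  tp <- file.path(tmp, "r.txt")
  write_graft_report(rep0, jp, tp)
  doc <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(doc$classification, "WITHIN")
  expect_match(readLines(tp), "KEEP", all = FALSE)
})
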