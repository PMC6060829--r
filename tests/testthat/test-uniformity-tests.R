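test_that("Rayleigh test hits its closed-form corner cases", {
  grid <- angles(2 * pi * (0:11) / 12)
  rg <- rayleigh_test(grid)
  expect_lt(unname(rg$statistic), 1e-12)
  expect_gt(rg$p.value, 0.999)

  conc <- rayleigh_test(angles(rep(2.1, 20)))
  expect_equal(unname(conc$statistic), 1)
  expect_lt(conc$p.value, 1e-6)

  expect_equal(rayleigh_test(angles(rep(1, 3)))$calibration_method,
               "monte_carlo")  # analytic approximation not trusted below n = 4
})

test_that("V-test responds to the pre-specified direction as cos(offset)", {
  at_mu0 <- v_test(angles(rep(0.9, 25)), mu0 = 0.9)
  expect_equal(unname(at_mu0$statistic), 1)
  expect_lt(at_mu0$p.value, 1e-6)

  orth <- v_test(angles(rep(0.9 + pi / 2, 25)), mu0 = 0.9)
  expect_lt(abs(unname(orth$statistic)), 1e-12)
  expect_equal(orth$p.value, 0.5, tolerance = 1e-12)

  expect_error(v_test(angles(rep(1, 10))), "mu0")
  deg <- v_test(angles(rep(45, 10), unit = "degrees"), mu0 = 45,
                mu0_unit = "degrees")
  expect_equal(unname(deg$statistic), 1)
})

test_that("Kuiper statistic matches brute force and is rotation invariant", {
  grid <- 2 * pi * (0:19) / 20
  expect_equal(unname(kuiper_test(angles(grid))$statistic), kuiper_brute(grid))
  expect_equal(unname(kuiper_test(angles(grid))$statistic), 1 / 20)

  set.seed(5)
  for (i in 1:5) {
    x <- runif(30, 0, 2 * pi)
    v0 <- unname(kuiper_test(angles(x))$statistic)
    expect_equal(unname(kuiper_test(angles(x + runif(1, 0, 2 * pi)))$statistic),
                 v0, tolerance = 1e-9)
    expect_equal(v0, kuiper_brute(x), tolerance = 1e-12)
  }
})

test_that("Watson statistic matches hand evaluation and is rotation invariant", {
  # antipodal pair: u = (0, 1/2), both centred terms vanish, U2 = 1/(12*2)
  expect_equal(unname(watson_test(angles(c(0, pi)))$statistic), 1 / 24)

  set.seed(6)
  x <- runif(30, 0, 2 * pi)
  u0 <- unname(watson_test(angles(x))$statistic)
  for (delta in runif(5, 0, 2 * pi)) {
    expect_equal(unname(watson_test(angles(x + delta))$statistic), u0,
                 tolerance = 1e-9)
  }
})

test_that("Rao spacing statistic is exact on grids and degenerate samples", {
  grid <- angles(2 * pi * (0:24) / 25)
  rg <- rao_spacing_test(grid, mc_reps = 999, seed = 1)
  expect_lt(unname(rg$statistic), 1e-12)
  expect_gt(rg$p.value, 0.999)

  ident <- angles(rep(1.234, 10))
  expect_equal(unname(rao_spacing_test(ident, mc_reps = 999, seed = 1)$statistic),
               2 * pi * (1 - 1 / 10))
  expect_equal(unname(rao_spacing_test(ident, mc_reps = 999, seed = 1)$statistic),
               rao_brute(as.numeric(ident)))

  set.seed(8)
  x <- runif(25, 0, 2 * pi)
  s0 <- unname(rao_spacing_test(angles(x), mc_reps = 999, seed = 1)$statistic)
  expect_equal(unname(rao_spacing_test(angles(x + 1.1), mc_reps = 999,
                                       seed = 1)$statistic), s0,
               tolerance = 1e-9)
})

test_that("Hermans-Rasson and smooth-test statistics are rotation invariant", {
  set.seed(9)
  x <- runif(25, 0, 2 * pi)
  cal_hr <- calibrate_null("hermans_rasson", 25, reps = 999, seed = 2)
  cal_bg <- calibrate_null("bogdan", 25, reps = 999, seed = 2)
  hr0 <- unname(hermans_rasson_test(angles(x), calibration = cal_hr)$statistic)
  bg0 <- bogdan_test(angles(x), calibration = cal_bg)
  for (delta in runif(5, 0, 2 * pi)) {
    xr <- angles(x + delta)
    expect_equal(unname(hermans_rasson_test(xr, calibration = cal_hr)$statistic),
                 hr0, tolerance = 1e-9)
    bgr <- bogdan_test(xr, calibration = cal_bg)
    expect_equal(unname(bgr$statistic), unname(bg0$statistic),
                 tolerance = 1e-9)
    expect_identical(bgr$selected_dim, bg0$selected_dim)
  }
})

test_that("null calibrations are deterministic, self-consistent and stable", {
  c1 <- calibrate_null("hermans_rasson", 20, reps = 999, seed = 5)
  c2 <- calibrate_null("hermans_rasson", 20, reps = 999, seed = 5)
  expect_identical(c1$sorted, c2$sorted)

  # the median null statistic sits at p ~ 0.5 by definition of the empirical p
  med <- stats::median(c1$sorted)
  x <- angles(rep(0, 20))  # placeholder sample; p computed from the statistic
  p_med <- (1 + sum(c1$sorted >= med)) / (c1$reps + 1)
  expect_equal(p_med, 0.5, tolerance = 0.01)

  # two independent large calibrations give nearly the same p for a fixed sample
  set.seed(77)
  y <- angles(runif(20, 0, 2 * pi))
  pa <- hermans_rasson_test(y, calibration = calibrate_null(
    "hermans_rasson", 20, reps = 9999, seed = 101))$p.value
  pb <- hermans_rasson_test(y, calibration = calibrate_null(
    "hermans_rasson", 20, reps = 9999, seed = 202))$p.value
  expect_lt(abs(pa - pb), 0.02)

  expect_error(hermans_rasson_test(y, calibration = calibrate_null(
    "hermans_rasson", 25, reps = 999, seed = 1)), "does not match")
  expect_error(hermans_rasson_test(y, calibration = calibrate_null(
    "rao", 20, reps = 999, seed = 1)), "'rao'")
})

test_that("analytic and Monte-Carlo p-values agree for the Rayleigh test", {
  n <- 25
  cal <- calibrate_null("rayleigh", n, reps = 9999, seed = 31)
  outside <- 0L
  for (i in 1:200) {
    x <- rcirc(n, dist_vonmises(0, 2), seed = 4000 + i)
    pa <- rayleigh_test(x)$p.value
    pm <- rayleigh_test(x, method = "monte_carlo", calibration = cal)$p.value
    band <- 3 * sqrt(max(pa * (1 - pa), 1e-6) / cal$reps) + 2 / cal$reps
    if (abs(pa - pm) > band + 0.004) outside <- outside + 1L
  }
  # 3-sigma bands admit rare excursions plus a small approximation bias
  expect_lte(outside, 10L)
})

test_that("Monte-Carlo p-values are uniform under the null", {
  # a valid MC-calibrated test must give ~uniform p on uniform data
  for (tt in c("hermans_rasson", "bogdan", "rao")) {
    cal <- calibrate_null(tt, 25, reps = 9999, seed = 55)
    m <- matrix(withr::with_seed(66, runif(10000 * 25, 0, 2 * pi)), 10000, 25)
    st <- circuniform:::stat_batch(tt, m, max_dim = 10L)
    p <- circuniform:::p_from_null(cal, st)
    ks <- max(abs(sort(p) - seq_along(p) / length(p)))
    expect_lt(ks, 0.02)
  }
})

test_that("the smooth test's selected dimension tracks the lowest informative harmonic", {
  # moderately concentrated unimodal data: the first harmonic carries the
  # signal and the Schwarz penalty keeps higher ones out
  dims_uni <- sapply(1:200, function(i) {
    m <- matrix(as.numeric(rcirc(25, dist_vonmises(0, 1.5), seed = 7000 + i)), 1)
    circuniform:::bogdan_stat_m(m, 10L)$dim
  })
  expect_gt(mean(dims_uni == 1), 0.6)

  # mirrored bimodal data: the first harmonic cancels, the second carries the
  # signal, so the selection must reach dimension two or higher
  dims_bi <- sapply(1:200, function(i) {
    m <- matrix(as.numeric(rcirc(25, mixture_modes(2, "symmetric", 3),
                                 seed = 7500 + i)), 1)
    circuniform:::bogdan_stat_m(m, 10L)$dim
  })
  expect_gt(mean(dims_bi >= 2), 0.6)
})

test_that("sample-size preconditions are enforced", {
  expect_error(kuiper_test(angles(1)), "at least 2")
  expect_error(watson_test(angles(1)), "at least 2")
  expect_error(rao_spacing_test(angles(c(1, 2, 3))), "at least 4")
  expect_error(hermans_rasson_test(angles(c(1, 2, 3))), "at least 4")
  expect_error(bogdan_test(angles(c(1, 2, 3, 4))), "at least 5")
  expect_error(bogdan_test(angles(runif(10)), max_dim = 0), "max_dim")
})

test_that("duplicate angles (zero spacings) are legal in every test", {
  x <- angles(rep(c(0.5, 2.5, 4.5), each = 4))
  expect_s3_class(rao_spacing_test(x, mc_reps = 999, seed = 1), "circ_test")
  expect_s3_class(kuiper_test(x), "circ_test")
  expect_s3_class(watson_test(x), "circ_test")
  expect_s3_class(hermans_rasson_test(x, mc_reps = 999, seed = 1), "circ_test")
})

test_that("V-test outpowers Rayleigh when its direction is right, and f-fold
           transformation restores Rayleigh power on mirrored modes", {
  # paired: identical seeds draw identical samples inside the engine
  vm <- dist_vonmises(mu = 0, kappa = 1)
  pv <- estimate_rejection_rate(test_config("v", mu0 = 0), vm, n = 15,
                                reps = 3000, seed = 17)
  pr <- estimate_rejection_rate("rayleigh", vm, n = 15, reps = 3000, seed = 17)
  expect_gt(pv$power, pr$power)

  bim <- mixture_modes(2, "symmetric", kappa = 3)
  p2x <- estimate_rejection_rate(test_config("rayleigh", ffold = 2), bim,
                                 n = 25, reps = 2000, seed = 18)
  praw <- estimate_rejection_rate("rayleigh", bim, n = 25, reps = 2000,
                                  seed = 18)
  phr <- estimate_rejection_rate("hermans_rasson", bim, n = 25, reps = 2000,
                                 seed = 18, null_reps = 4999)
  expect_gt(p2x$power, 0.8)
  expect_gt(phr$power, praw$power + 0.5)   # HR vastly outpowers raw Rayleigh
  expect_lt(praw$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("power rises monotonically in concentration and sample size", {
  sc <- scenario("unimodal_vm", sweep_values = c(0, 1, 2, 3),
                 sample_sizes = c(15, 40), reps = 1000,
                 tests = list("rayleigh", "kuiper", "watson",
                              test_config("rao", method = "monte_carlo")))
  res <- as.data.frame(run_scenario(sc, seed = 23, null_reps = 4999))
  noise <- 3 * sqrt(0.25 / 1000) * sqrt(2)
  for (tt in unique(res$test)) {
    for (n in c(15, 40)) {
      p <- res$power[res$test == tt & res$n == n]
      expect_true(all(diff(p) > -noise))
    }
    for (k in c(1, 2, 3)) {
      p <- res$power[res$test == tt & res$sweep_value == k]
      expect_true(all(diff(p) > -noise))
    }
  }
})
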