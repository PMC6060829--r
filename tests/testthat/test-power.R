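test_that("rejection-rate estimates are calibrated, saturate, and reproduce", {
  t1 <- estimate_rejection_rate("rayleigh", dist_uniform(), n = 25,
                                reps = 2000, seed = 3)
  expect_lt(abs(t1$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  sat <- estimate_rejection_rate("rayleigh", dist_vonmises(0, 6), n = 100,
                                 reps = 500, seed = 3)
  expect_gt(sat$power, 0.995)

  a <- estimate_rejection_rate("watson", dist_vonmises(0, 1), n = 20,
                               reps = 500, seed = 9)
  b <- estimate_rejection_rate("watson", dist_vonmises(0, 1), n = 20,
                               reps = 500, seed = 9)
  expect_identical(a, b)
})

test_that("a one-cell scenario and a direct estimate are the same computation", {
  sc <- scenario("bimodal_sym", sweep_values = 2, sample_sizes = 25,
                 tests = list("hermans_rasson"), reps = 300)
  row <- run_scenario(sc, seed = 12, null_reps = 1999)
  direct <- estimate_rejection_rate("hermans_rasson",
                                    mixture_modes(2, "symmetric", kappa = 2),
                                    n = 25, reps = 300, seed = 12,
                                    null_reps = 1999)
  expect_equal(row$power, direct$power)
  expect_equal(row$rejections, direct$rejections)
})

test_that("grid cells are independently re-runnable", {
  sc_full <- scenario("bimodal_sym", sweep_values = c(1, 3), sample_sizes = 25,
                      tests = list("kuiper"), reps = 300)
  sc_cell <- scenario("bimodal_sym", sweep_values = 3, sample_sizes = 25,
                      tests = list("kuiper"), reps = 300)
  full <- as.data.frame(run_scenario(sc_full, seed = 8))
  cell <- as.data.frame(run_scenario(sc_cell, seed = 8))
  expect_equal(full$power[full$sweep_value == 3], cell$power)
})

test_that("scenario presets carry the study grids", {
  expect_equal(scenario("type1")$sample_sizes, c(10, 15, 20, 25, 30, 40, 80, 100))
  expect_equal(scenario("type1")$reps, 100000)
  expect_equal(scenario("bimodal_weights")$sweep_values, seq(0.05, 0.5, 0.05))
  expect_equal(scenario("bimodal_sym")$sweep_values, seq(0, 6, 0.1))
  expect_equal(scenario("bimodal_delta")$sample_sizes, c(15, 25, 40, 100))

  k2 <- scenario("bimodal_kappa2")
  expect_equal(k2$sweep_values, seq(0, 6, 0.1))
  g <- k2$make_dist(4.2, k2$kappa)
  expect_equal(g$kappas, c(3, 4.2))   # first mode concentration held at 3

  w <- scenario("bimodal_weights", kappa = 2)
  gw <- w$make_dist(0.2, w$kappa)
  expect_equal(gw$weights, c(0.2, 0.8))
  expect_equal(gw$kappas, c(2, 2))

  mm <- scenario("multimodal", n_modes = 5, placement = "asymmetric")
  g5 <- mm$make_dist(3, mm$kappa)
  expect_length(g5$weights, 5)
  expect_equal(rad2deg(g5$mus), c(0, 45, 90, 135, 180))

  expect_error(scenario("no_such_scenario"))
  expect_error(scenario("type1", sweep_values = c(2, 1)), "increasing")
  expect_error(scenario("type1", reps = 10), "at least 100")
})

test_that("a 180-degree separation reproduces the symmetric bimodal law", {
  # same underlying distribution reached through two different scenarios
  reps <- 2000
  d180 <- run_scenario(scenario("bimodal_delta", sweep_values = 180,
                                sample_sizes = 25, kappa = 3,
                                tests = list("kuiper", "hermans_rasson"),
                                reps = reps), seed = 31, null_reps = 4999)
  sym3 <- run_scenario(scenario("bimodal_sym", sweep_values = 3,
                                sample_sizes = 25,
                                tests = list("kuiper", "hermans_rasson"),
                                reps = reps), seed = 32, null_reps = 4999)
  for (tt in c("kuiper", "hermans_rasson")) {
    p1 <- d180$power[d180$test == tt]
    p2 <- sym3$power[sym3$test == tt]
    tol <- 3 * sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / reps)
    expect_lt(abs(p1 - p2), tol)
  }
})

test_that("results tables are well-formed", {
  res <- run_scenario(scenario("type1", sample_sizes = 10,
                               tests = list("rayleigh", "kuiper"),
                               reps = 200), seed = 2)
  expect_s3_class(res, "power_result")
  expect_named(as.data.frame(res),
               c("scenario", "test", "n", "sweep_name", "sweep_value",
                 "rejections", "reps", "power", "se"))
  expect_true(all(res$power >= 0 & res$power <= 1))
  expect_equal(res$se, sqrt(res$power * (1 - res$power) / res$reps))
})
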