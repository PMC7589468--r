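test_that("every launched particle ends bound or lost, and reruns are bit-identical", {
  toy <- make_toy_fixture("single_gap")
  res1 <- simulate_device(toy$device, toy$ctx, toy$kin, toy$cfg)
  res2 <- simulate_device(toy$device, toy$ctx, toy$kin, toy$cfg)
  n_launched <- res1$batches_run * toy$cfg$n_particles_per_batch
  expect_equal(res1$n_bound + res1$n_lost, n_launched)
  expect_gte(res1$recovery, 0)
  expect_lte(res1$recovery, 1)
  expect_lte(res1$ci_low, res1$recovery)
  expect_gte(res1$ci_high, res1$recovery)
  expect_identical(tidy(res1), tidy(res2))
  expect_identical(res1$per_batch, res2$per_batch)
  # a different seed gives a different (but nearby) stream
  cfg2 <- toy$cfg
  cfg2$seed <- 999L
  res3 <- simulate_device(toy$device, toy$ctx, toy$kin, cfg2)
  expect_false(identical(res1$per_batch$n_bound, res3$per_batch$n_bound))
})

test_that("zero intrinsic rate yields exactly zero recovery", {
  toy <- make_toy_fixture("no_binding")
  res <- simulate_device(toy$device, toy$ctx, toy$kin, toy$cfg)
  expect_identical(res$n_bound, 0L)
  expect_equal(res$recovery, 0)
})

test_that("absorbing plug-flow capture matches the eigenfunction series", {
  D <- stokes_einstein_diffusivity(150e-9)
  out <- absorbing_run(D, u_mean = 4e-4, gap_um = 10, length_mm = 2,
                       n = 4000, seed = 7)
  expect_lt(abs(out$mc - out$closed_form), 0.02)
})

test_that("a parallel device is equivalent to one bed at the per-bed flow", {
  bed <- toy_bed()
  dev <- device_geometry(rep(list(bed), 4), "parallel")
  kin <- kinetics_params("rate", intrinsic_on_rate = 0.05)
  cfg <- fast_cfg(seed = 3)
  res_dev <- simulate_device(dev, transport_context(0.2), kin, cfg)
  res_bed <- simulate_bed(bed, transport_context(0.05), kin, cfg)
  expect_identical(tidy(res_dev), tidy(res_bed))
})

test_that("serial beds compose as survival products", {
  bed <- toy_bed()
  kin <- kinetics_params("rate", intrinsic_on_rate = 0.05)
  cfg <- fast_cfg(seed = 5, n = 4000, halfwidth = 0.01)
  ctx <- transport_context(0.05)
  two <- device_geometry(list(bed, bed), "serial")
  res2 <- simulate_device(two, ctx, kin, cfg)
  res1 <- simulate_bed(bed, ctx, kin, cfg)
  r1 <- res1$recovery
  expect_equal(res2$recovery, 1 - (1 - r1)^2, tolerance = 0.05)
  # bookkeeping: per-bed recoveries compose exactly to the device recovery
  expect_equal(1 - prod(1 - res2$per_bed_recovery), res2$recovery,
               tolerance = 1e-12)
  expect_equal(res2$n_bound + res2$n_lost,
               res2$batches_run * cfg$n_particles_per_batch)
})

test_that("recovery falls with flow rate and rises with bed length", {
  kin <- kinetics_params("rate", intrinsic_on_rate = 0.05)
  cfg <- fast_cfg(seed = 11, n = 2000, halfwidth = 0.015)
  sweep <- recovery_flow_sweep(toy_bed(), transport_context(0.05), kin, cfg,
                               c(0.02, 0.08, 0.32))
  tbl <- tidy(sweep)
  expect_true(all(diff(tbl$recovery) < 0))
  # longer bed, same flow: more residence time, at least as much capture
  short_bed <- toy_bed(length_mm = 1)
  long_bed <- toy_bed(length_mm = 4)
  ctx <- transport_context(0.05)
  r_short <- simulate_bed(short_bed, ctx, kin, cfg)$recovery
  r_long <- simulate_bed(long_bed, ctx, kin, cfg)$recovery
  expect_gt(r_long, r_short)
})

test_that("smaller pillar gaps capture better at matched interstitial velocity", {
  kin <- kinetics_params("rate", intrinsic_on_rate = 0.05)
  cfg <- fast_cfg(seed = 13, n = 2000, halfwidth = 0.015)
  bed10 <- toy_bed(spacing_um = 10)
  bed15 <- toy_bed(spacing_um = 15)
  u <- 3e-4 # m/s in both gaps
  q10 <- u * bed_open_area_for_test(bed10) * 60e9
  q15 <- u * bed_open_area_for_test(bed15) * 60e9
  r10 <- simulate_bed(bed10, transport_context(q10), kin, cfg)$recovery
  r15 <- simulate_bed(bed15, transport_context(q15), kin, cfg)$recovery
  expect_gt(r10, r15)
})

test_that("recovery is stable under time-step halving", {
  toy <- make_toy_fixture("single_gap")
  cfg <- simulation_config(n_particles_per_batch = 5000, max_batches = 20,
                           seed = 17, convergence_halfwidth = 0.004)
  bed <- toy$device$beds[[1]]
  dt_auto <- (bed$pillar_spacing / 20)^2 / (2 * toy$ctx$diffusivity)
  cfg_half <- simulation_config(n_particles_per_batch = 5000,
                                max_batches = 20, seed = 17,
                                convergence_halfwidth = 0.004,
                                dt = dt_auto / 2)
  r_auto <- simulate_bed(bed, toy$ctx, toy$kin, cfg)$recovery
  r_half <- simulate_bed(bed, toy$ctx, toy$kin, cfg_half)$recovery
  expect_lt(abs(r_auto - r_half), 0.01)
})

test_that("the convergence engine pools batches and tracks the CI width", {
  # constant runner: converges at the minimum two batches
  const_runner <- function(n, seed) list(n_bound = round(n / 2),
                                         n_lost = n - round(n / 2))
  cfg <- simulation_config(n_particles_per_batch = 10000, max_batches = 20,
                           seed = 1, convergence_halfwidth = 0.02)
  res <- run_until_converged(const_runner, cfg)
  expect_equal(res$batches_run, 2L)
  expect_true(res$converged)
  expect_equal(res$recovery, 0.5)
  # pooled recovery equals the particle-weighted mean of batch recoveries
  bern_runner <- function(n, seed) {
    set.seed(seed)
    b <- rbinom(1, n, 0.3)
    list(n_bound = b, n_lost = n - b)
  }
  cfg2 <- simulation_config(n_particles_per_batch = 500, max_batches = 50,
                            seed = 2, convergence_halfwidth = 0.01)
  res2 <- run_until_converged(bern_runner, cfg2)
  expect_equal(res2$recovery, sum(res2$per_batch$n_bound) /
                 sum(res2$per_batch$n))
  # CI half-width shrinks like 1/sqrt(total particles)
  hw <- res2$per_batch$halfwidth
  n_tot <- cumsum(res2$per_batch$n)
  ratio <- hw * sqrt(n_tot)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.2)
  # a runner that drops particles is rejected
  bad_runner <- function(n, seed) list(n_bound = 1, n_lost = n)
  expect_error(run_until_converged(bad_runner, cfg), "bound \\+ lost")
})

test_that("capacity guard flags runs that would saturate the monolayer", {
  toy <- make_toy_fixture("single_gap")
  res <- simulate_device(toy$device, toy$ctx, toy$kin, toy$cfg)
  d3 <- load_device_config(evcapture_fixture("evmap_3bed"))
  # typical released-EV concentration: well below capacity -> ok
  ok <- capacity_guard(res, d3, sample_volume_ul = 100,
                       concentration_per_ul = 1.6e8 / 100)
  expect_equal(ok$status, "ok")
  expect_lt(ok$utilisation, 1)
  # zero concentration -> ok
  expect_equal(capacity_guard(res, d3, 100, 0)$status, "ok")
  # force expected capture to the boundary: warning is inclusive
  cap <- ev_load_capacity(internal_surface_area(d3))
  conc <- cap / (100 * res$recovery)
  expect_warning(
    flag <- capacity_guard(res, d3, 100, conc),
    "capacity"
  )
  expect_equal(flag$status, "warning")
})

test_that("sweeps validate their flow grid and expose tidy/glance/autoplot", {
  toy <- make_toy_fixture("single_gap")
  expect_error(
    recovery_flow_sweep(toy$device, toy$ctx, toy$kin, toy$cfg, c(2, 1)),
    "increasing|TRUE"
  )
  sweep <- recovery_flow_sweep(toy$device, toy$ctx, toy$kin, toy$cfg,
                               c(0.05, 0.2))
  tbl <- tidy(sweep)
  expect_named(tbl, c("flow_ul_min", "recovery", "ci_low", "ci_high",
                      "n_bound", "n_lost", "batches", "converged"))
  g <- glance(sweep)
  expect_equal(g$n_flow_rates, 2)
  p <- autoplot(sweep)
  expect_s3_class(p, "ggplot")
  gr <- glance(sweep$recoveries[[1]])
  expect_true(all(c("u_mean", "dt", "residence_time_s") %in% names(gr)))
})
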