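#' Monte Carlo run configuration
#'
#' Controls the particle counts, time step, seeding and convergence rule
#' of the capture simulator. Batches of particles are run until the
#' binomial confidence interval on the pooled recovery is narrower than
#' `convergence_halfwidth` (default 0.5 percentage points at 95%
#' confidence), or `max_batches` is reached.
#'
#' When `dt = NULL` the time step is chosen so the RMS Brownian step
#' sqrt(2 D dt) equals `gap / dt_gap_fraction` (default gap/20), keeping
#' lateral jumps small relative to the channel while the capture
#' probability per step stays far from saturation.
#'
#' @param n_particles_per_batch Particles per batch.
#' @param max_batches Maximum number of batches.
#' @param dt Time step (s), or `NULL` to derive it from the gap.
#' @param dt_gap_fraction Gap divided by the RMS step when `dt` is auto.
#' @param seed Master seed; fully determines the particle stream.
#' @param convergence_halfwidth Target CI half-width on the recovery
#'   fraction.
#' @param ci_level Confidence level for the interval.
#' @param launch `"flux"` (inlet seeding proportional to local velocity,
#'   the physical inlet condition for a continuously infused sample) or
#'   `"uniform"`.
#' @param profile `"poiseuille"` or `"plug"` (uniform velocity override,
#'   used for closed-form benchmarking).
#' @param max_step_factor Hard cap on steps per particle, as a multiple
#'   of the nominal transit step count; exceeding it is reported as a
#'   diagnostic error.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_particles_per_batch = 2000,
                              max_batches = 50,
                              dt = NULL,
                              dt_gap_fraction = 20,
                              seed = 1,
                              convergence_halfwidth = 0.005,
                              ci_level = 0.95,
                              launch = c("flux", "uniform"),
                              profile = c("poiseuille", "plug"),
                              max_step_factor = 200) {
  launch <- match.arg(launch)
  profile <- match.arg(profile)
  stopifnot(n_particles_per_batch >= 1, max_batches >= 2,
            is.null(dt) || dt > 0, dt_gap_fraction > 0,
            convergence_halfwidth > 0, ci_level > 0, ci_level < 1,
            max_step_factor > 0)
  structure(
    list(
      n_particles_per_batch = as.integer(n_particles_per_batch),
      max_batches = as.integer(max_batches),
      dt = dt,
      dt_gap_fraction = dt_gap_fraction,
      seed = as.integer(seed),
      convergence_halfwidth = convergence_halfwidth,
      ci_level = ci_level,
      launch = launch,
      profile = profile,
      max_step_factor = max_step_factor
    ),
    class = "simulation_config"
  )
}

resolve_dt <- function(cfg, gap, D) {
  cfg$dt %||% ((gap / cfg$dt_gap_fraction)^2 / (2 * D))
}

# Deterministic per-purpose substream seeds derived from a master seed.
derive_seeds <- function(master_seed, n, stream = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed %% .Machine$integer.max + stream)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run batches until the recovery estimate converges
#'
#' Generic convergence engine: `batch_runner(n, seed)` must
#' deterministically (given `seed`) return a named vector or list with
#' elements `n_bound` and `n_lost` summing to `n`. Batches are pooled and
#' repeated until the binomial CI half-width on the pooled recovery drops
#' below the configured threshold (minimum two batches), or `max_batches`
#' is hit.
#'
#' @param batch_runner `function(n, seed)` returning bound/lost counts.
#' @param cfg A [simulation_config()].
#' @return A `recovery_result`: pooled counts, recovery fraction with
#'   confidence interval, convergence flag and a per-batch trace tibble.
#' @export
run_until_converged <- function(batch_runner, cfg) {
  stopifnot(is.function(batch_runner), inherits(cfg, "simulation_config"))
  seeds <- derive_seeds(cfg$seed, cfg$max_batches)
  n_bound <- 0L
  n_lost <- 0L
  trace <- vector("list", cfg$max_batches)
  converged <- FALSE
  batches <- 0L
  for (b in seq_len(cfg$max_batches)) {
    out <- batch_runner(cfg$n_particles_per_batch, seeds[b])
    if (out$n_bound + out$n_lost != cfg$n_particles_per_batch) {
      stop("batch runner lost particles: bound + lost != launched",
           call. = FALSE)
    }
    n_bound <- n_bound + out$n_bound
    n_lost <- n_lost + out$n_lost
    batches <- b
    ci <- recovery_ci(n_bound, n_bound + n_lost, cfg$ci_level)
    trace[[b]] <- tibble::tibble(
      batch = b, seed = seeds[b],
      n = cfg$n_particles_per_batch,
      n_bound = out$n_bound, n_lost = out$n_lost,
      batch_recovery = out$n_bound / (out$n_bound + out$n_lost),
      pooled_recovery = n_bound / (n_bound + n_lost),
      ci_low = ci[1], ci_high = ci[2],
      halfwidth = (ci[2] - ci[1]) / 2
    )
    if (b >= 2 && (ci[2] - ci[1]) / 2 <= cfg$convergence_halfwidth) {
      converged <- TRUE
      break
    }
  }
  new_recovery_result(n_bound, n_lost, batches, converged,
                      dplyr::bind_rows(trace[seq_len(batches)]), cfg)
}

recovery_ci <- function(x, n, level) {
  as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
}

new_recovery_result <- function(n_bound, n_lost, batches, converged,
                                trace, cfg, extra = list()) {
  ci <- recovery_ci(n_bound, n_bound + n_lost, cfg$ci_level)
  structure(
    c(list(
      n_bound = n_bound,
      n_lost = n_lost,
      recovery = n_bound / (n_bound + n_lost),
      ci_low = ci[1],
      ci_high = ci[2],
      batches_run = batches,
      converged = converged,
      per_batch = trace,
      config = cfg
    ), extra),
    class = "recovery_result"
  )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> recovery = %.1f%% (%.0f%% CI %.1f-%.1f%%), %d bound / %d lost, %d batch(es)%s\n",
    100 * x$recovery, 100 * x$config$ci_level, 100 * x$ci_low,
    100 * x$ci_high, x$n_bound, x$n_lost, x$batches_run,
    if (x$converged) ", converged" else ", NOT converged"
  ))
  invisible(x)
}

# Single-batch tracker for one bed: returns function(n) -> counts.
# RNG state is whatever the caller set; simulate_bed and the serial
# chain seed it per batch.
make_bed_tracker <- function(bed, ctx, kin, cfg) {
  gap <- bed$pillar_spacing
  if (kin$encounter_radius >= gap / 2) {
    stop("encounter radius must be smaller than half the pillar gap",
         call. = FALSE)
  }
  u_mean <- ctx$flow_rate / bed_open_cross_section(bed)
  D <- ctx$diffusivity
  dt <- resolve_dt(cfg, gap, D)
  # Along the flow path only the fraction lined by pillar faces carries
  # antibody; between pillar rows the unit-cell "wall" is open fluid.
  lined <- if (bed$n_pillars > 0) {
    bed$pillar_size / (bed$pillar_size + bed$pillar_spacing)
  } else {
    1
  }
  k_eff0 <- if (kin$mode == "rate") base_capture_hazard(kin) * lined else 0
  nominal_steps <- if (u_mean > 0) bed$length / (u_mean * dt) else 1e4
  max_steps <- max(1e4, cfg$max_step_factor * nominal_steps)

  tracker <- function(n) {
    out <- track_batch_cpp(
      n_particles = n, gap = gap, bed_length = bed$length,
      u_mean = u_mean, D = D, dt = dt,
      encounter_radius = kin$encounter_radius,
      k_eff0 = k_eff0,
      mode = if (kin$mode == "rate") 0L else 1L,
      p_encounter = if (kin$mode == "per_encounter") kin$p_encounter else 0,
      flux_weighted = cfg$launch == "flux",
      plug_flow = cfg$profile == "plug",
      max_steps = max_steps
    )
    if (out$n_stuck > 0) {
      stop(sprintf(
        paste0("%d particle(s) exceeded the step cap (%g steps). ",
               "Config: gap = %g m, L = %g m, u_mean = %g m/s, D = %g m^2/s, ",
               "dt = %g s"),
        out$n_stuck, max_steps, gap, bed$length, u_mean, D, dt
      ), call. = FALSE)
    }
    out
  }
  attr(tracker, "derived") <- list(u_mean = u_mean, D = D, dt = dt,
                                   residence_time = if (u_mean > 0) bed$length / u_mean else Inf)
  tracker
}

#' Simulate EV capture in a single pillar bed
#'
#' Tracks particles through the two-dimensional unit cell of the pillar
#' array: a straight channel of gap equal to the inter-pillar spacing
#' and length equal to the bed, whose two walls are the antibody-coated
#' capture surfaces. Particles start at the inlet, convect with the
#' local plane-Poiseuille velocity, diffuse laterally and
#' longitudinally, and are captured according to the kinetics model;
#' wall excursions that do not bind are reflected. A particle is bound
#' on a successful kinetics draw and lost once it passes the outlet.
#' Batches repeat until the recovery estimate converges (see
#' [run_until_converged()]).
#'
#' @param bed A [bed_geometry()].
#' @param ctx A [transport_context()] whose `flow_rate` is the flow
#'   through *this* bed.
#' @param kin A [kinetics_params()].
#' @param cfg A [simulation_config()].
#' @return A `recovery_result`.
#' @export
simulate_bed <- function(bed, ctx, kin, cfg) {
  stopifnot(inherits(bed, "bed_geometry"),
            inherits(ctx, "transport_context"),
            inherits(kin, "kinetics_params"),
            inherits(cfg, "simulation_config"))
  tracker <- make_bed_tracker(bed, ctx, kin, cfg)
  runner <- function(n, seed) {
    set.seed(seed)
    tracker(n)
  }
  res <- run_until_converged(runner, cfg)
  res$derived <- attr(tracker, "derived")
  res
}

#' Simulate EV capture in a multi-bed device
#'
#' Parallel devices split the flow evenly over identical beds, so the
#' device recovery equals that of one bed run at Q / n_beds (the
#' simulation is performed on a single bed at the per-bed flow). Serial
#' devices chain the beds: particles escaping bed i are re-launched into
#' bed i+1, so the device recovery composes as 1 - prod(1 - r_i) and the
#' aggregated counts satisfy bound + lost = particles launched.
#'
#' @param device A `device_geometry`.
#' @param ctx A [transport_context()] carrying the device-level flow.
#' @param kin A [kinetics_params()].
#' @param cfg A [simulation_config()].
#' @return A `recovery_result` (with a `per_bed` recovery vector for
#'   serial devices).
#' @export
simulate_device <- function(device, ctx, kin, cfg) {
  device <- as_device(device)
  if (device$arrangement == "parallel") {
    per_bed_ctx <- transport_context(
      ctx$flow_rate_ul_min / length(device$beds),
      particle_diameter_nm = ctx$particle_diameter * 1e9,
      temperature_K = ctx$temperature,
      viscosity_Pa_s = ctx$viscosity,
      diffusivity = ctx$diffusivity
    )
    return(simulate_bed(device$beds[[1]], per_bed_ctx, kin, cfg))
  }
  # serial: full flow through each bed; survivors of bed i seed bed i+1.
  # The whole chain runs inside one batch runner so the device-level
  # convergence rule applies to the composed recovery and
  # bound + lost = launched holds exactly.
  trackers <- lapply(device$beds, make_bed_tracker, ctx = ctx,
                     kin = kin, cfg = cfg)
  n_beds <- length(trackers)
  acc <- new.env()
  acc$entered <- integer(n_beds)
  acc$bound <- integer(n_beds)
  runner <- function(n, seed) {
    set.seed(seed)
    n_in <- n
    bound_total <- 0L
    for (i in seq_len(n_beds)) {
      if (n_in == 0L) break
      out <- trackers[[i]](n_in)
      acc$entered[i] <- acc$entered[i] + n_in
      acc$bound[i] <- acc$bound[i] + out$n_bound
      bound_total <- bound_total + out$n_bound
      n_in <- out$n_lost
    }
    list(n_bound = bound_total, n_lost = n_in)
  }
  res <- run_until_converged(runner, cfg)
  res$per_bed_recovery <- ifelse(acc$entered > 0,
                                 acc$bound / acc$entered, NA_real_)
  res$derived <- attr(trackers[[1]], "derived")
  res
}

#' Recovery as a function of flow rate
#'
#' Runs [simulate_device()] at each flow rate with shared geometry and
#' kinetics, using an independent RNG substream per flow rate derived
#' from the master seed.
#'
#' @param device A `device_geometry`.
#' @param ctx A [transport_context()]; its flow rate is replaced by each
#'   element of `flow_rates_ul_min` in turn.
#' @param kin A [kinetics_params()].
#' @param cfg A [simulation_config()].
#' @param flow_rates_ul_min Strictly increasing flow rates (uL/min).
#' @return A `sweep_result` containing a tibble of recoveries (see
#'   [tidy.sweep_result()]).
#' @export
recovery_flow_sweep <- function(device, ctx, kin, cfg, flow_rates_ul_min) {
  stopifnot(length(flow_rates_ul_min) >= 1,
            all(diff(flow_rates_ul_min) > 0))
  device <- as_device(device)
  flow_seeds <- derive_seeds(cfg$seed, length(flow_rates_ul_min), stream = 2L)
  results <- purrr::map2(flow_rates_ul_min, flow_seeds, function(q, s) {
    ctx_q <- transport_context(
      q,
      particle_diameter_nm = ctx$particle_diameter * 1e9,
      temperature_K = ctx$temperature,
      viscosity_Pa_s = ctx$viscosity,
      diffusivity = ctx$diffusivity
    )
    cfg_q <- cfg
    cfg_q$seed <- s
    simulate_device(device, ctx_q, kin, cfg_q)
  })
  structure(
    list(
      flow_rates = flow_rates_ul_min,
      recoveries = results,
      device = device$name,
      config = cfg
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> device '%s'\n", x$device))
  print(generics::tidy(x))
  invisible(x)
}

#' Check a run against the device's monolayer load capacity
#'
#' The simulator assumes dilute, non-saturating operation: captured
#' particles do not deplete antibody sites. This guard flags operating
#' points where the expected number of captured particles
#' (volume x concentration x recovery) meets or exceeds the monolayer
#' capacity of the device surface, where that assumption breaks down.
#'
#' @param result A `recovery_result`.
#' @param device The `device_geometry` that was simulated.
#' @param sample_volume_ul Processed sample volume (uL).
#' @param concentration_per_ul Particle concentration (particles/uL).
#' @param ev_diameter_nm Vesicle diameter for the capacity (nm).
#' @return A tibble with the expected capture, the capacity and a
#'   `status` of `"ok"` or `"warning"` (boundary inclusive); a warning
#'   condition is also signalled.
#' @export
capacity_guard <- function(result, device, sample_volume_ul,
                           concentration_per_ul, ev_diameter_nm = 150) {
  stopifnot(inherits(result, "recovery_result"),
            sample_volume_ul >= 0, concentration_per_ul >= 0)
  capacity <- ev_load_capacity(internal_surface_area(device), ev_diameter_nm)
  expected <- sample_volume_ul * concentration_per_ul * result$recovery
  status <- if (expected >= capacity) "warning" else "ok"
  if (status == "warning") {
    warning(sprintf(
      "expected capture (%.3g particles) reaches the monolayer capacity (%.3g); the linear-regime assumption is violated",
      expected, capacity
    ), call. = FALSE)
  }
  tibble::tibble(
    expected_captured = expected,
    capacity = capacity,
    utilisation = expected / capacity,
    status = status
  )
}
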