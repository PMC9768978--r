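# minimal two-electrode spike scaffold with one spike per electrode per NB
delay_scaffold <- function(lags, nb_period = 2) {
  n <- length(lags)
  starts <- seq_len(n) * nb_period
  nbs <- tibble::tibble(nb_id = seq_len(n), t_start = starts,
                        t_end = starts + 1, n_spikes = 2L,
                        t_peak = starts + 0.5, peak_rate = 1L)
  spikes <- tibble::tibble(
    electrode_id = rep(c(4L, 13L), n),
    time_s = as.vector(rbind(starts, starts + lags)),
    amplitude_uV = -50)
  list(nbs = nbs, spikes = validate_spikes(spikes))
}

test_that("constant onset lags are reported exactly", {
  sc <- delay_scaffold(rep(0.375, 31))
  d <- nb_onset_delays(sc$nbs, sc$spikes, 4, 13)
  expect_identical(nrow(d), 31L)
  expect_equal(attr(d, "mean_delay_s"), 0.375)
  expect_equal(attr(d, "sd_delay_s"), 0)
})

test_that("jittered lags recover the planted delay distribution", {
  set.seed(17)
  lags <- 0.375 + rnorm(500, 0, 0.166)
  sc <- delay_scaffold(lags)
  d <- nb_onset_delays(sc$nbs, sc$spikes, 4, 13)
  expect_equal(attr(d, "mean_delay_s"), 0.375, tolerance = 0.05)
  expect_equal(attr(d, "sd_delay_s"), 0.166, tolerance = 0.10)
})

test_that("bursts with a silent electrode are excluded and counted", {
  sc <- delay_scaffold(rep(0.2, 20))
  # silence the target in 5 bursts
  drop <- sc$spikes$electrode_id == 13 &
    sc$spikes$time_s < 11  # targets of the first 5 NBs (at 2.2 .. 10.2 s)
  sp <- sc$spikes[!drop, ]
  d <- nb_onset_delays(sc$nbs, sp, 4, 13)
  expect_identical(nrow(d), 15L)
  expect_identical(attr(d, "n_excluded"), 5L)
  expect_error(nb_onset_delays(sc$nbs, sp[sp$electrode_id == 4, ], 4, 13),
               "both electrodes")
})

test_that("pairwise and relative velocities are plain arithmetic", {
  expect_equal(pair_velocity(900, 0.3), 3.0)
  expect_equal(pair_velocity(1398.75, 0.375), 3.73)
  expect_equal(pair_velocity(1399, 0.375), 1.399 / 0.375)
  expect_error(pair_velocity(900, 0), "positive")
  expect_equal(relative_velocity(4, 2), 2)
  expect_equal(relative_velocity(2, 2), 1)
  expect_error(relative_velocity(1, 0), "positive")
  # delays scaled by 0.8 speed the velocity up by 1/0.8
  v0 <- pair_velocity(1398.75, 0.375)
  v1 <- pair_velocity(1398.75, 0.375 * 0.8)
  expect_equal(relative_velocity(v1, v0), 1.25, tolerance = 0.01)
})

test_that("the velocity fit equals the closed-form OLS solution", {
  set.seed(23)
  lat <- sort(runif(30, 0, 2e-3))
  dist <- 0.3e6 * lat + rnorm(30, 0, 20)
  fit <- fit_velocity(dist, lat)
  want <- ref_ols(lat, dist)
  expect_equal(fit$velocity_m_s, unname(want["slope"]) * 1e-6,
               tolerance = 1e-10)
  expect_equal(fit$intercept_um, unname(want["intercept"]),
               tolerance = 1e-10)

  # noiseless line: exact slope, R^2 = 1
  lat2 <- seq(0, 1e-3, length.out = 10)
  f2 <- fit_velocity(0.14e6 * lat2, lat2)
  expect_equal(f2$velocity_m_s, 0.14)
  expect_equal(f2$r_squared, 1)

  # seeded noisy line: within 5%, R^2 > 0.9
  set.seed(5)
  lat3 <- seq(0, 2e-3, length.out = 50)
  d3 <- 0.14e6 * lat3
  d3 <- d3 + rnorm(50, 0, 0.05 * diff(range(d3)))
  f3 <- fit_velocity(d3, lat3)
  expect_equal(f3$velocity_m_s, 0.14, tolerance = 0.05)
  expect_gt(f3$r_squared, 0.9)

  expect_error(fit_velocity(c(1, 2, 3), c(1e-3, 1e-3, 1e-3)), "degenerate")
  # two points: exact slope, flagged
  f4 <- fit_velocity(c(0, 100), c(0, 1e-3))
  expect_true(f4$exact)
  expect_equal(f4$velocity_m_s, 0.1)

  # invariance to time origin and unit conversion
  f5 <- fit_velocity(d3, lat3 + 0.25)
  expect_equal(f5$velocity_m_s, f3$velocity_m_s)
  f6 <- fit_velocity(d3 / 1000, lat3)   # mm instead of um
  expect_equal(f6$velocity_m_s * 1000, f3$velocity_m_s)

  # broom-style accessors
  expect_identical(names(glance(f3)),
                   c("velocity_m_s", "r_squared", "n_points", "intercept_s"))
  expect_identical(nrow(tidy(f3)), 2L)
})

test_that("somata are recovered as separated local maxima", {
  lay <- grid_layout(60, 60, 17.5)
  set.seed(41)
  peaks <- tibble::tibble(x = c(5, 25, 50, 10, 40, 55, 30) * 17.5,
                          y = c(5, 10, 8, 40, 35, 50, 55) * 17.5,
                          amp = c(120, 100, 140, 90, 110, 130, 95))
  amp <- purrr::map_dbl(seq_len(nrow(lay)), function(i) {
    sum(peaks$amp * exp(-((lay$x_um[i] - peaks$x)^2 +
                          (lay$y_um[i] - peaks$y)^2) / (2 * 30^2)))
  })
  am <- dplyr::mutate(lay, amplitude_uV = amp)
  somata <- localize_somata(am, min_amp = 40, min_sep_um = 150)
  expect_identical(nrow(somata), 7L)
  hit <- purrr::map_lgl(seq_len(nrow(peaks)), function(p) {
    any(abs(somata$x_um - peaks$x[p]) < 1e-6 &
        abs(somata$y_um - peaks$y[p]) < 1e-6)
  })
  expect_true(all(hit))

  # flat map below the floor: empty
  flat <- dplyr::mutate(lay, amplitude_uV = 5)
  expect_identical(nrow(localize_somata(flat, 40, 100)), 0L)

  # two close peaks: larger one suppresses the smaller
  two <- dplyr::mutate(grid_layout(3, 3, 17.5), amplitude_uV = 0)
  two$amplitude_uV[c(4, 5)] <- c(80, 100)
  s2 <- localize_somata(two, 40, 50)
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$electrode_id, 5L)

  # permutation invariance of the input row order
  s_perm <- localize_somata(am[sample(nrow(am)), ], 40, 150)
  expect_setequal(s_perm$electrode_id, somata$electrode_id)
})

test_that("the STA window and averaging law behave as expected", {
  ax <- gen_axon_dataset(seed = 2, noise_sd_uV = 3)
  sta <- spike_triggered_average(ax$rec, ax$triggers)
  expect_identical(ncol(sta$waveforms), 80L)   # 4 ms at 20 kHz
  expect_identical(sta$n_used, 60L)

  # single trigger: STA equals the raw segment
  one <- spike_triggered_average(ax$rec, ax$triggers[5])
  i0 <- round(ax$triggers[5] * ax$rec$fs) + 1L
  seg <- ax$rec$traces[, (i0 - 30):(i0 + 49)]
  expect_equal(unname(one$waveforms), unname(seg))

  # off-path channel is pure noise: residual RMS ~ sigma / sqrt(N)
  resid <- sta$waveforms[1, ]
  expect_equal(sqrt(mean(resid^2)), 3 / sqrt(60), tolerance = 0.3)

  # clipped triggers are dropped and counted
  clip <- spike_triggered_average(ax$rec, c(0.00001, ax$triggers))
  expect_identical(clip$n_dropped, 1L)
  expect_error(spike_triggered_average(ax$rec, 1e9), "inside")
})

test_that("a planted axonal path is recovered exactly and in order", {
  ax <- gen_axon_dataset(seed = 3, noise_sd_uV = 4)   # template SNR 10
  sta <- spike_triggered_average(ax$rec, ax$triggers)
  p <- trace_axon_path(sta, ax$truth$soma_electrode, rho_min = 0.7,
                       amp_min = 15)
  expect_identical(p$electrode_id, ax$truth$path_electrode_ids)
  expect_true(all(diff(p$latency_s) > 0))
  expect_true(all(diff(p$cum_dist_um) >= 0))
  expect_false(attr(p, "soma_only"))

  # impossible similarity threshold: soma-only path, flagged
  p0 <- trace_axon_path(sta, ax$truth$soma_electrode, rho_min = 1.01,
                        amp_min = 15)
  expect_identical(nrow(p0), 1L)
  expect_true(attr(p0, "soma_only"))
})

test_that("conduction velocity recovers the planted ground truth", {
  ax <- gen_axon_dataset(seed = 11, noise_sd_uV = 0)
  sta <- spike_triggered_average(ax$rec, ax$triggers)
  p <- trace_axon_path(sta, ax$truth$soma_electrode, rho_min = 0.7,
                       amp_min = 15)
  cv <- conduction_velocity(p)
  expect_equal(cv$velocity_m_s, 0.57, tolerance = 0.02)
  expect_gte(cv$r_squared, 0.999)

  # two-point path: exact slope
  p2 <- tibble::tibble(cum_dist_um = c(0, 70), latency_s = c(0, 1e-4))
  expect_equal(conduction_velocity(p2)$velocity_m_s, 0.7)
  expect_error(conduction_velocity(p2[1, ]), "fewer than 2")
})

test_that("network velocity is recovered from burst-onset waves", {
  net <- simulate_preset("cmos_network", seed = 6)
  fit <- fit_network_velocity(net$onsets, net$positions)
  expect_equal(fit$velocity_m_s, 0.14, tolerance = 0.10)
  expect_gt(fit$r_squared, 0.9)
  pts <- attr(fit, "points")
  expect_identical(nrow(pts), fit$n_points)
})
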