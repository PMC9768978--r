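test_that("every generator is a pure function of its seed", {
  lay <- grid_layout(4, 4, 450)
  sch <- burst_schedule(n_nb = 3, nb_spikes = 120, nb_duration_s = 0.2,
                        period_s = 1)
  g1 <- gen_spiketrains(lay, sch, background_hz = 1, seed = 5,
                        core_params = burst_params(min_candidate_spikes = 50))
  g2 <- gen_spiketrains(lay, sch, background_hz = 1, seed = 5,
                        core_params = burst_params(min_candidate_spikes = 50))
  expect_identical(g1$spikes, g2$spikes)
  g3 <- gen_spiketrains(lay, sch, background_hz = 1, seed = 6)
  expect_false(identical(g1$spikes$time_s, g3$spikes$time_s))

  r1 <- render_traces(g1$spikes[1:50, ], lay, 1.1, seed = 9)
  r2 <- render_traces(g1$spikes[1:50, ], lay, 1.1, seed = 9)
  expect_identical(r1$traces, r2$traces)

  a1 <- gen_axon_dataset(n_triggers = 5, seed = 4)
  a2 <- gen_axon_dataset(n_triggers = 5, seed = 4)
  expect_identical(a1$rec$traces, a2$rec$traces)

  gm <- tibble::tibble(condition = c("DMSO", "drug"),
                       concentration = c(0, 10), n_nb = c(20, 30))
  expect_identical(gen_param_samples(gm, 4, seed = 2),
                   gen_param_samples(gm, 4, seed = 2))

  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_spiketrains(lay, sch, seed = 1))
  expect_identical(runif(1), before)
})

test_that("planted spike counts and intervals are conserved", {
  lay <- grid_layout(4, 4, 450)
  g <- gen_spiketrains(lay, burst_schedule(n_nb = 20, nb_spikes = 600),
                       background_hz = 0, seed = 3)
  expect_identical(nrow(g$spikes), 12000L)
  expect_true(all(g$spikes$time_s >= 0 & g$spikes$time_s <= g$duration_s))
  # ground-truth windows enclose all their spikes
  expect_identical(sum(g$truth$nb_window$n_spikes), 12000L)
  expect_true(all(g$truth$nb_window$t_start <= g$truth$nb_window$t_end))
})

test_that("propagation offsets plant the requested onset delay", {
  lay <- grid_layout(4, 4, 1398.75 / (3 * sqrt(2)))
  g <- gen_spiketrains(lay, burst_schedule(n_nb = 10, nb_spikes = 600),
                       source_electrode = 4, velocity_mm_s = 3.73,
                       jitter_sd_s = 0, seed = 8)
  # electrode 13 sits 1398.75 um from electrode 4: delay = d / v = 0.375 s
  expect_equal(electrode_distance(lay, 4, 13), 1398.75)
  i4 <- match(4, lay$electrode_id); i13 <- match(13, lay$electrode_id)
  expect_equal(g$truth$offsets_s[[i13]] - g$truth$offsets_s[[i4]], 0.375,
               tolerance = 1e-12)
  # first spikes per NB realise the offsets exactly (jitter off)
  w <- g$truth$window_start_s
  expect_equal(unname(w[, i13] - w[, i4]), rep(0.375, 10))
  expect_error(
    gen_spiketrains(lay, burst_schedule(n_nb = 2), source_electrode = 4,
                    velocity_mm_s = 0, seed = 1),
    "velocity")
})

test_that("rendered traces carry the requested noise, spikes, and LFP", {
  lay <- mea_layout(1, 0, 0)
  empty <- tibble::tibble(electrode_id = integer(), time_s = numeric(),
                          amplitude_uV = numeric())
  # noise floor
  r <- render_traces(empty, lay, 2, noise_sd_uV = 4, seed = 1)
  expect_equal(sd(r$traces[1, ]), 4, tolerance = 0.02)

  # a single spike with no noise reproduces the template at its offset
  one <- tibble::tibble(electrode_id = 1L, time_s = 0.5003,
                        amplitude_uV = -60)
  r1 <- render_traces(one, lay, 1, noise_sd_uV = 0, amp_uV = 60, seed = 1)
  i <- round(0.5003 * 20000) + 1
  tt <- ((i - 10):(i + 10) - 1) / 20000 - 0.5003
  expect_equal(r1$traces[1, (i - 10):(i + 10)], spike_template(tt, 60))

  # an 8 Hz component gated to burst windows dominates the 6-10 Hz band
  lfp <- tibble::tibble(freq_hz = 8, amp_uV = 30, t_on_s = 2, t_off_s = 4)
  r2 <- render_traces(empty, lay, 6, fs = 10000, noise_sd_uV = 2,
                      lfp = lfp, seed = 2)
  wp <- wavelet_params(f_min = 2, f_max = 250, x_pixel_s = 1e-4)
  W <- cwt_morlet(r2$traces[1, ], 10000, wp)
  sc <- pixelate(W, 10000, wp)
  in_px <- seq(2.2 * 1e4, 3.8 * 1e4)
  out_px <- seq(4.4 * 1e4, 5.8 * 1e4)
  rows <- which(sc$f_grid >= 6 & sc$f_grid <= 10)
  ratio <- mean(sc$mag[rows, in_px]) / mean(sc$mag[rows, out_px])
  expect_gt(ratio, 5)
})

test_that("the axon dataset realises its planted geometry", {
  ax <- gen_axon_dataset(seed = 9, noise_sd_uV = 0)
  tru <- ax$truth
  expect_equal(tru$latency_s,
               tru$cum_dist_um / (tru$velocity_m_s * 1e6))
  # soma trough is 2.5x the axonal amplitude at the planted trough depth
  tmpl_min <- min(spike_template(seq(-2e-3, 2e-3, by = 5e-5), 1))
  i_soma <- match(tru$soma_electrode, ax$rec$layout$electrode_id)
  expect_equal(min(ax$rec$traces[i_soma, ]), 100 * tmpl_min,
               tolerance = 0.02)
  i_ax <- match(tru$path_electrode_ids[5], ax$rec$layout$electrode_id)
  expect_equal(min(ax$rec$traces[i_ax, ]), 40 * tmpl_min, tolerance = 0.02)
  # off-path electrodes are silent in the noiseless render
  off <- setdiff(seq_len(nrow(ax$rec$traces)),
                 match(tru$path_electrode_ids, ax$rec$layout$electrode_id))
  expect_identical(max(abs(ax$rec$traces[off, ])), 0)
})

test_that("detect -> netburst closes the loop on rendered bursts", {
  fx <- burst16_fixture()
  nbs <- detect_network_bursts(fx$spikes)
  tru <- fx$sim$truth$nb
  expect_identical(nrow(nbs), nrow(tru))
  expect_lt(max(abs(nbs$t_start - tru$t_start)), 0.010)
  expect_lt(max(abs(nbs$t_end - tru$t_end)), 0.010)
})
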