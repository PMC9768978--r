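#' Biphasic extracellular spike template
#'
#' Continuous-time template of a typical extracellular action potential:
#' a negative Gaussian trough (width ~0.4 ms) at `t = 0` followed by a
#' smaller positive overshoot, about 2 ms total. The spike time of a
#' rendered event is the trough centre. Evaluating the template as a
#' continuous function lets the generators place events at sub-sample
#' offsets.
#'
#' @param t_s Time relative to the spike (seconds); vectorised.
#' @param amp_uV Trough amplitude (positive number; the trough is
#'   `-amp_uV`).
#' @return Template values in microvolts.
#' @export
spike_template <- function(t_s, amp_uV = 60) {
  -amp_uV * exp(-t_s^2 / (2 * 0.0002^2)) +
    0.3 * amp_uV * exp(-(t_s - 0.0005)^2 / (2 * 0.0002^2))
}

#' Network-burst schedule
#'
#' Regular schedule of planted network bursts: `n_nb` bursts of
#' `nb_spikes` pooled spikes and `nb_duration_s` duration, one every
#' `period_s` starting at `start_s`.
#'
#' @param n_nb Number of bursts.
#' @param nb_spikes Pooled spikes per burst.
#' @param nb_duration_s Burst duration in seconds.
#' @param period_s Burst period in seconds (> `nb_duration_s`).
#' @param start_s Onset of the first burst.
#' @return Tibble `nb_id`, `onset_s`, `duration_s`, `n_spikes`.
#' @export
burst_schedule <- function(n_nb = 20, nb_spikes = 600, nb_duration_s = 0.4,
                           period_s = 2, start_s = 1) {
  stopifnot(n_nb >= 1, nb_spikes >= 1, nb_duration_s > 0,
            period_s > nb_duration_s, start_s >= 0)
  tibble::tibble(
    nb_id = seq_len(n_nb),
    onset_s = start_s + (seq_len(n_nb) - 1) * period_s,
    duration_s = nb_duration_s,
    n_spikes = as.integer(nb_spikes)
  )
}

# Draw n times from a Gaussian centred on the window, truncated to
# [lo, hi] (inverse-CDF sampling, so the count is exact).
rtrunc_norm <- function(n, lo, hi, mean, sd) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

#' Generate spike trains with planted network bursts
#'
#' Plants the bursts of `schedule` on the electrodes of `layout`. Within
#' each burst the pooled spike count is split evenly across electrodes;
#' each electrode's burst window starts at the scheduled onset plus, when
#' a propagation source is given, the travel time
#' `distance(source, e) / velocity` plus per-burst Gaussian jitter (the
#' source electrode ignites exactly on schedule and is not jittered).
#' Each electrode's first spike is pinned to its window start — the
#' ignition event — and the remaining spikes follow a truncated Gaussian
#' around the window centre, which gives the burst a well-defined
#' peak-rate bin. Background activity is homogeneous Poisson per
#' electrode. Everything is a pure function of the arguments and `seed`.
#'
#' @param layout Electrode layout.
#' @param schedule A [burst_schedule()].
#' @param duration_s Recording duration (defaults to the end of the last
#'   burst plus one second).
#' @param source_electrode Optional id of the propagation source.
#' @param velocity_mm_s Propagation velocity in mm/s (required with a
#'   source; must be > 0).
#' @param jitter_sd_s SD of the per-burst window-offset jitter (s).
#' @param background_hz Background rate per electrode (Hz).
#' @param amp_uV Nominal spike amplitude recorded in the event table.
#' @param core_params [burst_params()] used to express the ground-truth
#'   burst intervals as their ISI-chainable core (see below).
#' @param seed Integer seed.
#' @return List with `spikes` (event tibble), `truth` (a list) and
#'   `duration_s`. `truth$nb_window` holds the raw planted spans (first
#'   to last planted spike of each burst). Because the intra-burst
#'   profile is Gaussian, its sparse tails are not chainable at the
#'   burst detector's join interval — no detector working from spikes
#'   can recover them — so `truth$nb` additionally records the
#'   *recoverable* intervals: the 4-step result on the true, noise-free
#'   spike times under `core_params`. Closed-loop recovery is assessed
#'   against `truth$nb`. `truth` also carries `offsets_s` per electrode,
#'   `window_start_s`, `velocity_mm_s`, `jitter_sd_s` and `seed`.
#' @export
gen_spiketrains <- function(layout, schedule, duration_s = NULL,
                            source_electrode = NULL, velocity_mm_s = NULL,
                            jitter_sd_s = 0, background_hz = 0,
                            amp_uV = 60, core_params = burst_params(),
                            seed = 1) {
  if (!is.null(source_electrode)) {
    if (is.null(velocity_mm_s) || velocity_mm_s <= 0) {
      stop("propagation requested: velocity_mm_s must be > 0", call. = FALSE)
    }
    offs <- vapply(layout$electrode_id, function(e) {
      electrode_distance(layout, source_electrode, e) / 1000 / velocity_mm_s
    }, numeric(1))
  } else {
    offs <- rep(0, nrow(layout))
  }
  names(offs) <- layout$electrode_id
  if (is.null(duration_s)) {
    duration_s <- max(schedule$onset_s + schedule$duration_s) +
      max(offs) + 1
  }
  n_el <- nrow(layout)
  with_local_seed(seed, {
    win_start <- matrix(NA_real_, nrow(schedule), n_el)
    rows <- list()
    for (i in seq_len(nrow(schedule))) {
      n_per <- rep(schedule$n_spikes[i] %/% n_el, n_el)
      extra <- schedule$n_spikes[i] %% n_el
      if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
      for (e in seq_len(n_el)) {
        jit <- if (offs[e] > 0 && jitter_sd_s > 0) {
          stats::rnorm(1, 0, jitter_sd_s)
        } else 0
        w0 <- schedule$onset_s[i] + offs[e] + jit
        w1 <- w0 + schedule$duration_s[i]
        win_start[i, e] <- w0
        n_e <- n_per[e]
        if (n_e == 0) next
        tt <- w0
        if (n_e > 1) {
          # burst profile: uniform floor (dense, sharp edges, so burst
          # boundaries are well defined under detection thinning) plus a
          # Gaussian peak (a well-defined maximum-frequency bin), at
          # physiological per-electrode rates
          k <- n_e - 1L
          n_u <- floor(0.8 * k)
          tt <- c(tt, sort(c(
            stats::runif(n_u, w0, w1),
            rtrunc_norm(k - n_u, w0, w1, (w0 + w1) / 2,
                        schedule$duration_s[i] / 6))))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          electrode_id = layout$electrode_id[e],
          time_s = tt,
          amplitude_uV = -amp_uV,
          nb_id = schedule$nb_id[i]
        )
      }
    }
    spk <- dplyr::bind_rows(rows)
    if (background_hz > 0) {
      for (e in seq_len(n_el)) {
        n_bg <- stats::rpois(1, background_hz * duration_s)
        if (n_bg > 0) {
          spk <- dplyr::bind_rows(spk, tibble::tibble(
            electrode_id = layout$electrode_id[e],
            time_s = stats::runif(n_bg, 0, duration_s),
            amplitude_uV = -amp_uV,
            nb_id = NA_integer_
          ))
        }
      }
    }
    spk <- spk[spk$time_s >= 0 & spk$time_s <= duration_s, ]
    nb_true <- spk |>
      dplyr::filter(!is.na(.data$nb_id)) |>
      dplyr::group_by(.data$nb_id) |>
      dplyr::summarise(t_start = min(.data$time_s),
                       t_end = max(.data$time_s),
                       n_spikes = dplyr::n(), .groups = "drop")
    spikes <- validate_spikes(spk[, c("electrode_id", "time_s",
                                      "amplitude_uV")])
    nb_core <- detect_network_bursts(spikes, core_params)
    list(
      spikes = spikes,
      truth = list(
        nb = nb_core,
        nb_window = nb_true,
        spike_nb_id = spk$nb_id,
        offsets_s = offs,
        window_start_s = win_start,
        velocity_mm_s = velocity_mm_s,
        jitter_sd_s = jitter_sd_s,
        seed = seed
      ),
      duration_s = duration_s
    )
  })
}

#' Render raw voltage traces from spike events
#'
#' Builds a raw multichannel recording: i.i.d. Gaussian noise, the spike
#' template added at every event time (evaluated continuously, so
#' sub-sample event times are honoured), and optional low-frequency
#' field-potential components — amplitude-gated sinusoids, e.g.
#' time-locked to burst windows — summed onto all or selected channels.
#'
#' @param spikes Event tibble (electrode ids must be in `layout`).
#' @param layout Electrode layout.
#' @param duration_s Trace duration in seconds.
#' @param fs Sampling rate (>= 10 kHz so the 2 ms template is resolved).
#' @param noise_sd_uV Noise SD per channel in microvolts.
#' @param amp_uV Template trough amplitude; overrides the event table's
#'   amplitudes when not `NULL`.
#' @param lfp Optional tibble of oscillatory components with columns
#'   `freq_hz`, `amp_uV`, `t_on_s`, `t_off_s` and optionally
#'   `electrode_id` (`NA` = all channels).
#' @param seed Integer seed.
#' @return A raw [mea_recording()].
#' @export
render_traces <- function(spikes, layout, duration_s, fs = 20000,
                          noise_sd_uV = 4, amp_uV = 60, lfp = NULL,
                          seed = 1) {
  if (fs < 10000) stop("fs must be >= 10 kHz", call. = FALSE)
  n <- round(duration_s * fs)
  n_el <- nrow(layout)
  with_local_seed(seed, {
    tr <- matrix(stats::rnorm(n_el * n, 0, noise_sd_uV), nrow = n_el)
    half <- round(0.0015 * fs)                  # template support +-1.5 ms
    for (e in seq_len(n_el)) {
      st <- spikes$time_s[spikes$electrode_id == layout$electrode_id[e]]
      for (ts in st) {
        c0 <- round(ts * fs) + 1L
        if (c0 + half < 1L || c0 - half > n) next
        win <- max(1L, c0 - half):min(n, c0 + half)
        tr[e, win] <- tr[e, win] +
          spike_template((win - 1) / fs - ts, amp_uV %||% 60)
      }
    }
    if (!is.null(lfp) && nrow(lfp)) {
      tvec <- (seq_len(n) - 1) / fs
      for (r in seq_len(nrow(lfp))) {
        i0 <- max(1L, ceiling(lfp$t_on_s[r] * fs) + 1L)
        i1 <- min(n, floor(lfp$t_off_s[r] * fs))
        if (i1 < i0) next
        comp <- lfp$amp_uV[r] *
          sin(2 * pi * lfp$freq_hz[r] * (tvec[i0:i1] - lfp$t_on_s[r]))
        chans <- if (!"electrode_id" %in% names(lfp) ||
                     is.na(lfp$electrode_id[r])) {
          seq_len(n_el)
        } else match(lfp$electrode_id[r], layout$electrode_id)
        for (e in chans) tr[e, i0:i1] <- tr[e, i0:i1] + comp
      }
    }
    mea_recording(tr, fs = fs, layout = layout)
  })
}

#' Synthetic high-density axon-conduction dataset
#'
#' Emulates a local CMOS-array recording of one firing neuron whose axon
#' runs along a straight row of electrodes: every trigger deposits the
#' spike template on the soma electrode (larger amplitude) and on each
#' path electrode, delayed by its along-path distance divided by the
#' conduction velocity. Lateral amplitude decay is sharp
#' (`exp(-d/decay_um)`, truncated below 5%), so off-path electrodes carry
#' pure noise. Trigger times fall on exact sample ticks, so the planted
#' waveform repeats identically.
#'
#' @param grid_nrow,grid_ncol Electrode grid dimensions (<= 64 each).
#' @param pitch_um Grid pitch in micrometres.
#' @param velocity_m_s Planted conduction velocity (> 0).
#' @param path_row Grid row (1-based from bottom) carrying the axon.
#' @param path_cols Columns of the path; the first is the soma.
#' @param decay_um Lateral amplitude decay length.
#' @param n_triggers Number of firings.
#' @param period_s Inter-firing interval.
#' @param noise_sd_uV Noise SD.
#' @param amp_uV Axonal template amplitude; the soma gets `2.5 * amp_uV`.
#' @param fs Sampling rate.
#' @param seed Integer seed.
#' @return List `rec` (raw recording), `triggers` (times), `truth` (list:
#'   `soma_electrode`, `path_electrode_ids`, `latency_s`, `cum_dist_um`,
#'   `velocity_m_s`, `seed`).
#' @export
gen_axon_dataset <- function(grid_nrow = 16, grid_ncol = 16, pitch_um = 35,
                             velocity_m_s = 0.57, path_row = 8,
                             path_cols = 2:15, decay_um = 10,
                             n_triggers = 60, period_s = 0.03,
                             noise_sd_uV = 3, amp_uV = 40, fs = 20000,
                             seed = 1) {
  stopifnot(grid_nrow <= 64, grid_ncol <= 64, velocity_m_s > 0,
            path_row >= 1, path_row <= grid_nrow,
            all(path_cols >= 1), all(path_cols <= grid_ncol))
  layout <- grid_layout(grid_nrow, grid_ncol, pitch_um)
  path_ids <- as.integer((path_row - 1) * grid_ncol + path_cols)
  soma <- path_ids[1]
  cum_dist <- cumsum(c(0, abs(diff(path_cols)) * pitch_um))
  latency <- cum_dist / (velocity_m_s * 1e6)     # um / (um/s)
  duration_s <- n_triggers * period_s + 0.05
  n <- round(duration_s * fs)
  trig <- round((seq_len(n_triggers) - 0.5) * period_s * fs) / fs
  with_local_seed(seed, {
    tr <- matrix(stats::rnorm(nrow(layout) * n, 0, noise_sd_uV),
                 nrow = nrow(layout))
    # signal electrodes: the path plus any electrode within the lateral
    # decay reach of the path row
    px <- layout$x_um[match(path_ids, layout$electrode_id)]
    py <- layout$y_um[match(path_ids, layout$electrode_id)][1]
    for (e in seq_len(nrow(layout))) {
      dx <- layout$x_um[e]; dy <- layout$y_um[e]
      d_lat <- if (dx >= min(px) && dx <= max(px)) abs(dy - py) else {
        sqrt(min((dx - px)^2) + (dy - py)^2)
      }
      scale <- exp(-d_lat / decay_um)
      if (scale < 0.05) next
      on_path <- match(layout$electrode_id[e], path_ids)
      lat_e <- if (!is.na(on_path)) latency[on_path] else {
        (dx - px[1]) / (velocity_m_s * 1e6)
      }
      a_e <- amp_uV * scale * if (!is.na(on_path) && on_path == 1) 2.5 else 1
      half <- round(0.0015 * fs)
      for (ts in trig) {
        c0 <- round((ts + lat_e) * fs) + 1L
        win <- max(1L, c0 - half):min(n, c0 + half)
        tr[e, win] <- tr[e, win] +
          spike_template((win - 1) / fs - ts - lat_e, amp_uV = 1) * a_e
      }
    }
    list(
      rec = mea_recording(tr, fs = fs, layout = layout),
      triggers = trig,
      truth = list(
        soma_electrode = soma,
        path_electrode_ids = path_ids,
        latency_s = latency,
        cum_dist_um = cum_dist,
        velocity_m_s = velocity_m_s,
        seed = seed
      )
    )
  })
}

#' Synthetic network-burst onsets for identified neurons
#'
#' Emulates the repeated burst-onset propagation seen across identified
#' neurons on a high-density array: in every burst, the wave starts at
#' the first neuron of `positions` and reaches each other neuron after
#' `distance / velocity` plus Gaussian jitter.
#'
#' @param positions Tibble `neuron_id`, `x_um`, `y_um`; the first row is
#'   the source.
#' @param n_nb Number of bursts.
#' @param velocity_m_s Planted network propagation velocity.
#' @param jitter_sd_s Per-(burst, neuron) onset jitter SD.
#' @param period_s Burst period.
#' @param seed Integer seed.
#' @return Tibble `nb_id`, `neuron_id`, `onset_s`.
#' @export
gen_network_onsets <- function(positions, n_nb = 4, velocity_m_s = 0.14,
                               jitter_sd_s = 1e-3, period_s = 5,
                               seed = 1) {
  stopifnot(velocity_m_s > 0, n_nb >= 1)
  src <- positions[1, ]
  delay <- sqrt((positions$x_um - src$x_um)^2 +
                (positions$y_um - src$y_um)^2) / (velocity_m_s * 1e6)
  with_local_seed(seed, {
    purrr::map_dfr(seq_len(n_nb), function(i) {
      jit <- c(0, stats::rnorm(nrow(positions) - 1, 0, jitter_sd_s))
      tibble::tibble(
        nb_id = i,
        neuron_id = positions$neuron_id,
        onset_s = (i - 1) * period_s + delay + jit
      )
    })
  })
}

#' Synthetic dose-response parameter samples
#'
#' Draws a ten-parameter table with known group means: one row per
#' replicate well per group, each metric Normal around its group mean.
#'
#' @param group_means Tibble with `condition`, `concentration` and one
#'   column per burst metric giving that group's mean.
#' @param n_per_group Replicates per group (>= 2).
#' @param sd Noise SD: scalar, or named vector per metric.
#' @param seed Integer seed.
#' @return A parameter table as from [build_param_table()].
#' @export
gen_param_samples <- function(group_means, n_per_group, sd = 1, seed = 1) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  metrics <- intersect(burst_metric_names(), names(group_means))
  if (!length(metrics)) stop("group_means has no metric columns",
                             call. = FALSE)
  sds <- if (length(sd) == 1) stats::setNames(rep(sd, length(metrics)),
                                              metrics) else sd[metrics]
  with_local_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(group_means)), function(g) {
      out <- tibble::tibble(
        sample_id = paste0(group_means$condition[g], "_",
                           group_means$concentration[g], "_",
                           seq_len(n_per_group)),
        condition = group_means$condition[g],
        concentration = group_means$concentration[g]
      )
      base_sd <- if (length(sd) == 1) sd else 1
      for (m in burst_metric_names()) {
        out[[m]] <- if (m %in% metrics) {
          stats::rnorm(n_per_group, group_means[[m]][g], sds[[m]])
        } else stats::rnorm(n_per_group, 0, base_sd)   # null metric
      }
      out
    })
    rows[order(rows$condition, rows$concentration, rows$sample_id), ]
  })
}

#' Standard synthetic presets
#'
#' Ready-made study configurations used throughout the package's
#' validation:
#' \describe{
#'   \item{burst16}{16-electrode (4 x 4, 450 um pitch) well with 20
#'     synchronous bursts of 600 spikes (0.3 s each, every 2 s), sparse
#'     background, rendered at 20 kHz with noise SD 4 uV and spike
#'     amplitude 8 x noise (detection-limited regime).}
#'   \item{spheroid_pair}{Two-spheroid configuration: 4 x 4 grid scaled so
#'     the diagonal electrodes 4 and 13 sit 1398.75 um apart; bursts
#'     ignite at electrode 4 and reach electrode 13 after 0.375 s
#'     (velocity 3.73 mm/s), 31 bursts, onset jitter SD 0.166 s.}
#'   \item{cmos_axon}{[gen_axon_dataset()] defaults: 16 x 16 grid, 35 um
#'     pitch, 14-electrode axonal path at 0.57 m/s.}
#'   \item{cmos_network}{Seven identified neurons spanning ~2.4 mm,
#'     4 bursts, 0.14 m/s, 1 ms onset jitter (onset table only).}
#' }
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to the underlying generator.
#' @return The generator's return value (see each generator).
#' @export
simulate_preset <- function(preset = c("burst16", "spheroid_pair",
                                       "cmos_axon", "cmos_network"),
                            seed = 1, ...) {
  preset <- match.arg(preset)
  switch(preset,
    burst16 = {
      layout <- grid_layout(4, 4, pitch_um = 450)
      gt <- gen_spiketrains(layout, burst_schedule(), background_hz = 0.1,
                            amp_uV = 32, seed = seed, ...)
      gt$rec <- render_traces(gt$spikes, layout, gt$duration_s,
                              noise_sd_uV = 4, amp_uV = 32,
                              seed = seed + 1000L)
      gt
    },
    spheroid_pair = {
      layout <- grid_layout(4, 4, pitch_um = 1398.75 / (3 * sqrt(2)))
      # spheroids are multiunit sources: ~300 spikes per electrode per
      # burst (1 kHz instantaneous multiunit rate), so the leading
      # source-electrode segment of each burst is densely chainable
      gen_spiketrains(layout,
                      burst_schedule(n_nb = 31, nb_spikes = 4800,
                                     nb_duration_s = 0.3, period_s = 2),
                      source_electrode = 4, velocity_mm_s = 3.73,
                      jitter_sd_s = 0.166, background_hz = 0.1,
                      seed = seed, ...)
    },
    cmos_axon = gen_axon_dataset(seed = seed, ...),
    cmos_network = {
      positions <- tibble::tibble(
        neuron_id = 1:7,
        x_um = c(0, 400, 800, 1200, 1600, 2000, 2400),
        y_um = c(0, 100, -150, 300, -100, 200, 0)
      )
      list(positions = positions,
           onsets = gen_network_onsets(positions, seed = seed, ...))
    }
  )
}
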