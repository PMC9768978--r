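#' Network-burst onset delays between two electrodes
#'
#' For every network burst, the delay between the first spike of the
#' target electrode and the first spike of the reference electrode inside
#' the burst window. Bursts where either electrode is silent are excluded
#' (and counted). This is the per-burst onset-delay series used for
#' pairwise propagation-velocity estimates on two-spheroid preparations.
#'
#' @param nbs NB tibble from [detect_network_bursts()].
#' @param spikes Spike tibble.
#' @param ref_electrode,target_electrode Electrode ids.
#' @return Tibble with one row per usable NB: `nb_id`, `ref_onset_s`,
#'   `target_onset_s`, `delay_s`; attributes `n_excluded`, `mean_delay_s`,
#'   `sd_delay_s`.
#' @export
nb_onset_delays <- function(nbs, spikes, ref_electrode, target_electrode) {
  if (nrow(nbs) < 1) stop("no network bursts supplied", call. = FALSE)
  on <- nb_onsets(nbs, spikes)
  ref <- on[on$electrode_id == ref_electrode, c("nb_id", "onset_s")]
  tgt <- on[on$electrode_id == target_electrode, c("nb_id", "onset_s")]
  names(ref)[2] <- "ref_onset_s"
  names(tgt)[2] <- "target_onset_s"
  d <- dplyr::inner_join(ref, tgt, by = "nb_id")
  if (nrow(d) == 0) {
    stop("no burst has onsets on both electrodes ", ref_electrode, " and ",
         target_electrode, call. = FALSE)
  }
  d$delay_s <- d$target_onset_s - d$ref_onset_s
  structure(tibble::as_tibble(d),
            n_excluded = nrow(nbs) - nrow(d),
            mean_delay_s = mean(d$delay_s),
            sd_delay_s = stats::sd(d$delay_s))
}

#' Pairwise propagation velocity
#'
#' Velocity between two recording sites from the electrode separation and
#' the mean burst-onset delay, reported in mm/s (the natural scale for
#' polysynaptic network propagation).
#'
#' @param distance_um Electrode separation in micrometres (> 0).
#' @param mean_delay_s Mean onset delay in seconds (> 0).
#' @return Velocity in mm/s.
#' @export
pair_velocity <- function(distance_um, mean_delay_s) {
  if (distance_um <= 0) stop("distance must be positive", call. = FALSE)
  if (mean_delay_s <= 0) {
    stop("mean delay must be positive (check propagation direction)",
         call. = FALSE)
  }
  (distance_um / 1000) / mean_delay_s
}

#' Relative velocity under treatment
#'
#' @param v_treated,v_baseline Velocities in the same units;
#'   `v_baseline > 0`.
#' @return Dimensionless ratio `v_treated / v_baseline`.
#' @export
relative_velocity <- function(v_treated, v_baseline) {
  if (any(v_baseline <= 0)) stop("baseline velocity must be positive",
                                 call. = FALSE)
  v_treated / v_baseline
}

#' Velocity from a distance-versus-latency fit
#'
#' Ordinary least squares of inter-electrode distance (response, um) on
#' spike-time latency (predictor, s). The slope is the velocity; the
#' intercept is left free to absorb any alignment offset and is also
#' reported on the time axis (`-intercept/slope`). Two points give an
#' exact fit and are flagged.
#'
#' @param distance_um Distances in micrometres.
#' @param latency_s Latencies in seconds.
#' @return An object of class `velocity_fit` with `velocity_m_s`,
#'   `r_squared`, `n_points`, `intercept_um`, `intercept_s`, `exact`
#'   and the underlying `lm` fit. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_velocity <- function(distance_um, latency_s) {
  if (length(distance_um) != length(latency_s)) {
    stop("distance and latency vectors differ in length", call. = FALSE)
  }
  n <- length(distance_um)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(latency_s) == 0) {
    stop("degenerate fit: all latencies equal", call. = FALSE)
  }
  fit <- stats::lm(distance_um ~ latency_s)
  slope <- unname(stats::coef(fit)[2])       # um / s
  icpt <- unname(stats::coef(fit)[1])
  ss_tot <- sum((distance_um - mean(distance_um))^2)
  r2 <- if (n == 2 || ss_tot == 0) 1 else {
    1 - sum(stats::residuals(fit)^2) / ss_tot
  }
  structure(list(
    velocity_m_s = slope * 1e-6,
    r_squared = r2,
    n_points = n,
    intercept_um = icpt,
    intercept_s = -icpt / slope,
    exact = n == 2,
    fit = fit
  ), class = "velocity_fit")
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("<velocity_fit> v = %.4g m/s (R^2 = %.3f, n = %d)%s\n",
              x$velocity_m_s, x$r_squared, x$n_points,
              if (x$exact) " [exact 2-point fit]" else ""))
  invisible(x)
}

#' @export
tidy.velocity_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept_um", "velocity_um_s"),
    estimate = unname(co[, 1]),
    std_error = unname(co[, 2])
  )
}

#' @export
glance.velocity_fit <- function(x, ...) {
  tibble::tibble(velocity_m_s = x$velocity_m_s, r_squared = x$r_squared,
                 n_points = x$n_points, intercept_s = x$intercept_s)
}

#' Median spike amplitude per electrode
#'
#' The per-electrode "spike amplitude" used for soma localisation on
#' high-density arrays: the median absolute amplitude of that electrode's
#' detected spikes.
#'
#' @param spikes Spike tibble.
#' @param layout Layout; electrodes without spikes get amplitude 0.
#' @return Tibble `electrode_id`, `x_um`, `y_um`, `amplitude_uV`.
#' @export
amplitude_map <- function(spikes, layout) {
  amp <- dplyr::summarise(dplyr::group_by(spikes, .data$electrode_id),
                          amplitude_uV = stats::median(abs(.data$amplitude_uV)),
                          .groups = "drop")
  out <- dplyr::left_join(layout, amp, by = "electrode_id")
  out$amplitude_uV[is.na(out$amplitude_uV)] <- 0
  out
}

#' Soma localisation from a spike-amplitude map
#'
#' Locates cell bodies as local maxima of the spike-amplitude footprint:
#' electrodes at or above `min_amp` are taken in decreasing amplitude
#' order (ties broken toward the lower electrode id) and accepted greedily
#' if no already-accepted soma lies within `min_sep_um`.
#'
#' @param amp_map Tibble from [amplitude_map()] (needs `electrode_id`,
#'   `x_um`, `y_um`, `amplitude_uV`).
#' @param min_amp Amplitude floor in microvolts.
#' @param min_sep_um Minimum separation between somata.
#' @return Tibble of accepted somata, ordered by decreasing amplitude;
#'   possibly empty.
#' @export
localize_somata <- function(amp_map, min_amp, min_sep_um) {
  cand <- amp_map[amp_map$amplitude_uV >= min_amp, , drop = FALSE]
  cand <- cand[order(-cand$amplitude_uV, cand$electrode_id), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      d <- sqrt((cand$x_um[i] - cand$x_um[j])^2 +
                (cand$y_um[i] - cand$y_um[j])^2)
      if (d < min_sep_um) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  tibble::as_tibble(cand[keep, , drop = FALSE])
}

#' Spike-triggered average waveforms
#'
#' Averages, on every electrode, the 4 ms of signal around each trigger
#' (1.5 ms before to 2.5 ms after the reference neuron's firing times).
#' Triggers whose window would be clipped by the recording edges are
#' dropped and counted.
#'
#' @param rec A [mea_recording()].
#' @param trigger_times Reference spike times in seconds.
#' @param pre_s,post_s Window extent before/after the trigger (defaults
#'   1.5 and 2.5 ms).
#' @return Object of class `mea_sta`: list with `waveforms`
#'   (`n_channels x n_samples` matrix of mean waveforms), `time_s` (window
#'   time axis, 0 = trigger), `fs`, `layout`, `n_used`, `n_dropped`.
#' @export
spike_triggered_average <- function(rec, trigger_times, pre_s = 1.5e-3,
                                    post_s = 2.5e-3) {
  stopifnot(inherits(rec, "mea_recording"))
  n_pre <- round(pre_s * rec$fs)
  n_post <- round(post_s * rec$fs)
  len <- n_pre + n_post
  n <- ncol(rec$traces)
  idx0 <- round((trigger_times - rec$t0) * rec$fs) + 1L
  ok <- idx0 - n_pre >= 1L & idx0 + n_post - 1L <= n
  n_dropped <- sum(!ok)
  idx0 <- idx0[ok]
  if (!length(idx0)) {
    stop("no trigger lies fully inside the recording", call. = FALSE)
  }
  acc <- matrix(0, nrow = nrow(rec$traces), ncol = len)
  offs <- (-n_pre):(n_post - 1L)
  for (i0 in idx0) acc <- acc + rec$traces[, i0 + offs, drop = FALSE]
  structure(list(
    waveforms = acc / length(idx0),
    time_s = offs / rec$fs,
    fs = rec$fs,
    layout = rec$layout,
    n_used = length(idx0),
    n_dropped = n_dropped
  ), class = "mea_sta")
}

#' @export
print.mea_sta <- function(x, ...) {
  cat(sprintf("<mea_sta> %d channels x %d samples (%.1f ms), %d triggers",
              nrow(x$waveforms), ncol(x$waveforms),
              1000 * diff(range(x$time_s)), x$n_used),
      if (x$n_dropped) sprintf("(%d dropped)", x$n_dropped), "\n")
  invisible(x)
}

# Trough latency of one STA waveform, refined by 3-point parabolic
# interpolation around the sampled minimum (beats the sampling-interval
# quantisation for smooth templates).
sta_trough <- function(w, time_s) {
  i <- which.min(w)
  lat <- time_s[i]
  if (i > 1 && i < length(w)) {
    y1 <- w[i - 1]; y2 <- w[i]; y3 <- w[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den > 0) {
      lat <- lat + 0.5 * (y1 - y3) / den * (time_s[2] - time_s[1])
    }
  }
  list(latency_s = lat, trough_uV = -min(w))
}

# Max over lags of the normalised cross-correlation of two waveforms.
max_xcorr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  cc <- stats::convolve(a, b, conj = TRUE, type = "open")
  max(cc) / (na * nb)
}

#' Automated axon-path extraction from STA footprints
#'
#' Selects, from the per-electrode spike-triggered averages of one neuron,
#' the electrodes carrying its axonal signal: STA trough amplitude at
#' least `amp_min` and maximum normalised cross-correlation with the soma
#' STA (over lags) at least `rho_min`. Selected electrodes are ordered by
#' STA trough latency; the cumulative distance is the sum of consecutive
#' Euclidean inter-electrode distances along that order. This automates
#' the manual picking of "similar waveform" electrodes with a
#' deterministic rule.
#'
#' @param sta A `mea_sta` from [spike_triggered_average()].
#' @param soma_electrode Electrode id over the soma.
#' @param rho_min Waveform-similarity threshold in \[0, 1\] (default 0.7).
#' @param amp_min STA trough floor in microvolts.
#' @return Object of class `axon_path`: tibble `electrode_id`, `x_um`,
#'   `y_um`, `latency_s`, `trough_uV`, `rho`, `cum_dist_um`, ordered from
#'   the soma outward; attribute `soma_only` flags an empty selection.
#' @export
trace_axon_path <- function(sta, soma_electrode, rho_min = 0.7, amp_min) {
  stopifnot(inherits(sta, "mea_sta"))
  ids <- sta$layout$electrode_id
  si <- match(soma_electrode, ids)
  if (is.na(si)) stop("soma electrode not in layout", call. = FALSE)
  soma_w <- sta$waveforms[si, ]
  feats <- purrr::map_dfr(seq_along(ids), function(i) {
    tr <- sta_trough(sta$waveforms[i, ], sta$time_s)
    tibble::tibble(
      electrode_id = ids[i],
      x_um = sta$layout$x_um[i], y_um = sta$layout$y_um[i],
      latency_s = tr$latency_s, trough_uV = tr$trough_uV,
      rho = if (i == si) 1 else max_xcorr(sta$waveforms[i, ], soma_w)
    )
  })
  sel <- feats$trough_uV >= amp_min & feats$rho >= rho_min
  sel[si] <- TRUE                      # soma always anchors the path
  soma_only <- sum(sel) == 1L
  path <- feats[sel, , drop = FALSE]
  path <- path[order(path$latency_s, path$electrode_id), , drop = FALSE]
  seg <- c(0, sqrt(diff(path$x_um)^2 + diff(path$y_um)^2))
  path$cum_dist_um <- cumsum(seg)
  structure(tibble::as_tibble(path), class = c("axon_path", class(path)),
            soma_only = soma_only)
}

#' Axonal conduction velocity along a path
#'
#' Distance-versus-latency fit ([fit_velocity()]) over the ordered
#' electrodes of an [trace_axon_path()] result, using the cumulative
#' along-path distance and the STA trough latency per electrode.
#'
#' @param path An `axon_path` (or any tibble with `cum_dist_um`,
#'   `latency_s`).
#' @return A `velocity_fit`.
#' @export
conduction_velocity <- function(path) {
  if (nrow(path) < 2) stop("path has fewer than 2 electrodes", call. = FALSE)
  fit_velocity(path$cum_dist_um, path$latency_s)
}

#' Network propagation velocity across identified neurons
#'
#' Joint distance-versus-delay fit across network bursts for a set of
#' identified neurons on a high-density array. Within each burst the
#' reference is the earliest-firing neuron; each neuron contributes one
#' point per burst: its Euclidean distance from that burst's reference
#' neuron against its first-spike delay.
#'
#' @param onsets Tibble `nb_id`, `neuron_id`, `onset_s` (first spike of
#'   each neuron in each burst).
#' @param positions Tibble `neuron_id`, `x_um`, `y_um`.
#' @return A `velocity_fit`, with the per-point table in attribute
#'   `"points"`.
#' @export
fit_network_velocity <- function(onsets, positions) {
  pts <- purrr::map_dfr(split(onsets, onsets$nb_id), function(d) {
    ref <- d$neuron_id[which.min(d$onset_s)]
    rp <- positions[match(ref, positions$neuron_id), ]
    pp <- positions[match(d$neuron_id, positions$neuron_id), ]
    tibble::tibble(
      nb_id = d$nb_id,
      neuron_id = d$neuron_id,
      distance_um = sqrt((pp$x_um - rp$x_um)^2 + (pp$y_um - rp$y_um)^2),
      delay_s = d$onset_s - min(d$onset_s)
    )
  })
  pts <- pts[pts$delay_s > 0 | pts$distance_um > 0, , drop = FALSE]
  fit <- fit_velocity(pts$distance_um, pts$delay_s)
  attr(fit, "points") <- pts
  fit
}
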