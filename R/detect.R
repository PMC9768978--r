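#' Zero-phase high-pass filtering
#'
#' Applies an order-`order` Butterworth high-pass forward and backward
#' (zero phase) to every channel. Standard practice for extracellular
#' recordings: a 1 Hz corner removes drift for field-potential work and a
#' 100 Hz corner isolates the spike band for detection.
#'
#' @param rec A [mea_recording()].
#' @param cutoff_hz Corner frequency in Hz, must be below Nyquist.
#' @param order Filter order (>= 1); the default 4 is a common compromise
#'   between roll-off and ringing.
#' @return The filtered recording, with a `hp<cutoff>` tag appended to
#'   `filters`.
#' @export
highpass <- function(rec, cutoff_hz = 100, order = 4) {
  stopifnot(inherits(rec, "mea_recording"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2) {
    stop("cutoff must lie in (0, fs/2) = (0, ", rec$fs / 2, ") Hz",
         call. = FALSE)
  }
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  out <- rec
  for (i in seq_len(nrow(rec$traces))) {
    # removing the channel mean first keeps the filter's edge transient
    # independent of any DC offset
    v <- rec$traces[i, ]
    out$traces[i, ] <- signal::filtfilt(bf, v - mean(v))
  }
  out$filters <- c(rec$filters, paste0("hp", format(cutoff_hz)))
  out
}

#' Baseline noise estimate
#'
#' Estimates the standard deviation of the baseline noise of a spike-band
#' trace. The default is the median absolute deviation divided by 0.6745
#' (the Gaussian consistency constant), which tracks the quiescent-period
#' SD while being insensitive to sparse spikes. `method = "iterative"`
#' instead drops samples beyond 4 sigma and re-estimates the plain SD
#' (two passes), for comparison.
#'
#' @param x Numeric trace in microvolts.
#' @param fs Sampling rate in Hz; traces shorter than 0.5 s are rejected
#'   as too short for a stable estimate.
#' @param method `"mad"` (default) or `"iterative"`.
#' @return Estimated sigma in microvolts (>= 0), with the method recorded
#'   in the `"method"` attribute.
#' @export
estimate_sigma <- function(x, fs, method = c("mad", "iterative")) {
  method <- match.arg(method)
  if (length(x) < 0.5 * fs) {
    stop("trace too short for noise estimation (< 0.5 s)", call. = FALSE)
  }
  sigma <- if (method == "mad") {
    stats::median(abs(x - stats::median(x))) / 0.6745
  } else {
    s <- stats::sd(x)
    for (pass in 1:2) {
      keep <- abs(x) <= 4 * s
      if (!any(keep)) break
      s <- stats::sd(x[keep])
    }
    s
  }
  if (!is.finite(sigma)) sigma <- 0
  structure(sigma, method = method)
}

#' @rdname estimate_sigma
#' @param rec A recording; sigma is estimated per channel.
#' @return `estimate_noise()`: a tibble with `electrode_id`, `sigma_uV`,
#'   `method`.
#' @export
estimate_noise <- function(rec, method = c("mad", "iterative")) {
  method <- match.arg(method)
  tibble::tibble(
    electrode_id = rec$layout$electrode_id,
    sigma_uV = vapply(seq_len(nrow(rec$traces)), function(i) {
      as.numeric(estimate_sigma(rec$traces[i, ], rec$fs, method))
    }, numeric(1)),
    method = method
  )
}

#' Threshold spike detection
#'
#' Counts a spike when the (spike-band filtered) signal exceeds +/- k sigma,
#' with sigma the per-channel baseline-noise SD. An event is placed at the
#' extremum of the deflection within the alignment window after the
#' threshold crossing; crossings within the dead time of the previous
#' accepted crossing are ignored, so at most one event fires per dead-time
#' window. The amplitude reported is the signed extremum.
#'
#' The recording must carry a high-pass tag at or above `min_cutoff_hz`
#' (detection on unfiltered traces is a pipeline error); pass
#' `require_highpass = FALSE` to override.
#'
#' @param rec A filtered [mea_recording()].
#' @param k Threshold multiplier (default 5).
#' @param dead_time_s Minimum separation between events (default 1 ms).
#' @param align_window_s Extremum search window after the crossing
#'   (default 0.5 ms).
#' @param sigma Optional tibble `electrode_id`, `sigma_uV` to reuse noise
#'   estimates; computed via [estimate_noise()] when `NULL`.
#' @param min_cutoff_hz Smallest acceptable high-pass corner tag.
#' @param require_highpass Assert the high-pass precondition.
#' @return Spike tibble (`electrode_id`, `time_s`, `amplitude_uV`), sorted,
#'   with the sigma table attached as attribute `"sigma"`.
#' @export
detect_spikes <- function(rec, k = 5, dead_time_s = 1e-3,
                          align_window_s = 5e-4, sigma = NULL,
                          min_cutoff_hz = 100, require_highpass = TRUE) {
  stopifnot(inherits(rec, "mea_recording"))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (dead_time_s < 0) stop("dead_time_s must be >= 0", call. = FALSE)
  if (require_highpass) {
    cuts <- as.numeric(sub("^hp", "", grep("^hp", rec$filters, value = TRUE)))
    if (!length(cuts) || max(cuts) < min_cutoff_hz) {
      stop("recording is not high-pass filtered at >= ", min_cutoff_hz,
           " Hz; run highpass() first (or set require_highpass = FALSE)",
           call. = FALSE)
    }
  }
  if (is.null(sigma)) sigma <- estimate_noise(rec)
  dead_n <- round(dead_time_s * rec$fs)
  align_n <- round(align_window_s * rec$fs)
  out <- purrr::map_dfr(seq_len(nrow(rec$traces)), function(i) {
    v <- rec$traces[i, ]
    sd_i <- sigma$sigma_uV[match(rec$layout$electrode_id[i],
                                 sigma$electrode_id)]
    if (sd_i == 0) {
      if (any(v != 0)) {
        stop("sigma = 0 with a nonzero trace on electrode ",
             rec$layout$electrode_id[i], ": degenerate threshold",
             call. = FALSE)
      }
      return(NULL)
    }
    thr <- k * sd_i
    ev <- threshold_events(v, thr, dead_n, align_n)
    if (!length(ev$idx)) return(NULL)
    tibble::tibble(
      electrode_id = rec$layout$electrode_id[i],
      time_s = rec$t0 + (ev$idx - 1) / rec$fs,
      amplitude_uV = ev$amp
    )
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(electrode_id = integer(), time_s = numeric(),
                          amplitude_uV = numeric())
  }
  out <- validate_spikes(out)
  attr(out, "sigma") <- sigma
  attr(out, "k") <- k
  out
}

# Crossing scan on one channel: upward crossings of |v| through thr,
# dead time measured between accepted crossing samples, event placed at
# the extremum of |v| in [crossing, crossing + align_n].
threshold_events <- function(v, thr, dead_n, align_n) {
  a <- abs(v)
  n <- length(v)
  cross <- which(a[-1] >= thr & a[-n] < thr) + 1L
  idx <- integer(0)
  amp <- numeric(0)
  last <- -Inf
  for (cx in cross) {
    if (cx - last < dead_n) next
    last <- cx
    win <- cx:min(n, cx + align_n)
    j <- win[which.max(a[win])]
    idx <- c(idx, j)
    amp <- c(amp, v[j])
  }
  list(idx = idx, amp = amp)
}

#' Spike-rate histogram
#'
#' Counts spikes in half-open time bins `[i*bin_s, (i+1)*bin_s)`. The
#' default 50 ms bin matches the spikes-per-50-ms rate displays used for
#' MEA raster summaries.
#'
#' @param spikes Spike tibble.
#' @param bin_s Bin width in seconds (> 0).
#' @param duration_s Recording duration; defaults to the last spike's bin.
#' @param by_electrode Count per electrode instead of pooled.
#' @return Tibble with `bin`, `t_mid`, `n` (and `electrode_id` when
#'   `by_electrode`); counts always sum to the number of spikes.
#' @export
rate_histogram <- function(spikes, bin_s = 0.05, duration_s = NULL,
                           by_electrode = FALSE) {
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  n_bins <- if (!is.null(duration_s)) {
    max(1L, ceiling(duration_s / bin_s))
  } else if (nrow(spikes)) {
    floor(max(spikes$time_s) / bin_s) + 1L
  } else 1L
  count_one <- function(times) {
    b <- floor(times / bin_s)
    tabulate(b + 1L, nbins = n_bins)
  }
  grid <- tibble::tibble(
    bin = seq_len(n_bins) - 1L,
    t_mid = (seq_len(n_bins) - 0.5) * bin_s
  )
  if (!by_electrode) {
    grid$n <- count_one(spikes$time_s)
    grid
  } else {
    purrr::map_dfr(sort(unique(spikes$electrode_id)), function(e) {
      g <- grid
      g$electrode_id <- e
      g$n <- count_one(spikes$time_s[spikes$electrode_id == e])
      g
    })
  }
}
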