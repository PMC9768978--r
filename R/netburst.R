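#' Network-burst detection parameters
#'
#' The four thresholds of the 4-step network-burst (NB) detector. The
#' accepted ranges reflect the values used in practice for 16-electrode
#' wells: spikes separated by interspike intervals of 5-15 ms belong to
#' the same candidate; candidates below 50-100 spikes are eliminated;
#' candidates closer than 100-200 ms are combined; and a final NB must
#' contain more than 500-1500 spikes.
#'
#' @param isi_join_s Step 1 join interval, seconds (0.005-0.015).
#' @param min_candidate_spikes Step 2 minimum candidate size (50-100).
#' @param merge_gap_s Step 3 merge gap, seconds (0.1-0.2).
#' @param min_final_spikes Step 4 minimum final size (500-1500).
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(isi_join_s = 0.010, min_candidate_spikes = 50,
                         merge_gap_s = 0.100, min_final_spikes = 500) {
  chk <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi) {
      stop(name, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
    }
    x
  }
  structure(list(
    isi_join_s = chk(isi_join_s, 0.005, 0.015, "isi_join_s"),
    min_candidate_spikes = chk(min_candidate_spikes, 50, 100,
                               "min_candidate_spikes"),
    merge_gap_s = chk(merge_gap_s, 0.1, 0.2, "merge_gap_s"),
    min_final_spikes = chk(min_final_spikes, 500, 1500, "min_final_spikes")
  ), class = "burst_params")
}

#' Four-step network-burst detection
#'
#' Detects network bursts on the spike train pooled across all electrodes
#' of a well:
#' \enumerate{
#'   \item consecutive pooled spikes with gaps `<= isi_join_s` are joined
#'     into candidates;
#'   \item candidates with fewer than `min_candidate_spikes` spikes are
#'     discarded;
#'   \item surviving candidates separated by less than `merge_gap_s` are
#'     combined (pooled spikes falling between them are included);
#'   \item only bursts with more than `min_final_spikes` spikes are kept.
#' }
#' Burst boundaries are the first and last member spike. The peak-rate
#' time `t_peak` and `peak_rate` come from [max_frequency_time()].
#'
#' @param spikes Spike tibble (any electrode labelling; detection pools).
#' @param params A [burst_params()].
#' @param bin_s Bin width used for the peak-rate location (default 50 ms).
#' @return Tibble with one row per NB: `nb_id`, `t_start`, `t_end`,
#'   `n_spikes`, `t_peak`, `peak_rate` (spikes per bin), sorted and
#'   non-overlapping. Empty input gives an empty tibble.
#' @export
detect_network_bursts <- function(spikes, params = burst_params(),
                                  bin_s = 0.05) {
  stopifnot(inherits(params, "burst_params"))
  empty <- tibble::tibble(nb_id = integer(), t_start = numeric(),
                          t_end = numeric(), n_spikes = integer(),
                          t_peak = numeric(), peak_rate = integer())
  t <- sort(spikes$time_s)
  n <- length(t)
  if (n == 0) return(empty)

  # step 1: split where the gap exceeds the join interval
  brk <- which(diff(t) > params$isi_join_s)
  start <- c(1L, brk + 1L)
  end <- c(brk, n)

  # step 2: drop small candidates
  keep <- (end - start + 1L) >= params$min_candidate_spikes
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(empty)

  # step 3: merge candidates closer than the merge gap; spikes between
  # merged candidates are swallowed into the burst
  gap <- t[start[-1]] - t[end[-length(end)]]
  grp <- cumsum(c(1L, as.integer(gap >= params$merge_gap_s)))
  start <- tapply(start, grp, min)
  end <- tapply(end, grp, max)
  n_spk <- as.integer(end - start + 1L)

  # step 4: final size filter (strictly more than min_final_spikes)
  keep <- n_spk > params$min_final_spikes
  start <- start[keep]; end <- end[keep]; n_spk <- n_spk[keep]
  if (!length(start)) return(empty)

  nb <- tibble::tibble(
    nb_id = seq_along(start),
    t_start = t[start],
    t_end = t[end],
    n_spikes = n_spk
  )
  pk <- purrr::map2_dfr(nb$t_start, nb$t_end, function(a, b) {
    max_frequency_time(a, b, t, bin_s = bin_s)
  })
  nb$t_peak <- pk$t_peak
  nb$peak_rate <- pk$peak_rate
  nb
}

#' Time of maximum firing frequency within a burst
#'
#' Bins the pooled spikes of one NB into half-open bins of `bin_s`
#' starting at `t_start` and returns the centre of the maximal bin
#' (earliest bin on ties) and its count.
#'
#' @param t_start,t_end Burst interval in seconds.
#' @param times Pooled spike times (the whole recording is fine; only
#'   times in `[t_start, t_end]` are used, the final boundary inclusive so
#'   the last spike of the burst is counted).
#' @param bin_s Bin width (default 50 ms).
#' @return One-row tibble `t_peak`, `peak_rate`.
#' @export
max_frequency_time <- function(t_start, t_end, times, bin_s = 0.05) {
  tt <- times[times >= t_start & times <= t_end]
  if (!length(tt)) {
    return(tibble::tibble(t_peak = NA_real_, peak_rate = 0L))
  }
  b <- floor((tt - t_start) / bin_s)
  n_bins <- max(b) + 1L
  counts <- tabulate(b + 1L, nbins = n_bins)
  i <- which.max(counts)          # which.max takes the earliest tie
  tibble::tibble(t_peak = t_start + (i - 0.5) * bin_s,
                 peak_rate = counts[i])
}

#' Per-electrode burst onsets
#'
#' The beginning point of each network burst as seen by each electrode:
#' the electrode's first spike inside the pooled burst window that marks
#' sustained firing, i.e. that is followed by another spike from the same
#' electrode within `companion_gap_s`. An isolated stray spike early in
#' the window (background activity) is thereby not mistaken for the
#' electrode's burst onset. Electrodes whose spikes in the burst are all
#' isolated fall back to their first spike; electrodes silent during a
#' burst are absent from that burst's rows.
#'
#' @param nbs NB tibble from [detect_network_bursts()].
#' @param spikes Spike tibble.
#' @param companion_gap_s Maximum gap to the next same-electrode spike
#'   for an onset to count as sustained (default 50 ms).
#' @return Tibble `nb_id`, `electrode_id`, `onset_s`.
#' @export
nb_onsets <- function(nbs, spikes, companion_gap_s = 0.05) {
  sustained_first <- function(t) {
    t <- sort(t)
    if (length(t) >= 2) {
      i <- which(diff(t) <= companion_gap_s)
      if (length(i)) return(t[i[1]])
    }
    t[1]
  }
  purrr::map_dfr(seq_len(nrow(nbs)), function(i) {
    inb <- spikes[spikes$time_s >= nbs$t_start[i] &
                  spikes$time_s <= nbs$t_end[i], ]
    if (!nrow(inb)) return(NULL)
    dplyr::summarise(dplyr::group_by(inb, .data$electrode_id),
                     onset_s = sustained_first(.data$time_s),
                     .groups = "drop") |>
      dplyr::mutate(nb_id = nbs$nb_id[i], .before = 1)
  })
}

#' The ten-parameter burst panel
#'
#' Summarises a recording's bursting into the ten analytical parameters
#' used for dose-response heat maps: total spike count, NB count, mean and
#' CV of NB duration, of spikes per NB, of the maximum frequency (spikes
#' per 50 ms bin at the burst peak), and of the intermaximum frequency
#' interval (IMFI, the interval between the peak-rate times of consecutive
#' NBs). CVs use the sample SD (n - 1). Parameters that need at least two
#' bursts (three for the IMFI CV) are `NaN` below that count.
#'
#' @param spikes Spike tibble (all spikes, in and out of bursts).
#' @param nbs NB tibble from [detect_network_bursts()].
#' @param duration_s Recording duration (> 0).
#' @return One-row tibble with columns `total_spikes`, `n_nb`,
#'   `mean_nb_duration_s`, `mean_spikes_per_nb`, `mean_max_frequency`,
#'   `mean_imfi_s`, `cv_nb_duration`, `cv_spikes_per_nb`,
#'   `cv_max_frequency`, `cv_imfi`.
#' @export
compute_metrics <- function(spikes, nbs, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  cv <- function(x) stats::sd(x) / mean(x)
  n_nb <- nrow(nbs)
  dur <- nbs$t_end - nbs$t_start
  imfi <- if (n_nb >= 2) diff(nbs$t_peak) else numeric(0)
  tibble::tibble(
    total_spikes = nrow(spikes),
    n_nb = n_nb,
    mean_nb_duration_s = if (n_nb >= 1) mean(dur) else NaN,
    mean_spikes_per_nb = if (n_nb >= 1) mean(nbs$n_spikes) else NaN,
    mean_max_frequency = if (n_nb >= 1) mean(nbs$peak_rate) else NaN,
    mean_imfi_s = if (n_nb >= 2) mean(imfi) else NaN,
    cv_nb_duration = if (n_nb >= 2) cv(dur) else NaN,
    cv_spikes_per_nb = if (n_nb >= 2) cv(nbs$n_spikes) else NaN,
    cv_max_frequency = if (n_nb >= 2) cv(nbs$peak_rate) else NaN,
    cv_imfi = if (n_nb >= 3) cv(imfi) else NaN
  )
}

#' Names of the ten burst parameters
#' @return Character vector of the panel column names.
#' @export
burst_metric_names <- function() {
  c("total_spikes", "n_nb", "mean_nb_duration_s", "mean_spikes_per_nb",
    "mean_max_frequency", "mean_imfi_s", "cv_nb_duration",
    "cv_spikes_per_nb", "cv_max_frequency", "cv_imfi")
}

#' Raster plot of spikes with burst shading
#'
#' @param spikes Spike tibble.
#' @param nbs Optional NB tibble; bursts are shaded.
#' @return A ggplot.
#' @export
plot_raster <- function(spikes, nbs = NULL) {
  p <- ggplot2::ggplot(spikes,
    ggplot2::aes(x = .data$time_s, y = factor(.data$electrode_id))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "electrode")
  if (!is.null(nbs) && nrow(nbs)) {
    p <- p + ggplot2::geom_rect(
      data = nbs, inherit.aes = FALSE, alpha = 0.2, fill = "steelblue",
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf))
  }
  p
}
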