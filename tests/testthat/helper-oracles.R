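# Independent brute-force reference implementations used as oracles.
# These are deliberately written as plain nested scans, separate from the
# package's vectorised code paths.

# Reference 4-step network-burst detector: direct scan over the pooled,
# sorted spike list.
ref_network_bursts <- function(times, isi_join, min_cand, merge_gap,
                               min_final) {
  t <- sort(times)
  n <- length(t)
  if (n == 0) return(data.frame(t_start = numeric(), t_end = numeric(),
                                n_spikes = integer()))
  # step 1: chain spikes with gaps <= isi_join
  cand <- list()
  s <- 1
  for (i in seq_len(n)) {
    if (i == n || t[i + 1] - t[i] > isi_join) {
      cand[[length(cand) + 1]] <- c(s, i)
      s <- i + 1
    }
  }
  # step 2: drop candidates below the candidate minimum
  cand <- Filter(function(c) (c[2] - c[1] + 1) >= min_cand, cand)
  if (!length(cand)) return(data.frame(t_start = numeric(),
                                       t_end = numeric(),
                                       n_spikes = integer()))
  # step 3: merge candidates separated by less than the merge gap,
  # absorbing any pooled spikes that lie between them
  merged <- list(cand[[1]])
  for (c in cand[-1]) {
    last <- merged[[length(merged)]]
    if (t[c[1]] - t[last[2]] < merge_gap) {
      merged[[length(merged)]] <- c(last[1], c[2])
    } else {
      merged[[length(merged) + 1]] <- c
    }
  }
  # step 4: strict final size filter
  out <- data.frame(t_start = numeric(), t_end = numeric(),
                    n_spikes = integer())
  for (c in merged) {
    k <- c[2] - c[1] + 1
    if (k > min_final) {
      out <- rbind(out, data.frame(t_start = t[c[1]], t_end = t[c[2]],
                                   n_spikes = as.integer(k)))
    }
  }
  out
}

# Naive sample-by-sample threshold-crossing detector (same contract as
# the package's detector: upward crossings of |v| through thr, dead time
# between accepted crossings, event at the |v| extremum in the alignment
# window after the crossing).
ref_threshold_events <- function(v, thr, dead_n, align_n) {
  n <- length(v)
  idx <- integer(0)
  last <- -Inf
  for (i in 2:n) {
    if (abs(v[i]) >= thr && abs(v[i - 1]) < thr) {
      if (i - last >= dead_n) {
        win <- i:min(n, i + align_n)
        idx <- c(idx, win[which.max(abs(v[win]))])
        last <- i
      }
    }
  }
  idx
}

# Direct trapezoidal evaluation of the Morlet wavelet integral
# W(b, a) = (1/sqrt(a)) * int f(t) G((t - b)/a) dt at selected centres.
# O(N * L) time-domain sum, independent of the FFT path.
ref_cwt_point <- function(x, fs, f_hz, b_idx, f_b = 5, f_c = 1) {
  a <- 1 / f_hz
  dt <- 1 / fs
  tt <- (seq_along(x) - 1) * dt
  vapply(b_idx, function(bi) {
    b <- tt[bi]
    g <- meaburst::morlet((tt - b) / a, f_b, f_c)
    w <- rep(dt, length(x)); w[1] <- dt / 2; w[length(x)] <- dt / 2
    abs(sum(x * g * w) / sqrt(a))
  }, numeric(1))
}

# Closed-form OLS slope/intercept via the normal equations.
ref_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Random spike set with mixed burst-like clumps and background, for the
# oracle-equivalence sweep.
random_spike_set <- function(n_max = 1e4) {
  n_clump <- sample(0:6, 1)
  times <- numeric(0)
  t0 <- 0
  for (i in seq_len(n_clump)) {
    t0 <- t0 + runif(1, 0.05, 2)
    k <- sample(20:1600, 1)
    times <- c(times, t0 + sort(runif(k, 0, runif(1, 0.05, 0.6))))
  }
  n_bg <- sample(0:500, 1)
  times <- c(times, runif(n_bg, 0, max(t0 + 1, 5)))
  sort(times[seq_len(min(length(times), n_max))])
}

# Shared heavyweight fixture: the rendered burst16 pipeline, computed
# once per test run.
burst16_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- meaburst::simulate_preset("burst16", seed = 421)
      rec <- meaburst::highpass(sim$rec, 100)
      spikes <- meaburst::detect_spikes(rec)
      cache <<- list(sim = sim, rec = rec, spikes = spikes)
    }
    cache
  }
})
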