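#' Wavelet analysis parameters
#'
#' Parameters of the complex-Morlet continuous wavelet transform used to
#' quantify the low-frequency (field-potential) components of network
#' bursts. The frequency axis has 181 pixels spanning 0.1-250 Hz; spacing
#' is logarithmic, `f_k = 0.1 * 2500^(k/180)`, the usual scalogram
#' convention for a 3.4-decade band. The time axis is pixelised at 50 us
#' per pixel, i.e. one sample per pixel at the 20 kHz acquisition rate.
#' Scales map to frequency as `f = 1/a`, exact because the Morlet centre
#' frequency is 1.
#'
#' @param f_b Bandwidth parameter of the Morlet envelope (default 5).
#' @param f_c Centre frequency of the Morlet carrier (default 1).
#' @param f_min,f_max Frequency-axis endpoints in Hz (defaults 0.1, 250).
#' @param n_freq Number of frequency pixels (default 181).
#' @param x_pixel_s Time-pixel width in seconds (default 50e-6).
#' @return A list of class `wavelet_params` with the frequency grid in
#'   `$f_grid`.
#' @export
wavelet_params <- function(f_b = 5, f_c = 1, f_min = 0.1, f_max = 250,
                           n_freq = 181, x_pixel_s = 50e-6) {
  stopifnot(f_b > 0, f_c > 0, f_min > 0, f_max > f_min, n_freq >= 2,
            x_pixel_s > 0)
  f_grid <- f_min * (f_max / f_min)^(seq(0, 1, length.out = n_freq))
  f_grid[1] <- f_min; f_grid[n_freq] <- f_max
  structure(list(f_b = f_b, f_c = f_c, f_grid = f_grid,
                 x_pixel_s = x_pixel_s),
            class = "wavelet_params")
}

#' Complex Morlet mother wavelet
#'
#' `G(x) = (1 / sqrt(pi * f_b)) * exp(-x^2 / f_b) * exp(2i * pi * f_c * x)`:
#' a Gaussian envelope of bandwidth `f_b` carrying a complex exponential at
#' centre frequency `f_c`.
#'
#' @param x Evaluation points (numeric).
#' @param f_b,f_c Bandwidth and centre frequency.
#' @return Complex values of the mother wavelet.
#' @export
morlet <- function(x, f_b = 5, f_c = 1) {
  1 / sqrt(pi * f_b) * exp(-x^2 / f_b) * exp(2i * pi * f_c * x)
}

#' Continuous wavelet transform with the complex Morlet wavelet
#'
#' Computes `W(b, a) = (1/sqrt(a)) * integral f(t) G((t - b)/a) dt` on the
#' scale grid `a = 1/f` for every frequency pixel, by sampling the wavelet
#' at the trace's sampling interval and evaluating the convolution with
#' FFTs (dt-weighted discrete approximation of the integral). The wavelet
#' support is truncated at `|x| >= 4*sqrt(f_b)` where the envelope is below
#' `exp(-16)`. Intended for raw (unfiltered) single-channel traces, since
#' the low-frequency content is the object of interest.
#'
#' Rows whose truncated wavelet support exceeds the trace length are
#' edge-dominated; all rows carry a cone-of-influence mask marking the
#' edge-affected columns.
#'
#' @param x Numeric single-channel trace (microvolts).
#' @param fs Sampling rate in Hz.
#' @param params A [wavelet_params()].
#' @return Complex matrix `n_freq x length(x)`, rows ordered as
#'   `params$f_grid`, with attributes `f_grid`, `fs`, `coi` (logical
#'   matrix, `TRUE` where edge-affected) and `edge_dominated` (logical per
#'   row).
#' @export
cwt_morlet <- function(x, fs, params = wavelet_params()) {
  stopifnot(is.numeric(x), fs > 0)
  n <- length(x)
  f_grid <- params$f_grid
  dt <- 1 / fs
  half_x <- 4 * sqrt(params$f_b)          # support of G in wavelet units
  W <- matrix(0i, nrow = length(f_grid), ncol = n)
  coi <- matrix(FALSE, nrow = length(f_grid), ncol = n)
  edge_dom <- logical(length(f_grid))
  if (n == 0) {
    return(structure(W, f_grid = f_grid, fs = fs, coi = coi,
                     edge_dominated = edge_dom))
  }
  for (r in seq_along(f_grid)) {
    a <- 1 / f_grid[r]
    L <- min(ceiling(half_x * a * fs), n - 1L)   # half support, samples
    edge_dom[r] <- ceiling(half_x * a * fs) > (n - 1L)
    # g(u) = G(-u/a) sampled on u = (-L..L) * dt; conv(f, g)(b) = integral
    u <- (-L:L) * dt
    g <- morlet(-u / a, params$f_b, params$f_c)
    P <- stats::nextn(n + 2L * L + 1L, 2)
    fp <- c(x, rep(0, P - n))
    gp <- complex(real = rep(0, P))
    gp[1:(2L * L + 1L)] <- g
    conv <- stats::fft(stats::fft(fp) * stats::fft(gp), inverse = TRUE) / P
    # full convolution index: out[k] = sum_j f[j] g[k - j + 1]; the term
    # aligned with b at sample i is k = i + L
    W[r, ] <- conv[(1:n) + L] * dt / sqrt(a)
    m <- min(L, n)
    if (m > 0) coi[r, c(seq_len(m), n - seq_len(m) + 1L)] <- TRUE
  }
  structure(W, f_grid = f_grid, fs = fs, coi = coi,
            edge_dominated = edge_dom)
}

#' Scalogram pixelisation
#'
#' Collapses `|W|` onto the scalogram pixel grid: 181 frequency rows by
#' `ceil(duration / x_pixel_s)` time pixels, each time pixel the mean of
#' the samples it covers. At 20 kHz and 50 us pixels this is one sample
#' per pixel (the identity in time).
#'
#' @param W Complex matrix from [cwt_morlet()].
#' @param fs Sampling rate of the source trace.
#' @param params The [wavelet_params()] used.
#' @return An object of class `mea_scalogram`: list with `mag`
#'   (n_freq x N_X), `f_grid`, `x_pixel_s`, `duration_s`, `coi` (fraction
#'   of edge-affected samples per pixel) and `edge_dominated`.
#' @export
pixelate <- function(W, fs, params = wavelet_params()) {
  n <- ncol(W)
  spp <- fs * params$x_pixel_s
  if (abs(spp - round(spp)) > 1e-9 || round(spp) < 1) {
    stop("x_pixel_s must be a positive integer multiple of the sampling ",
         "interval (fs * x_pixel_s = ", spp, ")", call. = FALSE)
  }
  spp <- as.integer(round(spp))
  n_x <- ceiling(n / spp)
  pix <- rep(seq_len(n_x), each = spp)[seq_len(n)]
  mag <- abs(W)
  coi <- attr(W, "coi")
  if (spp == 1L) {
    mag_p <- mag
    coi_p <- coi * 1
  } else {
    grp <- factor(pix, levels = seq_len(n_x))
    mag_p <- t(apply(mag, 1, function(row) tapply(row, grp, mean)))
    coi_p <- t(apply(coi * 1, 1, function(row) tapply(row, grp, mean)))
  }
  structure(list(
    mag = unname(as.matrix(mag_p)),
    f_grid = attr(W, "f_grid"),
    x_pixel_s = params$x_pixel_s,
    duration_s = n / fs,
    coi = unname(as.matrix(coi_p)),
    edge_dominated = attr(W, "edge_dominated")
  ), class = "mea_scalogram")
}

#' @export
print.mea_scalogram <- function(x, ...) {
  cat(sprintf("<mea_scalogram> %d x %d pixels, %.3g-%.3g Hz, %.4g s\n",
              nrow(x$mag), ncol(x$mag), min(x$f_grid), max(x$f_grid),
              x$duration_s))
  invisible(x)
}

#' One-call scalogram of a recording channel
#'
#' @param rec A [mea_recording()] (raw, unfiltered).
#' @param electrode_id Which channel to transform.
#' @param params A [wavelet_params()].
#' @return A `mea_scalogram`.
#' @export
scalogram <- function(rec, electrode_id, params = wavelet_params()) {
  i <- match(electrode_id, rec$layout$electrode_id)
  if (is.na(i)) stop("electrode ", electrode_id, " not in layout",
                     call. = FALSE)
  pixelate(cwt_morlet(rec$traces[i, ], rec$fs, params), rec$fs, params)
}

#' Band quantification of a scalogram
#'
#' The per-pixel wavelet coefficient in a frequency band:
#' `WT_A = WT_S / (N_X * N_Y)` where `WT_S` is the sum of `|W|` over the
#' band's frequency rows and all time pixels, `N_X` the number of time
#' pixels and `N_Y` the number of frequency pixels in the band. With
#' `edge_exclude = TRUE` (default) pixels inside the cone of influence are
#' left out of both the sum and the pixel count, so edge transients do not
#' inflate the statistic.
#'
#' @param scal A `mea_scalogram`.
#' @param f_lo,f_hi Band limits in Hz (within the scalogram's grid range).
#' @param edge_exclude Exclude cone-of-influence pixels.
#' @return One-row tibble: `f_lo`, `f_hi`, `n_x`, `n_y`, `n_pixels_used`,
#'   `wt_s`, `wt_a`.
#' @export
band_quant <- function(scal, f_lo = NULL, f_hi = NULL, edge_exclude = TRUE) {
  stopifnot(inherits(scal, "mea_scalogram"))
  if (is.null(f_lo)) f_lo <- min(scal$f_grid)
  if (is.null(f_hi)) f_hi <- max(scal$f_grid)
  if (!(f_lo < f_hi)) stop("need f_lo < f_hi", call. = FALSE)
  rows <- which(scal$f_grid >= f_lo & scal$f_grid <= f_hi)
  if (!length(rows)) stop("empty frequency band [", f_lo, ", ", f_hi, "] Hz",
                          call. = FALSE)
  mag <- scal$mag[rows, , drop = FALSE]
  n_x <- ncol(mag); n_y <- length(rows)
  if (edge_exclude) {
    w <- 1 - scal$coi[rows, , drop = FALSE]   # usable fraction per pixel
    used <- sum(w)
    if (used == 0) {
      warning("entire band is edge-dominated; falling back to all pixels")
      w <- matrix(1, n_y, n_x); used <- n_x * n_y
    }
    wt_s <- sum(mag * w)
    wt_a <- wt_s / used
  } else {
    used <- n_x * n_y
    wt_s <- sum(mag)
    wt_a <- wt_s / (n_x * n_y)
  }
  tibble::tibble(f_lo = f_lo, f_hi = f_hi, n_x = n_x, n_y = n_y,
                 n_pixels_used = used, wt_s = wt_s, wt_a = wt_a)
}

#' Percent change of the band statistic between two scalogram quantifications
#'
#' Signed change `100 * (post - pre) / pre` of `WT_A`, the statistic used
#' to express drug- or stimulation-induced growth of the low-frequency
#' component relative to baseline. The post/pre ratio is also returned.
#'
#' @param pre,post One-row tibbles from [band_quant()] over the same band.
#' @return One-row tibble `percent_change`, `ratio`.
#' @export
band_change_percent <- function(pre, post) {
  if (!isTRUE(all.equal(c(pre$f_lo, pre$f_hi), c(post$f_lo, post$f_hi)))) {
    stop("pre and post quantifications use different bands", call. = FALSE)
  }
  if (pre$wt_a == 0) stop("undefined baseline: WT_A of pre is 0",
                          call. = FALSE)
  tibble::tibble(percent_change = 100 * (post$wt_a - pre$wt_a) / pre$wt_a,
                 ratio = post$wt_a / pre$wt_a)
}

#' @export
autoplot.mea_scalogram <- function(object, trans = "sqrt", ...) {
  d <- tidyr::expand_grid(
    row = seq_along(object$f_grid),
    col = seq_len(ncol(object$mag))
  )
  d$f_hz <- object$f_grid[d$row]
  d$time_s <- (d$col - 0.5) * object$x_pixel_s
  d$mag <- as.vector(t(object$mag))[(d$row - 1) * ncol(object$mag) + d$col]
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$f_hz,
                                  fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "|W|") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}
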