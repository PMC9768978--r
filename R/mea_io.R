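#' Electrode layouts
#'
#' An electrode layout is a tibble with columns `electrode_id` (integer,
#' unique), `x_um` and `y_um` (positions in micrometres, origin at the
#' bottom-left corner of the chip). `mea_layout()` validates a user-supplied
#' table; `grid_layout()` builds a regular rectangular grid numbered
#' row-major from the bottom-left.
#'
#' @param electrode_id Integer electrode labels (unique).
#' @param x_um,y_um Electrode positions in micrometres (finite).
#' @return A tibble with columns `electrode_id`, `x_um`, `y_um`.
#' @examples
#' grid_layout(4, 4, pitch_um = 450)
#' @export
mea_layout <- function(electrode_id, x_um, y_um) {
  electrode_id <- as.integer(electrode_id)
  if (length(electrode_id) < 1L) {
    stop("a layout needs at least one electrode", call. = FALSE)
  }
  if (anyDuplicated(electrode_id)) {
    stop("electrode ids must be unique", call. = FALSE)
  }
  if (!all(is.finite(x_um)) || !all(is.finite(y_um))) {
    stop("electrode positions must be finite", call. = FALSE)
  }
  if (length(x_um) != length(electrode_id) ||
      length(y_um) != length(electrode_id)) {
    stop("electrode_id, x_um and y_um must have equal length", call. = FALSE)
  }
  tibble::tibble(
    electrode_id = electrode_id,
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um)
  )
}

#' @rdname mea_layout
#' @param nrow,ncol Grid dimensions.
#' @param pitch_um Inter-electrode pitch in micrometres.
#' @param origin Numeric length-2, position of electrode 1 (bottom-left).
#' @export
grid_layout <- function(nrow, ncol, pitch_um, origin = c(0, 0)) {
  stopifnot(nrow >= 1, ncol >= 1, pitch_um > 0)
  ids <- seq_len(nrow * ncol)
  row <- (ids - 1L) %/% ncol   # 0-based row, bottom row first
  col <- (ids - 1L) %% ncol
  mea_layout(ids, origin[1] + col * pitch_um, origin[2] + row * pitch_um)
}

#' Euclidean distance between two electrodes
#'
#' @param layout A layout tibble (see [mea_layout()]).
#' @param id_a,id_b Electrode ids present in `layout`.
#' @return Distance in micrometres.
#' @export
electrode_distance <- function(layout, id_a, id_b) {
  a <- match(id_a, layout$electrode_id)
  b <- match(id_b, layout$electrode_id)
  if (is.na(a) || is.na(b)) {
    stop("electrode id not found in layout: ",
         paste(c(id_a, id_b)[c(is.na(a), is.na(b))], collapse = ", "),
         call. = FALSE)
  }
  sqrt((layout$x_um[a] - layout$x_um[b])^2 +
       (layout$y_um[a] - layout$y_um[b])^2)
}

#' @rdname mea_layout
#' @param path File path of a tab-separated layout
#'   (`electrode_id`, `x_um`, `y_um`).
#' @export
read_layout <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    electrode_id = readr::col_integer(),
    x_um = readr::col_double(),
    y_um = readr::col_double()
  ))
  mea_layout(d$electrode_id, d$x_um, d$y_um)
}

#' @rdname mea_layout
#' @param layout A layout tibble.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(layout, path)
  invisible(path)
}

#' Multichannel extracellular recording
#'
#' A recording holds the raw voltage traces as an `n_channels x n_samples`
#' matrix in microvolts, the sampling rate (default 20 kHz, the acquisition
#' rate of the MEA systems this package targets), the electrode layout, and
#' the start time. The `filters` field tags filtering already applied, so
#' downstream stages can assert their preconditions.
#'
#' @param traces Numeric matrix, channels in rows, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param layout Electrode layout; row i of `traces` is
#'   `layout$electrode_id[i]`.
#' @param t0 Start time in seconds.
#' @param filters Character vector of filter tags (e.g. `"hp100"`).
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(traces, fs = 20000, layout = NULL, t0 = 0,
                          filters = character()) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  if (is.null(layout)) layout <- mea_layout(seq_len(nrow(traces)),
                                            rep(0, nrow(traces)),
                                            seq_len(nrow(traces)))
  if (nrow(traces) != nrow(layout)) {
    stop("channel count (", nrow(traces), ") does not match layout size (",
         nrow(layout), ")", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  structure(
    list(traces = traces, fs = fs, layout = layout, t0 = t0,
         filters = filters),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %d channels x %d samples @ %g Hz (%.3f s)%s\n",
    nrow(x$traces), ncol(x$traces), x$fs, rec_duration(x),
    if (length(x$filters)) paste0(" [", paste(x$filters, collapse = ","), "]")
    else " [raw]"
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `mea_recording`.
#' @export
rec_duration <- function(rec) ncol(rec$traces) / rec$fs

#' Read and write raw recordings
#'
#' Traces are stored as a little-endian float32 raw matrix, channel-major
#' (all samples of channel 1, then channel 2, ...), with a JSON sidecar
#' `<name>.json` holding `fs_hz`, `unit`, `channel_ids`, `t0_s`, `filters`
#' and the layout file name. `write_recording()` also writes
#' `<name>.layout.tsv`.
#'
#' @param rec A `mea_recording`.
#' @param path Path of the `.f32` payload (sidecar paths are derived).
#' @return `read_recording()` returns a `mea_recording`; round trips are
#'   exact at float32 precision.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  base <- sub("\\.f32$", "", path)
  layout_file <- paste0(basename(base), ".layout.tsv")
  write_layout(rec$layout, file.path(dirname(path), layout_file))
  sidecar <- list(
    fs_hz = rec$fs, unit = "uV",
    channel_ids = rec$layout$electrode_id,
    t0_s = rec$t0, filters = rec$filters,
    layout_file = layout_file,
    n_samples = ncol(rec$traces)
  )
  jsonlite::write_json(sidecar, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  # channel-major: row i of traces is contiguous on disk
  writeBin(as.vector(t(rec$traces)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  base <- sub("\\.f32$", "", path)
  sidecar_path <- paste0(base, ".json")
  if (!file.exists(path)) stop("recording not found: ", path, call. = FALSE)
  if (!file.exists(sidecar_path)) {
    stop("missing JSON sidecar: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (k in c("fs_hz", "channel_ids", "n_samples")) {
    if (is.null(meta[[k]])) stop("sidecar lacks field '", k, "'", call. = FALSE)
  }
  if (!is.numeric(meta$fs_hz) || meta$fs_hz <= 0) {
    stop("sidecar fs_hz must be positive", call. = FALSE)
  }
  n_ch <- length(meta$channel_ids)
  n_s <- meta$n_samples
  raw <- readBin(path, what = "numeric", n = n_ch * n_s + 1L,
                 size = 4L, endian = "little")
  if (length(raw) != n_ch * n_s) {
    stop("trace size (", length(raw), " samples) inconsistent with sidecar (",
         n_ch, " channels x ", n_s, " samples)", call. = FALSE)
  }
  layout <- read_layout(file.path(dirname(path), meta$layout_file))
  if (!identical(sort(layout$electrode_id), sort(as.integer(meta$channel_ids)))) {
    stop("sidecar channel_ids disagree with layout file", call. = FALSE)
  }
  layout <- layout[match(meta$channel_ids, layout$electrode_id), ]
  mea_recording(matrix(raw, nrow = n_ch, byrow = TRUE),
                fs = as.numeric(meta$fs_hz),
                layout = layout, t0 = meta$t0_s %||% 0,
                filters = as.character(unlist(meta$filters)))
}

#' Spike event tables
#'
#' Spike events are plain tibbles with columns `electrode_id` (integer),
#' `time_s` and `amplitude_uV` (signed extremum). On disk they are TSV with
#' the same header. Events are kept sorted by electrode then time (stable
#' within ties).
#'
#' @param path TSV path.
#' @param layout Optional layout; if given, unknown electrode ids error.
#' @return A spike tibble.
#' @export
read_events <- function(path, layout = NULL) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    electrode_id = readr::col_integer(),
    time_s = readr::col_double(),
    amplitude_uV = readr::col_double()
  ))
  validate_spikes(d, layout)
}

#' @rdname read_events
#' @param spikes A spike tibble.
#' @export
write_events <- function(spikes, path) {
  readr::write_tsv(validate_spikes(spikes), path)
  invisible(path)
}

#' @rdname read_events
#' @param spikes A spike tibble to validate and sort.
#' @export
validate_spikes <- function(spikes, layout = NULL) {
  need <- c("electrode_id", "time_s", "amplitude_uV")
  if (!all(need %in% names(spikes))) {
    stop("spike table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(spikes) > 0) {
    if (any(spikes$time_s < 0) || any(!is.finite(spikes$time_s))) {
      stop("spike times must be finite and non-negative", call. = FALSE)
    }
    if (any(!is.finite(spikes$amplitude_uV))) {
      stop("spike amplitudes must be finite", call. = FALSE)
    }
    if (!is.null(layout) &&
        !all(spikes$electrode_id %in% layout$electrode_id)) {
      bad <- setdiff(unique(spikes$electrode_id), layout$electrode_id)
      stop("unknown electrode id(s) in events: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  # stable sort: electrode, then time; ties keep file order
  spikes <- tibble::as_tibble(spikes)
  ord <- order(spikes$electrode_id, spikes$time_s, method = "radix")
  spikes[ord, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
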