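#' Uniformly sampled continuous signal
#'
#' A `Trace` holds a regularly sampled signal (LFP, membrane potential, raw
#' extracellular voltage, phase speed, ...) together with its sampling rate,
#' units and start time. Sample `i` (1-based) covers the half-open time bin
#' `[t0 + (i-1)/fs, t0 + i/fs)`; this convention is used throughout when
#' assigning spikes to samples or states.
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling rate in Hz (> 0).
#' @param units character, e.g. `"mV"`, `"uV"`, `"a.u."`, `"deg/s"`.
#' @param t0 start time of the first sample, in seconds.
#' @return An object of class `"updown_trace"`.
#' @examples
#' tr <- trace(sin(2 * pi * 2 * seq(0, 1, by = 1e-3)), fs = 1000)
#' trace_duration(tr)
#' @export
trace <- function(samples, fs, units = "a.u.", t0 = 0) {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0, length(samples) >= 1L)
  structure(
    list(samples = samples, fs = fs, units = units, t0 = t0),
    class = "updown_trace"
  )
}

#' @export
print.updown_trace <- function(x, ...) {
  cat(sprintf(
    "<Trace> %d samples @ %g Hz [%s], t0 = %g s, duration = %g s\n",
    length(x$samples), x$fs, x$units, x$t0, trace_duration(x)
  ))
  invisible(x)
}

#' Trace time axis and duration
#'
#' @param x a [trace()] object.
#' @return `trace_times()` returns the time of each sample (seconds);
#'   `trace_duration()` the total covered duration `n/fs`.
#' @export
trace_times <- function(x) {
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' @rdname trace_times
#' @export
trace_duration <- function(x) length(x$samples) / x$fs

#' Map times to sample indices (nearest-sample)
#' @noRd
time_to_index <- function(x, t) {
  round((t - x$t0) * x$fs) + 1L
}

#' Spike train of a single cell
#'
#' @param times strictly increasing spike times in seconds.
#' @param cell_label label such as `"PV"`, `"SST"` or `"MUA"`.
#' @return An object of class `"updown_spikes"`.
#' @export
spike_train <- function(times, cell_label = "cell") {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("spike times must be strictly increasing")
  }
  structure(list(times = times, cell_label = cell_label),
            class = "updown_spikes")
}

#' @export
print.updown_spikes <- function(x, ...) {
  cat(sprintf("<SpikeTrain> '%s', %d spikes", x$cell_label, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}

#' State segmentation of a recording
#'
#' An ordered, non-overlapping set of labelled intervals (`up`, `down`,
#' `indeterminate`) covering a recording. Constructed from a data frame with
#' columns `onset`, `offset`, `label`.
#'
#' @param intervals data frame with numeric `onset`, `offset` (seconds) and
#'   character `label` in `c("up", "down", "indeterminate")`.
#' @return An object of class `"updown_segmentation"` (a data frame).
#' @export
segmentation <- function(intervals) {
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("onset", "offset", "label") %in% names(intervals)))
  intervals$label <- as.character(intervals$label)
  bad <- setdiff(unique(intervals$label), c("up", "down", "indeterminate"))
  if (length(bad)) stop("unknown state labels: ", paste(bad, collapse = ", "))
  if (any(intervals$offset <= intervals$onset)) {
    stop("all intervals must have offset > onset")
  }
  o <- order(intervals$onset)
  intervals <- intervals[o, , drop = FALSE]
  if (nrow(intervals) > 1 &&
      any(intervals$onset[-1] < intervals$offset[-nrow(intervals)] - 1e-9)) {
    stop("intervals must be non-overlapping")
  }
  rownames(intervals) <- NULL
  class(intervals) <- c("updown_segmentation", "data.frame")
  intervals
}

#' @export
print.updown_segmentation <- function(x, ...) {
  tab <- table(factor(x$label, c("up", "down", "indeterminate")))
  cat(sprintf(
    "<StateSegmentation> %d intervals (%d up, %d down, %d indeterminate), span [%g, %g] s\n",
    nrow(x), tab[["up"]], tab[["down"]], tab[["indeterminate"]],
    min(x$onset), max(x$offset)
  ))
  invisible(x)
}

#' Per-sample state labels of a segmentation
#'
#' Expands a segmentation to one label per sample of a reference trace, using
#' the half-open sample convention.
#'
#' @param states a [segmentation()].
#' @param ref a [trace()] giving the time base, or a list with `fs`, `t0`
#'   and `samples`.
#' @return character vector of labels, one per sample.
#' @export
states_to_labels <- function(states, ref) {
  tt <- trace_times(ref)
  lab <- rep("indeterminate", length(tt))
  idx <- findInterval(tt, states$onset)
  ok <- idx >= 1 & idx <= nrow(states)
  inside <- ok
  inside[ok] <- tt[ok] < states$offset[idx[ok]] + 1e-12
  lab[inside] <- states$label[idx[inside]]
  lab
}

#' Build a segmentation from per-sample labels
#'
#' Inverse of [states_to_labels()]: run-length encodes per-sample labels into
#' contiguous intervals.
#'
#' @param labels character vector of per-sample labels.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @return a [segmentation()].
#' @export
labels_to_states <- function(labels, fs, t0 = 0) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segmentation(data.frame(
    onset = t0 + (starts - 1) / fs,
    offset = t0 + ends / fs,
    label = r$values
  ))
}

#' Assign spikes to the interval containing them
#'
#' @param spikes a [spike_train()].
#' @param states a [segmentation()].
#' @return integer vector: for each spike, the row index of the containing
#'   interval in `states` (NA if outside the segmentation span). Containment
#'   uses the half-open convention `onset <= t < offset`.
#' @export
spikes_to_intervals <- function(spikes, states) {
  idx <- findInterval(spikes$times, states$onset)
  idx[idx < 1] <- NA_integer_
  ok <- !is.na(idx)
  ok[ok] <- spikes$times[!is.na(idx)] < states$offset[idx[!is.na(idx)]]
  idx[!ok] <- NA_integer_
  idx
}

# ---- file I/O -------------------------------------------------------------

#' Read and write traces, spike trains and segmentations
#'
#' Traces are stored as two-column CSV/TSV files (`time,value`); spike trains
#' as one time per line (or a one-column CSV); segmentations as CSV with
#' columns `onset,offset,label`. Values round-trip losslessly to better than
#' 1e-9 relative precision (times/values are written with 15 significant
#' digits).
#'
#' @param x object to write.
#' @param path file path. Files ending in `.tsv` are tab-separated.
#' @param units,cell_label metadata to attach on read.
#' @return the read object, or (for writers) `path` invisibly.
#' @name trace_io
NULL

.sep_for <- function(path) if (grepl("\\.tsv$", path)) "\t" else ","

#' @rdname trace_io
#' @export
write_trace <- function(x, path) {
  df <- data.frame(time = format(trace_times(x), digits = 15, trim = TRUE),
                   value = format(x$samples, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace <- function(path, units = "a.u.") {
  df <- utils::read.table(path, sep = .sep_for(path), header = TRUE)
  tt <- df[[1]]
  if (length(tt) < 2) stop("trace file must contain at least two samples")
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("trace file is not uniformly sampled")
  }
  trace(df[[2]], fs = 1 / stats::median(dt), units = units, t0 = tt[1])
}

#' @rdname trace_io
#' @export
write_spike_train <- function(x, path) {
  writeLines(format(x$times, digits = 15, trim = TRUE), path)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_spike_train <- function(path, cell_label = "cell") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1])))) {
    lines <- lines[-1]  # header line
  }
  spike_train(as.numeric(lines), cell_label = cell_label)
}

#' @rdname trace_io
#' @export
write_segmentation <- function(x, path) {
  df <- data.frame(onset = format(x$onset, digits = 15, trim = TRUE),
                   offset = format(x$offset, digits = 15, trim = TRUE),
                   label = x$label)
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_segmentation <- function(path) {
  df <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                          stringsAsFactors = FALSE)
  segmentation(df)
}

# Run code with a temporarily seeded RNG, restoring global RNG state after.
# @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
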