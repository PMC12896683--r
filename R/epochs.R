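# Epoch container: trials x sensors x samples array with a uniform time axis
# and a sidecar trial table. Time 0 s marks placeholder onset, 1.5 s marks
# search onset by convention.

#' Construct an epoch set
#'
#' Bundles a `trials x sensors x samples` data array with its time axis,
#' sampling rate and trial table, and validates the container invariants:
#' the time axis is strictly increasing with spacing `1/sfreq`, its length
#' matches the third array dimension, the trial table has one row per trial,
#' and whenever the epoch spans the conventional event times (0 s placeholder
#' onset, 1.5 s search onset) a sample lies within half a sample of each.
#'
#' @param data numeric array, trials x sensors x samples.
#' @param times numeric vector of sample times in seconds.
#' @param sfreq sampling rate in Hz (default 200).
#' @param trial_table trial table with one row per trial.
#' @param t_placeholder,t_search conventional event times (s).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq = 200, trial_table,
                      t_placeholder = 0, t_search = 1.5) {
  .assert(is.array(data) && length(dim(data)) == 3,
          "data must be a 3-d array (trials x sensors x samples)")
  .assert(length(times) == dim(data)[3],
          "length(times) must equal the number of samples")
  .assert(all(diff(times) > 0), "times must be strictly increasing")
  dt <- 1 / sfreq
  .assert(all(abs(diff(times) - dt) < dt * 1e-4),
          "times spacing inconsistent with sfreq")
  .assert(nrow(trial_table) == dim(data)[1],
          "trial table must have one row per trial")
  validate_trial_table(trial_table)
  for (ev in c(t_placeholder, t_search)) {
    if (min(times) <= ev && ev <= max(times)) {
      .assert(min(abs(times - ev)) <= dt / 2 + 1e-9,
              sprintf("no sample within half a sample of event time %g s", ev))
    }
  }
  structure(list(data = data, times = as.numeric(times), sfreq = sfreq,
                 trial_table = trial_table,
                 t_placeholder = t_placeholder, t_search = t_search),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d sensors x %d samples @ %g Hz, span [%g, %g] s\n",
              d[1], d[2], d[3], x$sfreq, x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials  <- function(x) dim(x$data)[1]
n_sensors <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

# subset trials, keeping the table in step
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$sfreq,
            epochs$trial_table[idx, , drop = FALSE],
            epochs$t_placeholder, epochs$t_search)
}

#' Restrict an epoch set to a half-open time interval
#'
#' Keeps the samples with `t0 <= t < t1`. Intervals are half-open so that
#' sample counts are unambiguous: slicing `[0, 1.5)` at 200 Hz keeps exactly
#' 300 samples. Labels and trials are untouched.
#'
#' @param epochs an `epoch_set`.
#' @param t0,t1 interval bounds in seconds, `t0 < t1`.
#' @return an `epoch_set` restricted to the interval.
#' @export
slice_time <- function(epochs, t0, t1) {
  .assert(t0 < t1, "t0 must be < t1")
  tol <- 1e-6 / epochs$sfreq
  idx <- which(epochs$times >= t0 - tol & epochs$times < t1 - tol)
  .assert(length(idx) > 0, "time slice selects no samples")
  epoch_set(epochs$data[, , idx, drop = FALSE], epochs$times[idx],
            epochs$sfreq, epochs$trial_table,
            epochs$t_placeholder, epochs$t_search)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and sensor, the mean over the half-open baseline
#' window `[b0, b1)`. After correction the baseline-window mean is zero to
#' numerical precision.
#'
#' @param epochs an `epoch_set`.
#' @param b0,b1 baseline window bounds in seconds; must lie within the epoch.
#' @return a baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, b0, b1) {
  .assert(b0 < b1, "b0 must be < b1")
  dt <- 1 / epochs$sfreq
  tol <- 1e-6 * dt
  .assert(b0 >= epochs$times[1] - tol &&
            b1 <= epochs$times[length(epochs$times)] + dt + tol,
          "baseline window outside epoch span")
  idx <- which(epochs$times >= b0 - tol & epochs$times < b1 - tol)
  .assert(length(idx) > 0, "baseline window selects no samples")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- epochs$data - as.vector(bl) # recycles over the sample dimension
  epoch_set(out, epochs$times, epochs$sfreq, epochs$trial_table,
            epochs$t_placeholder, epochs$t_search)
}

# ---------------------------------------------------------------------------
# On-disk container. A directory with named components mirroring a
# hierarchical array file:
#   meta.json        format version, dims, sfreq, event-time conventions
#   data.bin         float64 little-endian, column-major, dims in meta
#   times.bin        float64 little-endian
#   trial_table.csv  the trial table, "NA" for missing
# Writes are deterministic: the same epoch_set always produces byte-identical
# payload files.

#' Write / read an epoch set on disk
#'
#' `write_epochs` validates the container invariants and writes the
#' documented directory layout (see Details); `read_epochs` reads it back.
#' The pair is a lossless inverse: the data array round-trips bit-exactly and
#' the trial table losslessly.
#'
#' @details The on-disk container is a directory holding `meta.json` (format
#'   version, array dims, `sfreq`, event-time conventions), `data.bin` and
#'   `times.bin` (float64, little-endian, column-major) and
#'   `trial_table.csv`.
#'
#' @param epochs an `epoch_set`.
#' @param path directory path for the container.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  .assert(inherits(epochs, "epoch_set"), "not an epoch_set")
  # re-validate invariants before touching the disk
  epochs <- epoch_set(epochs$data, epochs$times, epochs$sfreq,
                      epochs$trial_table, epochs$t_placeholder, epochs$t_search)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(path), paste("cannot create directory:", path))
  meta <- list(format = "megmvpa-epochs", version = 1L,
               dims = dim(epochs$data), dim_order = c("trial", "sensor", "sample"),
               sfreq = epochs$sfreq,
               t_placeholder = epochs$t_placeholder, t_search = epochs$t_search,
               dtype = "float64", endian = "little")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  close(con)
  con <- file(file.path(path, "times.bin"), "wb")
  writeBin(epochs$times, con, size = 8, endian = "little")
  close(con)
  write_trial_table(epochs$trial_table, file.path(path, "trial_table.csv"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  .assert(dir.exists(path), paste("no such epoch container:", path))
  for (f in c("meta.json", "data.bin", "times.bin", "trial_table.csv")) {
    .assert(file.exists(file.path(path, f)),
            paste("epoch container missing component:", f))
  }
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  .assert(identical(meta$format, "megmvpa-epochs"), "unrecognized container format")
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(file.path(path, "data.bin"), "rb")
  dat <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
  close(con)
  .assert(length(dat) == n, "data.bin size inconsistent with dims")
  con <- file(file.path(path, "times.bin"), "rb")
  times <- readBin(con, "double", n = dims[3] + 1, size = 8, endian = "little")
  close(con)
  .assert(length(times) == dims[3], "times length inconsistent with sample count")
  tab <- read_trial_table(file.path(path, "trial_table.csv"))
  epoch_set(array(dat, dims), times, meta$sfreq, tab,
            meta$t_placeholder, meta$t_search)
}
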