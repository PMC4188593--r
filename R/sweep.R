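# Sweep containers.  A Sweep is one uniformly sampled trace (signal +
# stimulus + clamp mode + metadata); a SweepSet is an ordered collection of
# sweeps sharing a protocol and cell.

#' Construct a single sweep
#'
#' @param signal Sampled recording: membrane potential (mV) in current clamp,
#'   membrane current (pA) in voltage clamp.
#' @param stimulus Sampled stimulus (pA in current clamp, mV command or
#'   stimulator units in voltage clamp); same length as `signal`.
#' @param sampling_khz Sampling rate (kHz).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param cell_id Cell identifier.
#' @param group_label Treatment-group label (e.g. `"vehicle"`, `"mk801"`).
#' @param meta List of protocol metadata (step onset/duration/amplitude,
#'   holding potential, pulse times, ...).
#' @param conditions List of condition tags (`Mg_mM`, `drug`, `tags`,
#'   `label`).
#' @return Object of class `fsi_sweep`.
#' @export
new_sweep <- function(signal, stimulus, sampling_khz, mode, cell_id = "cell",
                      group_label = "custom", meta = list(),
                      conditions = list()) {
  if (length(signal) != length(stimulus))
    fsi_error("signal and stimulus must have the same length", "invalid_sweep")
  if (!is_scalar_number(sampling_khz) || sampling_khz <= 0)
    fsi_error("sampling_rate must be > 0", "invalid_sweep")
  if (!mode %in% c("current_clamp", "voltage_clamp"))
    fsi_error("mode must be current_clamp or voltage_clamp", "invalid_sweep")
  structure(
    list(signal = as.numeric(signal), stimulus = as.numeric(stimulus),
         sampling_khz = sampling_khz, mode = mode, cell_id = cell_id,
         group_label = group_label, meta = meta, conditions = conditions),
    class = "fsi_sweep")
}

#' Sample times of a sweep
#' @param sweep An `fsi_sweep`.
#' @return Times in ms, starting at 0.
#' @export
sweep_time <- function(sweep) {
  (seq_along(sweep$signal) - 1) / sweep$sampling_khz
}

#' Construct a sweep set
#'
#' @param sweeps List of `fsi_sweep` objects with identical sampling rate and
#'   mode.
#' @param protocol The shared `fsi_protocol` (or `NULL`).
#' @param cell_id Cell identifier.
#' @param group_label Treatment-group label.
#' @return Object of class `fsi_sweep_set`.
#' @export
new_sweep_set <- function(sweeps, protocol = NULL, cell_id = "cell",
                          group_label = "custom") {
  if (length(sweeps) == 0)
    fsi_error("a sweep set needs at least one sweep", "invalid_sweep")
  rates <- vapply(sweeps, function(s) s$sampling_khz, numeric(1))
  modes <- vapply(sweeps, function(s) s$mode, character(1))
  if (length(unique(rates)) != 1 || length(unique(modes)) != 1)
    fsi_error("all sweeps in a set must share sampling rate and mode",
              "invalid_sweep")
  if (!is.null(protocol) && identical(protocol$mode, "current_clamp") &&
      length(protocol$amplitudes) != length(sweeps))
    fsi_error("protocol amplitude list length must equal sweep count",
              "invalid_sweep")
  structure(list(sweeps = sweeps, protocol = protocol, cell_id = cell_id,
                 group_label = group_label),
            class = "fsi_sweep_set")
}

#' @export
length.fsi_sweep_set <- function(x) length(x$sweeps)

#' @export
`[[.fsi_sweep_set` <- function(x, i) x$sweeps[[i]]

#' @export
print.fsi_sweep <- function(x, ...) {
  cat(sprintf("<fsi_sweep> %s, %s, %d samples @ %g kHz (%.1f ms)\n",
              x$cell_id, x$mode, length(x$signal), x$sampling_khz,
              length(x$signal) / x$sampling_khz))
  invisible(x)
}

#' @export
print.fsi_sweep_set <- function(x, ...) {
  cat(sprintf("<fsi_sweep_set> cell %s (%s): %d sweeps, %s\n",
              x$cell_id, x$group_label, length(x$sweeps),
              x$sweeps[[1]]$mode))
  invisible(x)
}

#' @noRd
assert_mode <- function(sweep, mode) {
  if (!identical(sweep$mode, mode))
    fsi_error(sprintf("expected a %s sweep, got %s", mode, sweep$mode),
              "wrong_mode")
  invisible(sweep)
}
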