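#' @noRd
fsi_error <- function(message, class, call = sys.call(-1), data = list()) {
  cond <- structure(
    class = c(paste0("fsiephys_", class), "fsiephys_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral; thin wrapper kept so the integration rule is fixed in
# one place.
#' @noRd
trapz_q <- function(t, y) pracma::trapz(t, y)

# Robust per-sample noise SD from first differences of a trace.
#' @noRd
noise_sd_diff <- function(x) stats::mad(diff(x)) / sqrt(2)

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
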