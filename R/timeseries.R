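#' Uniformly sampled multi-channel time series
#'
#' The basic signal container used throughout the package: a strictly
#' increasing time vector `t` (seconds), a numeric matrix of channel values
#' (one column per named channel), and the sampling rate `fs` in Hz.
#' Spacing of `t` must be consistent with `fs` to within 1e-6 s.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param values Numeric matrix (or data.frame) with one column per channel;
#'   column names are the channel names. A plain vector is accepted for a
#'   single channel.
#' @param fs Sampling rate in Hz.
#' @param channel Channel name used when `values` is a bare vector.
#' @return An object of class `promet_ts` with fields `t`, `values`, `fs`.
#' @examples
#' ts <- promet_ts(seq(0, 1, by = 1 / 120), sin(seq(0, 1, by = 1 / 120)), 120)
#' ts_duration(ts)
#' @export
promet_ts <- function(t, values, fs, channel = "value") {
  if (is.null(dim(values))) {
    values <- matrix(as.numeric(values), ncol = 1,
                     dimnames = list(NULL, channel))
  } else {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
  }
  x <- structure(list(t = as.numeric(t), values = values, fs = as.numeric(fs)),
                 class = "promet_ts")
  validate_ts(x)
  x
}

#' @rdname promet_ts
#' @param x Object to validate.
#' @export
validate_ts <- function(x) {
  stopifnot(inherits(x, "promet_ts"))
  n <- length(x$t)
  if (n == 0L) stop_promet("empty_series", "time series has no samples")
  if (nrow(x$values) != n) {
    stop_promet("length_mismatch",
                "channel length (%d) differs from time base (%d)",
                nrow(x$values), n)
  }
  if (n > 1L) {
    dt <- diff(x$t)
    if (any(dt <= 0)) {
      stop_promet("nonmonotonic_time", "time vector is not strictly increasing")
    }
    if (any(abs(dt - 1 / x$fs) > 1e-6)) {
      stop_promet("sampling_rate_mismatch",
                  "sample spacing inconsistent with fs = %g Hz (max deviation %.3g s)",
                  x$fs, max(abs(dt - 1 / x$fs)))
    }
  }
  invisible(x)
}

#' @export
print.promet_ts <- function(x, ...) {
  cat(sprintf("<promet_ts> %d samples @ %g Hz, %.3f s, channels: %s\n",
              length(x$t), x$fs, ts_duration(x),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' @rdname promet_ts
#' @export
ts_duration <- function(x) {
  if (length(x$t) < 2L) return(0)
  x$t[length(x$t)] - x$t[1L]
}

#' Extract one channel of a time series as a numeric vector
#' @param x A `promet_ts`.
#' @param channel Channel name.
#' @return Numeric vector.
#' @export
ts_channel <- function(x, channel) {
  if (!channel %in% colnames(x$values)) {
    stop_promet("missing_channel", "channel '%s' not present (have: %s)",
                channel, paste(colnames(x$values), collapse = ", "))
  }
  x$values[, channel]
}

#' Restrict a time series to a time window
#' @param x A `promet_ts`.
#' @param start_s,end_s Window bounds in trial seconds (inclusive).
#' @return A `promet_ts` containing the samples with `start_s <= t <= end_s`.
#' @export
ts_window <- function(x, start_s, end_s) {
  keep <- x$t >= start_s - 1e-9 & x$t <= end_s + 1e-9
  if (!any(keep)) stop_promet("empty_window", "no samples in [%g, %g]", start_s, end_s)
  structure(list(t = x$t[keep], values = x$values[keep, , drop = FALSE], fs = x$fs),
            class = "promet_ts")
}

# Named condition objects so callers can distinguish validation failures.
stop_promet <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(paste0("promet_", code), "promet_error",
                              "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

warn_promet <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(paste0("promet_", code), "promet_warning",
                              "warning", "condition"),
                    list(message = msg, call = sys.call(-1)))
  warning(cond)
}
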