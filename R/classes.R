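#' Construct an LFP recording
#'
#' A recording is one continuous multichannel LFP session: a numeric matrix
#' (samples x channels) with sampling-rate and study metadata attached.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels, one per column.
#' @param state State label, one of `"naive"`, `"mild"`, `"moderate"` (or any
#'   label used consistently across the study).
#' @param session_id Session identifier string.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs, channels = colnames(data),
                          state = NA_character_, session_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("recording data must be numeric")
  if (any(!is.finite(data))) stop("recording data contains NaN/Inf")
  if (ncol(data) < 2L) stop("a recording needs at least 2 channels")
  if (is.null(channels)) stop("channel labels are required")
  if (length(channels) != ncol(data))
    stop("channel count (", ncol(data), ") != label count (",
         length(channels), ")")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  colnames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         state = state, session_id = session_id),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  state: %s  session: %s\n", x$state, x$session_id))
  invisible(x)
}

# internal: make a segment (a fixed-duration analysis trial cut from a
# recording); inherits the recording fields.
lfp_segment <- function(data, fs, channels, state, session_id,
                        index, duration) {
  seg <- lfp_recording(data, fs, channels, state, session_id)
  seg$parent_session <- session_id
  seg$index <- index
  seg$duration <- duration
  class(seg) <- c("lfp_segment", "lfp_recording")
  seg
}

#' @export
print.lfp_segment <- function(x, ...) {
  cat(sprintf(
    "<lfp_segment> #%d of session %s (%s): %d samples x %d ch @ %g Hz\n",
    x$index, x$parent_session, x$state, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# coerce matrix-or-recording-or-segment input to a plain data matrix
as_data_matrix <- function(x) {
  if (inherits(x, "lfp_recording")) x$data else as.matrix(x)
}
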