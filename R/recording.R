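#' The three breathing conditions
#'
#' Condition labels in their fixed order: `baseline` (relaxed nose/mouth
#' breathing), `loaded` (breathing against a resistance trainer, emulating
#' dyspnea) and `rapid_shallow` (25 breaths/min, emulating tachypnea).
#' This order is used everywhere a class order matters (confusion matrices,
#' reports, class indices).
#'
#' @return character vector of the three condition names.
#' @export
breathing_conditions <- function() c("baseline", "loaded", "rapid_shallow")

#' NIRS channel names
#'
#' The four device outputs.  Only `O2Hb` (oxygenated haemoglobin) and `HHb`
#' (deoxygenated haemoglobin) may be fed to a classifier; `THb` (their sum)
#' and `TSI` (their ratio) are derived quantities and are excluded by design
#' from model input.
#'
#' @return character vector of channel names.
#' @export
nirs_channels <- function() c("O2Hb", "HHb", "THb", "TSI")

#' Construct a NIRS recording
#'
#' One participant-condition time series: equal-length per-channel sample
#' sequences at a fixed sampling rate, plus a subject identifier and the
#' condition label.
#'
#' @param channels named list of equal-length numeric vectors; names must be
#'   a subset of [nirs_channels()].
#' @param condition one of [breathing_conditions()].
#' @param subject_id opaque subject identifier.
#' @param sampling_rate sampling rate in Hz (default 10).
#' @return an object of class `"nirs_recording"`.
#' @export
nirs_recording <- function(channels, condition, subject_id = "S01",
                           sampling_rate = 10) {
  condition <- match.arg(condition, breathing_conditions())
  if (!is.list(channels) || length(channels) == 0L)
    stop("at least one channel is required")
  bad <- setdiff(names(channels), nirs_channels())
  if (length(bad) || is.null(names(channels)))
    stop("unknown channel name(s): ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L)
    stop("all channel sequences must share one length; got ",
         paste(paste0(names(channels), "=", lens), collapse = ", "))
  if (!all(vapply(channels, is.numeric, logical(1L))))
    stop("channel sequences must be numeric")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  structure(list(channels = lapply(channels, as.numeric),
                 condition = condition,
                 subject_id = as.character(subject_id),
                 sampling_rate = sampling_rate),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf("NIRS recording: subject %s, condition %s\n", x$subject_id,
              x$condition))
  cat(sprintf("  %d samples at %g Hz (%.1f s), channels: %s\n", n,
              x$sampling_rate, n / x$sampling_rate,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
length.nirs_recording <- function(x) length(x$channels[[1L]])

# ---- window sets -----------------------------------------------------------

# internal constructor: x is n x channels x length
new_nirs_windows <- function(x, channels, label, subject_id, source_offset,
                             sampling_rate, normalized = FALSE) {
  stopifnot(length(dim(x)) == 3L, dim(x)[2L] == length(channels))
  label <- factor(as.character(label), levels = breathing_conditions())
  structure(list(x = x, channels = channels, label = label,
                 subject_id = as.character(subject_id),
                 source_offset = as.integer(source_offset),
                 sampling_rate = sampling_rate,
                 normalized = normalized),
            class = "nirs_windows")
}

#' @export
print.nirs_windows <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("%d NIRS window(s), %d channel(s) x %d samples (%s)\n",
              d[1L], d[2L], d[3L], paste(x$channels, collapse = ", ")))
  tb <- table(x$label)
  cat("  per condition: ",
      paste(paste0(names(tb), "=", as.integer(tb)), collapse = ", "), "\n")
  cat("  subjects:", length(unique(x$subject_id)),
      if (x$normalized) " (per-window zero-mean normalized)" else "", "\n")
  invisible(x)
}

#' @export
length.nirs_windows <- function(x) dim(x$x)[1L]

#' @export
`[.nirs_windows` <- function(x, i, ...) {
  new_nirs_windows(x$x[i, , , drop = FALSE], x$channels, x$label[i],
                   x$subject_id[i], x$source_offset[i], x$sampling_rate,
                   x$normalized)
}

# row-bind a list of nirs_windows with identical channel sets
bind_windows <- function(ws) {
  stopifnot(length(ws) >= 1L)
  ch <- ws[[1L]]$channels
  for (w in ws) stopifnot(identical(w$channels, ch))
  new_nirs_windows(
    x = do.call(abind3, lapply(ws, function(w) w$x)),
    channels = ch,
    label = unlist(lapply(ws, function(w) as.character(w$label))),
    subject_id = unlist(lapply(ws, function(w) w$subject_id)),
    source_offset = unlist(lapply(ws, function(w) w$source_offset)),
    sampling_rate = ws[[1L]]$sampling_rate,
    normalized = ws[[1L]]$normalized)
}

# bind 3D arrays along the first margin
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  n <- sum(vapply(xs, function(a) dim(a)[1L], integer(1L)))
  out <- array(NA_real_, c(n, d[2L], d[3L]))
  at <- 0L
  for (a in xs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
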