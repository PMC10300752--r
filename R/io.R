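#' Read a NIRS recording from a delimited text file
#'
#' Expects one sample per row with a header naming the channels
#' (comma-delimited by default).  A time column, if present, is ignored:
#' the sampling rate is metadata.  Non-numeric or missing cells are an
#' error naming the offending row and column — they are never silently
#' filled.
#'
#' An optional JSON exclusion mask (a list of `{"start": i, "end": j}`
#' 1-based inclusive sample ranges) removes artifact-bearing stretches;
#' the remaining samples are concatenated.  No automatic artifact
#' detection is performed.
#'
#' @param path CSV file path.
#' @param condition condition label of this recording, one of
#'   [breathing_conditions()].
#' @param subject_id subject identifier.
#' @param channel_map optional named character vector mapping canonical
#'   channel names to the column names in the file, e.g.
#'   `c(O2Hb = "oxy", HHb = "deoxy")`.  By default any columns already named
#'   as in [nirs_channels()] are taken.
#' @param sampling_rate sampling rate in Hz.
#' @param exclusion_mask path to a JSON mask file, or an equivalent list of
#'   `list(start =, end =)` ranges, or `NULL`.
#' @param sep field separator.
#' @return a [nirs_recording()].
#' @export
read_nirs_recording <- function(path, condition, subject_id = "S01",
                                channel_map = NULL, sampling_rate = 10,
                                exclusion_mask = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (nrow(df) == 0L) stop("no sample rows in ", path)
  if (is.null(channel_map)) {
    present <- intersect(nirs_channels(), names(df))
    if (!length(present))
      stop("no recognised channel columns in ", path,
           "; supply channel_map")
    channel_map <- stats::setNames(present, present)
  }
  missing_cols <- setdiff(unname(channel_map), names(df))
  if (length(missing_cols))
    stop("declared column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  channels <- list()
  for (canon in names(channel_map)) {
    raw <- df[[channel_map[[canon]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   raw[bad[1L]], bad[1L], channel_map[[canon]], path))
    channels[[canon]] <- val
  }
  if (!is.null(exclusion_mask)) {
    mask <- if (is.character(exclusion_mask))
      jsonlite::fromJSON(exclusion_mask, simplifyDataFrame = FALSE)
    else exclusion_mask
    drop <- unique(unlist(lapply(mask, function(r) {
      stopifnot(!is.null(r$start), !is.null(r$end))
      seq.int(r$start, r$end)
    })))
    n <- length(channels[[1L]])
    drop <- drop[drop >= 1L & drop <= n]
    if (length(drop))
      channels <- lapply(channels, function(v) v[-drop])
    if (!length(channels[[1L]]))
      stop("exclusion mask removed every sample of ", path)
  }
  nirs_recording(channels, condition, subject_id, sampling_rate)
}

#' Write a recording as CSV in the package dialect
#'
#' One sample per row, header row with channel names, comma-delimited,
#' with a leading `time` column in seconds.
#'
#' @param recording a [nirs_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nirs_recording <- function(recording, path) {
  stopifnot(inherits(recording, "nirs_recording"))
  n <- length(recording)
  df <- data.frame(time = (seq_len(n) - 1L) / recording$sampling_rate)
  for (ch in names(recording$channels)) df[[ch]] <- recording$channels[[ch]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Crop a recording into fixed-length windows
#'
#' Windows are taken left to right at the given stride; a trailing remainder
#' shorter than `window_len` is discarded, so a recording of length L yields
#' `floor(L / window_len)` windows at the default non-overlapping stride.
#' The study's unit is a 64-sample (6.4 s at 10 Hz) window.  Each window
#' inherits the recording's condition label and subject id and records its
#' 1-based start offset.
#'
#' @param recording a [nirs_recording()].
#' @param window_len window length in samples (default 64).
#' @param stride hop between window starts in samples; defaults to
#'   `window_len` (non-overlapping).
#' @return a window set of class `"nirs_windows"` (possibly empty).
#' @export
crop_windows <- function(recording, window_len = 64L, stride = window_len) {
  stopifnot(inherits(recording, "nirs_recording"))
  window_len <- as.integer(window_len)
  stride <- as.integer(stride)
  if (window_len < 1L || stride < 1L)
    stop("window_len and stride must be >= 1")
  n <- length(recording)
  starts <- seq.int(1L, by = stride,
                    length.out = max(0L, (n - window_len) %/% stride + 1L))
  chn <- names(recording$channels)
  x <- array(NA_real_, c(length(starts), length(chn), window_len))
  for (ci in seq_along(chn)) {
    v <- recording$channels[[ci]]
    for (wi in seq_along(starts))
      x[wi, ci, ] <- v[starts[wi] + 0:(window_len - 1L)]
  }
  if (any(!is.finite(x))) stop("non-finite sample values in recording")
  new_nirs_windows(x, chn,
                   label = rep(recording$condition, length(starts)),
                   subject_id = rep(recording$subject_id, length(starts)),
                   source_offset = starts,
                   sampling_rate = recording$sampling_rate)
}

#' Select model input channels
#'
#' Restricts a window set to the requested channels in the fixed order
#' O2Hb first, HHb second.  Only O2Hb and HHb are admissible model inputs:
#' THb and TSI are deterministic functions of the two and are excluded by
#' design.
#'
#' @param windows a `"nirs_windows"` set.
#' @param channels subset of `c("O2Hb", "HHb")`.
#' @return the window set restricted to `channels`.
#' @export
select_channels <- function(windows, channels) {
  stopifnot(inherits(windows, "nirs_windows"))
  banned <- intersect(channels, c("THb", "TSI"))
  if (length(banned))
    stop("channel(s) ", paste(banned, collapse = ", "),
         " are excluded by design as model inputs (derived from O2Hb/HHb)")
  unknown <- setdiff(channels, nirs_channels())
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(channels, windows$channels)
  if (length(absent))
    stop("channel(s) not present in windows: ",
         paste(absent, collapse = ", "))
  ord <- intersect(c("O2Hb", "HHb"), channels)   # fixed documented order
  sel <- match(ord, windows$channels)
  new_nirs_windows(windows$x[, sel, , drop = FALSE], ord, windows$label,
                   windows$subject_id, windows$source_offset,
                   windows$sampling_rate, windows$normalized)
}

#' Per-window zero-mean normalization
#'
#' Subtracts each window's per-channel mean, removing the slow hemodynamic
#' offset while preserving oscillation amplitude.  This is the default
#' input scaling of the classifier and is recorded in the fitted object.
#'
#' @param windows a `"nirs_windows"` set.
#' @return the normalized window set (flagged `normalized`).
#' @export
normalize_windows <- function(windows) {
  stopifnot(inherits(windows, "nirs_windows"))
  if (windows$normalized) return(windows)
  mu <- apply(windows$x, c(1L, 2L), mean)
  x <- windows$x - as.vector(mu)          # (n, C, L) minus (n, C) recycled
  new_nirs_windows(x, windows$channels, windows$label, windows$subject_id,
                   windows$source_offset, windows$sampling_rate,
                   normalized = TRUE)
}

#' Train/test split specification
#'
#' @param train_fraction fraction of windows (or subjects) assigned to the
#'   training side, strictly between 0 and 1; default 0.8 (the 80:20
#'   protocol).
#' @param mode `"stratified_random"` draws windows within each class with a
#'   per-class training count of `ceiling(train_fraction * class size)`;
#'   `"subject_level"` assigns whole subjects (`ceiling` of the subject
#'   count, e.g. 17 of 21 at 0.8) so no subject appears on both sides.
#' @param seed integer seed; identical seeds give identical splits.
#' @return an object of class `"split_spec"`.
#' @export
split_spec <- function(train_fraction = 0.8,
                       mode = c("stratified_random", "subject_level"),
                       seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  structure(list(train_fraction = train_fraction, mode = mode, seed = seed),
            class = "split_spec")
}

#' Split a window set into train and test sides
#'
#' The two sides are disjoint and their union is the input.  Stratified
#' mode reproduces the published per-class 80:20 counts (e.g. class sizes
#' 531/780/874 give 425/624/700 training windows); subject-level mode keeps
#' every subject wholly on one side.
#'
#' @param windows a `"nirs_windows"` set with labels (and subject ids for
#'   subject-level mode).
#' @param spec a [split_spec()].
#' @return list with `"nirs_windows"` elements `train` and `test`.
#' @export
split_windows <- function(windows, spec = split_spec()) {
  stopifnot(inherits(windows, "nirs_windows"), inherits(spec, "split_spec"))
  if (anyNA(windows$label)) stop("every window must be labeled")
  n <- length(windows)
  with_seed(spec$seed, {
    if (spec$mode == "stratified_random") {
      train_idx <- integer(0)
      for (cl in levels(droplevels(windows$label))) {
        ix <- which(windows$label == cl)
        n_tr <- as.integer(ceiling(spec$train_fraction * length(ix)))
        if (n_tr < 1L || n_tr >= length(ix))
          stop("class '", cl, "' has too few windows (", length(ix),
               ") to populate both sides at train_fraction ",
               spec$train_fraction)
        train_idx <- c(train_idx, sample(ix, n_tr))
      }
    } else {
      subjects <- unique(windows$subject_id)
      n_tr_s <- as.integer(ceiling(spec$train_fraction * length(subjects)))
      if (n_tr_s < 1L || n_tr_s >= length(subjects))
        stop("too few subjects (", length(subjects),
             ") to populate both sides at train_fraction ",
             spec$train_fraction)
      train_subj <- sample(subjects, n_tr_s)
      train_idx <- which(windows$subject_id %in% train_subj)
    }
    train_idx <- sort(train_idx)
    list(train = windows[train_idx],
         test = windows[setdiff(seq_len(n), train_idx)])
  })
}

#' Save / load a windowed dataset container
#'
#' Writes the window array together with labels, subject ids, offsets and
#' (optionally) split membership as one native serialized file.
#'
#' @param object a `"nirs_windows"` set or a `list(train =, test =)` split.
#' @param path file path (conventionally `.rds`).
#' @return `path` invisibly for the writer; the object for the reader.
#' @export
write_windows <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readRDS(path)
}
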