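#' @title Wearable-sensor recordings: activities, channels and storage format
#'
#' @description
#' Recordings follow the layout of public wearable-gait databases such as
#' HuGaDB: one tab-separated file per recording with optional `#`-prefixed
#' metadata lines, a header row of channel names, and one row per frame with
#' a trailing integer activity column named `act`. Inertial channels
#' (3-axis accelerometer + 3-axis gyroscope per body site) are stored as
#' int16 counts; the two EMG channels as uint8 counts.
#'
#' Body sites are coded `rf`/`lf` (feet), `rs`/`ls` (shins), `rt`/`lt`
#' (thighs); channels are named like `acc_rt_x` or `gyro_ls_z`, plus
#' `EMG_r` and `EMG_l`.
#'
#' @name hugadb-format
NULL

# Activity vocabulary, in the conventional table order of the dataset.
ACTIVITY_LEVELS <- c(
  "walking", "running", "going_up", "going_down",
  "sitting", "sitting_down", "standing_up", "standing"
)

# Activities during which gait inference runs (the "moving" superset plus
# static standing, which the gait model also sees).
GAIT_ACTIVITIES <- c("walking", "running", "going_up", "going_down", "standing")
MOVING_ACTIVITIES <- c("walking", "running", "going_up", "going_down")

INT16_MIN <- -32768L
INT16_MAX <- 32767L
UINT8_MAX <- 255L

# Accelerometer: +/-2 g at 16384 LSB/g; gyroscope: +/-2000 deg/s at
# 16.4 LSB/(deg/s). Used to convert scaled [-1,1] values back to physical
# units and by the synthetic sensor model for quantization.
ACC_LSB_PER_G <- 16384
GYRO_LSB_PER_DPS <- 16.4

#' Channel name vocabulary
#'
#' All channel names a recording may contain: `{acc,gyro} x {rf,rs,rt,lf,ls,lt}
#' x {x,y,z}` plus the two EMG channels.
#'
#' @return Character vector of the 38 canonical channel names.
#' @export
channel_vocabulary <- function() {
  inertial <- as.vector(outer(
    as.vector(outer(c("acc", "gyro"), c("rf", "rs", "rt", "lf", "ls", "lt"),
                    paste, sep = "_")),
    c("x", "y", "z"), paste, sep = "_"))
  c(sort(inertial), "EMG_r", "EMG_l")
}

#' Activity label codes
#'
#' Integer codes 1..8 in the standard activity-table order
#' (walking, running, going_up, going_down, sitting, sitting_down,
#' standing_up, standing); 0 means unlabeled.
#'
#' @return Named integer vector mapping activity name to code.
#' @export
activity_codes <- function() {
  stats::setNames(seq_along(ACTIVITY_LEVELS), ACTIVITY_LEVELS)
}

#' Activity names for label codes
#'
#' @param code Integer label code(s); values outside 1..8 give
#'   `"unlabeled"`.
#' @return Character vector of activity names.
#' @export
activity_name <- function(code) {
  out <- rep("unlabeled", length(code))
  ok <- code >= 1L & code <= length(ACTIVITY_LEVELS)
  out[ok] <- ACTIVITY_LEVELS[code[ok]]
  out
}

is_emg_channel <- function(name) startsWith(name, "EMG")

#' Construct a raw recording
#'
#' @param channels Named list of equal-length integer-valued vectors; names
#'   must come from [channel_vocabulary()]. Inertial channels in
#'   \[-32768, 32767\], EMG in \[0, 255\].
#' @param labels Integer per-frame activity codes (0 = unlabeled, 1..8 per
#'   [activity_codes()]).
#' @param fs Sampling rate in Hz (nominal 56.35).
#' @param participant_id Identifier string.
#' @param metadata Named character list of free-form metadata.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(channels, labels, fs = 56.35,
                          participant_id = "unknown", metadata = list()) {
  assert_that(is.list(channels) && length(channels) > 0L,
              "channels must be a non-empty named list")
  vocab <- channel_vocabulary()
  bad <- setdiff(names(channels), vocab)
  assert_that(length(bad) == 0L, "unknown channel name(s): %s",
              paste(bad, collapse = ", "))
  lens <- vapply(channels, length, integer(1))
  assert_that(length(unique(c(lens, length(labels)))) == 1L,
              "all channel series and the label series must have equal length")
  assert_that(is.numeric(fs) && length(fs) == 1L && fs > 0,
              "fs must be a positive number")
  structure(
    list(channels = lapply(channels, as.numeric),
         labels = as.integer(labels), fs = fs,
         participant_id = as.character(participant_id),
         metadata = metadata),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> participant %s: %d frames @ %.2f Hz, %d channels\n",
              x$participant_id, length(x$labels), x$fs, length(x$channels)))
  invisible(x)
}

#' @export
length.raw_recording <- function(x) length(x$labels)

#' @export
print.scaled_recording <- function(x, ...) {
  cat(sprintf("<scaled_recording> participant %s: %d frames @ %.2f Hz, %d channels\n",
              x$participant_id, length(x$labels), x$fs, length(x$channels)))
  invisible(x)
}

#' @export
length.scaled_recording <- function(x) length(x$labels)

#' Read a recording from a HuGaDB-style tab-separated file
#'
#' The dialect: optional leading `#` metadata lines (`# key=value`), one
#' tab-separated header row of channel names ending in `act`, then one row
#' per frame. Columns with names outside the channel vocabulary are dropped
#' with a warning.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param column_map Optional named character vector mapping external column
#'   names to canonical ones (see [read_column_map()]).
#' @param participant_id Identifier; defaults to the `participant` metadata
#'   entry when present, else the file name.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, fs = 56.35, column_map = NULL,
                           participant_id = NULL) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) > 0L, "empty file: %s", path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ml in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      meta[[trimws(key)]] <- trimws(sub("^[^=]*=", "", kv))
    }
  }
  body_idx <- which(!is_meta & nzchar(trimws(lines)))
  assert_that(length(body_idx) >= 1L, "no header row in %s", path)
  header_line <- body_idx[1L]
  header <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1L]]
  if (!is.null(column_map)) {
    hit <- header %in% names(column_map)
    header[hit] <- unname(column_map[header[hit]])
  }
  assert_that("act" %in% header, "header must contain an 'act' column (%s)", path)
  vocab <- channel_vocabulary()
  unknown <- setdiff(header, c(vocab, "act"))
  if (length(unknown) > 0L)
    warning(sprintf("ignoring unknown column(s) in %s: %s",
                    path, paste(unknown, collapse = ", ")), call. = FALSE)

  data_idx <- body_idx[body_idx > header_line]
  ncol_exp <- length(header)
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  lens <- lengths(fields)
  if (any(lens != ncol_exp)) {
    bad <- which(lens != ncol_exp)[1L]
    stop_gi("parse error in %s line %d: expected %d fields, found %d",
            path, data_idx[bad], ncol_exp, lens[bad])
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1L] / ncol_exp)
    stop_gi("parse error in %s line %d: non-numeric field",
            path, data_idx[bad_row])
  }
  m <- matrix(vals, ncol = ncol_exp, byrow = TRUE)
  colnames(m) <- header
  keep <- intersect(header, vocab)
  channels <- lapply(keep, function(ch) m[, ch])
  names(channels) <- keep
  if (is.null(participant_id))
    participant_id <- meta[["participant"]] %||% basename(path)
  fs_file <- suppressWarnings(as.numeric(meta[["fs"]] %||% NA))
  if (!is.na(fs_file)) fs <- fs_file
  raw_recording(channels, labels = as.integer(m[, "act"]), fs = fs,
                participant_id = participant_id, metadata = meta)
}

#' Write a recording to a HuGaDB-style tab-separated file
#'
#' Emits the dialect of [read_recording()]: `#` metadata lines (including
#' `participant` and `fs`), a header row, and integer-formatted frame rows
#' with the label in a final `act` column. Reading the file back reproduces
#' the numeric content exactly.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  meta <- rec$metadata
  meta[["participant"]] <- rec$participant_id
  meta[["fs"]] <- format(rec$fs, digits = 15)
  hdr <- c(sprintf("# %s=%s", names(meta), unlist(meta)),
           paste(c(names(rec$channels), "act"), collapse = "\t"))
  n <- length(rec$labels)
  if (n == 0L) {
    body <- character(0)
  } else {
    cols <- c(lapply(rec$channels, function(x) formatC(x, format = "d")),
              list(formatC(rec$labels, format = "d")))
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a column-name mapping file
#'
#' Plain `external=canonical` lines (INI style, `#` comments allowed), used
#' to adapt externally named columns to the canonical channel vocabulary.
#'
#' @param path File path.
#' @return Named character vector (names = external, values = canonical).
#' @export
read_column_map <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & grepl("=", lines, fixed = TRUE)]
  ext <- trimws(sub("=.*$", "", lines))
  canon <- trimws(sub("^[^=]*=", "", lines))
  bad <- setdiff(canon, channel_vocabulary())
  assert_that(length(bad) == 0L,
              "column map targets outside the channel vocabulary: %s",
              paste(bad, collapse = ", "))
  stats::setNames(canon, ext)
}

#' Scale integer sensor counts to the unit range
#'
#' Inertial (int16) channels are divided by 32768; EMG (uint8) channels are
#' midpoint-centered, `(v - 127.5) / 127.5`. Both maps are monotone and send
#' the storage-range endpoints to -1/+1 (inertial max 32767 maps just below
#' 1). Labels and sampling rate are unchanged.
#'
#' @param rec A [raw_recording()].
#' @return Object of class `scaled_recording` with values in \[-1, 1\].
#' @export
scale_raw <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  out <- rec
  for (ch in names(rec$channels)) {
    v <- rec$channels[[ch]]
    if (is_emg_channel(ch)) {
      bad <- which(v < 0 | v > UINT8_MAX)
      if (length(bad) > 0L)
        stop_gi("channel %s frame %d outside uint8 range [0, 255]: %g",
                ch, bad[1L], v[bad[1L]])
      out$channels[[ch]] <- (v - 127.5) / 127.5
    } else {
      bad <- which(v < INT16_MIN | v > INT16_MAX)
      if (length(bad) > 0L)
        stop_gi("channel %s frame %d outside int16 range [-32768, 32767]: %g",
                ch, bad[1L], v[bad[1L]])
      out$channels[[ch]] <- v / 32768
    }
  }
  class(out) <- "scaled_recording"
  out
}

#' Screen a recording for corrupted signals
#'
#' Flags channels in which at least `saturation_frac` of samples are pinned
#' at the storage-range extremes (overflow trimming, as seen in corrupted
#' gyroscope traces of public datasets), and label codes outside the
#' activity vocabulary. The recording is never modified.
#'
#' @param rec A [raw_recording()].
#' @param saturation_frac Fraction of saturated samples that triggers a
#'   saturation issue (default 0.01).
#' @return Data frame of issues with columns `type`, `where`, `detail`
#'   (zero rows when clean).
#' @export
validate_recording <- function(rec, saturation_frac = 0.01) {
  stopifnot(inherits(rec, "raw_recording"))
  issues <- list()
  n <- length(rec$labels)
  for (ch in names(rec$channels)) {
    v <- rec$channels[[ch]]
    sat <- if (is_emg_channel(ch)) v <= 0 | v >= UINT8_MAX
           else v <= INT16_MIN | v >= INT16_MAX
    frac <- if (n > 0L) mean(sat) else 0
    if (frac >= saturation_frac)
      issues[[length(issues) + 1L]] <- data.frame(
        type = "saturation", where = ch,
        detail = sprintf("%.1f%% of samples at storage-range extremes",
                         100 * frac))
  }
  bad_lab <- setdiff(unique(rec$labels), c(0L, seq_along(ACTIVITY_LEVELS)))
  for (bl in bad_lab)
    issues[[length(issues) + 1L]] <- data.frame(
      type = "unknown_label", where = "act",
      detail = sprintf("label code %d outside the activity vocabulary", bl))
  if (length(issues) == 0L)
    return(data.frame(type = character(0), where = character(0),
                      detail = character(0)))
  do.call(rbind, issues)
}
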