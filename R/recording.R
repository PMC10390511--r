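#' Construct a multi-channel EEG recording
#'
#' The basic container of the package: a channels x samples matrix in
#' microvolts plus sampling rate, channel labels, task-state tag and
#' participant id.
#'
#' @param data numeric matrix, channels x samples (µV).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param state task-state tag, one of `"rest_open"`, `"rest_closed"`,
#'   `"count_easy"`, `"count_hard"`, `"other"`.
#' @param participant_id participant identifier string.
#' @return an object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(500), 2), fs = 250,
#'                      channel_labels = c("Fz", "Cz"))
#' rec
new_recording <- function(data, fs, channel_labels,
                          state = "other", participant_id = "anon") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length (", length(channel_labels),
         ") != channel count (", nrow(data), ")")
  }
  state <- match.arg(state, c("rest_open", "rest_closed",
                              "count_easy", "count_hard", "other"))
  if (anyNA(data)) stop("recording contains NA samples")
  dimnames(data) <- list(channel_labels, NULL)
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 state = state,
                 participant_id = as.character(participant_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2),
      " s), state=", x$state, ", participant=", x$participant_id,
      "\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

# ---------------------------------------------------------------------------
# plain-text recording container
#
# One TSV file: '#' lines hold a JSON metadata object, then one row per
# channel with %.17g formatting, which round-trips IEEE doubles exactly.

#' Write a recording to the package's plain-text container
#'
#' The container is a TSV file whose first line is a `#`-prefixed JSON
#' object (fs, channel labels, state, participant id), followed by one row
#' per channel formatted with 17 significant digits so that
#' `read_recording(write_recording(x))` reproduces `x` bit-exactly.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path (conventionally `.eegtsv`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  meta <- jsonlite::toJSON(list(fs = rec$fs,
                                channel_labels = rec$channel_labels,
                                state = rec$state,
                                participant_id = rec$participant_id),
                           auto_unbox = TRUE, digits = NA)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", meta), con)
  lines <- apply(rec$data, 1, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a recording from the package's plain-text container
#' @param path file written by [write_recording()].
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "#")) {
    stop("not a recording container (missing '#' metadata line): ", path)
  }
  meta <- jsonlite::fromJSON(sub("^#", "", lines[[1]]))
  body <- lines[!startsWith(lines, "#")]
  data <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  new_recording(data, fs = as.numeric(meta$fs),
                channel_labels = meta$channel_labels,
                state = meta$state, participant_id = meta$participant_id)
}

# ---------------------------------------------------------------------------
# BrainVision (.vhdr/.eeg/.vmrk) -- read-only, plus a fixture writer

.bv_parse_header <- function(lines) {
  section <- ""
  kv <- list()
  for (l in lines) {
    l <- sub(";.*$", "", l)
    l <- trimws(l)
    if (!nzchar(l)) next
    if (grepl("^\\[.*\\]$", l)) {
      section <- gsub("\\[|\\]", "", l)
      kv[[section]] <- list()
    } else if (grepl("=", l, fixed = TRUE) && nzchar(section)) {
      eq <- regexpr("=", l, fixed = TRUE)
      key <- trimws(substr(l, 1, eq - 1))
      kv[[section]][[key]] <- trimws(substr(l, eq + 1, nchar(l)))
    }
  }
  kv
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr`/`.eeg`/`.vmrk` triplet produced by BrainVision
#' recorders. Binary formats `INT_16` and `IEEE_FLOAT_32` in multiplexed
#' orientation are supported; data are returned in µV (resolution applied).
#'
#' @param header_path path to the `.vhdr` header file.
#' @param state,participant_id tags attached to the returned recording
#'   (BrainVision files do not carry them).
#' @return an `eeg_recording` with labels in header order.
#' @export
read_brainvision <- function(header_path, state = "other",
                             participant_id = "anon") {
  if (!file.exists(header_path)) stop("missing header file: ", header_path)
  hdr <- .bv_parse_header(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", header_path)
  if (!is.null(ci$DataFormat) && toupper(ci$DataFormat) != "BINARY") {
    stop("unsupported BrainVision data format: ", ci$DataFormat)
  }
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED") {
    stop("unsupported data orientation: ", orient)
  }
  n_ch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # interval is in µs
  fmt <- toupper(bi$BinaryFormat %||% "INT_16")

  chans <- hdr[["Channel Infos"]]
  labels <- character(n_ch)
  resolution <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chans[[sprintf("Ch%d", i)]]
    if (is.null(entry)) stop("header missing Ch", i, " entry")
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
      resolution[i] <- as.numeric(parts[3])
    }
  }

  dir <- dirname(header_path)
  eeg_path <- file.path(dir, ci$DataFile)
  vmrk <- ci$MarkerFile
  if (!is.null(vmrk) && !file.exists(file.path(dir, vmrk))) {
    stop("missing companion marker file: ", vmrk)
  }
  if (!file.exists(eeg_path)) stop("missing companion data file: ", eeg_path)

  sz <- file.size(eeg_path)
  bytes_per <- switch(fmt, INT_16 = 2L, IEEE_FLOAT_32 = 4L,
                      stop("unsupported binary encoding: ", fmt))
  n_total <- sz %/% bytes_per
  if (sz %% (bytes_per * n_ch) != 0) {
    stop("truncated .eeg file: ", sz, " bytes is not a multiple of ",
         bytes_per * n_ch, " (", bytes_per, " bytes x ", n_ch,
         " channels); ", (bytes_per * n_ch) - sz %% (bytes_per * n_ch),
         " bytes short of a full sample frame")
  }
  con <- file(eeg_path, open = "rb")
  on.exit(close(con))
  raw <- if (fmt == "INT_16") {
    readBin(con, "integer", n = n_total, size = 2L, signed = TRUE,
            endian = "little")
  } else {
    readBin(con, "double", n = n_total, size = 4L, endian = "little")
  }
  m <- matrix(as.numeric(raw), nrow = n_ch)  # multiplexed: channels fastest
  m <- m * resolution
  new_recording(m, fs = fs, channel_labels = labels,
                state = state, participant_id = participant_id)
}

#' Write a BrainVision fixture triplet
#'
#' Test/demo helper producing a minimal, self-consistent
#' `.vhdr`/`.eeg`/`.vmrk` triplet readable by [read_brainvision()].
#' `IEEE_FLOAT_32` storage is lossy for arbitrary doubles; data that are
#' exactly representable in single precision round-trip exactly.
#'
#' @param rec an `eeg_recording`.
#' @param stem output path stem (files `<stem>.vhdr` etc. are written).
#' @param format `"IEEE_FLOAT_32"` (default) or `"INT_16"` (resolution
#'   0.1 µV/bit).
#' @return path of the written header, invisibly.
#' @export
write_brainvision <- function(rec, stem, format = "IEEE_FLOAT_32") {
  format <- match.arg(format, c("IEEE_FLOAT_32", "INT_16"))
  base <- basename(stem)
  hdr_path <- paste0(stem, ".vhdr")
  n_ch <- nrow(rec$data)
  res <- if (format == "INT_16") 0.1 else 1
  ch_lines <- sprintf("Ch%d=%s,,%g", seq_len(n_ch), rec$channel_labels, res)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "[Channel Infos]",
    ch_lines), hdr_path)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]",
               paste0("DataFile=", base, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"),
             paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), open = "wb")
  on.exit(close(con))
  v <- as.vector(rec$data) / res  # multiplexed order: channels fastest
  if (format == "INT_16") {
    writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
  } else {
    writeBin(v, con, size = 4L, endian = "little")
  }
  invisible(hdr_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
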