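#' Read a multichannel recording from delimited text
#'
#' The on-disk format is deliberately plain: a comma-separated sample table
#' (one column per channel; columns of different lengths are padded with empty
#' fields), a JSON sidecar `<base>.json` declaring per-channel sampling rate,
#' units, sample count and recording metadata, and an optional tab-separated
#' marker file `<base>_markers.tsv` with columns `time` and `label`. The
#' reader validates every container invariant and refuses malformed files —
#' it never silently repairs.
#'
#' @param path Path to the CSV sample table (sidecar paths are derived).
#' @return An [recording()] object.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path), class = "hp_io_error")
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    abort(sprintf("Missing sidecar metadata file: %s", sidecar), class = "hp_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$channels) || !nrow(as.data.frame(meta$channels)))
    abort("Sidecar declares no channels.", class = "hp_format_error")
  chan_meta <- as.data.frame(meta$channels)
  if (anyDuplicated(chan_meta$label))
    abort("Duplicate channel label in sidecar.", class = "hp_format_error")

  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    abort("Duplicate channel label in sample table header.", class = "hp_format_error")
  raw <- read.csv(path, header = TRUE, colClasses = "character",
                  check.names = FALSE, na.strings = NULL)
  if (!setequal(header, chan_meta$label))
    abort("Sample-table columns and sidecar channel labels disagree.",
          class = "hp_format_error")

  channels <- list()
  for (i in seq_len(nrow(chan_meta))) {
    lab <- chan_meta$label[i]
    n <- as.integer(chan_meta$n[i])
    txt <- raw[[lab]][seq_len(n)]
    val <- suppressWarnings(as.numeric(txt))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      abort(sprintf("Non-numeric sample in channel '%s' at line %d.", lab, bad + 1L),
            class = "hp_parse_error")
    }
    channels[[lab]] <- timeseries(val, fs = chan_meta$fs[i],
                                  start_time = chan_meta$start_time[i] %||% 0,
                                  label = lab, units = chan_meta$units[i] %||% "")
  }

  markers <- list()
  mpath <- markers_path(path)
  if (file.exists(mpath)) {
    mk <- read.delim(mpath, header = TRUE, colClasses = c("numeric", "character"))
    for (lab in unique(mk$label))
      markers[[lab]] <- event_series(mk$time[mk$label == lab], label = lab)
  }
  recording(channels, markers = markers,
            metadata = as.list(meta$metadata %||% list()))
}

#' Write a multichannel recording to delimited text
#'
#' Inverse of [read_recording()]: samples go to `path` (CSV, one column per
#' channel, full double precision), channel metadata to `<base>.json` and
#' markers (if any) to `<base>_markers.tsv`. Round-tripping reproduces
#' samples to text precision and labels/rates/markers exactly.
#'
#' @param rec An [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "hp_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("Directory does not exist: %s", dir), class = "hp_io_error")

  ns <- vapply(rec$channels, function(ch) length(ch$samples), integer(1))
  nmax <- max(ns)
  cols <- lapply(rec$channels, function(ch) {
    out <- c(format_samples(ch$samples), rep("", nmax - length(ch$samples)))
    out
  })
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  names(df) <- names(rec$channels)
  write.csv(df, path, row.names = FALSE, quote = FALSE)

  meta <- list(
    channels = data.frame(
      label = names(rec$channels),
      fs = vapply(rec$channels, function(ch) ch$fs, numeric(1)),
      units = vapply(rec$channels, function(ch) ch$units, character(1)),
      start_time = vapply(rec$channels, function(ch) ch$start_time, numeric(1)),
      n = ns
    ),
    metadata = rec$metadata
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  mpath <- markers_path(path)
  if (length(rec$markers)) {
    mk <- dplyr::bind_rows(lapply(rec$markers, as_tibble))
    utils::write.table(mk, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (file.exists(mpath)) {
    unlink(mpath)  # do not leave a stale marker file next to a marker-free table
  }
  invisible(path)
}

#' Read / write an event marker table
#'
#' Two-column tab-separated text (`time` in seconds, `label`).
#'
#' @param path Path to a marker TSV.
#' @return `read_markers()`: a named list of [event_series()], one per label.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path), class = "hp_io_error")
  mk <- read.delim(path, header = TRUE, colClasses = c("numeric", "character"))
  out <- list()
  for (lab in unique(mk$label)) out[[lab]] <- event_series(mk$time[mk$label == lab], label = lab)
  out
}

#' @rdname read_markers
#' @param events An `hp_events` or named list of them.
#' @export
write_markers <- function(events, path) {
  if (inherits(events, "hp_events")) events <- list(events)
  mk <- dplyr::bind_rows(lapply(events, as_tibble))
  utils::write.table(mk, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")
markers_path <- function(path) paste0(sub("\\.[^.]*$", "", path), "_markers.tsv")

format_samples <- function(x) {
  # 17 significant digits: lossless double -> text -> double round trip
  formatC(x, digits = 17, format = "g")
}
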