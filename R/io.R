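# Persistence of the internal containers and a minimal GDF 2.x reader.
#
# Internal containers are serialized as single-file RDS payloads wrapped in
# an explicit schema + version envelope, so a stale or foreign file fails
# loudly instead of deserializing into nonsense.

.schema_recording <- "misynergy-recording"
.schema_epochs <- "misynergy-epochs"
.schema_version <- 1L

#' Save / load an epoch set
#'
#' Lossless round trip of data, labels, sampling rate and provenance.
#'
#' @param epochs an [epoch_set()] (validated before writing).
#' @param path file path.
#' @return `load_epochs` returns the [epoch_set()]; `save_epochs` returns
#'   `path` invisibly.
#' @export
save_epochs <- function(epochs, path) {
  epochs <- validate_epoch_set(epochs)
  saveRDS(list(schema = .schema_epochs, version = .schema_version,
               data = epochs$data, labels = epochs$labels, fs = epochs$fs,
               provenance = epochs$provenance,
               channel_labels = epochs$channel_labels), path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$schema, .schema_epochs))
    stop("not a saved epoch set: ", path, call. = FALSE)
  if (!identical(x$version, .schema_version))
    stop("schema-version mismatch: file has ", x$version, ", expected ",
         .schema_version, call. = FALSE)
  epoch_set(x$data, x$labels, x$fs, x$provenance, x$channel_labels)
}

#' Save / load a continuous recording
#'
#' @param recording an [eeg_recording()] (validated before writing).
#' @param path file path.
#' @return `load_recording` returns the [eeg_recording()]; `save_recording`
#'   returns `path` invisibly.
#' @export
save_recording <- function(recording, path) {
  recording <- validate_recording(recording)
  saveRDS(list(schema = .schema_recording, version = .schema_version,
               signal = recording$signal, fs = recording$fs,
               channel_labels = recording$channel_labels,
               channel_kinds = recording$channel_kinds,
               events = recording$events), path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$schema, .schema_recording))
    stop("not a saved recording: ", path, call. = FALSE)
  if (!identical(x$version, .schema_version))
    stop("schema-version mismatch: file has ", x$version, ", expected ",
         .schema_version, call. = FALSE)
  eeg_recording(x$signal, x$fs, x$channel_labels, x$channel_kinds, x$events)
}

# ---- GDF 2.x ---------------------------------------------------------------

# little-endian scalar readers over a raw vector (0-based offsets)
.rb_u8 <- function(r, off) as.integer(r[off + 1L])
.rb_u16 <- function(r, off, n = 1L)
  readBin(r[off + seq_len(2L * n)], "integer", n, size = 2, signed = FALSE,
          endian = "little")
.rb_i32 <- function(r, off, n = 1L)
  readBin(r[off + seq_len(4L * n)], "integer", n, size = 4, endian = "little")
.rb_u32 <- function(r, off, n = 1L) {
  x <- as.numeric(.rb_i32(r, off, n))
  ifelse(x < 0, x + 2^32, x)
}
.rb_i64 <- function(r, off) {
  lo <- .rb_u32(r, off); hi <- .rb_i32(r, off + 4L)
  hi * 2^32 + lo
}
.rb_f32 <- function(r, off, n = 1L)
  readBin(r[off + seq_len(4L * n)], "double", n, size = 4, endian = "little")
.rb_f64 <- function(r, off, n = 1L)
  readBin(r[off + seq_len(8L * n)], "double", n, size = 8, endian = "little")
.rb_str <- function(r, off, width) {
  b <- r[off + seq_len(width)]
  trimws(rawToChar(b[b != as.raw(0)]))
}

# default IV-2a cue mapping: left, right, feet, tongue
.default_cue_map <- c(`769` = 0L, `770` = 1L, `771` = 2L, `772` = 3L)

#' Read a GDF 2.x recording
#'
#' Minimal reader for the General Data Format for biosignals, version 2.x —
#' the distribution format of the BCI Competition IV-2a dataset: fixed +
#' per-channel headers, uniformly sampled data records (int16, float32 or
#' float64), and the mode 1/3 event table. Cue event codes are translated to
#' class codes via `cue_map`; all other codes are preserved as raw protocol
#' codes. Channels whose label contains "EOG" are tagged EOG; in a
#' 25-channel file without EOG labels the last three channels are assumed
#' to be the EOG montage.
#'
#' @param path path to a GDF 2.x file.
#' @param cue_map named integer vector mapping event type codes to class
#'   codes 0..3 (default: 769-772 to left-hand, right-hand, feet, tongue).
#' @return An [eeg_recording()].
#' @export
read_gdf <- function(path, cue_map = .default_cue_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 256L)
    stop("corrupt GDF header: file shorter than the fixed header", call. = FALSE)
  magic <- rawToChar(r[1:8])
  if (substr(magic, 1, 3) != "GDF")
    stop("not a GDF file (magic: ", substr(magic, 1, 8), ")", call. = FALSE)
  ver <- suppressWarnings(as.numeric(substr(magic, 5, 8)))
  if (is.na(ver) || ver < 1.9)
    stop("unsupported GDF version: ", magic, call. = FALSE)

  head_len <- .rb_u16(r, 184L) * 256L
  n_rec <- .rb_i64(r, 236L)
  dur <- .rb_u32(r, 244L, 2L)                  # record length num/den seconds
  ns <- .rb_u16(r, 252L)
  if (length(r) < head_len || ns < 1L)
    stop("corrupt GDF header: truncated channel headers", call. = FALSE)

  off <- 256L
  labels <- vapply(seq_len(ns) - 1L, function(i)
    .rb_str(r, off + 16L * i, 16L), character(1))
  off <- off + 16L * ns + 80L * ns + 6L * ns + 2L * ns   # skip transducer,
  physmin <- .rb_f64(r, off, ns); off <- off + 8L * ns   # physdim, unitcodes
  physmax <- .rb_f64(r, off, ns); off <- off + 8L * ns
  digmin <- .rb_f64(r, off, ns); off <- off + 8L * ns
  digmax <- .rb_f64(r, off, ns); off <- off + 8L * ns
  off <- off + 68L * ns + 4L * ns + 4L * ns + 4L * ns    # prefilter fields
  spr <- .rb_i32(r, off, ns); off <- off + 4L * ns
  dtyp <- .rb_i32(r, off, ns)

  if (length(unique(spr)) != 1L)
    stop("unsupported GDF: per-channel sampling rates differ", call. = FALSE)
  spr <- spr[1L]
  rec_s <- dur[1L] / dur[2L]
  fs <- spr / rec_s

  type_bytes <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
                  `16` = 4L, `17` = 8L)
  bt <- type_bytes[as.character(dtyp)]
  if (anyNA(bt))
    stop("unsupported GDF data type code: ",
         paste(setdiff(dtyp, as.integer(names(type_bytes))), collapse = ", "),
         call. = FALSE)
  rec_bytes <- sum(bt * spr)
  data_end <- head_len + n_rec * rec_bytes
  if (length(r) < data_end)
    stop("corrupt GDF data: file shorter than the declared records",
         call. = FALSE)

  cal <- (physmax - physmin) / (digmax - digmin)
  cal[!is.finite(cal)] <- 1
  offs <- physmin - cal * digmin
  offs[!is.finite(offs)] <- 0

  signal <- matrix(0, ns, n_rec * spr)
  ch_off <- cumsum(c(0L, bt * spr))[seq_len(ns)]
  for (k in seq_len(n_rec)) {
    base <- head_len + (k - 1L) * rec_bytes
    for (ch in seq_len(ns)) {
      o <- base + ch_off[ch]
      v <- switch(as.character(dtyp[ch]),
        `1` = readBin(r[o + seq_len(spr)], "integer", spr, size = 1),
        `2` = readBin(r[o + seq_len(spr)], "integer", spr, size = 1,
                      signed = FALSE),
        `3` = readBin(r[o + seq_len(2L * spr)], "integer", spr, size = 2,
                      endian = "little"),
        `4` = .rb_u16(r, o, spr),
        `5` = .rb_i32(r, o, spr),
        `6` = .rb_u32(r, o, spr),
        `16` = .rb_f32(r, o, spr),
        `17` = .rb_f64(r, o, spr))
      signal[ch, (k - 1L) * spr + seq_len(spr)] <- v * cal[ch] + offs[ch]
    }
  }

  events <- data.frame(onset = integer(), code = integer())
  if (length(r) >= data_end + 8L) {
    eo <- data_end
    etmode <- .rb_u8(r, eo)
    if (etmode %in% c(1L, 3L)) {
      # version >= 1.94: header is mode(u8), n_events(u24), sample rate(f32)
      nev <- if (ver >= 1.94) {
        b <- as.integer(r[eo + 2:4])
        b[1] + b[2] * 256 + b[3] * 65536
      } else .rb_u32(r, eo + 4L)
      if (length(r) < eo + 8L + nev * 6L)
        stop("corrupt GDF event table", call. = FALSE)
      pos <- .rb_u32(r, eo + 8L, nev) - 1       # file stores 1-based samples
      typ <- .rb_u16(r, eo + 8L + 4L * nev, nev)
      code <- unname(cue_map[as.character(typ)])
      code[is.na(code)] <- typ[is.na(code)]
      keep <- pos >= 0 & pos < ncol(signal)
      events <- data.frame(onset = as.integer(pos[keep]),
                           code = as.integer(code[keep]))
    }
  }

  kinds <- ifelse(grepl("EOG", labels, ignore.case = TRUE), "EOG", "EEG")
  if (ns == 25L && !any(kinds == "EOG")) kinds[23:25] <- "EOG"
  if (ns != 25L)
    warning("unexpected channel count (", ns,
            ", IV-2a files have 25); best-effort EEG/EOG tagging",
            call. = FALSE)
  eeg_recording(signal, fs, labels, kinds, events)
}
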