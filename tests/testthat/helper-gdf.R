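# Synthetic GDF 2.20 writer used to exercise read_gdf() without any binary
# fixture in the repository. Writes the subset of the format the reader
# supports: float32/int16 data in uniform records and a mode-1 event table.
# Event codes follow the IV-2a convention (769..772 = cues).

write_synthetic_gdf <- function(recording, path, spr = NULL,
                                event_types = NULL) {
  sig <- recording$signal
  ns <- nrow(sig); fs <- recording$fs
  if (is.null(spr)) spr <- as.integer(fs)           # 1-second records
  n_rec <- ncol(sig) %/% spr
  stopifnot(n_rec * spr == ncol(sig))
  con <- file(path, "wb")
  on.exit(close(con))
  wr_str <- function(s, width) {
    b <- charToRaw(s)
    writeBin(c(b[seq_len(min(length(b), width))],
               raw(max(0L, width - length(b)))), con)
  }
  wr_zeros <- function(n) writeBin(raw(n), con)
  # fixed header (256 bytes)
  wr_str("GDF 2.20", 8L)
  wr_str("SYN-001 X synthetic", 66L)
  wr_zeros(10L)                                      # reserved
  wr_zeros(4L)                                       # sadm/weight/height/ghi
  wr_str("synthetic IV-2a-style session", 64L)
  wr_zeros(4L)                                       # location version
  writeBin(integer(3L), con, size = 4L)              # lat/lon/alt
  writeBin(raw(16L), con)                            # meas date + birthday
  writeBin(as.integer(1L + ns), con, size = 2L)      # header blocks
  wr_zeros(6L)
  wr_zeros(8L); wr_zeros(6L)                         # equipment, ip
  writeBin(integer(3L), con, size = 2L)              # headsize
  writeBin(numeric(6L), con, size = 4L)              # ref + gnd positions
  writeBin(c(n_rec, 0L), con, size = 4L)             # n_records (int64 le)
  writeBin(c(1L, as.integer(fs / spr)), con, size = 4L)  # record = spr/fs s
  writeBin(ns, con, size = 2L)
  wr_zeros(2L)
  # per-channel header arrays (256 bytes per channel in total)
  for (l in recording$channel_labels) wr_str(l, 16L)
  wr_zeros(80L * ns)                                 # transducer
  for (i in seq_len(ns)) wr_str("uV", 6L)            # obsolete phys dim
  writeBin(rep(4275L, ns), con, size = 2L)           # microvolt unit code
  writeBin(rep(-1000, ns), con, size = 8L)           # physmin
  writeBin(rep(1000, ns), con, size = 8L)            # physmax
  writeBin(rep(-1000, ns), con, size = 8L)           # digmin
  writeBin(rep(1000, ns), con, size = 8L)            # digmax
  wr_zeros(68L * ns)                                 # obsolete prefilter
  writeBin(numeric(3L * ns), con, size = 4L)         # lowpass/highpass/notch
  writeBin(rep(as.integer(spr), ns), con, size = 4L) # samples per record
  writeBin(rep(16L, ns), con, size = 4L)             # dtype: float32
  writeBin(numeric(3L * ns), con, size = 4L)         # xyz
  writeBin(numeric(5L * ns), con, size = 4L)         # sensor info
  # data records (channel-blocked within each record)
  for (k in seq_len(n_rec)) {
    cols <- (k - 1L) * spr + seq_len(spr)
    for (ch in seq_len(ns))
      writeBin(sig[ch, cols], con, size = 4L)
  }
  # event table (mode 1)
  ev <- recording$events
  if (is.null(event_types))
    event_types <- ifelse(ev$code %in% 0:3, 769L + ev$code, ev$code)
  writeBin(as.raw(1L), con)                          # mode
  nev <- nrow(ev)                                    # n_events as uint24
  writeBin(as.raw(c(nev %% 256L, (nev %/% 256L) %% 256L, nev %/% 65536L)), con)
  writeBin(as.numeric(fs), con, size = 4L)           # event sample rate (f32)
  writeBin(as.integer(ev$onset + 1L), con, size = 4L)  # 1-based positions
  writeBin(as.integer(event_types), con, size = 2L)
  invisible(path)
}
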