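# Shared fixtures built in code at test time.

f_grid_default <- conndyn::spectral_config()$f_grid

# recording holding pure sinusoids (one frequency per channel by recycling)
make_sine_recording <- function(freqs, fs = 250, dur = 60,
                                channels = paste0("ch", seq_along(freqs)),
                                subject_id = "sine",
                                events = data.frame(label = character(),
                                                    time = numeric())) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  samples <- t(vapply(freqs, function(f) sin(2 * pi * f * t), t))
  recording(subject_id, fs, channels, samples, events)
}

# 8-channel white-noise maintenance epoch on the canonical montage
make_noise_epoch <- function(dur = 60, fs = 250, seed = 1,
                             subject_id = "noise") {
  set.seed(seed)
  n <- round(dur * fs)
  rec <- recording(subject_id, fs, analysis_montage(),
                   matrix(rnorm(8 * n), nrow = 8),
                   events = data.frame(label = c("incision", "end"),
                                       time = c(0, dur)))
  extract_maintenance(rec, "incision", "end", start_offset = 0)
}

# cross_spectra object for two full-window signals
make_window_cs <- function(x, y, fs = 250) {
  window_csd(x, y, window_grid(), spectral_config(), fs)
}

# pooled (window-averaged) corrected wPLI spectrum for one channel pair
pooled_corrected <- function(x, y, fs = 250, n_perm = 20, seed = 9) {
  wlen <- 30 * fs; step <- 10 * fs
  n_win <- floor((length(x) - wlen) / step) + 1
  v <- matrix(NA_real_, n_win, 70)
  for (w in seq_len(n_win)) {
    i0 <- (w - 1) * step + 1
    cs <- make_window_cs(x[i0:(i0 + wlen - 1)], y[i0:(i0 + wlen - 1)], fs)
    v[w, ] <- corrected_wpli(wpli(cs), surrogate_wpli(cs, n_perm, seed))
  }
  colMeans(v)
}

# Minimal EDF+ file assembled byte-by-byte per the format layout
# (independent of the package reader). Signals: named channels at `fs`,
# physical range +-500 uV over digital +-32767, plus an annotations signal
# carrying one event per data record.
write_edf_fixture <- function(path, channels, samples, fs,
                              events = data.frame(label = character(),
                                                  time = numeric())) {
  ns <- length(channels) + 1L           # + annotations signal
  rec_dur <- 1                           # 1-s data records
  n_rec <- ncol(samples) / fs
  stopifnot(n_rec == round(n_rec))
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("patient", 80); wr("recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("EDF+C", 44)
  wr(n_rec, 8); wr(rec_dur, 8); wr(ns, 4)
  labs <- c(channels, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (l in labs) wr("", 80)
  for (l in labs) wr(ifelse(l == "EDF Annotations", "", "uV"), 8)
  for (l in labs) wr(ifelse(l == "EDF Annotations", -1, -500), 8)
  for (l in labs) wr(ifelse(l == "EDF Annotations", 1, 500), 8)
  for (l in labs) wr(-32768, 8)
  for (l in labs) wr(32767, 8)
  for (l in labs) wr("", 80)
  annot_words <- 32L
  for (l in labs) wr(ifelse(l == "EDF Annotations", annot_words, fs), 8)
  for (l in labs) wr("", 32)
  gain <- 500 / 32767
  for (r in seq_len(n_rec)) {
    for (ch in seq_along(channels)) {
      seg <- samples[ch, ((r - 1) * fs + 1):(r * fs)]
      writeBin(as.integer(round(seg / gain)), con, size = 2L,
               endian = "little")
    }
    # annotations record: timekeeping TAL, then events due in this record;
    # TALs are NUL-separated (NUL cannot live in an R string, so bytes)
    tals <- paste0("+", r - 1, "\x14\x14")
    due <- events[events$time >= r - 1 & events$time < r, , drop = FALSE]
    for (i in seq_len(nrow(due)))
      tals <- c(tals, paste0(sprintf("+%g", due$time[i]), "\x14",
                             due$label[i], "\x14"))
    bytes <- integer()
    for (tal in tals) bytes <- c(bytes, utf8ToInt(tal), 0L)
    bytes <- c(bytes, rep(0L, 2 * annot_words - length(bytes)))
    words <- bytes[seq(1, length(bytes), 2)] +
      256L * bytes[seq(2, length(bytes), 2)]
    words <- ifelse(words > 32767, words - 65536L, words)
    writeBin(as.integer(words), con, size = 2L, endian = "little")
  }
  invisible(path)
}
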