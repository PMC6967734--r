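# Minimal EDF / EDF+ reader. EDF is a fixed-layout ASCII header followed by
# little-endian int16 data records; EDF+ adds an "EDF Annotations" signal
# whose records hold time-stamped annotation lists (TALs). Only continuous
# recordings with a uniform sampling rate across ordinary signals are
# supported, which covers standard scalp-EEG exports.

read_edf <- function(path, subject_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    raw <- readBin(con, "raw", n = nchars)
    if (length(raw) < nchars) stopf("format error: truncated EDF header")
    trimws(rawToChar(raw))
  }
  rd(8)                       # version
  rd(80); rd(80)              # patient / recording id
  rd(8); rd(8)                # start date / time
  rd(8)                       # header length
  rd(44)                      # reserved ("EDF+C" for continuous EDF+)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("format error: bad EDF signal count")

  field <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- field(16)
  field(80)                   # transducer
  field(8)                    # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                   # prefiltering
  spr <- as.integer(field(8)) # samples per data record
  field(32)                   # reserved

  is_annot <- labels == "EDF Annotations"
  sig <- which(!is_annot)
  if (!length(sig)) stopf("format error: EDF file holds no ordinary signals")
  if (length(unique(spr[sig])) != 1L)
    stopf("metadata error: non-uniform sampling rate across EDF signals")
  if (is.na(rec_dur) || rec_dur <= 0)
    stopf("metadata error: missing data-record duration (sampling rate)")
  fs <- spr[sig[1]] / rec_dur

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min

  chunks <- vector("list", n_rec)
  annot_raw <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_mat <- matrix(NA_real_, nrow = length(sig), ncol = spr[sig[1]])
    row <- 0L
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      if (length(raw) < spr[s]) stopf("format error: truncated EDF record")
      if (is_annot[s]) {
        annot_raw[[r]] <- c(annot_raw[[r]], raw)
      } else {
        row <- row + 1L
        rec_mat[row, ] <- raw * gain[s] + offset[s]
      }
    }
    chunks[[r]] <- rec_mat
  }
  samples <- do.call(cbind, chunks)
  events <- parse_tal_events(annot_raw)
  recording(subject_id, fs, labels[sig], samples, events)
}

# TALs are "+<onset>[\x15<dur>]\x14<text>\x14...\x14\x00"; int16 words are
# re-interpreted as bytes (little-endian) before parsing.
parse_tal_events <- function(annot_raw) {
  words <- unlist(annot_raw)
  if (!length(words)) return(data.frame(label = character(), time = numeric()))
  u <- ifelse(words < 0, words + 65536, words)
  bytes <- as.vector(rbind(u %% 256L, u %/% 256L))
  # TALs are NUL-separated; split on zero bytes, then decode each TAL
  runs <- split(bytes, cumsum(bytes == 0L))
  tals <- vapply(runs, function(b) rawToChar(as.raw(b[b != 0L])),
                 character(1))
  tals <- tals[nzchar(tals)]
  out <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2L) next
    onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1])))
    if (is.na(onset)) next
    for (lab in parts[-1])
      out[[length(out) + 1L]] <- data.frame(label = lab, time = onset)
  }
  if (!length(out)) return(data.frame(label = character(), time = numeric()))
  ev <- do.call(rbind, out)
  ev[order(ev$time), , drop = FALSE]
}
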