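#' Sliding-window grid for connectivity analysis
#'
#' The maintenance epoch is divided into 30-s analysis windows advanced in
#' 10-s steps; each window is further divided into 2-s sub-windows with 50%
#' overlap, giving 29 sub-windows per window. Sub-windows are the unit over
#' which cross-spectra are estimated and pooled.
#'
#' @param window_len analysis window length, seconds.
#' @param step window step, seconds.
#' @param sub_len sub-window length, seconds.
#' @param sub_overlap sub-window overlap fraction in [0, 1).
#' @return object of class `window_grid`.
#' @export
window_grid <- function(window_len = 30, step = 10, sub_len = 2,
                        sub_overlap = 0.5) {
  stopifnot(window_len > 0, step > 0, sub_len > 0,
            sub_overlap >= 0, sub_overlap < 1)
  structure(list(window_len = window_len, step = step, sub_len = sub_len,
                 sub_overlap = sub_overlap),
            class = "window_grid")
}

#' Number of sub-windows per analysis window
#' @param grid a [window_grid].
#' @return integer count (29 for the default grid).
#' @export
n_subwindows <- function(grid) {
  hop <- grid$sub_len * (1 - grid$sub_overlap)
  as.integer(floor((grid$window_len - grid$sub_len) / hop) + 1)
}

#' Multitaper spectral configuration
#'
#' Time-bandwidth product 2 with 3 DPSS tapers; wPLI is evaluated on the
#' 0.5-35 Hz grid at 0.5 Hz steps (70 bins).
#'
#' @param nw time-bandwidth product.
#' @param n_tapers number of DPSS tapers (must be <= 2*nw - 1).
#' @param f_min,f_max,f_step frequency grid bounds and step, Hz.
#' @return object of class `spectral_config` with an `f_grid` field.
#' @export
spectral_config <- function(nw = 2, n_tapers = 3, f_min = 0.5, f_max = 35,
                            f_step = 0.5) {
  if (n_tapers > 2 * nw - 1)
    stopf("config error: n_tapers (%d) exceeds 2*nw - 1 = %g", n_tapers,
          2 * nw - 1)
  structure(list(nw = nw, n_tapers = n_tapers,
                 f_grid = seq(f_min, f_max, by = f_step)),
            class = "spectral_config")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal eigenproblem whose eigenvectors
#' are the DPSS, ordered by decreasing spectral concentration and normalized
#' to unit energy. Sign convention: symmetric tapers have positive mean,
#' antisymmetric tapers a positive initial slope. Results are cached per
#' (n, nw, k).
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix of tapers (columns).
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cached <- .conndyn_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  A[cbind(t_idx + 1, t_idx + 1)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  eg <- eigen(A, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tap[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2L == 1L) {               # symmetric: positive mean
      if (sum(v) < 0) v <- -v
    } else {                           # antisymmetric: positive initial slope
      if (sum((n - 1 - 2 * t_idx) * v) < 0) v <- -v
    }
    tap[, j] <- v
  }
  assign(key, tap, envir = .conndyn_cache)
  tap
}

.conndyn_cache <- new.env(parent = emptyenv())

#' Segment a maintenance epoch into analysis windows
#'
#' @param epoch a `maintenance_epoch`.
#' @param grid a [window_grid].
#' @return data frame with `window_index`, `start_sample`, `end_sample`,
#'   `t_center` (seconds from epoch start).
#' @export
segment_windows <- function(epoch, grid = window_grid()) {
  n <- ncol(epoch$samples)
  dur <- n / epoch$fs
  if (dur < grid$window_len)
    stopf("epoch-too-short error: %.1f s epoch < %.0f s window", dur,
          grid$window_len)
  wlen <- round(grid$window_len * epoch$fs)
  step <- round(grid$step * epoch$fs)
  n_win <- floor((n - wlen) / step) + 1L
  start <- (seq_len(n_win) - 1L) * step + 1L
  data.frame(window_index = seq_len(n_win),
             start_sample = start,
             end_sample = start + wlen - 1L,
             t_center = (start - 1L) / epoch$fs + grid$window_len / 2)
}

# frequency-grid bin indices into an nfft-point FFT at rate fs
grid_bins <- function(f_grid, fs, nfft) {
  bins <- as.integer(round(f_grid / (fs / nfft))) + 1L
  if (anyDuplicated(bins))
    stopf("config error: frequency grid maps to duplicate FFT bins")
  bins
}

# Tapered FFTs of every channel's sub-windows within one analysis window.
# Returns a complex array [n_sub, n_tapers, n_freq, n_channels].
window_tapered_fft <- function(x, fs, grid, cfg) {
  n_ch <- nrow(x)
  slen <- round(grid$sub_len * fs)
  hop <- round(grid$sub_len * (1 - grid$sub_overlap) * fs)
  n_sub <- n_subwindows(grid)
  nfft <- 2^ceiling(log2(slen))
  bins <- grid_bins(cfg$f_grid, fs, nfft)
  tap <- dpss_tapers(slen, cfg$nw, cfg$n_tapers)
  starts <- (seq_len(n_sub) - 1L) * hop + 1L
  # segment matrix: slen x (n_sub * n_ch), each column one sub-window
  seg_idx <- outer(0:(slen - 1L), starts, `+`)      # slen x n_sub
  out <- array(0i, dim = c(n_sub, cfg$n_tapers, length(bins), n_ch))
  buf <- matrix(0, nrow = nfft, ncol = n_sub * n_ch)
  for (k in seq_len(cfg$n_tapers)) {
    for (ch in seq_len(n_ch)) {
      seg <- matrix(x[ch, seg_idx], nrow = slen)
      buf[seq_len(slen), (ch - 1L) * n_sub + seq_len(n_sub)] <- seg * tap[, k]
    }
    ft <- stats::mvfft(buf)[bins, , drop = FALSE]  # n_freq x (n_sub*n_ch)
    for (ch in seq_len(n_ch))
      out[, k, , ch] <- t(ft[, (ch - 1L) * n_sub + seq_len(n_sub)])
  }
  out
}

#' Multitaper cross-spectral density of one sub-window pair
#'
#' Tapered Fourier transforms X_k, Y_k are evaluated by zero-padded FFT and
#' mapped to the analysis frequency grid by nearest bin; the CSD per taper k
#' is X_k(f) * conj(Y_k(f)).
#'
#' @param x,y equal-length signal vectors (one sub-window each).
#' @param cfg a [spectral_config].
#' @param fs sampling rate, Hz.
#' @return complex matrix, n_tapers x n_freq.
#' @export
multitaper_csd <- function(x, y, cfg = spectral_config(), fs) {
  if (length(x) != length(y))
    stopf("shape error: x and y lengths differ (%d vs %d)",
          length(x), length(y))
  n <- length(x)
  nfft <- 2^ceiling(log2(n))
  bins <- grid_bins(cfg$f_grid, fs, nfft)
  tap <- dpss_tapers(n, cfg$nw, cfg$n_tapers)
  xf <- stats::mvfft(rbind(tap * x, matrix(0, nfft - n, cfg$n_tapers)))
  yf <- stats::mvfft(rbind(tap * y, matrix(0, nfft - n, cfg$n_tapers)))
  t(xf[bins, , drop = FALSE] * Conj(yf[bins, , drop = FALSE]))
}

#' Cross-spectra of one channel pair over one analysis window
#'
#' Holds the tapered transforms of both channels for every sub-window, so
#' that both the aligned CSD and trial-shuffled (mispaired) surrogates can
#' be formed.
#'
#' @param xw,yw signal vectors covering one analysis window.
#' @param grid a [window_grid].
#' @param cfg a [spectral_config].
#' @param fs sampling rate, Hz.
#' @return object of class `cross_spectra` with complex arrays `xf`, `yf`
#'   of dimension [n_sub, n_tapers, n_freq] and the aligned `csd`.
#' @export
window_csd <- function(xw, yw, grid = window_grid(),
                       cfg = spectral_config(), fs) {
  if (length(xw) != length(yw)) stopf("shape error: channel lengths differ")
  ft <- window_tapered_fft(rbind(xw, yw), fs, grid, cfg)
  xf <- ft[, , , 1, drop = FALSE]; dim(xf) <- dim(ft)[1:3]
  yf <- ft[, , , 2, drop = FALSE]; dim(yf) <- dim(ft)[1:3]
  structure(list(xf = xf, yf = yf, csd = xf * Conj(yf),
                 f_grid = cfg$f_grid),
            class = "cross_spectra")
}

# |sum Im| / sum |Im| over the estimate axes, 0/0 -> 0.
wpli_from_im <- function(im) {
  # im: matrix estimates x freq
  num <- abs(colSums(im))
  den <- colSums(abs(im))
  out <- numeric(length(den))
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  out
}

#' Weighted phase lag index of a cross-spectra set
#'
#' wPLI(f) = |sum_j Im S_xy,j(f)| / sum_j |Im S_xy,j(f)|, pooling sub-windows
#' and tapers as i.i.d. estimates j. When every imaginary part vanishes at a
#' frequency (e.g. identical signals), the value is defined as 0: no
#' detectable lagged interaction.
#'
#' @param cs a `cross_spectra` object (or a complex array whose last
#'   dimension is frequency).
#' @return numeric vector over the frequency grid, in [0, 1].
#' @export
wpli <- function(cs) {
  csd <- if (inherits(cs, "cross_spectra")) cs$csd else cs
  d <- dim(csd)
  im <- matrix(Im(csd), ncol = d[length(d)])
  wpli_from_im(im)
}

#' Trial-shuffled surrogate wPLI
#'
#' Estimates the finite-sample bias of wPLI by recomputing it on deliberately
#' mispaired sub-windows: channel y's sub-window index is rotated by a cyclic
#' shift of at least 2 (a guaranteed derangement), the CSD reformed from the
#' stored tapered transforms, and wPLI recomputed. The mean over `n_perm`
#' seeded shifts is returned.
#'
#' @param cs a `cross_spectra` object.
#' @param n_perm number of permutations (default 20).
#' @param seed integer seed for the shift draw.
#' @return numeric vector over the frequency grid.
#' @export
surrogate_wpli <- function(cs, n_perm = 20, seed = 1) {
  if (n_perm < 1) stopf("config error: n_perm must be >= 1")
  n_sub <- dim(cs$xf)[1]
  if (n_sub < 2) stopf("config error: surrogate needs >= 2 sub-windows")
  shifts <- surrogate_shifts(n_sub, n_perm, seed)
  n_f <- dim(cs$xf)[3]
  acc <- numeric(n_f)
  for (s in shifts) {
    perm <- ((seq_len(n_sub) - 1L + s) %% n_sub) + 1L
    csd_s <- cs$xf * Conj(cs$yf[perm, , , drop = FALSE])
    acc <- acc + wpli_from_im(matrix(Im(csd_s), ncol = n_f))
  }
  acc / length(shifts)
}

# cyclic shifts in [2, n_sub - 2]; sampled without replacement when possible
surrogate_shifts <- function(n_sub, n_perm, seed) {
  pool <- seq(2L, max(2L, n_sub - 2L))
  set.seed(seed)
  if (length(pool) >= n_perm) sample(pool, n_perm)
  else sample(pool, n_perm, replace = TRUE)
}

#' Surrogate-corrected wPLI
#'
#' Element-wise raw minus surrogate. Values may be slightly negative; they
#' are retained unclipped so downstream cluster geometry is unbiased.
#'
#' @param raw,surrogate wPLI vectors on the same frequency grid.
#' @return numeric vector in [-1, 1].
#' @export
corrected_wpli <- function(raw, surrogate) {
  if (length(raw) != length(surrogate))
    stopf("shape error: frequency grids differ (%d vs %d)",
          length(raw), length(surrogate))
  raw - surrogate
}

#' Average wPLI vectors across the channel pairs of a region pair
#'
#' @param pair_values list (or matrix with pairs in rows) of per-pair wPLI
#'   vectors.
#' @return unweighted mean vector per frequency.
#' @export
pair_average <- function(pair_values) {
  if (is.list(pair_values)) pair_values <- do.call(rbind, pair_values)
  if (is.null(pair_values) || nrow(pair_values) == 0)
    stopf("config error: empty region pair")
  colMeans(pair_values)
}

region_pairs <- function() {
  rg <- region_channels()
  fpf <- expand.grid(a = rg$prefrontal, b = rg$frontal,
                     stringsAsFactors = FALSE)
  fp <- expand.grid(a = rg$frontal, b = rg$parietal,
                    stringsAsFactors = FALSE)
  list(fpf = fpf, fp = fp)
}

#' Surrogate-corrected wPLI features for one subject
#'
#' The per-window connectivity feature: for every 30-s window, the corrected
#' wPLI spectrum averaged over the 6 prefrontal-frontal channel pairs and
#' over the 9 frontal-parietal pairs (70 frequency bins each, 140 features
#' total). Windows under an optional suppression mask are still computed but
#' flagged, so later stages can exclude them.
#'
#' @param epoch a `maintenance_epoch` (8 canonical channels).
#' @param grid a [window_grid].
#' @param cfg a [spectral_config].
#' @param n_perm surrogate permutations per window.
#' @param seed integer seed (surrogate shifts).
#' @param suppression_mask optional logical vector, one flag per window.
#' @return data frame: `subject_id`, `window_index`, `t_center`,
#'   `suppressed`, then `fpf_<Hz>` and `fp_<Hz>` columns (140 in all).
#' @export
connectivity_features <- function(epoch, grid = window_grid(),
                                  cfg = spectral_config(), n_perm = 20,
                                  seed = 1, suppression_mask = NULL) {
  stopifnot(inherits(epoch, "maintenance_epoch"))
  if (!identical(epoch$channels, analysis_montage()))
    stopf("montage error: epoch channels are not the canonical montage")
  wins <- segment_windows(epoch, grid)
  n_win <- nrow(wins)
  if (is.null(suppression_mask)) suppression_mask <- rep(FALSE, n_win)
  if (length(suppression_mask) != n_win)
    stopf("shape error: suppression mask length %d for %d windows",
          length(suppression_mask), n_win)
  pairs <- region_pairs()
  ch <- analysis_montage()
  n_sub <- n_subwindows(grid)
  n_f <- length(cfg$f_grid)
  shifts <- surrogate_shifts(n_sub, n_perm, seed)
  est_dim <- n_sub * cfg$n_tapers

  fpf_out <- matrix(NA_real_, n_win, n_f)
  fp_out <- matrix(NA_real_, n_win, n_f)
  for (w in seq_len(n_win)) {
    xw <- epoch$samples[, wins$start_sample[w]:wins$end_sample[w],
                        drop = FALSE]
    ft <- window_tapered_fft(xw, epoch$fs, grid, cfg)
    perms <- lapply(shifts, function(s) ((seq_len(n_sub) - 1L + s) %% n_sub) + 1L)
    pair_corr <- function(tab) {
      vals <- matrix(NA_real_, nrow(tab), n_f)
      for (p in seq_len(nrow(tab))) {
        ia <- match(tab$a[p], ch); ib <- match(tab$b[p], ch)
        xf <- ft[, , , ia]; yf <- ft[, , , ib]
        raw <- wpli_from_im(matrix(Im(xf * Conj(yf)), est_dim, n_f))
        surr <- numeric(n_f)
        for (perm in perms) {
          imp <- Im(xf * Conj(yf[perm, , , drop = FALSE]))
          surr <- surr + wpli_from_im(matrix(imp, est_dim, n_f))
        }
        vals[p, ] <- corrected_wpli(raw, surr / length(perms))
      }
      pair_average(vals)
    }
    fpf_out[w, ] <- pair_corr(pairs$fpf)
    fp_out[w, ] <- pair_corr(pairs$fp)
  }
  fhz <- sprintf("%.1f", cfg$f_grid)
  colnames(fpf_out) <- paste0("fpf_", fhz)
  colnames(fp_out) <- paste0("fp_", fhz)
  cbind(data.frame(subject_id = epoch$subject_id,
                   window_index = wins$window_index,
                   t_center = wins$t_center,
                   suppressed = suppression_mask),
        as.data.frame(fpf_out), as.data.frame(fp_out))
}

#' Extract the 140-column feature matrix from a feature data frame
#' @param features data frame from [connectivity_features()] (possibly
#'   row-bound across subjects).
#' @param drop_suppressed drop masked windows (default TRUE).
#' @return numeric matrix, windows x 140.
#' @export
feature_matrix <- function(features, drop_suppressed = TRUE) {
  cols <- grep("^(fpf|fp)_", names(features), value = TRUE)
  keep <- if (drop_suppressed) !features$suppressed else rep(TRUE, nrow(features))
  as.matrix(features[keep, cols, drop = FALSE])
}
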