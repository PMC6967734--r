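#' Connectivity state specification
#'
#' A hidden state is a narrow-band, phase-lagged coupling between one region
#' pair: a shared band-limited oscillation is injected into both channel
#' groups, the lagging group receiving a copy phase-shifted by `lag`.
#'
#' @param name state name, one of S1..S5.
#' @param pair `"fpf"` (prefrontal-frontal) or `"fp"` (frontal-parietal).
#' @param band `c(f_lo, f_hi)` in Hz, within [0.5, 35].
#' @param lag phase lag in radians, in (0, pi); default pi/2 maximizes the
#'   imaginary cross-spectrum, the regime wPLI detects.
#' @param coupling_snr ratio of shared-oscillation power to the independent
#'   background-noise power within the band.
#' @return object of class `state_spec`.
#' @export
state_spec <- function(name, pair = c("fpf", "fp"), band, lag = pi / 2,
                       coupling_snr = 1.5) {
  pair <- match.arg(pair)
  if (band[1] < 0.5 || band[2] > 35 || band[1] >= band[2])
    stopf("config error: band must satisfy 0.5 <= f_lo < f_hi <= 35")
  if (lag <= 0 || lag >= pi)
    stopf("config error: lag must lie strictly inside (0, pi)")
  structure(list(name = name, pair = pair, band = band, lag = lag,
                 coupling_snr = coupling_snr),
            class = "state_spec")
}

#' Default five-state taxonomy
#'
#' S1: prefrontal-frontal alpha-beta (8-20 Hz); S2: prefrontal-frontal alpha
#' (8-12 Hz); S3: prefrontal-frontal delta (0.5-4 Hz); S4: frontal-parietal
#' theta (4-8 Hz); S5: frontal-parietal theta-alpha (4-12 Hz).
#'
#' @param coupling_snr shared-to-background in-band power ratio for every
#'   state.
#' @return named list of five [state_spec] objects.
#' @export
state_specs <- function(coupling_snr = 1.5) {
  list(S1 = state_spec("S1", "fpf", c(8, 20), coupling_snr = coupling_snr),
       S2 = state_spec("S2", "fpf", c(8, 12), coupling_snr = coupling_snr),
       S3 = state_spec("S3", "fpf", c(0.5, 4), coupling_snr = coupling_snr),
       S4 = state_spec("S4", "fp", c(4, 8), coupling_snr = coupling_snr),
       S5 = state_spec("S5", "fp", c(4, 12), coupling_snr = coupling_snr))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions: 45 subjects aged 18-80, 20-minute
#' maintenance epochs at 250 Hz, hidden states dwelling on a 30-s grid
#' (aligned to the 10-s analysis step) under a sticky uniform Markov chain,
#' and an age effect tilting stationary occupancy (negative for S1, positive
#' for S4).
#'
#' @param n_subjects cohort size.
#' @param age_range `c(min, max)` ages in years.
#' @param epoch_duration maintenance epoch length, seconds.
#' @param fs sampling rate, Hz.
#' @param window_grid hidden-state dwell step, seconds (a multiple of the
#'   analysis step).
#' @param base_transition_matrix 5x5 row-stochastic matrix over S1..S5.
#' @param age_effect named per-state log-odds slope on stationary occupancy
#'   per decade of age.
#' @param zero_lag_strength power ratio of an identical zero-phase common
#'   signal added to all channels (volume-conduction confound); 0 disables.
#' @param seed master seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 45, age_range = c(18, 80),
                          epoch_duration = 1200, fs = 250, window_grid = 30,
                          base_transition_matrix = NULL,
                          age_effect = c(S1 = -0.5, S2 = 0, S3 = 0,
                                         S4 = 0.4, S5 = 0),
                          zero_lag_strength = 0, seed = 1) {
  if (n_subjects < 1) stopf("config error: n_subjects must be >= 1")
  if (epoch_duration <= 0) stopf("config error: zero-duration epoch")
  if (is.null(base_transition_matrix)) {
    base_transition_matrix <- matrix(0.05, 5, 5)
    diag(base_transition_matrix) <- 0.80
  }
  rs <- rowSums(base_transition_matrix)
  if (any(abs(rs - 1) > 1e-9))
    stopf("config error: transition-matrix rows must sum to 1")
  if (nrow(base_transition_matrix) != ncol(base_transition_matrix))
    stopf("config error: transition matrix must be square")
  structure(list(n_subjects = n_subjects, age_range = age_range,
                 epoch_duration = epoch_duration, fs = fs,
                 window_grid = window_grid,
                 base_transition_matrix = base_transition_matrix,
                 age_effect = age_effect,
                 zero_lag_strength = zero_lag_strength, seed = seed),
            class = "cohort_config")
}

stationary_distribution <- function(P) {
  eg <- eigen(t(P))
  v <- Re(eg$vectors[, which.min(abs(eg$values - 1))])
  v / sum(v)
}

# Age-tilted chain: stationary occupancy pi(age) = softmax(log pi0 +
# slope * (age - center)/10); rebuilt as the reversible resampling chain
# T = (1 - d) I + d 1 pi', which keeps the base chain's dwell parameter d.
age_tilted_chain <- function(cfg, age, state_names) {
  P0 <- cfg$base_transition_matrix
  m <- length(state_names)
  if (nrow(P0) != m)
    stopf("config error: %d x %d transition matrix for %d states",
          nrow(P0), ncol(P0), m)
  dimnames(P0) <- list(state_names, state_names)
  if (m == 1) return(list(P = P0, pi = stats::setNames(1, state_names)))
  pi0 <- stationary_distribution(P0)
  d <- (1 - mean(diag(P0))) / (1 - mean(pi0))
  d <- min(max(d, 1e-6), 1)
  center <- mean(cfg$age_range)
  slopes <- cfg$age_effect[state_names]
  slopes[is.na(slopes)] <- 0
  lg <- log(pmax(pi0, 1e-12)) + as.numeric(slopes) * (age - center) / 10
  pi_age <- exp(lg - max(lg)); pi_age <- pi_age / sum(pi_age)
  P <- (1 - d) * diag(m) + d * matrix(pi_age, m, m, byrow = TRUE)
  dimnames(P) <- list(state_names, state_names)
  list(P = P, pi = stats::setNames(pi_age, state_names))
}

draw_markov <- function(P, pi0, n_steps) {
  states <- colnames(P)
  s <- integer(n_steps)
  s[1] <- sample.int(length(states), 1, prob = pi0)
  if (n_steps > 1)
    for (t in 2:n_steps) s[t] <- sample.int(length(states), 1, prob = P[s[t - 1], ])
  states[s]
}

# 1/f^2-like background: FFT coloring of white noise with amplitude 1/f
# (floored at 1 Hz), normalized to unit variance.
background_noise <- function(n, fs) {
  wn <- stats::rnorm(n)
  ft <- stats::fft(wn)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequencies
  amp <- 1 / pmax(f, 1)
  amp[1] <- 0                                # no DC
  x <- Re(stats::fft(ft * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited unit-variance noise plus a copy phase-shifted by `lag`
# (constant phase shift across the band)
band_source <- function(n, fs, band, lag) {
  wn <- stats::rnorm(n)
  ft <- stats::fft(wn)
  f <- c(0, seq_len(n - 1)) * fs / n
  pos <- f <= fs / 2
  folded <- ifelse(pos, f, fs - f)
  mask <- folded >= band[1] & folded <= band[2]
  ft[!mask] <- 0
  z <- Re(stats::fft(ft, inverse = TRUE)) / n
  shift <- ifelse(pos, exp(-1i * lag), exp(1i * lag))
  zl <- Re(stats::fft(ft * shift, inverse = TRUE)) / n
  sc <- stats::sd(z)
  list(lead = z / sc, lag = zl / sc)
}

band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- c(0, seq_len(n - 1)) * fs / n
  folded <- pmin(f, fs - f)
  sum(p[folded >= band[1] & folded <= band[2]]) / n^2
}

#' Generate one synthetic subject
#'
#' Draws a hidden connectivity-state sequence from the age-tilted Markov
#' chain, then synthesizes 8-channel EEG: independent 1/f^2-like background
#' noise in every channel, plus -- during each dwell step -- the active
#' state's shared band-limited oscillation injected into its leading channel
#' group and a phase-lagged copy into the lagging group, scaled so the
#' shared in-band power is `coupling_snr` times the background in-band
#' power.
#'
#' @param meta a [subject_meta] (age drives the chain tilt).
#' @param states list of [state_spec]s (chain states, in order S1..S5).
#' @param cfg a [cohort_config].
#' @param seed integer seed for this subject.
#' @param signals if `FALSE`, skip EEG synthesis and return only ground
#'   truth (used for chain-level calibration experiments).
#' @return list with `recording` (or `NULL`), and `ground_truth` (fields
#'   `subject_id`, `hidden_states`, `true_occupancy`,
#'   `true_transition_matrix`, `dwell_sec`).
#' @export
generate_subject <- function(meta, states = state_specs(),
                             cfg = cohort_config(), seed = 1,
                             signals = TRUE) {
  if (cfg$epoch_duration <= 0) stopf("config error: zero-duration epoch")
  set.seed(seed)
  n_steps <- max(1L, floor(cfg$epoch_duration / cfg$window_grid))
  chain <- age_tilted_chain(cfg, meta$age, names(states))
  hidden <- draw_markov(chain$P, chain$pi, n_steps)
  occ <- table(factor(hidden, levels = names(states)))
  gt <- list(subject_id = meta$subject_id, hidden_states = hidden,
             true_occupancy = as.numeric(occ) / n_steps,
             true_transition_matrix = chain$P,
             dwell_sec = cfg$window_grid)
  names(gt$true_occupancy) <- names(states)
  if (!signals) return(list(recording = NULL, ground_truth = gt))

  n <- round(cfg$epoch_duration * cfg$fs)
  ch <- analysis_montage()
  rg <- region_channels()
  x <- t(vapply(seq_along(ch), function(i) background_noise(n, cfg$fs),
                numeric(n)))
  step_len <- round(cfg$window_grid * cfg$fs)
  bg_bp <- vapply(names(states), function(s)
    mean(apply(x, 1, band_power_fraction, fs = cfg$fs,
               band = states[[s]]$band)), numeric(1))
  src <- lapply(states, function(sp)
    band_source(n, cfg$fs, sp$band, sp$lag))
  for (t in seq_len(n_steps)) {
    sname <- hidden[t]
    sp <- states[[sname]]
    i0 <- (t - 1L) * step_len + 1L
    i1 <- min(t * step_len, n)
    amp <- sqrt(sp$coupling_snr * bg_bp[sname])
    lead_ch <- if (sp$pair == "fpf") rg$prefrontal else rg$frontal
    lag_ch <- if (sp$pair == "fpf") rg$frontal else rg$parietal
    seg <- i0:i1
    for (c1 in match(lead_ch, ch))
      x[c1, seg] <- x[c1, seg] + amp * src[[sname]]$lead[seg]
    for (c2 in match(lag_ch, ch))
      x[c2, seg] <- x[c2, seg] + amp * src[[sname]]$lag[seg]
  }
  if (cfg$zero_lag_strength > 0) {
    common <- band_source(n, cfg$fs, c(8, 12), pi / 2)$lead
    x <- x + sqrt(cfg$zero_lag_strength) * matrix(common, nrow(x), n,
                                                  byrow = TRUE)
  }
  rec <- recording(meta$subject_id, cfg$fs, ch, x,
                   events = data.frame(label = c("incision", "maintenance_end"),
                                       time = c(0, n / cfg$fs)))
  list(recording = rec, ground_truth = gt)
}

#' Generate a synthetic cohort
#'
#' Ages are drawn uniformly over `age_range`; the nitrous flag and the
#' age-adjusted MAC multiple are drawn independently of age (non-confounding
#' by default). Per-subject seeds derive deterministically from `cfg$seed`.
#'
#' @param cfg a [cohort_config].
#' @param states list of [state_spec]s.
#' @param signals if `FALSE`, skip EEG synthesis (ground truth only).
#' @return list with `recordings`, `metas`, `ground_truths` (parallel lists).
#' @export
generate_cohort <- function(cfg = cohort_config(), states = state_specs(),
                            signals = TRUE) {
  set.seed(derive_seed(cfg$seed, "cohort-covariates"))
  n <- cfg$n_subjects
  ids <- sprintf("sub%03d", seq_len(n))
  ages <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  nitrous <- stats::runif(n) < 0.3
  mac <- pmax(0.4, stats::rnorm(n, mean = 1.0, sd = 0.15))
  mac40 <- mac40_table()
  metas <- lapply(seq_len(n), function(i) {
    # end-tidal sevoflurane consistent with the drawn MAC multiple, so that
    # mac_age_adjusted() recomputes it exactly
    frac <- mac[i] * mac40[["sevoflurane"]] * 10^(-0.00269 * (ages[i] - 40))
    subject_meta(ids[i], ages[i], nitrous[i],
                 c(sevoflurane = frac), mac_age_adjusted = mac[i])
  })
  out <- lapply(seq_len(n), function(i)
    generate_subject(metas[[i]], states, cfg,
                     seed = derive_seed(cfg$seed, ids[i], "synth"),
                     signals = signals))
  list(recordings = lapply(out, `[[`, "recording"),
       metas = metas,
       ground_truths = lapply(out, `[[`, "ground_truth"))
}

#' Hidden-state label for each analysis window
#'
#' Maps ground-truth dwell-step labels onto the 30-s/10-s analysis window
#' grid: each window gets the state occupying the majority of its span
#' (earliest on a tie).
#'
#' @param gt a ground-truth object from [generate_subject()].
#' @param epoch_duration epoch length in seconds.
#' @param grid a [window_grid].
#' @return character vector, one label per analysis window.
#' @export
window_truth <- function(gt, epoch_duration, grid = window_grid()) {
  n_win <- floor((epoch_duration - grid$window_len) / grid$step) + 1
  dwell <- gt$dwell_sec
  vapply(seq_len(n_win), function(w) {
    t0 <- (w - 1) * grid$step
    tt <- seq(t0 + 0.5, t0 + grid$window_len - 0.5, by = 1)
    idx <- pmin(floor(tt / dwell) + 1, length(gt$hidden_states))
    names(which.max(table(factor(gt$hidden_states[idx],
                                 levels = unique(gt$hidden_states[idx])))))
  }, character(1))
}
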