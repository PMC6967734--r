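canonical_states <- function() paste0("S", 1:5)

seq_labels <- function(seq) {
  if (inherits(seq, "state_sequence") || is.data.frame(seq)) seq$label
  else as.character(seq)
}

#' Occurrence rate per connectivity state
#'
#' Fraction of maintenance time (analysis windows) a subject spends in each
#' state. Unobserved named states are reported as 0; "suppressed" appears
#' only when present, and counts toward total time.
#'
#' @param seq a `state_sequence` (or character label vector).
#' @param state_names states to always report.
#' @return named numeric vector of fractions summing to 1.
#' @export
occurrence_rate <- function(seq, state_names = canonical_states()) {
  lab <- seq_labels(seq)
  if (!length(lab)) stopf("data error: empty state sequence")
  lev <- union(state_names, unique(lab))
  tab <- table(factor(lab, levels = lev))
  stats::setNames(as.numeric(tab) / length(lab), lev)
}

#' Empirical Markov transition matrix
#'
#' T[i, j] is the fraction of windows in state i whose immediate successor
#' (one analysis step later) is state j; self-transitions included. Pairs
#' straddling a suppressed window are not counted (the Markov assumption
#' concerns consecutive observations). Rows with no outgoing observations
#' are left as NA and flagged in the `undefined_rows` attribute.
#'
#' @param seq a `state_sequence` (or character label vector).
#' @param state_names states indexing the matrix.
#' @return row-stochastic matrix with attribute `undefined_rows`.
#' @export
transition_matrix <- function(seq, state_names = canonical_states()) {
  lab <- seq_labels(seq)
  if (length(lab) < 2) stopf("data error: need >= 2 windows")
  lev <- union(state_names, setdiff(unique(lab), "suppressed"))
  a <- lab[-length(lab)]; b <- lab[-1]
  ok <- a != "suppressed" & b != "suppressed"
  counts <- table(factor(a[ok], levels = lev), factor(b[ok], levels = lev))
  counts <- matrix(as.numeric(counts), length(lev), length(lev),
                   dimnames = list(lev, lev))
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  attr(P, "undefined_rows") <- lev[rs == 0]
  P
}

#' Global state transition probability
#'
#' Number of transitions between distinct connectivity states divided by
#' total maintenance time, measured in analysis-window steps (so a constant
#' sequence scores 0). Transitions into or out of "suppressed" do not count
#' as distinct-state transitions, but suppressed windows do count toward
#' time.
#'
#' @param seq a `state_sequence` (or character label vector).
#' @param denominator `"length"` (default; per-step rate) or
#'   `"length_minus_1"`.
#' @return fraction in [0, 1].
#' @export
global_transition_probability <- function(seq,
                                          denominator = c("length",
                                                          "length_minus_1")) {
  denominator <- match.arg(denominator)
  lab <- seq_labels(seq)
  if (length(lab) < 2) stopf("data error: need >= 2 windows")
  a <- lab[-length(lab)]; b <- lab[-1]
  n_trans <- sum(a != b & a != "suppressed" & b != "suppressed")
  den <- if (denominator == "length") length(lab) else length(lab) - 1L
  n_trans / den
}

#' Per-subject dynamics summary
#'
#' @param seq a `state_sequence`.
#' @param state_names states to report.
#' @return list with `subject_id`, `occurrence`, `transition_matrix`,
#'   `global_transition_probability`.
#' @export
dynamics_summary <- function(seq, state_names = canonical_states()) {
  sid <- if (is.data.frame(seq)) seq$subject_id[1] else "unknown"
  list(subject_id = sid,
       occurrence = occurrence_rate(seq, state_names),
       transition_matrix = transition_matrix(seq, state_names),
       global_transition_probability = global_transition_probability(seq))
}

#' Cohort dynamics table
#'
#' One row per subject: occurrence rates (`occ_S1`..), `gtp`, and the
#' flattened transition matrix (`T_S1_S1`, `T_S1_S2`, ...).
#'
#' @param seqs list of `state_sequence` objects.
#' @param state_names states to report.
#' @return data frame.
#' @export
cohort_dynamics <- function(seqs, state_names = canonical_states()) {
  rows <- lapply(seqs, function(s) {
    d <- dynamics_summary(s, state_names)
    occ <- unname(d$occurrence[state_names])
    supp <- if ("suppressed" %in% names(d$occurrence))
      d$occurrence[["suppressed"]] else 0
    Tm <- d$transition_matrix[state_names, state_names]
    tv <- as.numeric(t(Tm))
    names(tv) <- paste0("T_", rep(state_names, each = length(state_names)),
                        "_", rep(state_names, length(state_names)))
    cbind(data.frame(subject_id = d$subject_id),
          as.data.frame(t(stats::setNames(occ, paste0("occ_", state_names)))),
          data.frame(occ_suppressed = supp,
                     gtp = d$global_transition_probability),
          as.data.frame(t(tv)))
  })
  do.call(rbind, rows)
}
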