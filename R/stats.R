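#' Normality-routed correlation with age
#'
#' The distribution of each variable is assessed with the Shapiro-Wilk test;
#' if either rejects normality (p < `alpha_normality`) the association is
#' measured with Spearman's rank-order correlation, otherwise with Pearson
#' correlation. Two-sided p-values throughout.
#'
#' @param x,y paired per-subject values.
#' @param alpha_normality Shapiro-Wilk rejection threshold (default 0.05).
#' @param alpha_adjusted significance threshold recorded in the result
#'   (e.g. a Bonferroni-adjusted alpha).
#' @param variable label for the result row.
#' @return one-row data frame: `variable`, `method`, `coefficient`,
#'   `p_value`, `n`, `alpha_adjusted`, `significant`.
#' @export
route_correlation <- function(x, y, alpha_normality = 0.05,
                              alpha_adjusted = 0.05, variable = "x~y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stopf("data error: need >= 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined-correlation error: constant variable in '%s'", variable)
  swp <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  method <- if (any(swp < alpha_normality)) "spearman" else "pearson"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  data.frame(variable = variable, method = method,
             coefficient = unname(ct$estimate), p_value = ct$p.value,
             n = length(x), alpha_adjusted = alpha_adjusted,
             significant = ct$p.value < alpha_adjusted)
}

#' Bonferroni-adjusted per-test alpha
#' @param alpha_family family-wise error level (default 0.05).
#' @param m number of simultaneous tests.
#' @return per-test threshold `alpha_family / m`.
#' @export
bonferroni_alpha <- function(alpha_family = 0.05, m) {
  if (m < 1) stopf("config error: m must be >= 1")
  alpha_family / m
}

#' Benjamini-Hochberg step-up decision at FDR level q
#'
#' Sorts the p-values ascending, finds the largest rank i with
#' p_(i) <= i q / m, and declares every test at or below that rank
#' significant. The critical value is 0 when none pass.
#'
#' @param p_values named numeric vector of p-values in [0, 1].
#' @param q false-discovery-rate level (default 0.20).
#' @return list of class `fdr_decision`: `p_values`, `q`, `critical_value`,
#'   `significant` (names of significant tests).
#' @export
benjamini_hochberg <- function(p_values, q = 0.20) {
  p <- p_values[!is.na(p_values)]
  if (any(p < 0 | p > 1)) stopf("data error: p-values outside [0, 1]")
  m <- length(p)
  if (is.null(names(p))) names(p) <- paste0("test", seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= seq_len(m) * q / m)
  crit <- if (length(pass)) ps[max(pass)] else 0
  sig <- if (length(pass)) names(ps)[seq_len(max(pass))] else character()
  structure(list(p_values = p, q = q, critical_value = unname(crit),
                 significant = sig),
            class = "fdr_decision")
}

#' Covariate-adjusted regression of an outcome on age
#'
#' Ordinary least squares of the standardized (z-scored) outcome on
#' standardized age plus standardized covariates; reports the standardized
#' age coefficient with its 95% t-based confidence interval and two-sided
#' p-value.
#'
#' @param outcome per-subject outcome values.
#' @param age per-subject ages.
#' @param covariates optional per-subject covariate matrix or data frame.
#' @param outcome_name label for the result row.
#' @return one-row data frame: `outcome`, `beta_age`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `covariates`.
#' @export
adjusted_regression <- function(outcome, age, covariates = NULL,
                                outcome_name = "outcome") {
  z <- function(v) {
    if (stats::sd(v) == 0) stopf("collinearity error: constant predictor")
    (v - mean(v)) / stats::sd(v)
  }
  df <- data.frame(y = z(outcome), age = z(age))
  cov_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    for (nm in cov_names) df[[nm]] <- z(as.numeric(covariates[[nm]]))
  }
  if (nrow(df) <= ncol(df) + 1)
    stopf("data error: n must exceed number of predictors + 1")
  X <- as.matrix(df[-1])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stopf("collinearity error: rank-deficient design")
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "age", level = 0.95)
  data.frame(outcome = outcome_name, beta_age = sm["age", "Estimate"],
             ci_low = ci[1], ci_high = ci[2],
             p_value = sm["age", "Pr(>|t|)"], n = nrow(df),
             covariates = paste(cov_names, collapse = "+"))
}

#' MAC-40 reference concentrations
#'
#' End-tidal concentration (vol%) equal to one MAC at age 40, per agent.
#' Shipped as an editable table in `extdata/mac40.csv`.
#'
#' @param path optional path to an alternative table (columns `agent`,
#'   `mac40`).
#' @return named numeric vector.
#' @export
mac40_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mac40.csv", package = "conndyn")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$mac40, tab$agent)
}

#' Age-adjusted MAC multiple
#'
#' Anesthetic depth as a dimensionless multiple of the age-adjusted minimum
#' alveolar concentration: MAC(age) = MAC40 * 10^(-0.00269 (age - 40)) per
#' agent, summed additively across agents (including nitrous oxide).
#'
#' @param agent_fractions named end-tidal fractions (vol%) per agent.
#' @param age age in years.
#' @param mac40 named MAC-40 reference table (defaults to [mac40_table()]).
#' @return dimensionless MAC multiple.
#' @export
mac_age_adjusted <- function(agent_fractions, age, mac40 = mac40_table()) {
  if (any(agent_fractions < 0)) stopf("metadata error: negative fraction")
  unknown <- setdiff(names(agent_fractions), names(mac40))
  if (length(unknown))
    stopf("table-lookup error: unknown agent(s): %s",
          paste(unknown, collapse = ", "))
  mac_age <- mac40[names(agent_fractions)] * 10^(-0.00269 * (age - 40))
  sum(agent_fractions / mac_age)
}

#' Cohort statistics layer
#'
#' Runs the full association analysis of state dynamics with age:
#' (a) global transition probability vs age; (b) the four occurrence-rate
#' correlations (S1, S2, S4, S5) against the Bonferroni-adjusted alpha
#' (family level / 4 = 0.0125 at the default 0.05); (c) covariate-adjusted
#' regressions for every Bonferroni-significant occurrence rate (covariate:
#' age-adjusted MAC multiple; plus the nitrous flag for S1); (d) the 4x4
#' matrix of transition-probability correlations with age (self-transitions
#' included), controlled by Benjamini-Hochberg at `fdr_q`. S3 is not part
#' of the association analysis.
#'
#' @param dynamics_table cohort table from [cohort_dynamics()].
#' @param meta_table cohort metadata (subject_id, age, nitrous, mac).
#' @param family_alpha family-wise level for the occurrence tests.
#' @param fdr_q FDR level for the transition matrix.
#' @param occ_states occurrence-rate states analysed.
#' @return list of class `stats_report`: `gtp`, `occurrence`, `regressions`,
#'   `transitions`, `fdr`.
#' @export
run_statistics <- function(dynamics_table, meta_table, family_alpha = 0.05,
                           fdr_q = 0.20,
                           occ_states = c("S1", "S2", "S4", "S5")) {
  need <- c("subject_id", "age", "nitrous", "mac")
  missing <- setdiff(need, names(meta_table))
  if (length(missing))
    stopf("schema error: metadata lacks column(s): %s",
          paste(missing, collapse = ", "))
  dat <- merge(dynamics_table, meta_table, by = "subject_id")
  if (nrow(dat) < 4) stopf("data error: need >= 4 subjects after join")

  # degenerate variables (e.g. a state never visited in a small cohort)
  # yield an explicit NA row instead of aborting the whole report
  safe_cor <- function(x, y, variable, alpha_adjusted = family_alpha) {
    tryCatch(route_correlation(x, y, alpha_adjusted = alpha_adjusted,
                               variable = variable),
             error = function(e)
               data.frame(variable = variable, method = NA_character_,
                          coefficient = NA_real_, p_value = NA_real_,
                          n = sum(is.finite(x) & is.finite(y)),
                          alpha_adjusted = alpha_adjusted,
                          significant = NA))
  }

  gtp <- safe_cor(dat$age, dat$gtp, "gtp~age")

  a_bon <- bonferroni_alpha(family_alpha, length(occ_states))
  occ <- do.call(rbind, lapply(occ_states, function(s)
    safe_cor(dat$age, dat[[paste0("occ_", s)]],
             variable = paste0("occ_", s, "~age"),
             alpha_adjusted = a_bon)))

  regressions <- NULL
  for (s in occ_states[which(occ$significant)]) {
    covs <- data.frame(mac = dat$mac)
    if (s == "S1") covs$nitrous <- as.numeric(dat$nitrous)
    regressions <- rbind(regressions,
                         adjusted_regression(dat[[paste0("occ_", s)]],
                                             dat$age, covs,
                                             outcome_name = paste0("occ_", s)))
  }

  cells <- expand.grid(from = occ_states, to = occ_states,
                       stringsAsFactors = FALSE)
  trans <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    col <- paste0("T_", cells$from[i], "_", cells$to[i])
    v <- dat[[col]]
    ok <- is.finite(v)          # subjects with no outgoing obs drop pairwise
    safe_cor(dat$age[ok], v[ok], paste0(col, "~age"))
  }))
  fdr <- benjamini_hochberg(stats::setNames(trans$p_value, trans$variable),
                            q = fdr_q)
  trans$significant <- trans$variable %in% fdr$significant

  structure(list(gtp = gtp, occurrence = occ, regressions = regressions,
                 transitions = trans, fdr = fdr),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Global transition probability vs age:\n")
  print(x$gtp, row.names = FALSE)
  cat("\nOccurrence rates vs age (Bonferroni alpha =",
      format(x$occurrence$alpha_adjusted[1]), "):\n")
  print(x$occurrence, row.names = FALSE)
  if (!is.null(x$regressions)) {
    cat("\nAdjusted regressions (standardized beta):\n")
    print(x$regressions, row.names = FALSE)
  }
  cat(sprintf("\nTransition matrix vs age: %d/%d cells BH-significant (q = %g, critical p = %g)\n",
              length(x$fdr$significant), nrow(x$transitions), x$fdr$q,
              x$fdr$critical_value))
  invisible(x)
}
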