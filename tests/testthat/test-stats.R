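test_that("correlation routing follows Shapiro-Wilk on either variable", {
  set.seed(1)
  x <- rnorm(40)
  res <- route_correlation(x, 2 * x + 1, variable = "linear")
  expect_identical(res$method, "pearson")
  expect_equal(res$coefficient, 1)
  # heavy-tailed outlier flips the route to Spearman
  y <- x; y[1] <- 40
  res2 <- route_correlation(x, y)
  expect_identical(res2$method, "spearman")
  # strictly monotone nonlinear map: Spearman rho = 1 once routed there
  xm <- c(rnorm(39), 12)
  res3 <- route_correlation(xm, exp(xm))
  expect_identical(res3$method, "spearman")
  expect_equal(res3$coefficient, 1)
  expect_error(route_correlation(rep(1, 10), rnorm(10)),
               "undefined-correlation")
  expect_error(route_correlation(1:3, 1:3), "data error")
})

test_that("spearman coefficient matches the closed-form rank formula", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 12
    x <- sample(100, n)            # distinct values: no ties
    y <- sample(100, n)
    d <- rank(x) - rank(y)
    rho_formula <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    got <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(unname(got$estimate), rho_formula)
    expect_equal(cor(x, y, method = "spearman"), rho_formula)
  }
})

test_that("bonferroni threshold is the family alpha split across tests", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_identical(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "config error")
})

test_that("BH step-up matches a brute-force oracle on random instances", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    best <- 0
    for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) best <- i
    if (best == 0) character() else names(p)[ord[seq_len(best)]]
  }
  # boundary examples
  d1 <- benjamini_hochberg(c(a = 0.01), q = 0.2)
  expect_identical(d1$significant, "a")
  p16 <- stats::setNames(c(0.001, seq(0.8, 0.99, length.out = 15)),
                         paste0("t", 1:16))
  d2 <- benjamini_hochberg(p16, q = 0.2)
  expect_identical(d2$significant, "t1")
  expect_equal(d2$critical_value, 0.001)
  d0 <- benjamini_hochberg(c(a = 0.9, b = 0.95), q = 0.2)
  expect_identical(d0$significant, character())
  expect_equal(d0$critical_value, 0)
  # 100 random instances vs the exhaustive loop
  set.seed(7)
  for (rep in 1:100) {
    m <- sample(3:25, 1)
    p <- stats::setNames(round(runif(m), 3), paste0("t", seq_len(m)))
    q <- sample(c(0.05, 0.1, 0.2), 1)
    got <- benjamini_hochberg(p, q)
    expect_setequal(got$significant, bh_oracle(p, q))
  }
})

test_that("adjusted regression recovers self, nulls, and orthogonal covariates", {
  set.seed(11)
  age <- runif(45, 18, 80)
  r1 <- suppressWarnings(adjusted_regression(age, age))
  expect_equal(r1$beta_age, 1)
  expect_true(r1$ci_low <= 1 + 1e-9 && 1 - 1e-9 <= r1$ci_high)
  # outcome equal to a covariate orthogonal to age
  cov1 <- rnorm(45)
  cov1 <- residuals(lm(cov1 ~ age))          # exactly orthogonal
  r2 <- suppressWarnings(adjusted_regression(cov1, age,
                                             data.frame(c1 = cov1)))
  expect_lt(abs(r2$beta_age), 1e-8)
  expect_error(adjusted_regression(rnorm(45), age,
                                   data.frame(a2 = age)), "collinearity")
  expect_error(adjusted_regression(1:3, c(20, 30, 40)), "data error")
})

test_that("null outcomes give near-zero standardized betas at n = 45", {
  set.seed(13)
  hits <- 0
  for (rep in 1:40) {
    age <- runif(45, 18, 80)
    out <- rnorm(45)
    r <- adjusted_regression(out, age)
    if (abs(r$beta_age) >= 0.3) hits <- hits + 1
  }
  expect_lte(hits, 2)      # |beta| < 0.3 holds ~95% of the time under null
})

test_that("MAC multiples follow the age-adjusted potency relation", {
  m40 <- mac40_table()
  expect_true(all(c("sevoflurane", "isoflurane", "nitrous") %in% names(m40)))
  expect_equal(mac_age_adjusted(c(sevoflurane = m40[["sevoflurane"]]), 40), 1)
  two <- c(sevoflurane = m40[["sevoflurane"]] / 2,
           isoflurane = m40[["isoflurane"]] / 2)
  expect_equal(mac_age_adjusted(two, 40), 1)
  frac <- c(sevoflurane = 1.0)
  ratio <- mac_age_adjusted(frac, 80) / mac_age_adjusted(frac, 40)
  expect_equal(ratio, 10^(0.00269 * 40), tolerance = 1e-12)
  expect_error(mac_age_adjusted(c(xenon = 1), 40), "table-lookup")
})

test_that("adjustment shrinks a MAC-confounded age association toward zero", {
  set.seed(17)
  n <- 45
  age <- runif(n, 18, 80)
  mac <- 0.6 + 0.008 * age + rnorm(n, sd = 0.05)   # MAC tracks age
  outcome <- 2 * mac + rnorm(n, sd = 0.1)          # outcome depends on MAC only
  unadj <- cor(age, outcome)
  adj <- adjusted_regression(outcome, age, data.frame(mac = mac))
  expect_gt(abs(unadj), 0.5)
  expect_lt(abs(adj$beta_age), abs(unadj) / 2)
})

test_that("the statistics layer reports the full association analysis set", {
  set.seed(19)
  cfg <- cohort_config(n_subjects = 45, epoch_duration = 1200, seed = 23)
  coh <- generate_cohort(cfg, signals = FALSE)
  seqs <- lapply(coh$ground_truths, function(g) {
    structure(data.frame(subject_id = g$subject_id,
                         window_index = seq_along(g$hidden_states),
                         t_center = NA_real_, label = g$hidden_states),
              class = c("state_sequence", "data.frame"))
  })
  dyn <- cohort_dynamics(seqs)
  meta <- meta_table(coh$metas)
  rep <- run_statistics(dyn, meta)
  expect_s3_class(rep, "stats_report")
  expect_equal(nrow(rep$occurrence), 4)
  expect_equal(rep$occurrence$alpha_adjusted, rep(0.0125, 4))
  expect_equal(nrow(rep$transitions), 16)
  # planted effects carry the right signs
  s1 <- rep$occurrence[rep$occurrence$variable == "occ_S1~age", ]
  s4 <- rep$occurrence[rep$occurrence$variable == "occ_S4~age", ]
  expect_lt(s1$coefficient, 0)
  expect_gt(s4$coefficient, 0)
  # regressions only follow Bonferroni-significant occurrence tests,
  # and S1's regression includes the nitrous covariate
  if (!is.null(rep$regressions) && "occ_S1" %in% rep$regressions$outcome) {
    r <- rep$regressions[rep$regressions$outcome == "occ_S1", ]
    expect_match(r$covariates, "nitrous")
  }
  expect_error(run_statistics(dyn, meta[, c("subject_id", "age")]),
               "schema error")
})
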