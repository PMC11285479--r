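# Small synthetic metrics/skew tables for assemble_table tests.
make_metrics_skew <- function(n = 25, seed = 99) {
  set.seed(seed)
  metrics <- data.frame(
    group_id = paste0("g", 1:n),
    colony = sample(paste0("c", 1:3), n, replace = TRUE),
    year = sample(2003:2013, n, replace = TRUE),
    n_females = sample(3:11, n, replace = TRUE),
    grc = stats::runif(n),
    h_prime = stats::runif(n, 0.1, 1),
    stringsAsFactors = FALSE)
  skew <- data.frame(
    group_id = metrics$group_id, year = metrics$year,
    m_index = stats::rnorm(n, 1, 0.9), stringsAsFactors = FALSE)
  list(metrics = metrics, skew = skew)
}

test_that("assembled analysis columns are standardised and joins drop
           incomplete groups", {
  ms <- make_metrics_skew()
  tab <- assemble_table(ms$metrics, ms$skew)
  expect_equal(nrow(tab), 25L)
  for (col in c("m_std", "grc_ls", "hprime_ls", "gsize_ls")) {
    expect_lt(abs(mean(tab[[col]])), 1e-10)
    expect_equal(stats::sd(tab[[col]]), 1)
  }
  # a group with no skew result is excluded by the join
  tab2 <- assemble_table(ms$metrics, ms$skew[-1, ])
  expect_equal(nrow(tab2), 24L)
  expect_false("g1" %in% tab2$group_id)
})

test_that("zero GRC values get the half-minimum offset before the log", {
  ms <- make_metrics_skew(n = 10)
  ms$metrics$grc[1] <- 0
  tab <- assemble_table(ms$metrics, ms$skew[1:10, ])
  expect_true(all(is.finite(tab$grc_ls)))
  # the zero-GRC group sits strictly below every positive-GRC group
  expect_equal(tab$group_id[which.min(tab$grc_ls)], "g1")
})

test_that("degenerate assembly inputs are refused", {
  ms <- make_metrics_skew(n = 6)
  expect_error(assemble_table(ms$metrics[1:2, ], ms$skew), "fewer than 3")
  ms$metrics$grc <- 0.5 # constant predictor
  expect_error(assemble_table(ms$metrics, ms$skew), "constant column")
})

test_that("with random-effect variances forced to zero the mixed model
           collapses exactly to OLS", {
  rows <- simulate_group_years(n = 60, beta_grc = 0.5, beta_hprime = 0.2,
                               seed = 12)
  fit <- suppressWarnings(fit_skew_model(rows))
  # evaluate the same model at theta = 0 (both variance components zero)
  at_zero <- suppressMessages(update(
    fit$fit, start = list(theta = c(0, 0)),
    control = lme4::lmerControl(optimizer = NULL, calc.derivs = FALSE)))
  ols <- stats::lm(m_std ~ grc_ls + hprime_ls + gsize_ls, data = rows)
  expect_equal(unname(lme4::fixef(at_zero)), unname(stats::coef(ols)),
               tolerance = 1e-10)
  vc <- as.data.frame(lme4::VarCorr(at_zero))
  expect_equal(vc$vcov[vc$grp != "Residual"], c(0, 0))
  # and the R2 identity follows: conditional equals marginal at theta = 0
  r2 <- nakagawa_r2(at_zero)
  expect_equal(r2[["conditional"]], r2[["marginal"]])
})

test_that("the fitted GRC coefficient recovers the simulation truth", {
  covered <- 0
  for (r in 1:20) {
    rows <- simulate_group_years(n = 200, beta_grc = 0.6, seed = 500 + r)
    fit <- suppressWarnings(fit_skew_model(rows))
    co <- fit$coefficients["grc_ls", ]
    if (abs(co$estimate - 0.6) < 1.96 * co$se) covered <- covered + 1
  }
  expect_gte(covered, 17) # nominal 95% coverage, binomial slack
})

test_that("p-value flavours agree in direction and Satterthwaite is optional", {
  skip_if_not_installed("lmerTest")
  rows <- simulate_group_years(n = 80, beta_grc = 0.6, seed = 77)
  wald <- suppressWarnings(fit_skew_model(rows, pvalues = "wald"))
  satt <- suppressWarnings(fit_skew_model(rows, pvalues = "satterthwaite"))
  expect_equal(satt$coefficients$estimate, wald$coefficients$estimate,
               tolerance = 1e-6)
  # t-based p-values are never smaller than Wald-z ones
  expect_true(all(satt$coefficients$p >= wald$coefficients$p - 1e-12))
})

test_that("marginal and conditional R2 satisfy their identities and recover
           planted variance shares", {
  # no random variance: conditional equals marginal
  rows0 <- simulate_group_years(n = 60, beta_grc = 0.5, colony_sd = 0,
                                year_sd = 0, seed = 21)
  fit0 <- suppressWarnings(fit_skew_model(rows0))
  expect_equal(fit0$r2_conditional, fit0$r2_marginal, tolerance = 1e-6)
  # intercept-only model explains no fixed-effect variance
  rowsn <- simulate_group_years(n = 50, beta_grc = 0, seed = 22)
  rowsn$one <- 0
  fitn <- suppressWarnings(
    lme4::lmer(m_std ~ 1 + (1 | colony) + (1 | year_f), data = rowsn))
  expect_equal(unname(nakagawa_r2(fitn)[["marginal"]]), 0, tolerance = 1e-10)
  # planted shares: beta = 0.6, sds (0.4, 0.4, 0.7) over many levels
  rows <- simulate_group_years(n = 500, beta_grc = 0.6, n_colonies = 15,
                               n_years = 15, seed = 23)
  fit <- suppressWarnings(fit_skew_model(rows, fixed = "grc_ls"))
  tot <- 0.6^2 + 0.4^2 + 0.4^2 + 0.7^2
  expect_lt(abs(fit$r2_marginal - 0.6^2 / tot), 0.05)
  expect_lt(abs(fit$r2_conditional - (0.6^2 + 0.32) / tot), 0.05)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("semi-partial R2 isolates each predictor's contribution", {
  rows <- simulate_group_years(n = 150, beta_grc = 0.6, beta_hprime = 0.4,
                               seed = 31)
  fit <- suppressWarnings(fit_skew_model(rows))
  sp <- suppressWarnings(semi_partial_r2(fit, n_boot = 40, seed = 5))
  # independently simulated predictors are near-orthogonal: parts add up
  # (exact orthogonality is exercised in the acceptance suite)
  parts <- sp$part_r2[sp$term %in% fit$fixed]
  full <- sp$part_r2[sp$term == "full_model"]
  expect_lt(abs(sum(parts) - full), 0.06)
  # the null predictor contributes nothing and its CI covers 0
  null_row <- sp[sp$term == "gsize_ls", ]
  expect_lt(null_row$part_r2, 0.03)
  expect_lte(null_row$ci_lower, 0.005)
  # seeded bootstrap is reproducible
  sp2 <- suppressWarnings(semi_partial_r2(fit, n_boot = 40, seed = 5))
  expect_identical(sp, sp2)
})

test_that("AICc equals AIC plus the closed-form correction and penalises
           noise predictors on average", {
  rows <- simulate_group_years(n = 40, beta_grc = 0.6, seed = 41)
  fit <- suppressWarnings(fit_skew_model(rows))
  k <- attr(stats::logLik(fit$fit_ml), "df")
  n <- nrow(rows)
  expect_equal(fit$aicc - stats::AIC(fit$fit_ml), 2 * k * (k + 1) / (n - k - 1))
  # adding a pure-noise predictor raises AICc more often than not
  worse <- 0
  for (r in 1:20) {
    d <- simulate_group_years(n = 40, beta_grc = 0.6, seed = 600 + r)
    base <- suppressWarnings(fit_skew_model(d, fixed = "grc_ls"))
    noisy <- suppressWarnings(fit_skew_model(d, fixed = c("grc_ls", "hprime_ls")))
    if (noisy$aicc > base$aicc) worse <- worse + 1
  }
  expect_gte(worse, 13)
})

test_that("VIF is 1 for single or orthogonal predictors and flags collinear
           designs", {
  rows <- simulate_group_years(n = 100, seed = 51)
  expect_equal(unname(vif_fixed(rows, "grc_ls")), 1)
  # exactly orthogonalised pair
  rows$ortho <- stats::residuals(stats::lm(hprime_ls ~ grc_ls, data = rows))
  v <- vif_fixed(rows, c("grc_ls", "ortho"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  rows$dup <- rows$grc_ls
  expect_warning(vc <- vif_fixed(rows, c("grc_ls", "dup")), "singular")
  expect_true(all(vc >= 1e6 - 1))
  # VIFs always >= 1
  v3 <- vif_fixed(rows, c("grc_ls", "hprime_ls", "gsize_ls"))
  expect_true(all(v3 >= 1 - 1e-10))
})

test_that("VIF agrees with the standard regression-based definition", {
  skip_if_not_installed("car")
  rows <- simulate_group_years(n = 80, seed = 61)
  rows$corr <- 0.7 * rows$grc_ls + 0.5 * stats::rnorm(80)
  lmfit <- stats::lm(m_std ~ grc_ls + hprime_ls + corr, data = rows)
  expect_equal(unname(vif_fixed(rows, c("grc_ls", "hprime_ls", "corr"))),
               unname(car::vif(lmfit)), tolerance = 1e-8)
})

test_that("the model ladder reports all four candidate structures", {
  ms <- make_metrics_skew()
  tab <- assemble_table(ms$metrics, ms$skew)
  ladder <- suppressWarnings(fit_model_ladder(tab))
  expect_setequal(ladder$comparison$model,
                  c("full", "grc_size", "hprime_size", "size_only"))
  expect_true(all(ladder$comparison$r2_conditional >=
                    ladder$comparison$r2_marginal - 1e-10))
  expect_s3_class(ladder$fits$full, "skew_lmm")
  # methods on the fitted object
  fit <- ladder$fits$full
  expect_length(coef(fit), 4L)
  expect_equal(length(residuals(fit)), nrow(tab))
  expect_equal(length(predict(fit)), nrow(tab))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(tab), 2L))
})

test_that("model fitting refuses inadequate inputs", {
  ms <- make_metrics_skew(n = 10)
  tab <- assemble_table(ms$metrics, ms$skew)
  expect_error(fit_skew_model(tab[1:2, ]), "at least 3")
  expect_error(fit_skew_model(tab, fixed = character(0)), "fixed effect")
  expect_error(fit_skew_model(tab, fixed = "not_a_column"), "not in data")
})
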