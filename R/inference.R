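#' Assemble the group-year analysis table
#'
#' Joins hierarchy metrics and skew results on (group_id, year), keeps only
#' groups for which GRC, h' and M are all defined, log-transforms the three
#' predictors (GRC, h', group size) and z-standardises everything, M
#' included, over the analysis set. GRC (and h') can legitimately be 0, so
#' before the log an offset of half the smallest positive observed value of
#' that column is added to its zeros (configurable via `log_offset`).
#'
#' @param metrics data frame with columns `group_id`, `colony`, `year`,
#'   `n_females`, `grc`, `h_prime` (one row per group-year, e.g. stacked
#'   [hierarchy_metrics()] output).
#' @param skew_results data frame from [skew_by_group()] (needs `group_id`,
#'   `year`, `m_index`).
#' @param log_offset offset added to zeros before the log transform; `NULL`
#'   (default) uses half the smallest positive value of each column.
#' @return A data frame with identifiers plus `m_std`, `grc_ls`,
#'   `hprime_ls`, `gsize_ls` (log-standardised) and `n_females`; at least 3
#'   rows or an error.
#' @export
assemble_table <- function(metrics, skew_results, log_offset = NULL) {
  tab <- merge(metrics, skew_results[, c("group_id", "year", "m_index")],
               by = c("group_id", "year"))
  tab <- tab[stats::complete.cases(tab[, c("grc", "h_prime", "m_index")]), ,
             drop = FALSE]
  if (nrow(tab) < 3) {
    stop("analysis table has fewer than 3 complete group-years; refusing to fit")
  }
  log_shift <- function(x) {
    if (any(x < 0)) stop("negative values cannot be log-transformed")
    if (any(x == 0)) {
      off <- log_offset %||% (min(x[x > 0]) / 2)
      if (!is.finite(off) || off <= 0) {
        stop("column is identically zero: log transform undefined")
      }
      x[x == 0] <- off
    }
    log(x)
  }
  zscore <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("constant column: standardisation undefined")
    (x - mean(x)) / s
  }
  tab$grc_ls <- zscore(log_shift(tab$grc))
  tab$hprime_ls <- zscore(log_shift(tab$h_prime))
  tab$gsize_ls <- zscore(log_shift(tab$n_females))
  tab$m_std <- zscore(tab$m_index)
  tab$colony <- factor(tab$colony)
  tab$year_f <- factor(tab$year)
  rownames(tab) <- NULL
  tab
}

#' Fit the group-level skew mixed model
#'
#' Fits a linear mixed model for standardised reproductive skew with crossed
#' random intercepts for colony and year:
#' `m_std ~ fixed effects + (1 | colony) + (1 | year)`. Estimates and
#' standard errors come from the REML fit; a maximum-likelihood refit of the
#' same model is kept for information-criterion comparison ([aicc()]).
#' Fixed-effect p-values are Wald z by default; Satterthwaite degrees of
#' freedom are available when the \pkg{lmerTest} package is installed.
#'
#' @param rows a group-year table from [assemble_table()] (or any data frame
#'   with the response, predictors and grouping factors).
#' @param fixed character vector of fixed-effect column names.
#' @param response response column name.
#' @param random character vector of grouping-factor column names for the
#'   random intercepts.
#' @param pvalues `"wald"` (default) or `"satterthwaite"`.
#' @return An object of class `"skew_lmm"`; see [summary.skew_lmm()]. A
#'   singular fit (a variance component estimated at zero) warns and
#'   reports the zero component rather than failing.
#' @export
fit_skew_model <- function(rows,
                           fixed = c("grc_ls", "hprime_ls", "gsize_ls"),
                           response = "m_std",
                           random = c("colony", "year_f"),
                           pvalues = c("wald", "satterthwaite")) {
  pvalues <- match.arg(pvalues)
  if (nrow(rows) < 3) stop("need at least 3 group-years to fit")
  if (length(fixed) < 1) stop("need at least one fixed effect")
  miss <- setdiff(c(response, fixed, random), names(rows))
  if (length(miss) > 0) stop("columns not in data: ", paste(miss, collapse = ", "))
  for (g in random) rows[[g]] <- factor(rows[[g]])
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
  fit <- lme4::lmer(fml, data = rows, REML = TRUE)
  fit_ml <- lme4::refitML(fit)
  if (lme4::isSingular(fit)) {
    warning("singular fit: at least one random-effect variance is estimated at 0")
  }

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  if (pvalues == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("pvalues = 'satterthwaite' needs the lmerTest package")
    }
    lt <- lmerTest::lmer(fml, data = rows, REML = TRUE)
    ct <- stats::coef(summary(lt))
    p <- ct[, "Pr(>|t|)"]
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  coefs <- data.frame(estimate = est, se = se, z = z, p = p)

  vc <- as.data.frame(lme4::VarCorr(fit))
  ranvar <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  r2 <- nakagawa_r2(fit)

  obj <- structure(list(
    fit = fit, fit_ml = fit_ml, formula = fml,
    coefficients = coefs, random_variances = ranvar,
    r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
    fixed = fixed, response = response, random = random,
    data = rows, pvalues = pvalues,
    call = match.call()
  ), class = "skew_lmm")
  obj$aicc <- tryCatch(aicc(obj), error = function(e) {
    warning("AICc not defined for this fit: ", conditionMessage(e))
    NA_real_
  })
  obj$vif <- vif_fixed(rows, fixed)
  obj
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-partitioning R-squared for a Gaussian mixed model: marginal
#' R-squared is the variance of the fixed-effect predictions over the total
#' (fixed + summed random-intercept variances + residual); conditional
#' R-squared adds the random-effect variances to the numerator, i.e. the
#' variance explained by fixed and random effects jointly.
#'
#' @param model a `skew_lmm` or a fitted `merMod`.
#' @return Named numeric vector `c(marginal =, conditional =)`.
#' @export
nakagawa_r2 <- function(model) {
  fit <- if (inherits(model, "skew_lmm")) model$fit else model
  x <- lme4::getME(fit, "X")
  var_fixed <- stats::var(as.vector(x %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- sum(vc$vcov[vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  tot <- var_fixed + var_rand + var_res
  c(marginal = var_fixed / tot, conditional = (var_fixed + var_rand) / tot)
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k + 1) / (n - k - 1)` with `k` the number of estimated
#' parameters (fixed effects + variance components + residual variance) and
#' `n` the number of rows. Computed from the maximum-likelihood fit, never
#' the REML fit, so models with different fixed effects are comparable.
#'
#' @param model a `skew_lmm` or an ML-fitted `merMod`.
#' @return AICc (error when `n <= k + 1`, where the correction blows up).
#' @export
aicc <- function(model) {
  fit <- if (inherits(model, "skew_lmm")) model$fit_ml else model
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n <= k + 1) stop("AICc undefined: n <= k + 1")
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Variance inflation factors of the fixed-effect design
#'
#' Computed from the correlation matrix of the fixed-effect columns:
#' `VIF_j = [R^-1]_jj`. A single predictor has VIF 1 by convention. A
#' numerically singular design (perfectly collinear predictors) is reported
#' as VIF capped at 1e6 with a warning rather than an error.
#'
#' @param rows data frame containing the predictors.
#' @param predictors character vector of predictor column names.
#' @return Named numeric vector of VIFs (all >= 1 up to rounding).
#' @export
vif_fixed <- function(rows, predictors) {
  if (length(predictors) == 1) return(stats::setNames(1, predictors))
  x <- as.matrix(rows[, predictors, drop = FALSE])
  r <- stats::cor(x)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(inv))) {
    warning("fixed-effect design is (near-)singular; VIF capped at 1e6")
    return(stats::setNames(rep(1e6, length(predictors)), predictors))
  }
  v <- pmin(diag(inv), 1e6)
  stats::setNames(v, predictors)
}

#' Semi-partial (part) R-squared per fixed effect
#'
#' Each predictor's contribution is the drop in marginal R-squared when that
#' predictor is removed from the full model:
#' `partR2_j = R2m(full) - R2m(full minus j)`. Confidence intervals come
#' from a parametric bootstrap: the response is simulated from the fitted
#' full model (new random effects and residuals each draw), the full and
#' every reduced model are refitted, and the part R-squared recomputed.
#' Iterations whose refit fails are skipped and counted (a warning is
#' issued when more than 10% are lost).
#'
#' @param model a `skew_lmm`.
#' @param n_boot parametric bootstrap iterations (the conventional choice
#'   here is 100).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return A data frame, one row per predictor plus one for the full model:
#'   `term`, `part_r2`, `ci_lower`, `ci_upper`, with attribute `"n_failed"`.
#' @export
semi_partial_r2 <- function(model, n_boot = 100L, seed = 1L, level = 0.95) {
  stopifnot(inherits(model, "skew_lmm"))
  fixed <- model$fixed
  rows <- model$data
  full_r2m <- unname(nakagawa_r2(model$fit)[["marginal"]])

  reduced_formula <- function(drop) {
    keep <- setdiff(fixed, drop)
    rhs <- if (length(keep) == 0) "1" else paste(keep, collapse = " + ")
    stats::as.formula(paste(
      model$response, "~", rhs, "+",
      paste(sprintf("(1 | %s)", model$random), collapse = " + ")))
  }
  reduced_fits <- lapply(fixed, function(f) {
    lme4::lmer(reduced_formula(f), data = rows, REML = TRUE)
  })
  point <- vapply(reduced_fits, function(rf) {
    full_r2m - unname(nakagawa_r2(rf)[["marginal"]])
  }, numeric(1))

  n_failed <- 0L
  boot <- with_seed(seed, {
    sims <- stats::simulate(model$fit, nsim = n_boot)
    res <- matrix(NA_real_, n_boot, length(fixed) + 1L)
    for (b in seq_len(n_boot)) {
      y <- sims[[b]]
      vals <- tryCatch({
        d <- rows
        d[[model$response]] <- y
        full_b <- suppressWarnings(suppressMessages(
          lme4::lmer(model$formula, data = d, REML = TRUE)))
        r2_full_b <- unname(nakagawa_r2(full_b)[["marginal"]])
        parts <- vapply(fixed, function(f) {
          red_b <- suppressWarnings(suppressMessages(
            lme4::lmer(reduced_formula(f), data = d, REML = TRUE)))
          r2_full_b - unname(nakagawa_r2(red_b)[["marginal"]])
        }, numeric(1))
        c(parts, r2_full_b)
      }, error = function(e) NULL)
      if (is.null(vals)) n_failed <- n_failed + 1L else res[b, ] <- vals
    }
    res
  })
  if (n_failed > 0.1 * n_boot) {
    warning(n_failed, " of ", n_boot, " bootstrap refits failed")
  }
  alpha <- (1 - level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(
    term = c(fixed, "full_model"),
    part_r2 = c(point, full_r2m),
    ci_lower = ci[1, ],
    ci_upper = ci[2, ],
    row.names = NULL)
  attr(out, "n_failed") <- n_failed
  out
}

#' Fit the standard model ladder
#'
#' Fits the four models used to judge which measure of social control
#' carries the signal: the full model (GRC + h' + group size), GRC + group
#' size, h' + group size, and group size alone, all with the same crossed
#' colony and year random intercepts, and tabulates AICc, marginal and
#' conditional R-squared for each.
#'
#' @param rows a group-year table from [assemble_table()].
#' @param ... passed to [fit_skew_model()].
#' @return An object of class `"skew_model_ladder"`: list of `skew_lmm`
#'   fits plus a `comparison` data frame.
#' @export
fit_model_ladder <- function(rows, ...) {
  specs <- list(
    full = c("grc_ls", "hprime_ls", "gsize_ls"),
    grc_size = c("grc_ls", "gsize_ls"),
    hprime_size = c("hprime_ls", "gsize_ls"),
    size_only = "gsize_ls")
  fits <- lapply(specs, function(fx) fit_skew_model(rows, fixed = fx, ...))
  comparison <- data.frame(
    model = names(specs),
    n_fixed = lengths(specs),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    r2_marginal = vapply(fits, `[[`, numeric(1), "r2_marginal"),
    r2_conditional = vapply(fits, `[[`, numeric(1), "r2_conditional"),
    row.names = NULL)
  structure(list(fits = fits, comparison = comparison, n = nrow(rows)),
            class = "skew_model_ladder")
}

#' @export
print.skew_model_ladder <- function(x, digits = 3, ...) {
  cat("Skew model ladder (", x$n, " group-years)\n\n", sep = "")
  print(format(x$comparison, digits = digits), row.names = FALSE)
  invisible(x)
}

# ---- skew_lmm methods -------------------------------------------------------

#' @export
print.skew_lmm <- function(x, digits = 3, ...) {
  cat("Group-level skew mixed model:",
      deparse(stats::formula(x$fit)), "\n")
  cat(sprintf("n = %d group-years; R2 marginal = %.3f, conditional = %.3f; AICc = %.2f\n\n",
              nrow(x$data), x$r2_marginal, x$r2_conditional, x$aicc))
  stats::printCoefmat(as.matrix(x$coefficients), digits = digits,
               P.values = TRUE, has.Pvalue = TRUE, cs.ind = 1:2, tst.ind = 3)
  invisible(x)
}

#' Summarise a fitted skew model
#'
#' @param object a `skew_lmm`.
#' @param ... unused.
#' @return The object, invisibly, after printing coefficients, random-effect
#'   variances, R-squared decomposition, AICc and VIFs.
#' @export
summary.skew_lmm <- function(object, ...) {
  print(object)
  cat("\nRandom-effect variances:\n")
  print(round(object$random_variances, 4))
  cat("\nVariance inflation factors:\n")
  print(round(object$vif, 2))
  invisible(object)
}

#' @export
coef.skew_lmm <- function(object, ...) lme4::fixef(object$fit)

#' @export
predict.skew_lmm <- function(object, newdata = NULL, re.form = NULL, ...) {
  if (is.null(newdata)) {
    stats::predict(object$fit, re.form = re.form, ...)
  } else {
    stats::predict(object$fit, newdata = newdata, re.form = re.form,
                   allow.new.levels = TRUE, ...)
  }
}

#' @export
residuals.skew_lmm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
simulate.skew_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Marginal-effect plot for one predictor
#'
#' Plots standardised skew against one standardised predictor with the
#' model's marginal effect line and a pointwise Wald 95% confidence band
#' (other predictors held at 0, their sample mean).
#'
#' @param x a `skew_lmm`.
#' @param predictor which fixed effect to display (default the first).
#' @param level confidence level for the band.
#' @param ... passed to [plot()].
#' @export
plot.skew_lmm <- function(x, predictor = x$fixed[1], level = 0.95, ...) {
  rows <- x$data
  xs <- seq(min(rows[[predictor]]), max(rows[[predictor]]), length.out = 100)
  nd <- as.data.frame(stats::setNames(
    lapply(x$fixed, function(f) if (f == predictor) xs else 0), x$fixed))
  X <- cbind(1, as.matrix(nd[, x$fixed, drop = FALSE]))
  beta <- lme4::fixef(x$fit)
  pred <- as.vector(X %*% beta)
  se <- sqrt(rowSums((X %*% as.matrix(stats::vcov(x$fit))) * X))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  graphics::plot(rows[[predictor]], rows[[x$response]],
                 xlab = predictor, ylab = x$response, pch = 19,
                 col = grDevices::adjustcolor("black", 0.6), ...)
  graphics::polygon(c(xs, rev(xs)), c(pred - zq * se, rev(pred + zq * se)),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(xs, pred, col = "steelblue", lwd = 2)
  invisible(x)
}
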