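#' Wilcoxon signed-rank test with continuity correction
#'
#' Paired test of whether `x` systematically exceeds `y`. Differences
#' `d = x - y` equal to zero are dropped before ranking (Wilcoxon's
#' convention); `|d|` is ranked with average ranks for ties; the statistic
#' `V` is the sum of ranks of positive differences. The p-value uses the
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends to
#'   exceed y) or `"less"`.
#' @return List of class `pullup_wilcoxon`: `V`, `z`, `p_value`, `n_pairs`,
#'   `n_nonzero`, `alternative`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[!is.na(d)]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("undefined: no nonzero differences")

  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) stop("undefined: zero variance (all ranks tied out)")
  sigma <- sqrt(sigma2)

  cc <- 0.5
  z <- switch(alternative,
    two.sided = (V - mu - sign(V - mu) * cc) / sigma,
    greater = (V - mu - cc) / sigma,
    less = (V - mu + cc) / sigma)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z))
  p <- min(1, p)

  structure(list(V = V, z = z, p_value = p, n_pairs = n_pairs,
                 n_nonzero = n, alternative = alternative),
            class = "pullup_wilcoxon")
}

#' @export
print.pullup_wilcoxon <- function(x, ...) {
  cat("Wilcoxon signed rank test with continuity correction\n")
  cat(sprintf("  V = %g, z = %.4f, p = %.4g (%s), n = %d (%d nonzero)\n",
              x$V, x$z, x$p_value, x$alternative, x$n_pairs, x$n_nonzero))
  invisible(x)
}

#' Logistic regression of a binary outcome
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]), reported with Wald standard errors and p-values and
#' with the fit statistics used throughout the unit tables: deviance
#' (`-2 logLik`), `AIC = deviance + 2k`, `BIC = deviance + k log n`.
#' Separation (a coefficient diverging with `|beta| > 15`) is flagged as
#' non-converged; estimates are still returned.
#'
#' @param outcome Binary 0/1 vector.
#' @param design Data frame of predictors (one column per term); an
#'   intercept is added automatically.
#' @return List of class `pullup_logit`: `coefficients` (data frame term /
#'   beta / se / p), `log_likelihood`, `deviance`, `aic`, `bic`, `n`,
#'   `converged`, and the underlying `glm` object as `fit`.
#' @export
fit_logistic <- function(outcome, design) {
  stopifnot(is.data.frame(design), nrow(design) == length(outcome))
  if (length(unique(outcome[!is.na(outcome)])) < 2) {
    stop("outcome has a single class; logistic fit undefined")
  }
  if (nrow(design) <= ncol(design) + 1) stop("more terms than observations")
  dat <- cbind(data.frame(.y = outcome), design)
  rhs <- if (ncol(design)) paste(names(design), collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))

  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      p = sm[, 4], row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit))
  n <- stats::nobs(fit)
  separated <- any(abs(stats::coef(fit)) > 15)
  if (separated) {
    warning("possible separation: |beta| > 15; fit flagged non-converged")
  }
  structure(list(coefficients = coefs,
                 log_likelihood = ll,
                 deviance = -2 * ll,
                 aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(n),
                 n = n,
                 converged = fit$converged && !separated,
                 fit = fit),
            class = "pullup_logit")
}

#' @export
print.pullup_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f)%s\n",
              x$n, x$log_likelihood, x$aic, x$bic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Full inferential analysis of one therapeutic-community unit
#'
#' Produces the per-unit reporting set: descriptive statistics, the two
#' Wilcoxon signed-rank tests of hierarchy climb (overall vs last-month
#' maximum and mean centrality), and four logistic regressions of
#' graduation — one per hierarchy measure, each with the shared controls
#' age, LSI-R, minority race and days in program. Residents flagged
#' incomplete are excluded from the regressions.
#'
#' @param summaries Hierarchy summary table from [summarize_all()].
#' @param roster Roster data frame.
#' @param small_n Threshold below which a small-sample warning is attached.
#' @return List of class `pullup_unit_results`: `descriptives`,
#'   `wilcoxon_max`, `wilcoxon_mean` (each either a `pullup_wilcoxon` or a
#'   `"no hierarchy movement"` message), `models` (named list of
#'   `pullup_logit`, one per measure), `n_complete`, `warnings`.
#' @export
run_unit_analysis <- function(summaries, roster, small_n = 20L) {
  dat <- merge(summaries, roster, by = "resident_id", sort = FALSE)
  complete <- dat[!dat$incomplete, , drop = FALSE]
  warns <- character(0)
  if (nrow(complete) < small_n) {
    warns <- c(warns, sprintf("small sample: %d complete residents", nrow(complete)))
  }

  descriptives <- unit_descriptives(dat)

  pairs <- paired_measures(summaries)
  run_wilcoxon <- function(p) {
    tryCatch(wilcoxon_signed_rank(p$overall, p$last_month),
             error = function(e) "no hierarchy movement")
  }
  wil_max <- run_wilcoxon(pairs$max)
  wil_mean <- run_wilcoxon(pairs$mean)

  measures <- c("lm_max_ec", "lm_mean_ec", "max_ec", "mean_ec")
  controls <- c("age", "lsi_r", "race_minority", "days_in_program")
  models <- lapply(measures, function(m) {
    design <- complete[, c(m, controls), drop = FALSE]
    tryCatch(fit_logistic(complete$graduated, design),
             error = function(e) conditionMessage(e))
  })
  names(models) <- measures

  structure(list(descriptives = descriptives, wilcoxon_max = wil_max,
                 wilcoxon_mean = wil_mean, models = models,
                 n_complete = nrow(complete), warnings = warns),
            class = "pullup_unit_results")
}

unit_descriptives <- function(dat) {
  msd <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  prop <- function(v) c(mean = mean(v, na.rm = TRUE), sd = NA_real_)
  rows <- rbind(
    graduation = prop(dat$graduated),
    age = msd(dat$age),
    lsi_r = msd(dat$lsi_r),
    race_minority = prop(dat$race_minority),
    days_in_program = msd(dat$days_in_program),
    max_ec = msd(dat$max_ec),
    lm_max_ec = msd(dat$lm_max_ec),
    mean_ec = msd(dat$mean_ec),
    lm_mean_ec = msd(dat$lm_mean_ec))
  data.frame(variable = rownames(rows), mean = rows[, "mean"],
             sd = rows[, "sd"], row.names = NULL)
}

#' @export
print.pullup_unit_results <- function(x, ...) {
  cat("Unit analysis —", x$n_complete, "complete residents\n\n")
  cat("Descriptives:\n")
  print(format(x$descriptives, digits = 3), row.names = FALSE)
  cat("\nHierarchy climb (overall vs last month):\n  maximum: ")
  if (inherits(x$wilcoxon_max, "pullup_wilcoxon")) {
    cat(sprintf("V = %g, p = %.3g\n", x$wilcoxon_max$V, x$wilcoxon_max$p_value))
  } else cat(x$wilcoxon_max, "\n")
  cat("  mean:    ")
  if (inherits(x$wilcoxon_mean, "pullup_wilcoxon")) {
    cat(sprintf("V = %g, p = %.3g\n", x$wilcoxon_mean$V, x$wilcoxon_mean$p_value))
  } else cat(x$wilcoxon_mean, "\n")
  cat("\nGraduation models (hierarchy-measure coefficient):\n")
  for (m in names(x$models)) {
    fit <- x$models[[m]]
    if (inherits(fit, "pullup_logit")) {
      row <- fit$coefficients[fit$coefficients$term == m, ]
      cat(sprintf("  %-11s beta = %8.3f  se = %6.3f  p = %.3g%s\n",
                  m, row$beta, row$se, row$p, stars(row$p)))
    } else cat(sprintf("  %-11s %s\n", m, fit))
  }
  if (length(x$warnings)) cat("\nWarnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) return(" ***")
  if (p < 0.01) return(" **")
  if (p < 0.05) return(" *")
  ""
}

#' Predicted probability of graduation along a hierarchy measure
#'
#' Evaluates the fitted model's inverse-logit linear predictor over a grid
#' of measure values, holding the other terms at a covariate profile
#' (defaults to the fitting sample's means).
#'
#' @param fit A `pullup_logit` from [fit_logistic()].
#' @param measure_name Term to vary.
#' @param grid Numeric grid of measure values.
#' @param covariate_profile Named list/vector of values for the remaining
#'   terms; missing entries default to sample means.
#' @return Data frame `measure_value`, `probability`.
#' @export
predicted_probability_curve <- function(fit, measure_name, grid,
                                        covariate_profile = NULL) {
  stopifnot(inherits(fit, "pullup_logit"))
  if (!fit$converged) stop("fit did not converge; curve not meaningful")
  terms <- setdiff(fit$coefficients$term, "(Intercept)")
  if (!measure_name %in% terms) stop("unknown term: ", measure_name)

  mf <- fit$fit$model
  observed <- mf[[measure_name]]
  if (any(grid > 2 * max(observed))) {
    warning("grid extends far beyond the observed range of ", measure_name)
  }
  profile <- vapply(setdiff(terms, measure_name), function(tm) {
    if (!is.null(covariate_profile) && tm %in% names(covariate_profile)) {
      as.numeric(covariate_profile[[tm]])
    } else mean(mf[[tm]])
  }, numeric(1))

  newdata <- as.data.frame(c(stats::setNames(list(grid), measure_name),
                             as.list(profile)))
  eta <- stats::predict(fit$fit, newdata = newdata, type = "link")
  data.frame(measure_value = grid, probability = stats::plogis(as.numeric(eta)))
}
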