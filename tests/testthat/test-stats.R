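test_that("all-positive differences give the maximal statistic", {
  x <- 11:20; y <- 1:10
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$V, 55)
  expect_equal(w$n_nonzero, 10)
})

test_that("V matches a naive recomputation and wilcox.test across random samples", {
  set.seed(201)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    x <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties and zeros
    y <- round(rnorm(n), sample(0:2, 1))
    if (all(x == y)) next
    w <- wilcoxon_signed_rank(x, y)
    expect_equal(w$V, naive_wilcoxon_V(x, y))
    ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                               exact = FALSE, correct = TRUE))
    expect_equal(unname(w$V), unname(ref$statistic))
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal p with continuity correction tracks the exact enumeration", {
  d <- c(3, -1, 4, -2, 6, 5, -0.5, 2)
  x <- d; y <- rep(0, length(d))
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$V, naive_wilcoxon_V(x, y))
  expect_lt(abs(w$p_value - exact_wilcoxon_p(x, y)), 0.03)

  set.seed(202)
  for (i in 1:25) {
    n <- sample(8:12, 1)
    x <- rnorm(n); y <- rnorm(n)  # continuous: no ties
    w <- wilcoxon_signed_rank(x, y)
    expect_lt(abs(w$p_value - exact_wilcoxon_p(x, y)), 0.03)
  }
})

test_that("identical pairs make the signed-rank test undefined", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "no nonzero differences")
})

test_that("intercept-only fit on a balanced outcome gives logit one half", {
  y <- rep(c(0, 1), 20)
  fit <- fit_logistic(y, data.frame(row.names = seq_along(y)))
  expect_equal(fit$coefficients$beta, 0, tolerance = 1e-12)
  expect_equal(unname(plogis(fit$coefficients$beta)), 0.5)
})

test_that("logistic estimates match direct likelihood maximization", {
  set.seed(203)
  n <- 30
  design <- data.frame(x1 = rnorm(n), x2 = runif(n))
  eta <- 0.5 + 1.2 * design$x1 - 0.8 * design$x2
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(y, design)

  X <- cbind(1, as.matrix(design))
  beta_oracle <- optim_logistic_oracle(y, X)
  expect_equal(unname(fit$coefficients$beta), unname(beta_oracle),
               tolerance = 1e-6)
  # score equations hold at the returned estimates
  expect_lt(max(abs(logistic_score(fit$coefficients$beta, y, X))), 1e-6)
  # fit-statistic identities
  expect_equal(fit$deviance, -2 * fit$log_likelihood)
  k <- nrow(fit$coefficients)
  expect_equal(fit$aic, fit$deviance + 2 * k)
  expect_equal(fit$bic, fit$deviance + k * log(fit$n))
  expect_true(all(fit$coefficients$se > 0))
})

test_that("one-class outcomes and separation are flagged", {
  design <- data.frame(x = rnorm(30))
  expect_error(fit_logistic(rep(1, 30), design), "single class")

  x <- c(rnorm(15, -3), rnorm(15, 3))
  y <- as.integer(x > 0)
  expect_warning(fit <- fit_logistic(y, data.frame(x = x)), "separation")
  expect_false(fit$converged)
})

test_that("adding a predictor never increases the deviance", {
  set.seed(204)
  for (i in 1:10) {
    n <- 60
    d1 <- data.frame(a = rnorm(n))
    d2 <- cbind(d1, b = rnorm(n))
    y <- rbinom(n, 1, plogis(0.3 * d1$a))
    f1 <- fit_logistic(y, d1)
    f2 <- fit_logistic(y, d2)
    expect_lte(f2$deviance, f1$deviance + 1e-10)
  }
})

test_that("unit analysis fits four models sharing n and controls", {
  set.seed(205)
  sim <- simulate_unit(quick_sim())
  res <- suppressWarnings(run_pipeline(sim = quick_sim(seed = 205)))
  expect_s3_class(res, "pullup_unit_results")
  ns <- vapply(res$models, function(m) m$n, numeric(1))
  expect_equal(unname(ns), rep(res$n_complete, 4))
  expect_equal(names(res$models), c("lm_max_ec", "lm_mean_ec", "max_ec", "mean_ec"))
  for (nm in names(res$models)) {
    expect_setequal(res$models[[nm]]$coefficients$term,
                    c("(Intercept)", nm, "age", "lsi_r", "race_minority",
                      "days_in_program"))
  }
})

test_that("constant trajectories are reported as no hierarchy movement", {
  summ <- data.frame(resident_id = sprintf("R%02d", 1:25),
                     max_ec = 0.5, mean_ec = 0.5, lm_max_ec = 0.5,
                     lm_mean_ec = 0.5, n_weeks = 6, n_lm_weeks = 4)
  roster <- data.frame(resident_id = summ$resident_id,
                       entry_date = as.Date("2019-01-01"),
                       exit_date = as.Date("2019-03-01"),
                       graduated = rep(c(0L, 1L), length.out = 25),
                       age = rnorm(25, 30), race_minority = 0L,
                       lsi_r = rnorm(25, 25), days_in_program = 59,
                       incomplete = FALSE)
  res <- suppressWarnings(run_unit_analysis(summ, roster))
  expect_equal(res$wilcoxon_max, "no hierarchy movement")
  expect_equal(res$wilcoxon_mean, "no hierarchy movement")
})

test_that("small units carry a small-sample warning", {
  set.seed(206)
  summ <- data.frame(resident_id = sprintf("R%02d", 1:10),
                     max_ec = runif(10), mean_ec = runif(10, 0, 0.5),
                     lm_max_ec = runif(10, 0, 0.5), lm_mean_ec = runif(10, 0, 0.3),
                     n_weeks = 6, n_lm_weeks = 4)
  roster <- data.frame(resident_id = summ$resident_id,
                       entry_date = as.Date("2019-01-01"),
                       exit_date = as.Date("2019-03-01"),
                       graduated = rep(c(0L, 1L), 5),
                       age = rnorm(10, 30), race_minority = rep(0:1, 5),
                       lsi_r = rnorm(10, 25), days_in_program = rnorm(10, 60, 5),
                       incomplete = FALSE)
  res <- suppressWarnings(run_unit_analysis(summ, roster))
  expect_match(res$warnings, "small sample", all = FALSE)
})

test_that("predicted probability curves respect the logistic geometry", {
  set.seed(207)
  n <- 200
  design <- data.frame(m = runif(n), age = rnorm(n, 30, 5))
  y <- rbinom(n, 1, plogis(1 - 2 * design$m))
  fit <- fit_logistic(y, design)
  curve <- predicted_probability_curve(fit, "m", seq(0, 1, 0.1))
  expect_true(all(diff(curve$probability) < 0))  # beta_m < 0 => decreasing
  expect_true(all(curve$probability > 0 & curve$probability < 1))

  # where the linear predictor crosses zero the probability is 1/2
  b <- fit$coefficients
  beta0 <- b$beta[b$term == "(Intercept)"]
  beta_m <- b$beta[b$term == "m"]
  beta_a <- b$beta[b$term == "age"]
  a0 <- mean(fit$fit$model$age)
  m_half <- -(beta0 + beta_a * a0) / beta_m
  p_half <- predicted_probability_curve(fit, "m", m_half)
  expect_equal(p_half$probability, 0.5, tolerance = 1e-10)

  expect_warning(predicted_probability_curve(fit, "m", 5), "beyond the observed")
})
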