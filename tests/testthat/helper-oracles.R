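# Shared fixtures and independent oracles used across the suite.

# Wrap a weight matrix as a weekly network object.
make_net <- function(W, ids = sprintf("n%d", seq_len(nrow(W)))) {
  dimnames(W) <- list(ids, ids)
  structure(list(window = list(index = 0L, start = as.Date("2019-01-01"),
                               end = as.Date("2019-01-08")),
                 nodes = ids, W = W),
            class = "pullup_weekly_network")
}

# Random weighted digraph on n nodes (uses the current RNG stream).
random_digraph <- function(n, max_weight = 3) {
  W <- matrix(rpois(n * n, runif(1, 0, 0.5) * max_weight), n, n)
  diag(W) <- 0
  make_net(W)
}

# The classic pecking order: C and D correct B, B corrects A.
pecking_net <- function() {
  ids <- c("A", "B", "C", "D")
  W <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  W["C", "B"] <- 1L
  W["D", "B"] <- 1L
  W["B", "A"] <- 1L
  make_net(W, ids)
}

# Naive independent signed-rank statistic: ranks computed from scratch by
# counting, not via rank().
naive_wilcoxon_V <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  a <- abs(d)
  r <- vapply(a, function(ai) sum(a < ai) + (sum(a == ai) + 1) / 2, numeric(1))
  sum(r[d > 0])
}

# Exact two-sided p by enumerating all 2^n sign assignments of |d|.
exact_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Direct maximization of the written-out Bernoulli log-likelihood,
# independent of glm's IRLS path.
optim_logistic_oracle <- function(y, X) {
  nll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(beta) {
    eta <- as.numeric(X %*% beta)
    -as.numeric(t(X) %*% (y - plogis(eta)))
  }
  fit <- optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# Score (gradient of the log-likelihood) at given coefficients.
logistic_score <- function(beta, y, X) {
  as.numeric(t(X) %*% (y - plogis(as.numeric(X %*% beta))))
}

# Small, quick simulator config for module tests; overrides win.
quick_sim <- function(seed = 1, ...) {
  defaults <- list(n_beds = 20L, arrival_rate = 0.5, mean_tenure_days = 80,
                   tenure_sd_days = 20, span_days = 180L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Write a corrections / roster CSV fixture into a temp file.
write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
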