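quiet_fit <- function(...) suppressWarnings(em_fit(...))

test_that("points exactly on one line recover its slope almost exactly", {
  set.seed(1)
  x <- rnorm(100, sd = 0.05)
  sel <- make_harmonised(beta_I = x, se_I = rep(0.01, 100),
                         beta_P = 0.5 * x, se_P = rep(0.01, 100))
  fit <- quiet_fit(sel, em_config(n_restarts = 3, bootstrap_B = 0))
  expect_equal(fit$b1, 0.5, tolerance = 1e-6)
  expect_true(all(fit$responsibilities >= 0 & fit$responsibilities <= 1))
})

test_that("EM recovers mixture parameters from direct draws", {
  ## parameter-recovery oracle: repeated draws from the mixture itself
  R <- 30
  bhat <- pihat <- numeric(R)
  for (r in seq_len(R)) {
    d <- simulate_mixture_pairs(3000, b1 = -0.4, pi1 = 0.6, sI2 = 1,
                                sigIP = 0.3, sP2 = 1, tau2 = 1e-4,
                                seed = 1000 + r)
    f <- quiet_fit(d, em_config(n_restarts = 3, bootstrap_B = 0, seed = r))
    bhat[r] <- f$b1; pihat[r] <- f$pi_target
  }
  mc_se <- sd(bhat) / sqrt(R)
  expect_lt(abs(mean(bhat) - (-0.4)), 3 * max(mc_se, 1e-4))
  expect_lt(abs(mean(pihat) - 0.6), 0.05)
})

test_that("log-likelihood at a single origin point matches the closed form", {
  sel <- data.frame(beta_I = 0, beta_P = 0, se_I = 0.01, se_P = 0.01)
  p <- list(b1 = -0.4, s2 = 0.1, pi1 = 0.7, v1 = 2, v2 = 2,
            sigma1_sq = 1.2, sigma2_sq = 8)
  g <- 0.01^2
  ## mixture of two bivariate normal densities evaluated at (0, 0)
  d1 <- 1 / (2 * pi * sqrt(2) * sqrt(g * 1.2))
  d2 <- 1 / (2 * pi * sqrt(2) * sqrt(g * 8))
  expect_equal(loglikelihood(p, sel), log(0.7 * d1 + 0.3 * d2),
               tolerance = 1e-12)
})

test_that("pi1 = 1 collapses the likelihood to component 1", {
  set.seed(2)
  sel <- data.frame(beta_I = rnorm(20), beta_P = rnorm(20),
                    se_I = rep(1, 20), se_P = rep(1, 20))
  p <- list(b1 = 0.3, s2 = -2, pi1 = 1, v1 = 1.5, v2 = 1.5,
            sigma1_sq = 2, sigma2_sq = 5)
  direct <- sum(dnorm(sel$beta_I, 0, sqrt(1.5), log = TRUE) +
                  dnorm(sel$beta_P, 0.3 * sel$beta_I, sqrt(2), log = TRUE))
  expect_equal(loglikelihood(p, sel), direct, tolerance = 1e-12)
})

test_that("EM log-likelihood trace is non-decreasing on varied datasets", {
  for (r in 1:5) {
    d <- simulate_mixture_pairs(400, b1 = -0.3, pi1 = 0.5, sI2 = 1,
                                sigIP = -0.2, sP2 = 0.8, tau2 = 0.01,
                                seed = 20 + r)
    f <- quiet_fit(d, em_config(n_restarts = 2, bootstrap_B = 0, seed = r))
    expect_true(all(diff(f$loglik_trace) >= -1e-8 * (1 + abs(f$loglik))))
    ## ascent from initialisation
    expect_gte(f$loglik, f$loglik_trace[1] - 1e-8)
  }
})

test_that("target-component rule follows residual concentration and pi x v", {
  base <- list(b1 = -0.4, s2 = 0.2, sigma1_sq = 1, sigma2_sq = 4)
  ## shared variance: densest line wins (pi_k / sqrt(sigma_k))
  p1 <- c(base, list(pi1 = 0.7, v1 = 1e-3, v2 = 1e-3))
  expect_equal(select_target_component(p1), 1L)  # 0.7/1 > 0.3/2
  p1b <- c(base, list(pi1 = 0.3, v1 = 1e-3, v2 = 1e-3))
  expect_equal(select_target_component(p1b), 2L) # 0.3/1 < 0.7/2
  p1c <- c(base, list(pi1 = 0.4, v1 = 1e-3, v2 = 1e-3))
  expect_equal(select_target_component(p1c), 1L) # 0.4/1 > 0.6/2
  ## unequal variances: 0.3 * 7e-4 > 0.7 * 1e-4 -> component 1
  p2 <- c(base, list(pi1 = 0.3, v1 = 7e-4, v2 = 1e-4))
  expect_equal(select_target_component(p2), 1L)
  ## and the reverse picks component 2
  p3 <- c(base, list(pi1 = 0.3, v1 = 1e-4, v2 = 7e-4))
  expect_equal(select_target_component(p3), 2L)
})

test_that("b1 is exactly equivariant to scaling and sign of the inputs", {
  d <- simulate_mixture_pairs(800, b1 = -0.4, pi1 = 0.6, sI2 = 1,
                              sigIP = 0.3, sP2 = 1, tau2 = 1e-3, seed = 5)
  cfg <- em_config(n_restarts = 3, bootstrap_B = 0, seed = 9, tol = 1e-12)
  f0 <- quiet_fit(d, cfg)
  ## scale outcome by a power of two (the log-likelihood shifts by a
  ## constant, so the stopping iteration may differ by one; equality is up
  ## to the convergence tolerance)
  d_y <- d; d_y$beta_P <- 2 * d$beta_P; d_y$se_P <- 2 * d$se_P
  expect_equal(quiet_fit(d_y, cfg)$b1, 2 * f0$b1, tolerance = 1e-8)
  ## negating the outcome negates every step bit for bit
  d_n <- d; d_n$beta_P <- -d$beta_P
  expect_identical(quiet_fit(d_n, cfg)$b1, -f0$b1)
  ## scale incidence by a power of two
  d_x <- d; d_x$beta_I <- 2 * d$beta_I
  expect_equal(quiet_fit(d_x, cfg)$b1, f0$b1 / 2, tolerance = 1e-8)
})

test_that("degenerate or undersized selections raise errors", {
  tiny <- make_harmonised(beta_I = rnorm(5), se_I = rep(0.01, 5),
                          beta_P = rnorm(5), se_P = rep(0.01, 5))
  expect_error(em_fit(tiny), "need >=")
  flat <- make_harmonised(beta_I = rep(0, 30), se_I = rep(0.01, 30),
                          beta_P = rnorm(30), se_P = rep(0.01, 30))
  expect_error(em_fit(flat), "degenerate")
})

test_that("bootstrap SE is near zero for exactly collinear data", {
  set.seed(3)
  x <- rnorm(60, sd = 0.05)
  sel <- make_harmonised(beta_I = x, se_I = rep(0.01, 60),
                         beta_P = -0.25 * x, se_P = rep(0.01, 60))
  cfg <- em_config(n_restarts = 2, bootstrap_B = 100, seed = 4)
  fit <- suppressWarnings(bootstrap_se(sel, quiet_fit(sel, cfg), cfg))
  expect_lt(fit$se_b1, 1e-6)
  expect_true(fit$ci_b1[1] <= fit$b1 && fit$b1 <= fit$ci_b1[2])
})

test_that("bootstrap SE tracks the sampling SD of the estimator", {
  ## empirical sampling distribution over fresh replicates
  R <- 120
  cfg1 <- em_config(n_restarts = 1, bootstrap_B = 0, seed = 1)
  bhat <- vapply(seq_len(R), function(r) {
    d <- simulate_mixture_pairs(400, b1 = -0.4, pi1 = 0.6, sI2 = 1,
                                sigIP = 0.25, sP2 = 0.8, tau2 = 1e-3,
                                seed = 5000 + r)
    quiet_fit(d, cfg1)$b1
  }, numeric(1))
  emp_sd <- sd(bhat)
  d0 <- simulate_mixture_pairs(400, b1 = -0.4, pi1 = 0.6, sI2 = 1,
                               sigIP = 0.25, sP2 = 0.8, tau2 = 1e-3,
                               seed = 99)
  cfgB <- em_config(n_restarts = 2, bootstrap_B = 500, seed = 17)
  fit <- suppressWarnings(bootstrap_se(d0, quiet_fit(d0, cfgB), cfgB))
  expect_lt(abs(fit$se_b1 - emp_sd) / emp_sd, 0.25)
  ## percentile CI covers the point estimate on well-separated data
  expect_true(fit$ci_b1[1] <= fit$b1 && fit$b1 <= fit$ci_b1[2])
})

test_that("hunt_slope propagates an empty selection as an error", {
  h <- make_harmonised(beta_I = rnorm(30, sd = 0.001),
                       se_I = rep(0.01, 30),
                       beta_P = rnorm(30), se_P = rep(0.01, 30),
                       p_I = rep(0.5, 30))
  expect_error(hunt_slope(h, selection_config(1e-4)), "no variants pass")
})

test_that("with lambda = 1 the target weight absorbs the null mass", {
  ## 85% null variants sit at the origin, on any line through it: the
  ## proportional component captures them together with the I-only cluster
  st <- simulate_study(preset_scenario("sc2", seed = 31), mode = "summary")
  fit <- hunt_slope(st$sumstats, selection_config(lambda = 1),
                    em_config(n_restarts = 3, bootstrap_B = 0, seed = 31))
  expect_gt(fit$pi_target, 0.75)  # pi1 + pi4 = 0.90 approximately
  expect_lt(fit$pi_target, 0.99)
  ## with the null mass included, estimation noise in beta_I makes flat
  ## lines fit the nulls better: the slope keeps its sign but shrinks
  expect_lt(fit$b1, 0)
  expect_lt(abs(fit$b1), abs(st$realized_slope) + 0.05)
})

test_that("the fitted component recovers the I-only cluster under s1", {
  ## 1% I-only variants with large effects vs 9% both-trait variants
  hits <- 0L
  runs <- 20L
  for (r in seq_len(runs)) {
    st <- simulate_study(preset_scenario("s1", rho_d = 0.5,
                                         seed = 300 + r),
                         mode = "summary")
    fit <- hunt_slope(st$sumstats, selection_config(0.001),
                      em_config(n_restarts = 3, bootstrap_B = 0, seed = r))
    sel <- select_incidence_snps(st$sumstats, selection_config(0.001))
    gi <- sel$cluster == "GI."
    if (mean(fit$responsibilities[gi]) > 0.8 &&
        abs(fit$b1 - st$realized_slope) < 0.1) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)  # >= 95% of runs
})

test_that("fit serialises to JSON with finite core fields", {
  d <- simulate_mixture_pairs(300, b1 = -0.4, pi1 = 0.6, sI2 = 1,
                              sigIP = 0.3, sP2 = 1, tau2 = 1e-3, seed = 8)
  fit <- suppressWarnings(
    hunt_slope(make_harmonised(d$beta_I, d$se_I, d$beta_P, d$se_P,
                               p_I = rep(1e-6, nrow(d))),
               selection_config(0.001),
               em_config(n_restarts = 2, bootstrap_B = 100, seed = 2)))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  got <- jsonlite::read_json(path)
  expect_equal(got$b1, fit$b1, tolerance = 1e-12)
  expect_true(is.finite(got$se_b1))
  expect_equal(got$n_snps, 300L)
})
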