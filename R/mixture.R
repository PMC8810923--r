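#' EM settings for the two-component slope mixture
#'
#' @param max_iter Maximum EM iterations per start (default 5000).
#' @param tol Convergence tolerance on the change in log-likelihood
#'   (default 1e-8).
#' @param n_restarts Number of random restarts; the best final
#'   log-likelihood wins (default 10).
#' @param seed Integer seed controlling restarts and the bootstrap.
#' @param eq12_faithful Logical; when `TRUE` (default) the marginal variance
#'   of the incidence effects is shared between the two components, matching
#'   the constrained mixture in which both clusters draw their incidence
#'   effects from the same normal. When `FALSE` each component carries its
#'   own marginal variance, which makes the "explains more variation"
#'   target-selection rule non-trivial.
#' @param bootstrap_B Number of bootstrap resamples for the slope standard
#'   error (default 1000; published real-data analyses typically use 10000).
#' @param min_snps Minimum number of selected variants required to attempt
#'   the fit (default 20).
#' @return An object of class `sh_em_config`.
#' @export
em_config <- function(max_iter = 5000, tol = 1e-8, n_restarts = 10,
                      seed = 1L, eq12_faithful = TRUE, bootstrap_B = 1000,
                      min_snps = 20) {
  stopifnot(max_iter >= 1, tol > 0, n_restarts >= 1, min_snps >= 2)
  if (bootstrap_B > 0 && bootstrap_B < 100) {
    stop("bootstrap_B must be 0 (skip) or >= 100", call. = FALSE)
  }
  structure(list(max_iter = max_iter, tol = tol, n_restarts = n_restarts,
                 seed = as.integer(seed), eq12_faithful = eq12_faithful,
                 bootstrap_B = bootstrap_B, min_snps = min_snps),
            class = "sh_em_config")
}

# Conditional ("two lines") parameterisation of the constrained bivariate
# mixture. Component 1 is the proportional cluster: incidence effects
# x ~ N(0, v1) and outcome effects y | x ~ N(b1*x, g_i * sigma1_sq), where
# g_i = se_P,i^2 is the known per-variant sampling variance and sigma1_sq a
# free relative overdispersion regularising the otherwise rank-1 component
# covariance. Component 2 adds direct-outcome-effect variance:
# x ~ N(0, v2), y | x ~ N(s2*x, g_i * sigma2_sq) with s2 = b1 + cov_IP/v2
# and sigma2_sq >= sigma1_sq. Scaling the conditional variances by g_i
# absorbs the strong allele-frequency dependence of the sampling noise
# (var ~ 1/(2*maf*(1-maf))); with constant SEs it reduces to a
# homoscedastic two-line mixture.
sh_params <- function(b1, s2, pi1, v1, v2, sigma1_sq, sigma2_sq,
                      g_med = NA_real_) {
  list(b1 = b1, s2 = s2, pi1 = pi1, v1 = v1, v2 = v2,
       sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq, g_med = g_med,
       tau2 = sigma1_sq * g_med, psi2 = sigma2_sq * g_med,
       cov_IP = (s2 - b1) * v2,
       var_bP_direct = (sigma2_sq - sigma1_sq) * g_med + (s2 - b1)^2 * v2)
}

comp_logdens <- function(x, y, v, slope, sigma_sq, g) {
  stats::dnorm(x, 0, sqrt(v), log = TRUE) +
    stats::dnorm(y, slope * x, sqrt(g * sigma_sq), log = TRUE)
}

# per-variant noise scale for the conditional variances
noise_scale <- function(selected) {
  if (!is.null(selected$se_P) && all(is.finite(selected$se_P)) &&
      all(selected$se_P > 0)) {
    selected$se_P^2
  } else {
    rep(1, nrow(selected))
  }
}

#' Log-likelihood of the two-component slope mixture
#'
#' Sum over variants of the log mixture density of the observed
#' (incidence, outcome) effect pairs under a parameter set as produced by
#' [em_fit()]. The per-variant noise scale is taken from `selected$se_P`
#' (squared); when SEs are absent a unit scale is used and the
#' overdispersion parameters are absolute variances.
#'
#' @param params Parameter list with elements `b1`, `s2`, `pi1`, `v1`,
#'   `v2`, `sigma1_sq`, `sigma2_sq`.
#' @param selected Data frame with columns `beta_I`, `beta_P` (and
#'   usually `se_P`).
#' @return The observed-data log-likelihood (a scalar).
#' @export
loglikelihood <- function(params, selected) {
  x <- selected$beta_I; y <- selected$beta_P
  g <- noise_scale(selected)
  l1 <- log(params$pi1) +
    comp_logdens(x, y, params$v1, params$b1, params$sigma1_sq, g)
  l2 <- log1p(-params$pi1) +
    comp_logdens(x, y, params$v2, params$s2, params$sigma2_sq, g)
  m <- pmax(l1, l2)
  ll <- m + log(exp(l1 - m) + exp(l2 - m))
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1]
    stop("non-finite mixture density at row ", bad,
         " (beta_I = ", x[bad], ", beta_P = ", y[bad], ")", call. = FALSE)
  }
  sum(ll)
}

SIGMA_FLOOR <- 1e-10

# One full EM run from a given initialisation. Returns params,
# responsibilities (posterior probability of component 1), trace, flags.
em_run <- function(x, y, g, init, cfg) {
  p <- init
  n <- length(x)
  df <- data.frame(beta_I = x, beta_P = y, se_P = sqrt(g))
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  mean_x2 <- mean(x^2)
  g_med <- stats::median(g)
  for (it in seq_len(cfg$max_iter)) {
    ## E-step
    l1 <- log(p$pi1) + comp_logdens(x, y, p$v1, p$b1, p$sigma1_sq, g)
    l2 <- log1p(-p$pi1) + comp_logdens(x, y, p$v2, p$s2, p$sigma2_sq, g)
    r <- 1 / (1 + exp(l2 - l1))
    ## M-step (all closed form)
    w1 <- sum(r); w2 <- n - w1
    pi1 <- min(max(w1 / n, 1e-6), 1 - 1e-6)
    if (cfg$eq12_faithful) {
      v1 <- v2 <- mean_x2
    } else {
      v1 <- max(sum(r * x^2) / max(w1, 1e-12), 1e-12)
      v2 <- max(sum((1 - r) * x^2) / max(w2, 1e-12), 1e-12)
    }
    b1 <- sum(r * x * y / g) / max(sum(r * x^2 / g), 1e-300)
    s2 <- sum((1 - r) * x * y / g) / max(sum((1 - r) * x^2 / g), 1e-300)
    sig1 <- max(sum(r * (y - b1 * x)^2 / g) / max(w1, 1e-12), SIGMA_FLOOR)
    sig2 <- max(sum((1 - r) * (y - s2 * x)^2 / g) / max(w2, 1e-12),
                SIGMA_FLOOR)
    if (sig2 < sig1) {
      # keep component 1 as the tighter line: swap labels
      tmp_b <- b1; b1 <- s2; s2 <- tmp_b
      tmp_s <- sig1; sig1 <- sig2; sig2 <- tmp_s
      tmp_v <- v1; v1 <- v2; v2 <- tmp_v
      pi1 <- 1 - pi1
    }
    p <- sh_params(b1, s2, pi1, v1, v2, sig1, sig2, g_med)
    ll <- loglikelihood(p, df)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < cfg$tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ## final responsibilities under the returned parameters
  l1 <- log(p$pi1) + comp_logdens(x, y, p$v1, p$b1, p$sigma1_sq, g)
  l2 <- log1p(-p$pi1) + comp_logdens(x, y, p$v2, p$s2, p$sigma2_sq, g)
  r <- 1 / (1 + exp(l2 - l1))
  list(params = p, responsibilities = r, loglik = ll_old,
       loglik_trace = trace, converged = converged, n_iter = length(trace))
}

# Geometric-mean ("reduced major axis") slope: sign(cov) * sd(y)/sd(x).
# Chosen over total least squares because it is exactly equivariant to
# rescaling either axis, which the whole fit inherits.
gm_slope <- function(x, y) {
  sdx <- stats::sd(x)
  if (sdx < 1e-300) return(0)
  s <- sign(stats::cov(x, y))
  if (s == 0) s <- 1
  s * stats::sd(y) / sdx
}

em_inits <- function(x, y, g, cfg) {
  b0 <- gm_slope(x, y)
  dir0 <- if (b0 < 0) -1 else 1  # keeps inits odd under y -> -y
  big <- abs(x) >= stats::median(abs(x))
  ratio_sd <- stats::sd(y[big] / x[big])
  if (!is.finite(ratio_sd) || ratio_sd <= 0) ratio_sd <- abs(b0) + 1
  v0 <- mean(x^2)
  g_med <- stats::median(g)
  # component 1 starts at the sampling-noise level (tight line); component
  # 2 at the overall residual spread about the initial line
  sig1_0 <- 1.5
  sig2_0 <- max(stats::var(y - b0 * x) / g_med, 3 * sig1_0)
  inits <- vector("list", cfg$n_restarts)
  jit <- withr_seed(cfg$seed,
                    matrix(stats::rnorm(2 * cfg$n_restarts), ncol = 2))
  for (k in seq_len(cfg$n_restarts)) {
    j <- if (k == 1) c(0, 0) else jit[k, ]
    b_init <- b0 + dir0 * j[1] * ratio_sd
    s_init <- b0 + dir0 * ((if (k %% 2 == 0) 1 else -1) + j[2]) * ratio_sd
    inits[[k]] <- sh_params(b_init, s_init, 0.5, v0, v0, sig1_0, sig2_0,
                            g_med)
  }
  inits
}

#' Fit the constrained two-component mixture by EM
#'
#' Fits a bivariate Gaussian mixture to the selected (incidence, outcome)
#' effect pairs in which one component concentrates on a line through the
#' origin (the cluster of variants acting only through the conditioning
#' trait, whose outcome associations are pure collider bias) and the other
#' permits additional direct-outcome-effect variance and covariance. The
#' slope of the proportional component is the bias-correction factor.
#'
#' Each component's scatter about its line is modelled as
#' `sigma_k^2 * se_P^2` — proportional to the per-variant sampling
#' variance, whose strong allele-frequency dependence would otherwise make
#' low-frequency line-cluster variants look like outliers. `sigma1_sq`
#' plays the role of a residual-variance regulariser for the otherwise
#' singular proportional component (near 1 when the scatter is pure
#' sampling noise); `sigma2_sq >= sigma1_sq` absorbs the direct-effect
#' variance. Multiple seeded restarts are run from jittered
#' geometric-mean-slope initialisations and the best final log-likelihood
#' is kept.
#'
#' @param selected Harmonised table after selection (columns `beta_I`,
#'   `se_I`, `beta_P`, `se_P`).
#' @param cfg An [em_config()].
#' @return An object of class `sh_fit`: list with `params`, `b1` (slope of
#'   the target component), `target` (component index), `pi_target`,
#'   `responsibilities` (posterior probability of the target component per
#'   variant), `loglik`, `loglik_trace`, `converged`, `n_iter`, `n_snps`,
#'   and (after [bootstrap_se()]) `se_b1`, `ci_b1`.
#' @export
em_fit <- function(selected, cfg = em_config()) {
  stopifnot(inherits(cfg, "sh_em_config"))
  x <- selected$beta_I; y <- selected$beta_P
  if (length(x) < cfg$min_snps) {
    stop("em_fit: only ", length(x), " selected variants; need >= ",
         cfg$min_snps, call. = FALSE)
  }
  if (all(abs(x) < 1e-12)) {
    stop("em_fit: degenerate selection, all incidence effects ~ 0",
         call. = FALSE)
  }
  g <- noise_scale(selected)
  inits <- em_inits(x, y, g, cfg)
  best <- NULL
  for (init in inits) {
    run <- em_run(x, y, g, init, cfg)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged) {
    warning("em_fit: EM did not converge within ", cfg$max_iter,
            " iterations; returning best iterate")
  }
  fit <- structure(
    list(params = best$params,
         responsibilities = best$responsibilities,
         loglik = best$loglik, loglik_trace = best$loglik_trace,
         converged = best$converged, n_iter = best$n_iter,
         n_snps = length(x), cfg = cfg,
         se_b1 = NA_real_, ci_b1 = c(NA_real_, NA_real_)),
    class = "sh_fit")
  tgt <- select_target_component(fit)
  fit$target <- tgt
  fit$b1 <- if (tgt == 1L) fit$params$b1 else fit$params$s2
  fit$pi_target <- if (tgt == 1L) fit$params$pi1 else 1 - fit$params$pi1
  if (tgt == 2L) fit$responsibilities <- 1 - fit$responsibilities
  fit
}

#' Choose the component representing the incidence-only cluster
#'
#' Under the shared-marginal-variance (faithful) parameterisation the
#' target is the component whose line carries the greatest residual
#' density — the operational form of the zero-modal-residual assumption:
#' the incidence-only cluster contributes the most common
#' outcome/incidence ratio. The height of component k's residual density
#' at its own line is proportional to `pi_k / sqrt(sigma_k_sq)`, so the
#' component maximising that concentration is returned. Neither the mixing
#' weight alone (the incidence-only cluster can be outnumbered after
#' selection) nor tightness alone (a sliver of a diffuse cluster can be
#' locally tighter) identifies the target reliably; their ratio does.
#'
#' When the components carry separate marginal variances, the target is
#' instead the component maximising `pi_k * v_k` — the share of variation
#' in the conditioning trait it explains — with ties broken toward the
#' component with the smaller conditional variance about its line.
#'
#' @param fit An `sh_fit` (or a bare parameter list).
#' @return Component index, 1 or 2.
#' @export
select_target_component <- function(fit) {
  p <- if (inherits(fit, "sh_fit")) fit$params else fit
  shared_v <- abs(p$v1 - p$v2) <= 1e-9 * max(p$v1, p$v2)
  if (shared_v) {
    conc <- c(p$pi1 / sqrt(p$sigma1_sq),
              (1 - p$pi1) / sqrt(p$sigma2_sq))
    if (abs(conc[1] - conc[2]) <= 1e-9 * max(conc)) {
      warning("select_target_component: equal residual concentration; ",
              "keeping component 1 (tighter)")
      return(1L)
    }
    return(if (conc[1] >= conc[2]) 1L else 2L)
  }
  score <- c(p$pi1 * p$v1, (1 - p$pi1) * p$v2)
  rel_tie <- abs(score[1] - score[2]) <= 1e-6 * max(score)
  if (rel_tie) {
    if (p$sigma2_sq > p$sigma1_sq) return(1L)
    warning("select_target_component: exact tie, keeping component 1")
    return(1L)
  }
  if (score[1] >= score[2]) 1L else 2L
}

#' Bootstrap standard error of the correction factor
#'
#' Resamples the selected variants with replacement `cfg$bootstrap_B` times
#' and refits the EM from the point estimate (single start per resample).
#' The standard error is the standard deviation of the target-component
#' slope across resamples; the confidence interval is the 2.5/97.5
#' percentile interval. Deterministic given `cfg$seed`.
#'
#' @param selected The selected harmonised table used for the point fit.
#' @param fit The point-estimate `sh_fit`.
#' @param cfg An [em_config()]; `bootstrap_B` controls the resample count.
#' @return `fit` with `se_b1`, `ci_b1`, `bootstrap_b1` (the resample
#'   slopes) and `bootstrap_nonconverged` filled in. If more than 5% of
#'   resample fits fail to converge a warning is recorded.
#' @export
bootstrap_se <- function(selected, fit, cfg = fit$cfg) {
  B <- cfg$bootstrap_B
  if (B <= 0) return(fit)
  x <- selected$beta_I; y <- selected$beta_P
  g <- noise_scale(selected)
  n <- length(x)
  boot_cfg <- cfg
  boot_cfg$n_restarts <- 1L
  bs <- numeric(B)
  bad <- 0L
  idx_all <- withr_seed(cfg$seed + 1L,
                        matrix(sample.int(n, n * B, replace = TRUE),
                               nrow = n))
  for (b in seq_len(B)) {
    idx <- idx_all[, b]
    run <- em_run(x[idx], y[idx], g[idx], fit$params, boot_cfg)
    if (!run$converged) bad <- bad + 1L
    tgt <- select_target_component(run$params)
    bs[b] <- if (tgt == 1L) run$params$b1 else run$params$s2
  }
  if (bad / B > 0.05) {
    warning("bootstrap_se: ", bad, "/", B, " resample fits non-converged")
  }
  fit$se_b1 <- stats::sd(bs)
  fit$ci_b1 <- unname(stats::quantile(bs, c(0.025, 0.975)))
  fit$bootstrap_b1 <- bs
  fit$bootstrap_nonconverged <- bad
  fit
}

#' Estimate the collider-bias correction factor end to end
#'
#' Pipeline: select incidence-associated variants at threshold lambda, fit
#' the two-component mixture by EM, pick the component representing the
#' incidence-only cluster, and (optionally) bootstrap the slope standard
#' error. The returned fit's `b1` is the correction factor to pass to
#' [adjust_associations()].
#'
#' @param harmonised A harmonised table (see [harmonise()]).
#' @param selection_cfg A [selection_config()].
#' @param em_cfg An [em_config()].
#' @return An `sh_fit` (see [em_fit()]), with `n_selected` recording the
#'   size of the selected set.
#' @export
hunt_slope <- function(harmonised, selection_cfg = selection_config(),
                       em_cfg = em_config()) {
  selected <- select_incidence_snps(harmonised, selection_cfg)
  fit <- em_fit(selected, em_cfg)
  fit <- bootstrap_se(selected, fit, em_cfg)
  fit$n_selected <- nrow(selected)
  fit$lambda <- selection_cfg$lambda
  fit
}

#' @export
print.sh_fit <- function(x, ...) {
  cat("Slope-Hunter mixture fit\n")
  cat(sprintf("  correction factor b1: %.4f", x$b1))
  if (is.finite(x$se_b1)) {
    cat(sprintf(" (bootstrap SE %.4f, 95%% CI %.4f to %.4f)",
                x$se_b1, x$ci_b1[1], x$ci_b1[2]))
  }
  cat("\n")
  cat(sprintf("  target-cluster weight pi1*: %.3f (component %d)\n",
              x$pi_target, x$target))
  cat(sprintf("  variants: %d; EM iterations: %d; converged: %s\n",
              x$n_snps, x$n_iter, x$converged))
  invisible(x)
}

#' Serialise a mixture fit to JSON
#'
#' @param fit An `sh_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(b1 = fit$b1, se_b1 = fit$se_b1, ci_b1 = fit$ci_b1,
              pi_target = fit$pi_target, target_component = fit$target,
              params = fit$params[c("b1", "s2", "pi1", "v1", "v2",
                                    "sigma1_sq", "sigma2_sq", "tau2",
                                    "psi2", "cov_IP", "var_bP_direct")],
              loglik = fit$loglik, converged = fit$converged,
              n_iter = fit$n_iter, n_snps = fit$n_snps,
              seed = fit$cfg$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
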