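#' Configuration of the four-cluster generative model
#'
#' Describes one simulated conditional-GWAS study: a quantitative
#' conditioning trait I and a quantitative outcome P, both with heritability
#' `h2_I`/`h2_P`, sharing a non-genetic confounder U that explains `conf2`
#' of the variance of each trait (positive loadings), analysed for
#' `n_snps` independent Hardy-Weinberg variants in `n_individuals`
#' unrelated individuals. Variants fall into four clusters: affecting I
#' only, both traits, P only, or neither (`cluster_props`). Cluster effect
#' sizes are drawn normal and rescaled so each cluster's explained variance
#' share is hit exactly (using per-variant variance `2*maf*(1-maf)`).
#'
#' The direct effects of the both-trait cluster on I and P are bivariate
#' normal with correlation `rho_d`, or, when `mediated = TRUE`, act through
#' a single shared exposure giving perfectly correlated direct effects with
#' the sign of `rho_d`.
#'
#' @param n_individuals Sample size (default 20000).
#' @param n_snps Number of independent variants (default 10000).
#' @param cluster_props Proportions of variants in the clusters
#'   (I-only, both, P-only, neither); must sum to 1.
#' @param r2_I_split Shares of the variance of I explained by the I-only
#'   and both-trait clusters; must sum to `h2_I`.
#' @param h2_I,h2_P Trait heritabilities (default 0.5 each).
#' @param conf2 Confounder share of variance in both traits (default 0.40).
#' @param rho_d Correlation of direct effects on I and P for the both-trait
#'   cluster (sign only, when `mediated`).
#' @param p_split Shares of the variance of P explained by the both-trait
#'   and P-only clusters; must sum to `h2_P`. Default `NULL` mirrors the
#'   incidence split: the both-trait cluster explains the same share of P
#'   as it does of I, with the P-only cluster taking the remainder.
#' @param maf_range Minor-allele-frequency range, uniform (default
#'   0.01–0.49).
#' @param mediated Single-shared-exposure mode for the both-trait cluster.
#' @param beta_IP Causal effect of I on P (default 0; its value does not
#'   enter the bias mechanism).
#' @param seed Integer seed.
#' @return An object of class `sh_scenario`.
#' @export
scenario_config <- function(n_individuals = 20000, n_snps = 10000,
                            cluster_props = c(0.05, 0.05, 0.05, 0.85),
                            r2_I_split = c(0.25, 0.25),
                            h2_I = 0.5, h2_P = 0.5, conf2 = 0.40,
                            rho_d = 0, p_split = NULL,
                            maf_range = c(0.01, 0.49), mediated = FALSE,
                            beta_IP = 0, seed = 1L) {
  stopifnot(length(cluster_props) == 4,
            abs(sum(cluster_props) - 1) < 1e-8,
            length(r2_I_split) == 2,
            abs(sum(r2_I_split) - h2_I) < 1e-8,
            rho_d >= -1, rho_d <= 1)
  if (is.null(p_split)) p_split <- c(r2_I_split[2], h2_P - r2_I_split[2])
  stopifnot(length(p_split) == 2, abs(sum(p_split) - h2_P) < 1e-8,
            all(p_split >= 0))
  if (h2_I + conf2 >= 1 || h2_P + conf2 >= 1) {
    stop("variance budget infeasible: heritability + confounder share ",
         "must leave a positive residual", call. = FALSE)
  }
  structure(list(n_individuals = as.numeric(n_individuals),
                 n_snps = as.integer(n_snps),
                 cluster_props = cluster_props,
                 r2_I_split = r2_I_split, h2_I = h2_I, h2_P = h2_P,
                 conf2 = conf2, rho_d = rho_d, p_split = p_split,
                 maf_range = maf_range, mediated = mediated,
                 beta_IP = beta_IP, seed = as.integer(seed)),
            class = "sh_scenario")
}

#' Preset study scenarios
#'
#' Named configurations of the generative model:
#' \describe{
#'   \item{`sc1`, `sc2`, `sc3`}{the main scenarios — 5% of variants in each
#'     of the I-only, both-trait and P-only clusters, with the I-only
#'     cluster explaining more (0.35 vs 0.15), equal (0.25 vs 0.25) or less
#'     (0.15 vs 0.35) of the variance of I than the both-trait cluster.}
#'   \item{`s1`, `s2`}{fewer I-only variants (1%) against 9% both-trait
#'     variants, with the I-only cluster explaining a larger (s1) or equal
#'     (s2) share of I.}
#'   \item{`s3`, `s4`}{both-trait effects act through a single shared
#'     exposure (perfect direct-effect correlation), explaining less (s3)
#'     or more (s4) of I than the I-only cluster; s4 puts the modal
#'     outcome/incidence ratio on the both-trait cluster, violating the
#'     zero-modal-residual assumption.}
#'   \item{`fig5a`, `fig5b`}{single-dataset illustration configurations:
#'     the balanced scenario with uncorrelated direct effects, and with
#'     direct-effect correlation 0.4.}
#' }
#'
#' @param name Preset name (see above).
#' @param rho_d Direct-effect correlation (ignored by `fig5a`/`fig5b`,
#'   which fix it; sign only for `s3`/`s4`).
#' @param ... Overrides passed on to [scenario_config()] (e.g. `seed`,
#'   `n_individuals`).
#' @return An `sh_scenario`.
#' @export
preset_scenario <- function(name, rho_d = 0, ...) {
  presets <- list(
    sc1 = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
               r2_I_split = c(0.35, 0.15)),
    sc2 = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
               r2_I_split = c(0.25, 0.25)),
    sc3 = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
               r2_I_split = c(0.15, 0.35)),
    s1 = list(cluster_props = c(0.01, 0.09, 0.05, 0.85),
              r2_I_split = c(0.35, 0.15)),
    s2 = list(cluster_props = c(0.01, 0.09, 0.05, 0.85),
              r2_I_split = c(0.25, 0.25)),
    s3 = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
              r2_I_split = c(0.35, 0.15), mediated = TRUE),
    s4 = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
              r2_I_split = c(0.15, 0.35), mediated = TRUE),
    fig5a = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
                 r2_I_split = c(0.25, 0.25), rho_d = 0),
    fig5b = list(cluster_props = c(0.05, 0.05, 0.05, 0.85),
                 r2_I_split = c(0.25, 0.25), rho_d = 0.4)
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; choose one of ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  args <- presets[[name]]
  if (is.null(args$rho_d)) args$rho_d <- rho_d
  do.call(scenario_config, utils::modifyList(args, list(...)))
}

# Draw per-cluster true effect sizes. Effects are normal on the
# standardised-genotype scale (each variant's expected explained variance
# is independent of its allele frequency), converted to the per-allele
# scale by 1/sqrt(vg) with vg = 2*maf*(1-maf), and rescaled so each
# cluster's realised explained variance hits its target share exactly.
draw_true_effects <- function(cfg, maf) {
  m <- cfg$n_snps
  vg <- 2 * maf * (1 - maf)
  counts <- round(cfg$cluster_props * m)
  counts[4] <- m - sum(counts[1:3])
  cluster <- rep(c("GI.", "GIP", "G.P", "G.."), counts)
  beta_I <- numeric(m)
  beta_P <- numeric(m)
  scale_to <- function(z, vg, target) {
    if (target <= 0) return(z * 0)
    (z / sqrt(vg)) * sqrt(target / sum(z^2))
  }
  i1 <- which(cluster == "GI."); i2 <- which(cluster == "GIP")
  i3 <- which(cluster == "G.P")
  beta_I[i1] <- scale_to(stats::rnorm(length(i1)), vg[i1],
                         cfg$r2_I_split[1])
  if (cfg$mediated) {
    alpha <- stats::rnorm(length(i2))
    beta_I[i2] <- scale_to(alpha, vg[i2], cfg$r2_I_split[2])
    beta_P[i2] <- sign(if (cfg$rho_d == 0) 1 else cfg$rho_d) *
      scale_to(alpha, vg[i2], cfg$p_split[1])
  } else {
    z1 <- stats::rnorm(length(i2))
    z2 <- cfg$rho_d * z1 + sqrt(1 - cfg$rho_d^2) *
      stats::rnorm(length(i2))
    beta_I[i2] <- scale_to(z1, vg[i2], cfg$r2_I_split[2])
    beta_P[i2] <- scale_to(z2, vg[i2], cfg$p_split[1])
  }
  beta_P[i3] <- scale_to(stats::rnorm(length(i3)), vg[i3], cfg$p_split[2])
  list(cluster = cluster, beta_I = beta_I, beta_P = beta_P, vg = vg)
}

# Population bias slope from the structural model: minus the shared
# covariance of I and P given a focal variant over the variance of I given
# that variant (~1 on the standardised scale). The shared covariance is the
# confounder term plus the direct-effect covariance of the both-trait
# cluster.
closed_form_slope <- function(cfg) {
  cov_d <- if (cfg$mediated) {
    sign(if (cfg$rho_d == 0) 1 else cfg$rho_d) *
      sqrt(cfg$r2_I_split[2] * cfg$p_split[1])
  } else {
    cfg$rho_d * sqrt(cfg$r2_I_split[2] * cfg$p_split[1])
  }
  -(cfg$conf2 + cov_d)
}

block_seed <- function(seed, b) {
  as.integer((as.numeric(seed) * 1009 + 7919 * b) %% 2147483047)
}

# Per-SNP OLS of I ~ G and P ~ G + I for one genotype block.
# Ic, Pc are the centred trait vectors; Sii, Sip, Spp their cross-moments.
block_ols <- function(G, Ic, Pc, Sii, Sip, Spp) {
  n <- nrow(G)
  cm <- colMeans(G)
  Sgg <- colSums(G^2) - n * cm^2
  Sgi <- as.numeric(crossprod(G, Ic))
  Sgp <- as.numeric(crossprod(G, Pc))
  ## marginal regression I ~ G
  beta_I <- Sgi / Sgg
  rss_I <- Sii - beta_I^2 * Sgg
  se_I <- sqrt(rss_I / (n - 2) / Sgg)
  ## conditional regression P ~ G + I
  D <- Sgg * Sii - Sgi^2
  beta_P <- (Sgp * Sii - Sip * Sgi) / D
  beta_IP <- (Sip * Sgg - Sgp * Sgi) / D
  rss_P <- Spp - beta_P * Sgp - beta_IP * Sip
  se_P <- sqrt(rss_P / (n - 3) * Sii / D)
  list(beta_I = beta_I, se_I = se_I, beta_P = beta_P, se_P = se_P)
}

#' Simulate one conditional-GWAS study with full ground truth
#'
#' Generates a dataset under the four-cluster model of [scenario_config()]
#' and computes per-variant summary statistics: the incidence effects from
#' marginal OLS of I on genotype, and the (collider-biased) conditional
#' outcome effects from OLS of P on genotype and I.
#'
#' Two modes are available. `"individual"` simulates genotypes
#' (Binomial(2, maf)), traits, and runs the per-variant regressions — the
#' reference data-generating process. `"summary"` draws the estimated
#' effects directly from the sampling distributions implied by the
#' individual-level model (`beta_I_hat ~ N(beta_I, s_I^2)`,
#' `beta_P_hat ~ N(beta_P + b * beta_I, s_P'^2)` with `b` the population
#' bias slope), which is orders of magnitude faster but approximate: the
#' sampling correlation between the two estimates is ignored.
#'
#' @param cfg An [scenario_config()] / [preset_scenario()].
#' @param mode `"individual"` or `"summary"`.
#' @param block_size Variants per genotype block in individual mode
#'   (memory/speed trade-off; results are independent of it given the seed
#'   layout, which is per block).
#' @return An object of class `sh_study`: list with `cfg`, `mode`, `truth`
#'   (data frame: `snp_id`, `maf`, `cluster`, `beta_I_true`,
#'   `beta_P_true`), `sumstats` (a harmonised-format table with an added
#'   `cluster` column), `true_slope` (closed-form population bias slope)
#'   and `realized_slope` (through-origin regression of the realised bias
#'   `beta_P_hat - beta_P_true` on `beta_I_hat` over the I-affecting
#'   variants).
#' @export
simulate_study <- function(cfg, mode = c("individual", "summary"),
                           block_size = 250L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "sh_scenario"))
  n <- cfg$n_individuals; m <- cfg$n_snps
  eff <- withr_seed(cfg$seed, {
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    e <- draw_true_effects(cfg, maf)
    e$maf <- maf
    e
  })
  b_cf <- closed_form_slope(cfg)

  if (mode == "individual") {
    env <- withr_seed(cfg$seed + 2L, list(
      U = stats::rnorm(n),
      eps_I = stats::rnorm(n, 0, sqrt(1 - cfg$h2_I - cfg$conf2)),
      eps_P = stats::rnorm(n, 0, sqrt(1 - cfg$h2_P - cfg$conf2))
    ))
    blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))
    gen_block <- function(b) {
      idx <- blocks[[b]]
      withr_seed(block_seed(cfg$seed, b), {
        matrix(stats::rbinom(n * length(idx), 2L,
                             rep(eff$maf[idx], each = n)),
               nrow = n)
      })
    }
    ## pass 1: genetic values of both traits
    Ig <- numeric(n); Pg <- numeric(n)
    for (b in seq_along(blocks)) {
      G <- gen_block(b)
      idx <- blocks[[b]]
      Ig <- Ig + as.numeric(G %*% eff$beta_I[idx])
      Pg <- Pg + as.numeric(G %*% eff$beta_P[idx])
    }
    I <- Ig + sqrt(cfg$conf2) * env$U + env$eps_I
    P <- Pg + sqrt(cfg$conf2) * env$U + cfg$beta_IP * I + env$eps_P
    Ic <- I - mean(I); Pc <- P - mean(P)
    Sii <- sum(Ic^2); Sip <- sum(Ic * Pc); Spp <- sum(Pc^2)
    ## pass 2: per-variant regressions (blocks regenerated from their seeds)
    bI <- sI <- bP <- sP <- numeric(m)
    for (b in seq_along(blocks)) {
      G <- gen_block(b)
      idx <- blocks[[b]]
      o <- block_ols(G, Ic, Pc, Sii, Sip, Spp)
      bI[idx] <- o$beta_I; sI[idx] <- o$se_I
      bP[idx] <- o$beta_P; sP[idx] <- o$se_P
    }
    var_I <- Sii / (n - 1); var_P <- Spp / (n - 1)
  } else {
    draws <- withr_seed(cfg$seed + 1L, {
      list(zI = stats::rnorm(m), zP = stats::rnorm(m))
    })
    vg <- eff$vg
    sI <- sqrt(pmax(1 - eff$beta_I^2 * vg, 1e-12) / (n * vg))
    cor_IP <- cfg$conf2 +
      sum(eff$beta_I * eff$beta_P * vg) + cfg$beta_IP
    sP <- sqrt(pmax(1 - cor_IP^2, 1e-12) / (n * vg))
    bI <- eff$beta_I + draws$zI * sI
    bP <- eff$beta_P + b_cf * eff$beta_I + draws$zP * sP
    var_I <- var_P <- NA_real_
  }

  ids <- sprintf("snp%05d", seq_len(m))
  truth <- data.frame(snp_id = ids, maf = eff$maf, cluster = eff$cluster,
                      beta_I_true = eff$beta_I, beta_P_true = eff$beta_P,
                      stringsAsFactors = FALSE)
  sumstats <- data.frame(
    snp_id = ids, effect_allele = "A", other_allele = "G",
    beta_I = bI, se_I = sI, p_I = wald_pvalue(bI, sI),
    beta_P = bP, se_P = sP, p_P = wald_pvalue(bP, sP),
    cluster = eff$cluster, stringsAsFactors = FALSE
  )
  class(sumstats) <- c("sh_harmonised", "data.frame")

  aff <- eff$cluster %in% c("GI.", "GIP")
  bias <- bP[aff] - eff$beta_P[aff]
  xh <- bI[aff]
  realized <- sum(xh * bias) / sum(xh^2)

  structure(list(cfg = cfg, mode = mode, truth = truth,
                 sumstats = sumstats, true_slope = b_cf,
                 realized_slope = realized,
                 var_I = var_I, var_P = var_P, seed = cfg$seed),
            class = "sh_study")
}

#' @export
print.sh_study <- function(x, ...) {
  cat(sprintf("Simulated conditional-GWAS study (%s mode)\n", x$mode))
  cat(sprintf("  %d variants x %d individuals, rho_d = %.2f%s\n",
              x$cfg$n_snps, x$cfg$n_individuals, x$cfg$rho_d,
              if (x$cfg$mediated) " (mediated)" else ""))
  cat(sprintf("  population bias slope: %.4f; realised slope: %.4f\n",
              x$true_slope, x$realized_slope))
  invisible(x)
}

#' Empirical bias-slope oracle for a scenario
#'
#' Computes the collider-bias slope two ways: (i) the closed-form
#' population value from the structural model, and (ii) empirically, by
#' simulating one individual-level study and regressing the realised bias
#' of the I-only variants' conditional outcome estimates on their estimated
#' incidence effects (through the origin). The empirical value — which
#' includes the regression-dilution attenuation inherent in working on the
#' estimated-effect scale — is returned, with the closed form attached as
#' an attribute and reported via `message()`. The two are expected to
#' differ by the regression-dilution attenuation factor (roughly
#' `(1 - lambda) * |b|`, up to ~0.1 for the strongest simulated slopes at
#' the default sample size); a warning is raised only if they disagree by
#' more than `tolerance`, which would indicate an inconsistency rather
#' than attenuation.
#'
#' @param cfg An [scenario_config()].
#' @param n_replicates Average the empirical slope over this many seeds
#'   (default 1).
#' @param tolerance Warn when |empirical - closed form| exceeds this
#'   (default 0.2).
#' @return The empirical slope, with attributes `closed_form` and
#'   `per_replicate`.
#' @export
true_slope <- function(cfg, n_replicates = 1, tolerance = 0.2) {
  vals <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(cfg$seed + (r - 1))
    st <- simulate_study(cfg_r, mode = "individual")
    gi <- st$sumstats$cluster == "GI."
    x <- st$sumstats$beta_I[gi]
    y <- st$sumstats$beta_P[gi]  # true direct effect is 0 for this cluster
    vals[r] <- sum(x * y) / sum(x^2)
  }
  emp <- mean(vals)
  cf <- closed_form_slope(cfg)
  message(sprintf("true_slope: empirical %.4f, closed form %.4f", emp, cf))
  if (abs(emp - cf) > tolerance) {
    warning("true_slope: empirical and closed-form slopes differ by more ",
            "than ", tolerance)
  }
  structure(emp, closed_form = cf, per_replicate = vals)
}

#' Draw effect pairs directly from the two-component slope mixture
#'
#' Samples observed (incidence, outcome) effect pairs from the constrained
#' mixture itself: with probability `pi1` a point lies on the proportional
#' line (`y = b1 x` plus `N(0, tau2)` scatter); otherwise it carries an
#' additional direct outcome effect with variance `sP2` and covariance
#' `sigIP` with the incidence effect. Used as a parameter-recovery oracle
#' for [em_fit()] and as a compact synthetic-fixture generator.
#'
#' @param n Number of variants.
#' @param b1 Proportional-cluster slope.
#' @param pi1 Mixing weight of the proportional cluster.
#' @param sI2 Marginal variance of the incidence effects (both components).
#' @param sigIP Covariance of incidence and direct outcome effects in the
#'   second component.
#' @param sP2 Direct-outcome-effect variance of the second component.
#' @param tau2 Measurement scatter about both lines (default 0).
#' @param seed Integer seed.
#' @return Data frame with `beta_I`, `beta_P`, `se_I`, `se_P`, `component`.
#' @export
simulate_mixture_pairs <- function(n, b1, pi1, sI2, sigIP, sP2,
                                   tau2 = 0, seed = 1L) {
  stopifnot(pi1 > 0, pi1 < 1, sI2 > 0, sP2 >= 0,
            sigIP^2 <= sI2 * sP2 + 1e-12)
  withr_seed(seed, {
    comp <- ifelse(stats::runif(n) < pi1, 1L, 2L)
    x <- stats::rnorm(n, 0, sqrt(sI2))
    y_direct <- numeric(n)
    i2 <- comp == 2L
    cond_var <- sP2 - sigIP^2 / sI2
    y_direct[i2] <- (sigIP / sI2) * x[i2] +
      stats::rnorm(sum(i2), 0, sqrt(max(cond_var, 0)))
    y <- b1 * x + y_direct + stats::rnorm(n, 0, sqrt(tau2))
    se <- rep(max(sqrt(tau2), 1e-4), n)
    data.frame(beta_I = x, beta_P = y, se_I = se, se_P = se,
               component = comp)
  })
}

#' Write a simulated study to disk
#'
#' Writes `<prefix>_truth.tsv` (per-variant ground truth) and
#' `<prefix>_sumstats.tsv` (estimated summary statistics readable by
#' [read_sumstats()] twice — incidence columns and outcome columns).
#'
#' @param study An `sh_study`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_study <- function(study, prefix) {
  p1 <- paste0(prefix, "_truth.tsv")
  p2 <- paste0(prefix, "_sumstats.tsv")
  utils::write.table(study$truth, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$sumstats, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
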