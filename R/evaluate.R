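#' Per-replicate performance metrics
#'
#' Scores one or more adjusted (or unadjusted) association tables against
#' the ground truth of a simulated study. For each method the following are
#' computed at significance level `alpha`:
#' \itemize{
#'   \item `type1_null_all`: share of variants truly null for the outcome
#'     (the I-only and null clusters) with `p < alpha`;
#'   \item `type1_GI`: the same share over the I-only cluster alone, where
#'     all of the collider bias sits;
#'   \item `fwer_GI`: 1 if at least one I-only variant is significant after
#'     Bonferroni correction (`alpha / n_snps`), else 0;
#'   \item `power_causal_all`: share of variants with true direct outcome
#'     effects (both-trait and P-only clusters) with `p < alpha`;
#'   \item `power_GIP`: the same over the both-trait cluster;
#'   \item `mean_abs_bias`, `mse`: mean absolute error and mean squared
#'     error of the effect estimates against the true direct effects, over
#'     all variants;
#'   \item `mean_abs_bias_I`, `mse_I`: the same over I-affecting variants.
#' }
#'
#' @param study An `sh_study` (provides the truth labels).
#' @param adjusted Named list of data frames, one per method, each with
#'   columns `snp_id`, `beta_adj`, `se_adj`, `p_adj` (as produced by
#'   [adjust_associations()]).
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per method and the metric columns
#'   above.
#' @export
evaluate_metrics <- function(study, adjusted, alpha = 0.05) {
  stopifnot(inherits(study, "sh_study"), is.list(adjusted),
            length(names(adjusted)) == length(adjusted))
  truth <- study$truth
  if (is.null(truth$cluster)) stop("study truth lacks cluster labels",
                                   call. = FALSE)
  n_snps <- nrow(truth)
  rows <- lapply(names(adjusted), function(method) {
    a <- adjusted[[method]]
    ord <- match(truth$snp_id, a$snp_id)
    if (any(is.na(ord))) stop("adjusted table for '", method,
                              "' is missing variants", call. = FALSE)
    a <- a[ord, , drop = FALSE]
    null_P <- truth$cluster %in% c("GI.", "G..")
    gi <- truth$cluster == "GI."
    causal <- truth$cluster %in% c("GIP", "G.P")
    gip <- truth$cluster == "GIP"
    err <- a$beta_adj - truth$beta_P_true
    data.frame(
      method = method,
      type1_null_all = mean(a$p_adj[null_P] < alpha),
      type1_GI = mean(a$p_adj[gi] < alpha),
      fwer_GI = as.numeric(any(a$p_adj[gi] < alpha / n_snps)),
      power_causal_all = mean(a$p_adj[causal] < alpha),
      power_GIP = mean(a$p_adj[gip] < alpha),
      mean_abs_bias = mean(abs(err)),
      mse = mean(err^2),
      mean_abs_bias_I = mean(abs(err[gi | gip])),
      mse_I = mean(err[gi | gip]^2),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Build the per-method adjusted tables for one simulated study.
# Returns list(tables = named list, slopes = named numeric).
fit_methods <- function(study, methods, lambda, em_cfg) {
  ss <- study$sumstats
  tables <- list(); slopes <- c()
  if ("unadjusted" %in% methods) {
    tables$unadjusted <- data.frame(snp_id = ss$snp_id,
                                    beta_adj = ss$beta_P,
                                    se_adj = ss$se_P, p_adj = ss$p_P,
                                    stringsAsFactors = FALSE)
    slopes["unadjusted"] <- 0
  }
  if ("SH" %in% methods) {
    fit <- hunt_slope(ss, selection_config(lambda = lambda), em_cfg)
    tables$SH <- adjust_associations(ss, fit$b1, method = "SH")
    slopes["SH"] <- fit$b1
  }
  if ("DHO" %in% methods) {
    dho <- dho_estimate(ss)
    tables$DHO <- adjust_associations(ss, dho$b_ho, method = "DHO")
    slopes["DHO"] <- dho$b_ho
  }
  list(tables = tables, slopes = slopes)
}

#' Run the scenario x correlation x method evaluation grid
#'
#' Replicates each (preset, rho_d) cell `n_replicates` times with
#' independent seeds, applies each estimator, and aggregates
#' [evaluate_metrics()] plus the correction-factor distribution into a
#' long-format table of means and Monte-Carlo standard errors.
#'
#' @param presets Character vector of [preset_scenario()] names.
#' @param rho_levels Numeric vector of direct-effect correlations.
#' @param methods Subset of `c("unadjusted", "SH", "DHO")`.
#' @param n_replicates Replicates per cell.
#' @param seed Base seed; replicate r of cell k uses a seed derived from
#'   it, so the whole grid is reproducible.
#' @param mode Simulation mode (default `"summary"` for tractable grids;
#'   `"individual"` is the reference process).
#' @param lambda Selection threshold for the Slope-Hunter fits.
#' @param em_cfg EM settings; the default disables the bootstrap, which is
#'   not needed for grid metrics.
#' @param alpha Significance level.
#' @param n_individuals,n_snps Optional overrides of the preset sizes.
#' @return A data frame in long format: `scenario`, `rho_d`, `method`,
#'   `metric`, `value` (mean over replicates), `mc_se`, `n_reps`. The
#'   metrics include those of [evaluate_metrics()] plus `slope_est` (mean
#'   fitted correction factor), `slope_sd` (its SD across replicates) and
#'   `slope_bias` (mean fitted minus realised bias slope). Replicates whose
#'   fit fails are dropped and counted in the `n_failed` attribute.
#' @export
run_grid <- function(presets, rho_levels, methods = c("unadjusted", "SH",
                                                      "DHO"),
                     n_replicates = 100, seed = 1L, mode = "summary",
                     lambda = 0.001,
                     em_cfg = em_config(n_restarts = 3, bootstrap_B = 0),
                     alpha = 0.05, n_individuals = NULL, n_snps = NULL) {
  stopifnot(n_replicates >= 1)
  out <- list(); n_failed <- 0L
  cell <- 0L
  for (preset in presets) for (rho in rho_levels) {
    cell <- cell + 1L
    reps <- vector("list", n_replicates)
    slopes <- matrix(NA_real_, n_replicates, length(methods),
                     dimnames = list(NULL, methods))
    true_slopes <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- as.integer((as.numeric(seed) * 131071 +
                                cell * 8191 + r) %% 2147483047)
      args <- list(name = preset, rho_d = rho, seed = rep_seed)
      if (!is.null(n_individuals)) args$n_individuals <- n_individuals
      if (!is.null(n_snps)) args$n_snps <- n_snps
      cfg <- do.call(preset_scenario, args)
      res <- tryCatch({
        study <- simulate_study(cfg, mode = mode)
        fm <- fit_methods(study, methods, lambda, em_cfg)
        met <- evaluate_metrics(study, fm$tables, alpha)
        list(met = met, slopes = fm$slopes, ts = study$realized_slope)
      }, error = function(e) {
        message("replicate failed (", preset, ", rho ", rho, ", r ", r,
                "): ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      reps[[r]] <- res$met
      slopes[r, names(res$slopes)] <- res$slopes
      true_slopes[r] <- res$ts
    }
    ok <- !vapply(reps, is.null, logical(1))
    if (!any(ok)) next
    mets <- do.call(rbind, reps[ok])
    metric_cols <- setdiff(names(mets), "method")
    for (method in unique(mets$method)) {
      sub <- mets[mets$method == method, metric_cols, drop = FALSE]
      mu <- colMeans(sub)
      mcse <- apply(sub, 2, stats::sd) / sqrt(nrow(sub))
      rows <- data.frame(scenario = preset, rho_d = rho, method = method,
                         metric = metric_cols, value = unname(mu),
                         mc_se = unname(mcse), n_reps = nrow(sub),
                         stringsAsFactors = FALSE)
      sl <- slopes[ok, method]
      extra <- data.frame(
        scenario = preset, rho_d = rho, method = method,
        metric = c("slope_est", "slope_sd", "slope_bias"),
        value = c(mean(sl), stats::sd(sl),
                  mean(sl - true_slopes[ok])),
        mc_se = c(stats::sd(sl) / sqrt(sum(ok)), NA,
                  stats::sd(sl) / sqrt(sum(ok))),
        n_reps = sum(ok), stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- rbind(rows, extra)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_failed") <- n_failed
  res
}
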