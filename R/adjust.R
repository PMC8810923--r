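#' Collider-bias-adjusted variant-outcome associations
#'
#' Subtracts the bias component from every variant's conditional outcome
#' association: `beta_adj = beta_P - b1 * beta_I`. The adjustment applies to
#' all variants (selected or not); variants with no incidence effect are
#' unchanged, as they suffer no collider bias.
#'
#' Standard errors are computed per `se_mode`:
#' \describe{
#'   \item{`"propagate"`}{`sqrt(se_P^2 + b1^2 * se_I^2)` — independent-error
#'     propagation treating `b1` as fixed (the default).}
#'   \item{`"propagate+slope"`}{additionally carries the slope uncertainty:
#'     `sqrt(se_P^2 + b1^2 * se_I^2 + beta_I^2 * se_b1^2)`.}
#' }
#'
#' @param harmonised A harmonised table (see [harmonise()]).
#' @param b1 Correction factor (slope), e.g. `fit$b1` from [hunt_slope()].
#' @param se_b1 Standard error of `b1`; required for `"propagate+slope"`.
#' @param se_mode `"propagate"` or `"propagate+slope"`.
#' @param method Label stored in the `method` column (default `"SH"`).
#' @return A data frame with `snp_id`, `beta_adj`, `se_adj`, `p_adj`
#'   (two-sided Wald), `method`, alongside the input effect columns.
#' @export
adjust_associations <- function(harmonised, b1, se_b1 = NA_real_,
                                se_mode = c("propagate", "propagate+slope"),
                                method = "SH") {
  se_mode <- match.arg(se_mode)
  stopifnot(is.finite(b1))
  beta_adj <- harmonised$beta_P - b1 * harmonised$beta_I
  var_adj <- harmonised$se_P^2 + b1^2 * harmonised$se_I^2
  if (se_mode == "propagate+slope") {
    if (!is.finite(se_b1)) {
      stop("se_mode 'propagate+slope' requires a finite se_b1",
           call. = FALSE)
    }
    var_adj <- var_adj + harmonised$beta_I^2 * se_b1^2
  }
  se_adj <- sqrt(var_adj)
  out <- data.frame(
    snp_id = harmonised$snp_id,
    beta_I = harmonised$beta_I, se_I = harmonised$se_I,
    beta_P = harmonised$beta_P, se_P = harmonised$se_P,
    beta_adj = beta_adj, se_adj = se_adj,
    p_adj = wald_pvalue(beta_adj, se_adj),
    method = method,
    stringsAsFactors = FALSE
  )
  if ("effect_allele" %in% names(harmonised)) {
    out$effect_allele <- harmonised$effect_allele
    out$other_allele <- harmonised$other_allele
  }
  out
}

#' Hedges-Olkin-corrected regression estimator of the bias slope
#'
#' The comparator estimator: ordinary least squares of the conditional
#' outcome effects on the incidence effects over *all* harmonised variants
#' (no selection threshold), with the Hedges-Olkin regression-dilution
#' correction replacing the regressor variance by its measurement-error-free
#' part, `var(beta_I) - mean(se_I^2)`. Valid when incidence effects are
#' linearly uncorrelated with direct outcome effects; correlated direct
#' effects bias this estimator toward the direct-effect slope.
#'
#' @param harmonised A harmonised table with `beta_I`, `se_I`, `beta_P`.
#' @return An object of class `sh_dho`: list with `b_raw` (uncorrected OLS
#'   slope), `b_ho` (dilution-corrected slope), `mean_sI2`, `n_snps`.
#' @export
dho_estimate <- function(harmonised) {
  x <- harmonised$beta_I; y <- harmonised$beta_P
  if (length(x) < 3) stop("dho_estimate: need >= 3 variants", call. = FALSE)
  mean_sI2 <- mean(harmonised$se_I^2)
  vx <- stats::var(x)
  cxy <- stats::cov(x, y)
  denom <- vx - mean_sI2
  if (!is.finite(denom) || denom <= 0) {
    stop("dho_estimate: var(beta_I) does not exceed mean(se_I^2); ",
         "dilution correction undefined", call. = FALSE)
  }
  structure(list(b_raw = cxy / vx, b_ho = cxy / denom,
                 mean_sI2 = mean_sI2, n_snps = length(x)),
            class = "sh_dho")
}

#' @export
print.sh_dho <- function(x, ...) {
  cat(sprintf(paste0("Hedges-Olkin regression slope: %.4f ",
                     "(uncorrected OLS %.4f; %d variants)\n"),
              x$b_ho, x$b_raw, x$n_snps))
  invisible(x)
}

#' Side-by-side unadjusted / Slope-Hunter / Hedges-Olkin report
#'
#' @param harmonised A harmonised table.
#' @param sh_fit An `sh_fit` from [hunt_slope()] (or `NULL` to omit).
#' @param dho_fit An `sh_dho` from [dho_estimate()] (or `NULL` to omit).
#' @param se_mode Passed to [adjust_associations()].
#' @return A data frame with one row per variant carrying the incidence
#'   effects plus, per method, adjusted beta, SE and p-value columns
#'   (`BETA_UNADJ` ... `P_DHO`). Write with [write_sumstats()].
#' @export
compare_report <- function(harmonised, sh_fit = NULL, dho_fit = NULL,
                           se_mode = "propagate") {
  if (nrow(harmonised) == 0L) {
    return(data.frame(SNP = character(0)))
  }
  rep_cols <- data.frame(
    SNP = harmonised$snp_id,
    EA = if ("effect_allele" %in% names(harmonised))
      harmonised$effect_allele else NA_character_,
    OA = if ("other_allele" %in% names(harmonised))
      harmonised$other_allele else NA_character_,
    BETA_I = harmonised$beta_I, SE_I = harmonised$se_I,
    BETA_UNADJ = harmonised$beta_P, SE_UNADJ = harmonised$se_P,
    P_UNADJ = wald_pvalue(harmonised$beta_P, harmonised$se_P),
    stringsAsFactors = FALSE
  )
  if (!is.null(sh_fit)) {
    adj <- adjust_associations(harmonised, sh_fit$b1, sh_fit$se_b1,
                               se_mode = se_mode, method = "SH")
    rep_cols$BETA_SH <- adj$beta_adj
    rep_cols$SE_SH <- adj$se_adj
    rep_cols$P_SH <- adj$p_adj
  }
  if (!is.null(dho_fit)) {
    adj <- adjust_associations(harmonised, dho_fit$b_ho,
                               se_mode = "propagate", method = "DHO")
    rep_cols$BETA_DHO <- adj$beta_adj
    rep_cols$SE_DHO <- adj$se_adj
    rep_cols$P_DHO <- adj$p_adj
  }
  rep_cols
}
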