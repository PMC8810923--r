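#' Two-sided Wald p-value
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return `2 * pnorm(-abs(beta / se))`, in (0, 1].
#' @examples
#' wald_pvalue(1.959964, 1) # ~0.05
#' @export
wald_pvalue <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("wald_pvalue: se must be finite and > 0", call. = FALSE)
  }
  2 * stats::pnorm(-abs(beta / se))
}

#' Selection settings for the incidence-associated variant set
#'
#' @param lambda P-value threshold for declaring a variant associated with
#'   the conditioning trait; variants with `p < lambda` enter the mixture
#'   fit. Default 0.001. The fitted slope is typically insensitive to this
#'   choice except at very permissive values, but a sensitivity sweep over
#'   several thresholds is good practice.
#' @param selection_pvalues Optional named numeric vector of per-variant
#'   p-values from an independent study of the conditioning trait, used for
#'   selection instead of the analysis table's own p-values to avoid
#'   winner's-curse bias.
#' @return An object of class `sh_selection`.
#' @export
selection_config <- function(lambda = 0.001, selection_pvalues = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            lambda > 0, lambda <= 1)
  if (!is.null(selection_pvalues) && is.null(names(selection_pvalues))) {
    stop("selection_pvalues must be named by snp_id", call. = FALSE)
  }
  structure(list(lambda = lambda, selection_pvalues = selection_pvalues),
            class = "sh_selection")
}

#' Select variants associated with the conditioning trait
#'
#' Retains the harmonised variants whose incidence-association p-value is
#' strictly below the threshold `lambda`. P-values are taken, in order of
#' preference, from (i) `cfg$selection_pvalues` (an independent selection
#' study), (ii) the table's `p_I` column, (iii) a two-sided Wald test
#' recomputed from `beta_I`/`se_I` (the recomputation is reported via
#' `message()`). Stored effect sizes and standard errors are never altered.
#'
#' @param table A harmonised table (see [harmonise()]).
#' @param cfg A [selection_config()].
#' @return The subset of `table` passing selection.
#' @export
select_incidence_snps <- function(table, cfg = selection_config()) {
  stopifnot(inherits(cfg, "sh_selection"))
  if (!is.null(cfg$selection_pvalues)) {
    p <- unname(cfg$selection_pvalues[table$snp_id])
  } else if ("p_I" %in% names(table) && !all(is.na(table$p_I))) {
    p <- table$p_I
  } else {
    message("select_incidence_snps: recomputing p_I from beta_I/se_I ",
            "(Wald test)")
    p <- wald_pvalue(table$beta_I, table$se_I)
  }
  keep <- !is.na(p) & p < cfg$lambda
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("select_incidence_snps: no variants pass lambda = ", cfg$lambda,
         "; consider raising the threshold", call. = FALSE)
  }
  out
}
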