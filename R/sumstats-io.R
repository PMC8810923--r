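#' Describe the physical columns of a summary-statistics file
#'
#' GWAS summary statistics come in many column dialects. A column map names
#' the physical column that carries each logical field. `beta` and `se` are
#' mandatory; everything else is optional and will be `NA` when absent.
#'
#' @param snp_id,effect_allele,other_allele,eaf,beta,se,pvalue,n,chrom,pos
#'   Column names in the file. Set to `NULL` for fields the file lacks.
#' @return An object of class `sh_column_map` (named list).
#' @examples
#' column_map(beta = "BETA", se = "SE", snp_id = "rsid")
#' @export
column_map <- function(snp_id = "SNP", effect_allele = "EA",
                       other_allele = "OA", eaf = "EAF",
                       beta = "BETA", se = "SE", pvalue = "P", n = "N",
                       chrom = NULL, pos = NULL) {
  if (is.null(beta) || is.null(se)) {
    stop("column_map: 'beta' and 'se' columns are mandatory", call. = FALSE)
  }
  structure(list(snp_id = snp_id, effect_allele = effect_allele,
                 other_allele = other_allele, eaf = eaf, beta = beta,
                 se = se, pvalue = pvalue, n = n, chrom = chrom, pos = pos),
            class = "sh_column_map")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file of per-SNP association statistics and returns
#' a standardised data frame (one row per variant). Rows with a missing or
#' non-positive standard error, or an unparsable effect size, are dropped;
#' the number dropped is reported via `message()`. Duplicate variant ids are
#' resolved by keeping the first occurrence (with a warning), so that ids are
#' unique within the returned table.
#'
#' @param path Path to a delimited text file with a header row.
#' @param cmap A [column_map()] describing the file's columns.
#' @param delimiter Field delimiter; `""` (default) splits on any whitespace.
#' @return A data frame of class `sh_sumstats` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`
#'   (and `chrom`/`pos` when mapped). Alleles are uppercased.
#' @export
read_sumstats <- function(path, cmap = column_map(), delimiter = "") {
  stopifnot(inherits(cmap, "sh_column_map"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  missing_cols <- setdiff(c(cmap$beta, cmap$se), names(raw))
  if (length(missing_cols)) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pull <- function(field, as = "character") {
    col <- cmap[[field]]
    if (is.null(col) || !col %in% names(raw)) return(rep(NA, nrow(raw)))
    x <- raw[[col]]
    if (as == "numeric") suppressWarnings(as.numeric(x)) else as.character(x)
  }
  out <- data.frame(
    snp_id        = pull("snp_id"),
    effect_allele = toupper(pull("effect_allele")),
    other_allele  = toupper(pull("other_allele")),
    eaf           = pull("eaf", "numeric"),
    beta          = pull("beta", "numeric"),
    se            = pull("se", "numeric"),
    pvalue        = pull("pvalue", "numeric"),
    n             = pull("n", "numeric"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cmap$chrom)) out$chrom <- pull("chrom")
  if (!is.null(cmap$pos)) out$pos <- pull("pos", "numeric")
  if (all(is.na(out$snp_id))) out$snp_id <- paste0("row", seq_len(nrow(out)))

  keep <- is.finite(out$beta) & is.finite(out$se) & out$se > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("read_sumstats: dropped ", n_drop,
            " row(s) with missing beta or non-positive SE")
    out <- out[keep, , drop = FALSE]
  }
  dup <- duplicated(out$snp_id)
  if (any(dup)) {
    warning("read_sumstats: ", sum(dup),
            " duplicate snp_id(s) dropped (first occurrence kept)")
    out <- out[!dup, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("no usable rows in ", path, call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("sh_sumstats", "data.frame")
  out
}

#' Write a summary-statistics or harmonised table to TSV
#'
#' @param x A data frame (e.g. from [read_sumstats()] or [harmonise()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonise incidence and conditional-outcome summary statistics
#'
#' Intersects two summary-statistics tables on variant id and aligns the
#' outcome effects to the incidence table's effect allele. When the outcome
#' table reports the swapped allele pair, its beta is sign-flipped (and its
#' allele frequency complemented). Variants whose allele pairs do not match
#' even after a swap are dropped. Allele comparison is an exact string match
#' after uppercasing, so indel alleles (e.g. `A`/`AACTT`) are supported.
#'
#' Palindromic variants (A/T or C/G) cannot be strand-checked from alleles
#' alone and are handled per `palindromic_policy`:
#' \describe{
#'   \item{`"keep"`}{retain them, trusting that both studies report the same
#'     strand (the default; appropriate when both tables use matched rsIDs).}
#'   \item{`"drop"`}{remove them.}
#'   \item{`"drop_if_eaf_ambiguous"`}{remove those whose effect-allele
#'     frequency (in either table) lies in (0.4, 0.6) or is missing, where
#'     frequency cannot resolve the strand.}
#' }
#'
#' @param incidence Summary statistics for the conditioning trait I.
#' @param outcome Summary statistics for the outcome P conditional on I.
#' @param palindromic_policy One of `"keep"`, `"drop"`,
#'   `"drop_if_eaf_ambiguous"`.
#' @return A data frame of class `sh_harmonised` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_I`, `se_I`, `p_I`, `beta_P`,
#'   `se_P`, `p_P` (p-values carried over when present, else `NA`).
#' @export
harmonise <- function(incidence, outcome,
                      palindromic_policy = c("keep", "drop",
                                             "drop_if_eaf_ambiguous")) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(nrow(incidence) > 0, nrow(outcome) > 0)
  common <- intersect(incidence$snp_id, outcome$snp_id)
  if (length(common) == 0L) {
    stop("harmonise: no variants shared between the two tables", call. = FALSE)
  }
  inc <- incidence[match(common, incidence$snp_id), , drop = FALSE]
  out <- outcome[match(common, outcome$snp_id), , drop = FALSE]

  same <- inc$effect_allele == out$effect_allele &
    inc$other_allele == out$other_allele
  swapped <- inc$effect_allele == out$other_allele &
    inc$other_allele == out$effect_allele
  # alleles unavailable on either side: match on id alone
  no_alleles <- is.na(inc$effect_allele) | is.na(out$effect_allele)
  same[no_alleles] <- TRUE
  swapped[no_alleles] <- FALSE

  beta_P <- ifelse(swapped, -out$beta, out$beta)
  eaf_P <- ifelse(swapped, 1 - out$eaf, out$eaf)
  keep <- same | swapped

  pal <- is_palindromic(inc$effect_allele, inc$other_allele) & !no_alleles
  if (palindromic_policy == "drop") {
    keep <- keep & !pal
  } else if (palindromic_policy == "drop_if_eaf_ambiguous") {
    ambiguous <- function(f) is.na(f) | (f > 0.4 & f < 0.6)
    keep <- keep & !(pal & (ambiguous(inc$eaf) | ambiguous(eaf_P)))
  }

  h <- data.frame(
    snp_id        = inc$snp_id,
    effect_allele = inc$effect_allele,
    other_allele  = inc$other_allele,
    beta_I = inc$beta, se_I = inc$se, p_I = inc$pvalue,
    beta_P = beta_P, se_P = out$se, p_P = out$pvalue,
    stringsAsFactors = FALSE
  )
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0L) stop("harmonise: no variants survive allele checks",
                          call. = FALSE)
  rownames(h) <- NULL
  class(h) <- c("sh_harmonised", "data.frame")
  h
}

#' Read a pairwise LD report
#'
#' @param path Text file with columns `snp_a`, `snp_b`, `r2` (plink-style
#'   exports can be remapped via `cols`, a length-3 character vector naming
#'   the physical columns in that order, e.g. `c("SNP_A", "SNP_B", "R2")`).
#' @param delimiter Field delimiter; `""` splits on whitespace.
#' @param cols Physical names of the SNP-pair and r-squared columns.
#' @return A data frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_report <- function(path, delimiter = "",
                           cols = c("snp_a", "snp_b", "r2")) {
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE)
  if (!all(cols %in% names(raw))) {
    stop("LD report must carry columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  data.frame(snp_a = as.character(raw[[cols[1]]]),
             snp_b = as.character(raw[[cols[2]]]),
             r2 = as.numeric(raw[[cols[3]]]),
             stringsAsFactors = FALSE)
}

#' Randomly ordered greedy LD pruning
#'
#' Prunes a harmonised table to an approximately independent set of variants.
#' Variants are visited in a seeded random order (so that pruning does not
#' favour small p-values, avoiding winner's-curse artefacts); a variant is
#' retained unless its r-squared with an already-retained variant lying
#' within `window_snps` positions (in table order) exceeds `r2_threshold`.
#' Pairs absent from the LD report are treated as unlinked (r-squared 0).
#'
#' @param table A harmonised table (or any data frame with `snp_id`).
#' @param ld_report Data frame with `snp_a`, `snp_b`, `r2`
#'   (see [read_ld_report()]); `NULL` means all pairs unlinked.
#' @param r2_threshold Retain only pairs at or below this r-squared
#'   (default 0.1).
#' @param window_snps Window half-width in consecutive table positions
#'   (default 250).
#' @param seed Integer seed controlling the random visiting order.
#' @return The pruned table, rows in their original order.
#' @export
ld_prune <- function(table, ld_report = NULL, r2_threshold = 0.1,
                     window_snps = 250, seed = 1L) {
  n <- nrow(table)
  if (n == 0L || is.null(ld_report) || nrow(ld_report) == 0L) return(table)
  ids <- table$snp_id
  key <- function(a, b) paste(a, b, sep = "\r")
  r2map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(ld_report))) {
    a <- ld_report$snp_a[i]; b <- ld_report$snp_b[i]
    v <- ld_report$r2[i]
    assign(key(a, b), v, envir = r2map)
    assign(key(b, a), v, envir = r2map)
  }
  lookup <- function(a, b) {
    k <- key(a, b)
    if (exists(k, envir = r2map, inherits = FALSE)) {
      get(k, envir = r2map, inherits = FALSE)
    } else 0
  }
  order_visit <- withr_seed(seed, sample.int(n))
  retained <- logical(n)
  for (i in order_visit) {
    lo <- max(1L, i - window_snps); hi <- min(n, i + window_snps)
    near <- which(retained[lo:hi]) + lo - 1L
    ok <- TRUE
    for (j in near) {
      if (lookup(ids[i], ids[j]) > r2_threshold) { ok <- FALSE; break }
    }
    retained[i] <- ok
  }
  table[retained, , drop = FALSE]
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
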