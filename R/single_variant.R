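#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Exhaustive hypergeometric evaluation of the two-sided Fisher exact test
#' under the probability-mass rule: with margins fixed, P is the sum of
#' probabilities of all tables whose probability does not exceed that of the
#' observed table (a relative tolerance of 1e-7 guards against floating-point
#' ties, matching common practice).
#'
#' @param a,b,c,d cell counts: case minor, case major, control minor,
#'   control major alleles.
#' @return list with `p` and `or` (cross-product odds ratio `(a*d)/(b*c)`;
#'   `Inf` when `b*c == 0` and `a*d > 0`; `NA` for the all-zero table).
#' @examples
#' fisher_two_sided(10, 1016, 0, 3138)
#' @export
fisher_two_sided <- function(a, b, c, d) {
  for (x in list(a, b, c, d)) stop_if_not_scalar_count(x, "cell")
  n <- a + b + c + d
  if (n == 0) return(list(p = 1, or = NA_real_))
  m1 <- a + b          # case alleles
  k <- a + c           # minor alleles
  lo <- max(0L, k - (c + d))
  hi <- min(k, m1)
  x <- lo:hi
  logp <- dhyper(x, m1, c + d, k, log = TRUE)
  lp_obs <- dhyper(a, m1, c + d, k, log = TRUE)
  p <- sum(exp(logp[logp <= lp_obs + 1e-7]))
  or <- if (b * d == 0 && a * c == 0) NA_real_
        else if (b * c == 0) { if (a * d > 0) Inf else NA_real_ }
        else (a * d) / (b * c)
  list(p = min(p, 1), or = or)
}

# vectorized two-sided Fisher P over many tables (same rule as fisher_two_sided)
fisher_two_sided_p <- function(a, b, c, d) {
  n <- length(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + b[i]; m2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (m1 + m2 == 0 || k == 0 || k == m1 + m2) { p[i] <- 1; next }
    lo <- max(0L, k - m2); hi <- min(k, m1)
    logp <- dhyper(lo:hi, m1, m2, k, log = TRUE)
    lp_obs <- dhyper(a[i], m1, m2, k, log = TRUE)
    p[i] <- min(sum(exp(logp[logp <= lp_obs + 1e-7])), 1)
  }
  p
}

#' Minimum attainable Fisher P for a variant
#'
#' The smallest two-sided Fisher P a variant could reach given its total
#' minor-allele count, attained when every minor allele falls in cases:
#' the P of the table `(m, N_case - m, 0, N_control)`. Used to prune
#' variants that cannot reach significance before Bonferroni correction.
#'
#' @param m total minor-allele count.
#' @param n_case_alleles,n_control_alleles group allele totals.
#' @return minimum possible two-sided P.
#' @export
min_possible_p <- function(m, n_case_alleles, n_control_alleles) {
  stop_if_not_scalar_count(m, "m")
  if (m > n_case_alleles) stop("m exceeds the case allele total")
  fisher_two_sided(m, n_case_alleles - m, 0, n_control_alleles)$p
}

#' Prune variants by minimum attainable P
#'
#' Iterates to the fixed point of: threshold `t = alpha / |retained|`; drop
#' variants whose minimum possible P exceeds `t`. Variants that cannot reach
#' the Bonferroni threshold implied by their own inclusion contribute only
#' multiple-testing burden and are disregarded.
#'
#' @param p_min numeric vector of per-variant minimum possible P-values.
#' @param alpha family-wise error rate.
#' @return list with `retained` (logical vector) and `threshold` (final
#'   `alpha / |retained|`; `NA` if nothing is retained).
#' @export
prune_by_min_possible_p <- function(p_min, alpha = 0.05) {
  if (length(p_min) == 0L) stop("empty candidate set")
  retained <- rep(TRUE, length(p_min))
  repeat {
    n_ret <- sum(retained)
    if (n_ret == 0L) return(list(retained = retained, threshold = NA_real_))
    t <- alpha / n_ret
    new_ret <- retained & (p_min <= t)
    if (identical(new_ret, retained)) break
    retained <- new_ret
  }
  list(retained = retained, threshold = alpha / sum(retained))
}

#' Single-variant Fisher association scan
#'
#' Two-sided Fisher exact test on case vs control minor-allele counts for
#' each QC-passed variant, with minimum-possible-P pruning and Bonferroni
#' significance flagging at `alpha / |retained|`.
#'
#' @param geno samples x variants genotype matrix (0/1/2/NA).
#' @param is_case logical vector over samples.
#' @param variant_keys columns to test (default all).
#' @param alpha family-wise error rate.
#' @param maf_max report only variants with combined MAF at or below this
#'   (`NULL` for the all-MAF "relaxed" view).
#' @return data.frame: variant key, per-group minor/total allele counts,
#'   combined MAF, OR, P, p_min, significance flag; attribute `threshold`
#'   carries the post-pruning Bonferroni threshold.
#' @export
single_variant_scan <- function(geno, is_case, variant_keys = colnames(geno),
                                alpha = 0.05, maf_max = 0.05) {
  if (length(variant_keys) == 0L)
    return(empty_sv_table())
  sub <- geno[, variant_keys, drop = FALSE]
  case_alt <- colSums(sub[is_case, , drop = FALSE], na.rm = TRUE)
  ctrl_alt <- colSums(sub[!is_case, , drop = FALSE], na.rm = TRUE)
  case_n <- 2L * colSums(!is.na(sub[is_case, , drop = FALSE]))
  ctrl_n <- 2L * colSums(!is.na(sub[!is_case, , drop = FALSE]))
  alt_f <- (case_alt + ctrl_alt) / pmax(case_n + ctrl_n, 1L)
  # minor allele orientation
  flip <- alt_f > 0.5
  ca_min <- ifelse(flip, case_n - case_alt, case_alt)
  co_min <- ifelse(flip, ctrl_n - ctrl_alt, ctrl_alt)
  maf <- (ca_min + co_min) / pmax(case_n + ctrl_n, 1L)
  if (!is.null(maf_max)) {
    keep <- maf <= maf_max
    variant_keys <- variant_keys[keep]
    ca_min <- ca_min[keep]; co_min <- co_min[keep]
    case_n <- case_n[keep]; ctrl_n <- ctrl_n[keep]; maf <- maf[keep]
  }
  if (length(variant_keys) == 0L) return(empty_sv_table())
  p_min <- fisher_two_sided_p(pmin(ca_min + co_min, case_n),
                              case_n - pmin(ca_min + co_min, case_n),
                              pmax(ca_min + co_min - case_n, 0),
                              ctrl_n - pmax(ca_min + co_min - case_n, 0))
  pr <- prune_by_min_possible_p(p_min, alpha = alpha)
  keep <- pr$retained
  variant_keys <- variant_keys[keep]
  ca_min <- ca_min[keep]; co_min <- co_min[keep]
  case_n <- case_n[keep]; ctrl_n <- ctrl_n[keep]
  maf <- maf[keep]; p_min <- p_min[keep]
  if (length(variant_keys) == 0L) return(empty_sv_table())
  p <- fisher_two_sided_p(ca_min, case_n - ca_min, co_min, ctrl_n - co_min)
  or <- mapply(function(a, b, c, d) fisher_two_sided(a, b, c, d)$or,
               ca_min, case_n - ca_min, co_min, ctrl_n - co_min)
  out <- data.frame(
    variant_key = variant_keys,
    case_minor = ca_min, case_alleles = case_n,
    control_minor = co_min, control_alleles = ctrl_n,
    maf = maf, or = or, P = p, p_min = p_min,
    significant = p < pr$threshold,
    stringsAsFactors = FALSE)
  out <- out[order(out$P), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- pr$threshold
  out
}

empty_sv_table <- function() {
  out <- data.frame(variant_key = character(0), case_minor = numeric(0),
                    case_alleles = numeric(0), control_minor = numeric(0),
                    control_alleles = numeric(0), maf = numeric(0),
                    or = numeric(0), P = numeric(0), p_min = numeric(0),
                    significant = logical(0))
  attr(out, "threshold") <- NA_real_
  out
}

#' Trimmed genomic inflation factor
#'
#' Genomic inflation lambda computed on the weakest `1 - trim` fraction of
#' P-values (the smallest `trim` fraction — the putative signals — is
#' removed). P-values are mapped to 1-df chi-square quantiles; lambda is the
#' ratio of their observed median to the median of the correspondingly
#' truncated null. At `trim = 0.10` the truncated-null median is the 45th
#' percentile of the chi-square(1) distribution, because the surviving null
#' P-values are uniform on (trim, 1] with median `(1 + trim) / 2`.
#'
#' @param p numeric vector of P-values (>= 10 required).
#' @param trim fraction of smallest P-values to remove.
#' @return lambda estimate.
#' @export
genomic_inflation_trimmed <- function(p, trim = 0.10) {
  p <- p[!is.na(p)]
  if (length(p) < 10L) stop("need at least 10 P-values")
  if (trim < 0 || trim >= 1) stop("trim must be in [0, 1)")
  p_sorted <- sort(p)
  drop_n <- floor(trim * length(p))
  kept <- p_sorted[(drop_n + 1L):length(p)]
  chisq <- qchisq(kept, df = 1, lower.tail = FALSE)
  null_median <- qchisq((1 + trim) / 2, df = 1, lower.tail = FALSE)
  median(chisq) / null_median
}
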