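#' Exact permutation null for the T1 collapsing burden statistic
#'
#' Builds the exact distribution of the case allele total \eqn{S} for a gene
#' under random reassignment of case/control labels with group sizes fixed.
#' Only carrier samples (those with at least one qualifying alternate allele)
#' enter explicitly; non-carriers contribute weight zero and are handled
#' analytically. With all carrier weights equal to 1 the law of \eqn{S} is
#' hypergeometric; with unequal weights the distribution is obtained by an
#' exact subset-count convolution in log space.
#'
#' @param weights integer vector of per-carrier qualifying allele counts
#'   (length K, all > 0). Zero-weight entries are dropped.
#' @param n_case,n_control cohort group sizes.
#' @return object of class `perm_null`: list with `support` (attainable values
#'   of S), `prob` (their probabilities), `weights`, `n_case`, `n_control`.
#' @examples
#' pn <- perm_null(rep(1, 6), n_case = 513, n_control = 1569)
#' sum(pn$prob)  # 1
#' @export
perm_null <- function(weights, n_case, n_control) {
  stop_if_not_scalar_count(n_case, "n_case")
  stop_if_not_scalar_count(n_control, "n_control")
  if (n_case < 1 || n_control < 1) stop("both groups must be non-empty")
  weights <- as.integer(weights[weights > 0])
  K <- length(weights)
  N <- n_case + n_control
  if (K > N) stop("more carriers than samples")
  if (K == 0L) {
    out <- list(support = 0L, prob = 1, weights = integer(0),
                n_case = n_case, n_control = n_control)
    class(out) <- "perm_null"
    return(out)
  }
  jmax <- min(K, n_case)
  # P(j carriers land in cases), j = 0..K; impossible j get probability 0
  pj <- dhyper(0:K, n_case, n_control, K)
  if (all(weights == 1L)) {
    support <- 0:K
    prob <- pj
  } else {
    sw <- sum(weights)
    # log N_j(s): number of size-j subsets of carriers with weight sum s
    L <- matrix(-Inf, nrow = K + 1L, ncol = sw + 1L)  # rows j=0..K, cols s=0..sw
    L[1L, 1L] <- 0
    for (w in weights) {
      shifted <- matrix(-Inf, nrow = K + 1L, ncol = sw + 1L)
      shifted[2:(K + 1L), (w + 1L):(sw + 1L)] <- L[1:K, 1:(sw + 1L - w)]
      L <- logspace_add(L, shifted)
    }
    # P(S = s) = sum_j N_j(s) * C(N-K, n_case-j) / C(N, n_case)
    lw <- lchoose(N - K, n_case - (0:K)) - lchoose(N, n_case)
    lw[!is.finite(lw)] <- -Inf
    pmat <- exp(L + lw)          # recycle lw down columns (rows are j)
    prob <- colSums(pmat)
    support <- 0:sw
    keep <- prob > 0 | support == 0L
    support <- support[keep]
    prob <- prob[keep]
  }
  prob <- prob / sum(prob)
  out <- list(support = support, prob = prob, weights = weights,
              n_case = n_case, n_control = n_control)
  class(out) <- "perm_null"
  out
}

#' Exact one-sided permutation P-value for a gene burden
#'
#' One-sided P for an excess of qualifying alleles in cases, evaluated on the
#' exact permutation distribution of the case allele total S. The default
#' convention is mid-P, `Pr(S > S_obs) + 0.5 * Pr(S = S_obs)`, which removes
#' most of the conservatism of the discrete null; the plain tail
#' `Pr(S >= S_obs)` is available via `convention = "tail"`.
#'
#' @param null a `perm_null` object, or an integer weight vector (in which
#'   case `n_case`/`n_control` must be supplied).
#' @param s_obs observed case allele total.
#' @param convention `"midp"` (default) or `"tail"`.
#' @param n_case,n_control used only when `null` is a weight vector.
#' @return P-value in (0, 1].
#' @examples
#' # six case carriers, no control carriers, one allele each
#' exact_permutation_midp(rep(1, 6), 6, n_case = 513, n_control = 1569)
#' @export
exact_permutation_midp <- function(null, s_obs, convention = c("midp", "tail"),
                                   n_case = NULL, n_control = NULL) {
  convention <- match.arg(convention)
  if (!inherits(null, "perm_null")) {
    null <- perm_null(null, n_case, n_control)
  }
  stop_if_not_scalar_count(s_obs, "s_obs")
  if (!s_obs %in% null$support && s_obs > max(null$support))
    stop("s_obs outside the support of the permutation null")
  # weight-1 fast path: hypergeometric closed form
  K <- length(null$weights)
  if (K > 0L && all(null$weights == 1L)) {
    p_gt <- phyper(s_obs, null$n_case, null$n_control, K, lower.tail = FALSE)
    p_eq <- dhyper(s_obs, null$n_case, null$n_control, K)
  } else {
    p_gt <- sum(null$prob[null$support > s_obs])
    p_eq <- sum(null$prob[null$support == s_obs])
  }
  p <- if (convention == "midp") p_gt + 0.5 * p_eq else p_gt + p_eq
  min(max(p, .Machine$double.xmin), 1)
}

#' Monte-Carlo permutation P-value for a gene burden
#'
#' Estimates the one-sided permutation P by randomly reassigning case/control
#' labels `B` times. Included for instances whose carrier count exceeds the
#' exact-path limit and as an independent check on the exact path.
#'
#' @param weights per-carrier qualifying allele counts.
#' @param n_case,n_control group sizes (labels permuted with these fixed).
#' @param s_obs observed case allele total.
#' @param B number of permutations (>= 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param convention `"midp"` or `"tail"`.
#' @return list with `p` (estimate), `se` (binomial standard error), `B`.
#' @export
monte_carlo_permutation_midp <- function(weights, s_obs, n_case, n_control,
                                         B = 1e6, seed = NULL,
                                         convention = c("midp", "tail")) {
  convention <- match.arg(convention)
  if (B < 1e3) stop("B must be at least 1000")
  weights <- as.integer(weights[weights > 0])
  K <- length(weights)
  if (!is.null(seed)) set.seed(seed)
  if (K == 0L) {
    s_perm <- rep(0L, B)
  } else {
    # number of carriers landing in the case group per permutation
    j <- rhyper(B, n_case, n_control, K)
    if (all(weights == 1L)) {
      s_perm <- j
    } else if (K <= 64L) {
      # which carriers: uniform random subset of size j, via within-row ranks
      U <- matrix(runif(B * K), nrow = B, ncol = K)
      rk <- matrix(0L, nrow = B, ncol = K)
      for (a in seq_len(K)) for (b in seq_len(K)) {
        rk[, a] <- rk[, a] + (U[, b] <= U[, a])
      }
      s_perm <- as.vector((rk <= j) %*% weights)
    } else {
      s_perm <- vapply(j, function(jj) sum(sample(weights, jj)), numeric(1))
    }
  }
  n_gt <- sum(s_perm > s_obs)
  n_eq <- sum(s_perm == s_obs)
  p <- if (convention == "midp") (n_gt + 0.5 * n_eq) / B else (n_gt + n_eq) / B
  list(p = p, se = sqrt(max(p, 1 / B) * (1 - min(p, 1 - 1 / B)) / B), B = B)
}

#' Collapse a gene's qualifying variants into a burden configuration
#'
#' Sums qualifying alternate-allele counts per sample for one (gene, class)
#' set and summarizes the carrier configuration: the observed case allele
#' total S, carrier sample counts per group, per-carrier weights, and
#' unique-variant counts overall / in cases / in controls.
#'
#' @param geno samples x variants genotype matrix (0/1/2 alternate-allele
#'   counts, NA = missing; missing contributes 0 to the burden).
#' @param variant_keys columns of `geno` to aggregate (qualifying set).
#' @param is_case logical vector over samples.
#' @return list with `s_obs`, `weights` (per-carrier), `case_carriers`,
#'   `control_carriers`, `unique_total`, `unique_case`, `unique_control`,
#'   `n_case`, `n_control`; or `NULL` when the qualifying set is empty.
#' @export
collapse_gene <- function(geno, variant_keys, is_case) {
  if (length(variant_keys) == 0L) return(NULL)
  sub <- geno[, variant_keys, drop = FALSE]
  sub[is.na(sub)] <- 0L
  w <- as.integer(rowSums(sub))
  carrier <- w > 0L
  per_var_case <- colSums(sub[is_case, , drop = FALSE] > 0L) > 0L
  per_var_ctrl <- colSums(sub[!is_case, , drop = FALSE] > 0L) > 0L
  list(
    s_obs = sum(w[is_case]),
    weights = w[carrier],
    case_carriers = sum(carrier & is_case),
    control_carriers = sum(carrier & !is_case),
    unique_total = sum(per_var_case | per_var_ctrl),
    unique_case = sum(per_var_case),
    unique_control = sum(per_var_ctrl),
    n_case = sum(is_case),
    n_control = sum(!is_case)
  )
}

#' Gene-burden scan over nested variant classes
#'
#' Runs the T1 collapsing burden test for every admitted gene and each of the
#' three nested classes. A gene is admitted when its Class 3 (widest class)
#' carrier-sample count reaches `min_samples`; all three class tests are then
#' computed for it. The exome-wide significance threshold is
#' `alpha / (number of tests computed with >= 1 carrier)`.
#'
#' @param geno samples x variants genotype matrix.
#' @param class_sets result of [build_gene_class_sets()].
#' @param is_case logical vector over samples.
#' @param min_samples gene admission floor on Class 3 carrier samples.
#' @param alpha family-wise error rate for the exome-wide threshold.
#' @param convention P-value convention, `"midp"` or `"tail"`.
#' @param exact_limit exact permutation path used when carriers <= this;
#'   Monte-Carlo beyond.
#' @param B,seed Monte-Carlo settings for genes beyond `exact_limit`.
#' @return data.frame, one row per (gene, class) test, ordered by per-gene
#'   minimum P (ties broken by gene symbol), with an attached
#'   `exome_wide_threshold` attribute.
#' @export
burden_scan <- function(geno, class_sets, is_case, min_samples = 10,
                        alpha = 0.05, convention = c("midp", "tail"),
                        exact_limit = 500, B = 1e6, seed = NULL) {
  convention <- match.arg(convention)
  genes <- unique(class_sets$gene)
  rows <- list()
  for (g in genes) {
    gs <- class_sets[class_sets$gene == g, , drop = FALSE]
    k3 <- gs$variant_key[gs$class_id == 3L]
    adm <- collapse_gene(geno, k3, is_case)
    if (is.null(adm) || (adm$case_carriers + adm$control_carriers) < min_samples) next
    for (cl in 1:3) {
      keys <- gs$variant_key[gs$class_id == cl]
      cf <- collapse_gene(geno, keys, is_case)
      if (is.null(cf) || length(cf$weights) == 0L) next
      K <- length(cf$weights)
      if (K <= exact_limit) {
        p <- exact_permutation_midp(perm_null(cf$weights, cf$n_case, cf$n_control),
                                    cf$s_obs, convention = convention)
        method <- "exact"; mc_se <- NA_real_
      } else {
        mc <- monte_carlo_permutation_midp(cf$weights, cf$s_obs, cf$n_case,
                                           cf$n_control, B = B, seed = seed,
                                           convention = convention)
        p <- mc$p; method <- "monte_carlo"; mc_se <- mc$se
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, class_id = cl, P = p, s_obs = cf$s_obs,
        case_samples = cf$case_carriers, control_samples = cf$control_carriers,
        unique_total = cf$unique_total, unique_case = cf$unique_case,
        unique_control = cf$unique_control, method = method, mc_se = mc_se,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    res <- data.frame(gene = character(0), class_id = integer(0), P = numeric(0),
                      s_obs = integer(0), case_samples = integer(0),
                      control_samples = integer(0), unique_total = integer(0),
                      unique_case = integer(0), unique_control = integer(0),
                      method = character(0), mc_se = numeric(0))
    attr(res, "exome_wide_threshold") <- NA_real_
    return(res)
  }
  res <- do.call(rbind, rows)
  thr <- alpha / nrow(res)
  res$significant <- res$P < thr
  # order by per-gene minimum P, ties by gene symbol
  pmin_by_gene <- tapply(res$P, res$gene, min)
  res <- res[order(pmin_by_gene[res$gene], res$gene, res$class_id), ]
  rownames(res) <- NULL
  attr(res, "exome_wide_threshold") <- thr
  res
}

#' Candidate susceptibility gene panel assessment
#'
#' Restricts a burden scan to an a-priori gene panel and applies a
#' panel-sized Bonferroni threshold (`alpha / length(gene_list)`), the
#' standard device for testing known cancer susceptibility genes without
#' paying the exome-wide multiplicity price.
#'
#' @param burden_results data.frame from [burden_scan()].
#' @param gene_list character vector of panel gene symbols.
#' @param alpha family-wise error rate.
#' @return list with `results` (panel subset, flagged at the panel threshold),
#'   `threshold`, and `untested` (panel genes absent from the scan).
#' @export
csg_panel_test <- function(burden_results, gene_list, alpha = 0.05) {
  if (length(gene_list) == 0L) stop("gene_list must be non-empty")
  gene_list <- unique(gene_list)
  thr <- alpha / length(gene_list)
  sub <- burden_results[burden_results$gene %in% gene_list, , drop = FALSE]
  untested <- setdiff(gene_list, sub$gene)
  if (nrow(sub) == 0L) warning("none of the listed genes were tested")
  sub$significant <- sub$P < thr
  rownames(sub) <- NULL
  list(results = sub, threshold = thr, untested = untested)
}

#' One-sided binomial test for preferential loss of the wild-type allele
#'
#' Among tumors informative for loss of heterozygosity at a candidate locus,
#' tests whether the wild-type allele is lost more often than chance
#' (`X ~ Binomial(n, 1/2)`, upper tail).
#'
#' @param n_informative informative tumor/germline pairs.
#' @param n_wildtype_lost pairs in which the wild-type allele was lost.
#' @return one-sided P-value `Pr(X >= n_wildtype_lost)`.
#' @export
loh_binomial_test <- function(n_informative, n_wildtype_lost) {
  stop_if_not_scalar_count(n_informative, "n_informative")
  stop_if_not_scalar_count(n_wildtype_lost, "n_wildtype_lost")
  if (n_wildtype_lost > n_informative)
    stop("n_wildtype_lost cannot exceed n_informative")
  pbinom(n_wildtype_lost - 1, n_informative, 0.5, lower.tail = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stop_if_not_scalar_count(n_tests, "n_tests")
  if (n_tests < 1) stop("n_tests must be positive")
  alpha / n_tests
}
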