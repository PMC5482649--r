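#' Genotype-support filter
#'
#' Sets non-reference genotype calls to missing unless they are adequately
#' supported: genotype quality >= `gq_min`, alternate-allele read depth
#' strictly greater than `alt_depth_min`, and a site truth-tranche
#' sensitivity below the class-specific cap (`snv_tranche_max` for SNVs,
#' `indel_tranche_max` for indels). Homozygous-reference calls are not
#' subject to the filter. Calls with missing GQ or AD are set to missing
#' with a warning.
#'
#' @param geno samples x variants genotype matrix (0/1/2/NA).
#' @param gq samples x variants genotype-quality matrix.
#' @param ad_alt samples x variants alternate-allele depth matrix.
#' @param tranche per-variant tranche sensitivity.
#' @param is_indel per-variant logical.
#' @param gq_min,alt_depth_min,snv_tranche_max,indel_tranche_max thresholds.
#' @return filtered genotype matrix.
#' @export
genotype_support_filter <- function(geno, gq, ad_alt, tranche, is_indel,
                                    gq_min = 30, alt_depth_min = 3,
                                    snv_tranche_max = 99.5,
                                    indel_tranche_max = 99) {
  nonref <- !is.na(geno) & geno > 0L
  meta_missing <- nonref & (is.na(gq) | is.na(ad_alt))
  if (any(meta_missing))
    warning(sum(meta_missing), " non-reference calls lack GQ/AD and were set to missing")
  tranche_cap <- ifelse(is_indel, indel_tranche_max, snv_tranche_max)
  tranche_ok <- matrix(rep(tranche < tranche_cap, each = nrow(geno)),
                       nrow = nrow(geno))
  fail <- nonref & (meta_missing | gq < gq_min | ad_alt <= alt_depth_min | !tranche_ok)
  fail[is.na(fail)] <- TRUE
  geno[nonref & fail] <- NA_integer_
  geno
}

#' Per-sample missingness over a designated SNV subset
#'
#' @param geno samples x variants genotype matrix.
#' @param subset_keys columns forming the high-confidence common-SNV subset.
#' @return named numeric vector of per-sample no-call rates.
#' @export
sample_missingness <- function(geno, subset_keys) {
  if (length(subset_keys) == 0L) stop("common-SNV subset is empty")
  sub <- geno[, subset_keys, drop = FALSE]
  rowMeans(is.na(sub))
}

#' Per-sample heterozygosity over a designated SNV subset
#'
#' Heterozygous calls divided by called genotypes, per sample.
#'
#' @inheritParams sample_missingness
#' @return named numeric vector; `NaN` for samples with no called genotypes.
#' @export
sample_heterozygosity <- function(geno, subset_keys) {
  if (length(subset_keys) == 0L) stop("common-SNV subset is empty")
  sub <- geno[, subset_keys, drop = FALSE]
  rowSums(sub == 1L, na.rm = TRUE) / rowSums(!is.na(sub))
}

#' Flag upper outliers by the k-standard-deviation rule
#'
#' Flags values strictly greater than `mean + k * SD`. The SD is the
#' population (n-denominator) standard deviation computed over all samples,
#' candidates included, in a single pass.
#'
#' @param values numeric vector (length >= 2).
#' @param k number of standard deviations.
#' @return logical vector of flags.
#' @export
flag_outliers_3sd <- function(values, k = 3) {
  if (length(values) < 2L) stop("need at least 2 values")
  mu <- mean(values, na.rm = TRUE)
  sdev <- sqrt(mean((values - mu)^2, na.rm = TRUE))
  if (sdev == 0) return(rep(FALSE, length(values)))
  out <- values > mu + k * sdev
  out[is.na(out)] <- FALSE
  out
}

#' Sex check from X-chromosome heterozygosity
#'
#' Infers sex from an inbreeding-style statistic on X-chromosome common
#' SNVs: `F = 1 - observed het rate / expected het rate`, where the expected
#' rate is the mean of `2 p (1 - p)` over the sites (allele frequencies
#' estimated from the cohort). `F > f_male` infers male, `F < f_female`
#' female, otherwise undetermined (never excluded). A discrepancy is flagged
#' only when both the inferred and reported sex are determined and disagree.
#'
#' @param x_geno samples x X-variants genotype matrix.
#' @param reported_sex character vector, values in `{"M", "F", "unknown"}`.
#' @param f_male,f_female inference cutoffs on F.
#' @return data.frame with `f_stat`, `inferred_sex`, `discrepancy`.
#' @export
sex_check <- function(x_geno, reported_sex, f_male = 0.8, f_female = 0.2) {
  n <- length(reported_sex)
  if (is.null(x_geno) || ncol(x_geno) == 0L) {
    return(data.frame(f_stat = rep(NA_real_, n),
                      inferred_sex = rep("undetermined", n),
                      discrepancy = rep(FALSE, n)))
  }
  af <- colMeans(x_geno, na.rm = TRUE) / 2
  exp_het <- mean(2 * af * (1 - af))
  obs_het <- rowSums(x_geno == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(x_geno)), 1L)
  f_stat <- if (exp_het > 0) 1 - obs_het / exp_het else rep(NA_real_, n)
  inferred <- ifelse(is.na(f_stat), "undetermined",
                     ifelse(f_stat > f_male, "M",
                            ifelse(f_stat < f_female, "F", "undetermined")))
  disc <- inferred != "undetermined" & reported_sex %in% c("M", "F") &
    inferred != reported_sex
  data.frame(f_stat = f_stat, inferred_sex = inferred, discrepancy = disc)
}

#' Detect duplicated samples by genotype concordance
#'
#' Computes pairwise genotype concordance over mutually called sites of the
#' common-SNV subset and reports pairs exceeding the concordance threshold.
#' Within each pair the member with the higher missingness is marked for
#' exclusion. For large subsets, concordance is evaluated on at most
#' `max_sites` sites.
#'
#' @param geno samples x variants genotype matrix.
#' @param subset_keys common-SNV subset columns.
#' @param threshold concordance above which a pair is called a duplicate.
#' @param min_shared minimum mutually called sites for a pair to be assessed.
#' @param max_sites cap on subset size used for the pairwise computation.
#' @return data.frame with `sample1`, `sample2`, `concordance`, `exclude`
#'   (the member flagged for exclusion).
#' @export
detect_duplicates <- function(geno, subset_keys, threshold = 0.95,
                              min_shared = 200, max_sites = 1000) {
  if (length(subset_keys) == 0L) stop("common-SNV subset is empty")
  if (length(subset_keys) > max_sites)
    subset_keys <- subset_keys[seq_len(max_sites)]
  sub <- geno[, subset_keys, drop = FALSE]
  called <- !is.na(sub)
  agree <- matrix(0, nrow(sub), nrow(sub))
  for (g in 0:2) {
    M <- (sub == g) & called
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "numeric"
    agree <- agree + tcrossprod(M)
  }
  shared <- tcrossprod(called * 1)
  conc <- agree / pmax(shared, 1)
  conc[shared < min_shared] <- 0
  diag(conc) <- 0
  hits <- which(conc > threshold & upper.tri(conc), arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(sample1 = character(0), sample2 = character(0),
                      concordance = numeric(0), exclude = character(0)))
  }
  miss <- rowMeans(is.na(sub))
  ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  data.frame(
    sample1 = ids[hits[, 1]],
    sample2 = ids[hits[, 2]],
    concordance = conc[hits],
    exclude = ifelse(miss[hits[, 1]] >= miss[hits[, 2]],
                     ids[hits[, 1]], ids[hits[, 2]]),
    stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact conditional test: given the allele counts, sums the probabilities of
#' all heterozygote counts whose conditional probability does not exceed that
#' of the observed count. A chi-square goodness-of-fit alternative is
#' available via `method = "chisq"`.
#'
#' @param n_homref,n_het,n_homalt genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt, method = c("exact", "chisq")) {
  method <- match.arg(method)
  for (x in list(n_homref, n_het, n_homalt)) stop_if_not_scalar_count(x, "count")
  n <- n_homref + n_het + n_homalt
  if (n == 0L) return(1)
  n_a <- 2L * n_homalt + n_het       # minor-orientation not required; symmetric
  n_r <- 2L * n_homref + n_het
  rare <- min(n_a, n_r)
  if (rare == 0L) return(1)
  if (method == "chisq") {
    p_alt <- n_a / (2 * n)
    exp_cnt <- n * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
    x2 <- sum((c(n_homref, n_het, n_homalt) - exp_cnt)^2 / exp_cnt)
    return(pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # enumerate heterozygote counts with the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  logp <- lgamma(n + 1) - lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - rare - hets) / 2 + 1) + hets * log(2) +
    lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[hets == n_het]
  min(sum(prob[prob <= p_obs * (1 + 1e-10)]), 1)
}

#' Allele-balance test for a heterozygous call
#'
#' Chi-square goodness-of-fit of the ref/alt read depths against 50:50:
#' `X^2 = (ref - alt)^2 / (ref + alt)` on 1 df. The (sample, variant) pair is
#' excluded when `P < p_cut`.
#'
#' @param ref_depth,alt_depth read depths supporting each allele.
#' @param p_cut exclusion threshold.
#' @return list with `p`, `x2`, `exclude`.
#' @export
allele_balance_test <- function(ref_depth, alt_depth, p_cut = 1e-4) {
  total <- ref_depth + alt_depth
  if (any(total <= 0))
    return(list(p = 0, x2 = NA_real_, exclude = TRUE))
  x2 <- (ref_depth - alt_depth)^2 / total
  p <- pchisq(x2, df = 1, lower.tail = FALSE)
  list(p = p, x2 = x2, exclude = p < p_cut)
}

# vectorized allele-balance P for het calls
allele_balance_p <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  x2 <- (ref_depth - alt_depth)^2 / pmax(total, 1)
  p <- pchisq(x2, df = 1, lower.tail = FALSE)
  p[total <= 0 | is.na(total)] <- 0
  p
}

#' Differential-missingness test for a variant
#'
#' Two-sided Fisher exact test on the 2x2 table of called/missing genotype
#' counts by case/control status.
#'
#' @param case_called,case_missing,control_called,control_missing counts.
#' @return two-sided P-value.
#' @export
differential_missingness_test <- function(case_called, case_missing,
                                          control_called, control_missing) {
  fisher_two_sided(case_missing, case_called, control_missing, control_called)$p
}

#' Sample-level quality control
#'
#' Applies the sample-exclusion rules over the common-SNV subset: sex
#' discrepancy, missingness and heterozygosity outliers (each `> mean +
#' 3 SD`), externally supplied ancestry exclusions, and duplicate detection.
#' A sample is excluded when any flag is set; the reason string lists every
#' flag that fired.
#'
#' @param geno samples x variants genotype matrix (after genotype-support
#'   filtering).
#' @param samples sample sheet data.frame (`sample_id`, `status`,
#'   `reported_sex`).
#' @param common_snv_keys autosomal common-SNV subset columns.
#' @param x_keys X-chromosome common-SNV columns (may be empty).
#' @param ancestry_excluded sample ids excluded on ancestry grounds.
#' @param k SD multiplier for the outlier rules.
#' @param dup_threshold duplicate concordance threshold.
#' @return data.frame, one row per sample: rates, the five flags, `excluded`,
#'   `reason`; duplicate pair table attached as attribute `duplicates`.
#' @export
sample_qc <- function(geno, samples, common_snv_keys, x_keys = character(0),
                      ancestry_excluded = character(0), k = 3,
                      dup_threshold = 0.95) {
  miss <- sample_missingness(geno, common_snv_keys)
  het <- sample_heterozygosity(geno, common_snv_keys)
  f_miss <- flag_outliers_3sd(miss, k = k)
  f_het <- flag_outliers_3sd(het, k = k)
  sx <- sex_check(if (length(x_keys)) geno[, x_keys, drop = FALSE] else NULL,
                  samples$reported_sex)
  dups <- detect_duplicates(geno, common_snv_keys, threshold = dup_threshold)
  f_dup <- samples$sample_id %in% dups$exclude
  f_anc <- samples$sample_id %in% ancestry_excluded
  flags <- cbind(sex_discrepancy = sx$discrepancy,
                 high_missingness = f_miss,
                 high_heterozygosity = f_het,
                 ancestry_excluded = f_anc,
                 duplicate = f_dup)
  reason <- apply(flags, 1, function(r) paste(colnames(flags)[r], collapse = ";"))
  out <- data.frame(
    sample_id = samples$sample_id,
    missingness = miss, heterozygosity = het,
    f_stat = sx$f_stat, inferred_sex = sx$inferred_sex,
    sex_discrepancy = sx$discrepancy,
    high_missingness = f_miss, high_heterozygosity = f_het,
    ancestry_excluded = f_anc, duplicate = f_dup,
    excluded = rowSums(flags) > 0,
    reason = reason,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "duplicates") <- dups
  out
}

#' Variant-level QC for the single-variant association track
#'
#' A variant is discarded when any of: alignability != 1; within
#' `repeat_bp` of a simple repeat (distance 0 means inside); HWE exact
#' P < `hwe_cut` in cases or in controls (tested separately); case/control
#' differential no-call P < `diffmiss_cut`; or no-call rate > `nocall_max`
#' in either group.
#'
#' @param geno samples x variants genotype matrix (support-filtered).
#' @param is_case logical over samples.
#' @param annotations data.frame with `variant_key`, `alignability`,
#'   `repeat_distance`.
#' @param hwe_cut,diffmiss_cut,nocall_max,repeat_bp thresholds.
#' @param hwe_method passed to [hwe_exact_test()].
#' @return data.frame, one row per variant, one logical column per filter
#'   plus `pass`.
#' @export
single_variant_qc <- function(geno, is_case, annotations, hwe_cut = 1e-5,
                              diffmiss_cut = 1e-5, nocall_max = 0.03,
                              repeat_bp = 10, hwe_method = "exact") {
  ann <- check_variant_annotations(annotations, colnames(geno))
  per_variant_qc(geno, is_case, ann,
                 hwe_groups = "separate", hwe_cut = hwe_cut,
                 diffmiss_cut = diffmiss_cut, nocall_max = nocall_max,
                 nocall_inclusive = FALSE, repeat_bp = repeat_bp,
                 hwe_method = hwe_method, track = "single_variant")
}

#' Variant-level QC for the gene-centric burden track
#'
#' A variant is discarded when any of: alignability != 1; within a simple
#' repeat (or within `repeat_bp`); combined-cohort HWE exact P < `hwe_cut`;
#' or no-call rate >= `nocall_max` in either group (inclusive bound). Allele
#' balance is applied per (sample, variant) beforehand via
#' [apply_allele_balance()].
#'
#' @inheritParams single_variant_qc
#' @export
gene_centric_qc <- function(geno, is_case, annotations, hwe_cut = 1e-8,
                            nocall_max = 0.25, repeat_bp = 10,
                            hwe_method = "exact") {
  ann <- check_variant_annotations(annotations, colnames(geno))
  per_variant_qc(geno, is_case, ann,
                 hwe_groups = "combined", hwe_cut = hwe_cut,
                 diffmiss_cut = NA, nocall_max = nocall_max,
                 nocall_inclusive = TRUE, repeat_bp = repeat_bp,
                 hwe_method = hwe_method, track = "gene_centric")
}

check_variant_annotations <- function(annotations, keys) {
  need <- c("variant_key", "alignability", "repeat_distance")
  missing_cols <- setdiff(need, names(annotations))
  if (length(missing_cols))
    stop("annotation table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  idx <- match(keys, annotations$variant_key)
  if (anyNA(idx))
    stop("annotations missing for variants: ",
         paste(head(keys[is.na(idx)], 5), collapse = ", "))
  annotations[idx, , drop = FALSE]
}

per_variant_qc <- function(geno, is_case, ann, hwe_groups, hwe_cut,
                           diffmiss_cut, nocall_max, nocall_inclusive,
                           repeat_bp, hwe_method, track) {
  p <- ncol(geno)
  case_g <- geno[is_case, , drop = FALSE]
  ctrl_g <- geno[!is_case, , drop = FALSE]
  nc_case <- colMeans(is.na(case_g))
  nc_ctrl <- colMeans(is.na(ctrl_g))
  hwe_p <- numeric(p)
  diff_p <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    if (hwe_groups == "separate") {
      pa <- hwe_exact_test(sum(case_g[, j] == 0L, na.rm = TRUE),
                           sum(case_g[, j] == 1L, na.rm = TRUE),
                           sum(case_g[, j] == 2L, na.rm = TRUE),
                           method = hwe_method)
      pu <- hwe_exact_test(sum(ctrl_g[, j] == 0L, na.rm = TRUE),
                           sum(ctrl_g[, j] == 1L, na.rm = TRUE),
                           sum(ctrl_g[, j] == 2L, na.rm = TRUE),
                           method = hwe_method)
      hwe_p[j] <- min(pa, pu)
    } else {
      hwe_p[j] <- hwe_exact_test(sum(geno[, j] == 0L, na.rm = TRUE),
                                 sum(geno[, j] == 1L, na.rm = TRUE),
                                 sum(geno[, j] == 2L, na.rm = TRUE),
                                 method = hwe_method)
    }
    if (!is.na(diffmiss_cut)) {
      diff_p[j] <- differential_missingness_test(
        sum(!is.na(case_g[, j])), sum(is.na(case_g[, j])),
        sum(!is.na(ctrl_g[, j])), sum(is.na(ctrl_g[, j])))
    }
  }
  f_align <- ann$alignability != 1
  f_repeat <- ann$repeat_distance <= repeat_bp
  f_hwe <- hwe_p < hwe_cut
  f_diff <- if (is.na(diffmiss_cut)) rep(FALSE, p) else diff_p < diffmiss_cut
  f_nocall <- if (nocall_inclusive) {
    nc_case >= nocall_max | nc_ctrl >= nocall_max
  } else {
    nc_case > nocall_max | nc_ctrl > nocall_max
  }
  out <- data.frame(
    variant_key = ann$variant_key,
    track = track,
    fail_alignability = f_align,
    fail_repeat = f_repeat,
    fail_hwe = f_hwe,
    fail_diff_missingness = f_diff,
    fail_nocall = f_nocall,
    hwe_p = hwe_p, diffmiss_p = diff_p,
    nocall_case = nc_case, nocall_control = nc_ctrl,
    pass = !(f_align | f_repeat | f_hwe | f_diff | f_nocall),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply per-call allele-balance exclusions
#'
#' Sets heterozygous calls with significantly unbalanced ref/alt read
#' support (chi-square P below `p_cut`) to missing, per (sample, variant).
#'
#' @param geno samples x variants genotype matrix.
#' @param ad_ref,ad_alt read-depth matrices aligned with `geno`.
#' @param p_cut exclusion threshold.
#' @return genotype matrix with failing het calls set to missing.
#' @export
apply_allele_balance <- function(geno, ad_ref, ad_alt, p_cut = 1e-4) {
  het <- !is.na(geno) & geno == 1L
  if (!any(het)) return(geno)
  p <- matrix(1, nrow(geno), ncol(geno))
  p[het] <- allele_balance_p(ad_ref[het], ad_alt[het])
  geno[het & p < p_cut] <- NA_integer_
  geno
}
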