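#' Pipeline configuration
#'
#' Bundles every threshold applied by [run_pipeline()], defaulted to the
#' analysis values: genotype support GQ >= 30 / alt depth > 3 / tranche
#' < 99.5 (SNV) and < 99 (indel); 3-SD sample outlier rules; single-variant
#' track HWE 1e-5 (cases or controls separately), differential missingness
#' 1e-5, no-call > 0.03; gene-centric track allele balance 1e-4, combined
#' HWE 1e-8, no-call >= 0.25; rare-variant MAF cap 1%; gene admission at
#' >= 10 carrier samples; alpha 0.05 throughout.
#'
#' @param ... overrides for any default listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    gq_min = 30, alt_depth_min = 3, snv_tranche_max = 99.5,
    indel_tranche_max = 99,
    outlier_k = 3, dup_threshold = 0.95,
    sv_hwe_cut = 1e-5, sv_diffmiss_cut = 1e-5, sv_nocall_max = 0.03,
    gc_ab_cut = 1e-4, gc_hwe_cut = 1e-8, gc_nocall_max = 0.25,
    repeat_bp = 10, hwe_method = "exact",
    maf_threshold = 0.01, min_samples = 10, alpha = 0.05,
    maf_max = 0.05, trim = 0.10,
    convention = "midp", exact_limit = 500, perm_B = 1e6,
    ancestry_excluded = character(0), csg_list = NULL, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full case-control analysis pipeline on a cohort
#'
#' Stage order is fixed: genotype-support filtering, sample QC over the
#' common-SNV subset (with sample exclusion), track-specific variant QC,
#' class-set construction, then the single-variant Fisher scan and the
#' gene-burden scan (plus the candidate-gene panel test when a gene list is
#' configured). Every exclusion is recorded in the returned bundle.
#'
#' @param cohort an `rv_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config a [pipeline_config()].
#' @return list of class `rv_report`: `sample_qc`, `exclusion_summary`,
#'   `variant_qc_single`, `variant_qc_gene`, `single_variant`, `burden`,
#'   `csg_panel` (or NULL), `thresholds`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "rv_cohort"))
  ann <- cohort$annotations
  v <- cohort$variants

  # stage 1: genotype-support filter
  geno <- cohort$geno
  if (!is.null(cohort$gq) && !is.null(cohort$ad_alt)) {
    idx <- match(colnames(geno), ann$variant_key)
    geno <- genotype_support_filter(
      geno, cohort$gq, cohort$ad_alt,
      tranche = ann$tranche[idx], is_indel = ann$is_indel[idx],
      gq_min = config$gq_min, alt_depth_min = config$alt_depth_min,
      snv_tranche_max = config$snv_tranche_max,
      indel_tranche_max = config$indel_tranche_max)
  }

  # stage 2: sample QC
  common_keys <- v$variant_key[v$is_common_snv & !v$chrom_x]
  x_keys <- v$variant_key[v$chrom_x]
  sqc <- sample_qc(geno, cohort$samples, common_keys, x_keys,
                   ancestry_excluded = config$ancestry_excluded,
                   k = config$outlier_k, dup_threshold = config$dup_threshold)
  keep_samples <- !sqc$excluded
  excl_summary <- c(
    sex_discrepancy = sum(sqc$sex_discrepancy),
    high_missingness = sum(sqc$high_missingness),
    high_heterozygosity = sum(sqc$high_heterozygosity),
    ancestry_excluded = sum(sqc$ancestry_excluded),
    duplicate = sum(sqc$duplicate),
    total_excluded = sum(sqc$excluded))
  geno <- geno[keep_samples, , drop = FALSE]
  samples <- cohort$samples[keep_samples, , drop = FALSE]
  is_case <- samples$status == "case"

  # stage 3: variant QC, analysis (non common-SNV) sites per track
  test_keys <- v$variant_key[!v$is_common_snv]
  vqc_sv <- single_variant_qc(
    geno[, test_keys, drop = FALSE], is_case, ann,
    hwe_cut = config$sv_hwe_cut, diffmiss_cut = config$sv_diffmiss_cut,
    nocall_max = config$sv_nocall_max, repeat_bp = config$repeat_bp,
    hwe_method = config$hwe_method)
  geno_gc <- geno
  if (!is.null(cohort$ad_ref) && !is.null(cohort$ad_alt)) {
    geno_gc <- apply_allele_balance(
      geno, cohort$ad_ref[keep_samples, , drop = FALSE],
      cohort$ad_alt[keep_samples, , drop = FALSE], p_cut = config$gc_ab_cut)
  }
  vqc_gc <- gene_centric_qc(
    geno_gc[, test_keys, drop = FALSE], is_case, ann,
    hwe_cut = config$gc_hwe_cut, nocall_max = config$gc_nocall_max,
    repeat_bp = config$repeat_bp, hwe_method = config$hwe_method)

  # stage 4: scans
  sv_keys <- vqc_sv$variant_key[vqc_sv$pass]
  sv <- single_variant_scan(geno, is_case, sv_keys, alpha = config$alpha,
                            maf_max = config$maf_max)
  gc_keys <- vqc_gc$variant_key[vqc_gc$pass]
  class_sets <- build_gene_class_sets(
    geno_gc[, gc_keys, drop = FALSE],
    ann[ann$variant_key %in% gc_keys, , drop = FALSE],
    maf_threshold = config$maf_threshold)
  burden <- burden_scan(geno_gc, class_sets, is_case,
                        min_samples = config$min_samples,
                        alpha = config$alpha,
                        convention = config$convention,
                        exact_limit = config$exact_limit,
                        B = config$perm_B, seed = config$seed)
  csg <- NULL
  if (!is.null(config$csg_list) && length(config$csg_list) > 0)
    csg <- csg_panel_test(burden, config$csg_list, alpha = config$alpha)

  out <- list(sample_qc = sqc, exclusion_summary = excl_summary,
              variant_qc_single = vqc_sv, variant_qc_gene = vqc_gc,
              class_sets = class_sets, single_variant = sv, burden = burden,
              csg_panel = csg,
              thresholds = list(
                single_variant = attr(sv, "threshold"),
                exome_wide = attr(burden, "exome_wide_threshold"),
                csg_panel = if (!is.null(csg)) csg$threshold else NULL),
              config = config)
  class(out) <- "rv_report"
  out
}

#' @export
print.rv_report <- function(x, ...) {
  cat("rare-variant case-control analysis report\n")
  cat("  samples excluded:", x$exclusion_summary[["total_excluded"]], "\n")
  cat("  single-variant tests:", nrow(x$single_variant),
      "(threshold", format(x$thresholds$single_variant, digits = 3), ")\n")
  cat("  burden tests:", nrow(x$burden),
      "(threshold", format(x$thresholds$exome_wide, digits = 3), ")\n")
  if (nrow(x$burden)) {
    top <- x$burden[1, ]
    cat(sprintf("  top burden gene: %s class %d P = %.3g\n",
                top$gene, top$class_id, top$P))
  }
  invisible(x)
}
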