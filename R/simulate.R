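#' Simulation configuration for a synthetic case-control exome cohort
#'
#' Default values emulate the analysis cohort of a rare-variant exome study:
#' 513 cases, 1,569 controls, a rare-variant frequency spectrum with 80% of
#' sites below 1% MAF and the remainder up to 5%, a designated
#' high-confidence common-SNV panel (6,100 autosomal sites at MAF 0.2-0.5)
#' used for sample QC, and a small X-chromosome block enabling the sex check.
#'
#' @param n_case,n_control group sizes.
#' @param n_genes number of autosomal genes.
#' @param variants_per_gene mean variants per gene (Poisson, floored at 1).
#' @param rare_fraction fraction of gene variants with population MAF < 0.01
#'   (log-uniform on \[1e-4, 0.01)); the rest are uniform on \[0.01, 0.05\].
#' @param common_snv_count designated common-SNV sites for sample QC.
#' @param x_snv_count X-chromosome common SNVs for the sex check.
#' @param baseline_missingness per-call no-call probability.
#' @param planted_signals list of [planted_signal()] objects.
#' @param n_missingness_outliers,n_het_outliers,n_duplicate_pairs,n_sex_mismatch,n_hwe_sites,n_repeat_sites
#'   counts of injected sample/site failure modes (all 0 by default).
#' @param missingness_outlier_rate no-call rate given to injected
#'   missingness outliers (default 10x baseline).
#' @param low_gq_rate fraction of non-reference calls given GQ below 30.
#' @param imbalanced_het_rate fraction of heterozygous calls whose alternate
#'   reads are drawn with success probability 0.1 instead of 0.5.
#' @param depth_mu,depth_size negative-binomial read-depth model.
#' @param seed RNG seed (required: the generator is deterministic given the
#'   config).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_case = 513, n_control = 1569, n_genes = 100,
                       variants_per_gene = 3, rare_fraction = 0.8,
                       common_snv_count = 6100, x_snv_count = 200,
                       baseline_missingness = 0.005,
                       planted_signals = list(),
                       n_missingness_outliers = 0, n_het_outliers = 0,
                       n_duplicate_pairs = 0, n_sex_mismatch = 0,
                       n_hwe_sites = 0, n_repeat_sites = 0,
                       missingness_outlier_rate = 10 * baseline_missingness,
                       low_gq_rate = 0.03, imbalanced_het_rate = 0,
                       depth_mu = 50, depth_size = 10, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, n_genes >= 0,
            rare_fraction >= 0, rare_fraction <= 1,
            baseline_missingness >= 0, baseline_missingness <= 1,
            low_gq_rate >= 0, low_gq_rate <= 1,
            imbalanced_het_rate >= 0, imbalanced_het_rate <= 1)
  if (n_duplicate_pairs > floor((n_case + n_control) / 2))
    stop("cannot inject more duplicate pairs than floor(n/2)")
  for (ps in planted_signals) {
    if (!inherits(ps, "planted_signal")) stop("planted_signals must be planted_signal objects")
    if (ps$mode == "exact_counts" &&
        (ps$case_carriers > n_case || ps$control_carriers > n_control))
      stop(sprintf("planted signal in gene '%s' requests more carriers than the cohort holds",
                   ps$gene))
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Describe a gene-level burden signal to plant in a synthetic cohort
#'
#' @param gene gene symbol; created in the cohort if not among the simulated
#'   genes.
#' @param variant_class severity class of the planted variant (1, 2 or 3).
#' @param mode `"exact_counts"` (plant exactly the requested carrier
#'   configuration) or `"relative_risk"` (carriers drawn binomially at a
#'   per-carrier relative risk).
#' @param case_carriers,control_carriers carrier sample counts
#'   (`exact_counts` mode).
#' @param rr per-carrier relative risk (`relative_risk` mode).
#' @param carrier_freq population (control) carrier fraction
#'   (`relative_risk` mode).
#' @param weights per-carrier allele multiplicities in `{1, 2}`
#'   (`exact_counts` mode; default all 1; a weight of 2 plants a
#'   homozygous-alternate carrier).
#' @return object of class `planted_signal`.
#' @export
planted_signal <- function(gene, variant_class = 3,
                           mode = c("exact_counts", "relative_risk"),
                           case_carriers = 0, control_carriers = 0,
                           rr = 1, carrier_freq = 0.01, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(variant_class %in% 1:3, rr >= 0,
            carrier_freq > 0, carrier_freq < 1)
  if (mode == "exact_counts") {
    n_car <- case_carriers + control_carriers
    if (is.null(weights)) weights <- rep(1L, n_car)
    if (length(weights) != n_car || !all(weights %in% 1:2))
      stop("weights must give one multiplicity in {1,2} per carrier")
  }
  out <- list(gene = gene, variant_class = as.integer(variant_class),
              mode = mode, case_carriers = case_carriers,
              control_carriers = control_carriers, rr = rr,
              carrier_freq = carrier_freq, weights = weights)
  class(out) <- "planted_signal"
  out
}

#' Simulate a case-control exome cohort
#'
#' Generates a genotype matrix (samples x variants, alternate-allele counts
#' 0/1/2 or NA), genotype metadata (GQ and per-allele depths), a sample
#' sheet, a variant annotation table, and a truth log recording planted
#' signals and injected failures. Null variants draw genotypes from
#' Hardy-Weinberg proportions at their population frequency, so case and
#' control carrier probabilities are equal by construction. When the config
#' requests failure injections they are applied via [inject_qc_failures()]
#' before returning.
#'
#' Genotype metadata model: read depth per call is negative binomial
#' (`depth_mu`, `depth_size`); heterozygote alternate reads are
#' binomial(depth, 0.5) except for designated imbalanced calls
#' (binomial(depth, 0.1)); GQ is discrete with mass `1 - low_gq_rate` on
#' 30-99 and `low_gq_rate` on 2-29.
#'
#' @param config a [sim_config()] object.
#' @return object of class `rv_cohort`: list with `geno`, `gq`, `ad_ref`,
#'   `ad_alt` (matrices), `samples`, `variants`, `annotations`
#'   (data.frames), and `truth` (list).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  sample_id <- sprintf("S%05d", seq_len(n))
  status <- c(rep("case", config$n_case), rep("control", config$n_control))
  true_sex <- sample(c("M", "F"), n, replace = TRUE)
  samples <- data.frame(sample_id = sample_id, status = status,
                        reported_sex = true_sex, stringsAsFactors = FALSE)

  genes <- if (config$n_genes > 0) sprintf("GENE%04d", seq_len(config$n_genes)) else character(0)
  nv_gene <- if (config$n_genes > 0) pmax(1L, rpois(config$n_genes, config$variants_per_gene)) else integer(0)

  # --- variant table -------------------------------------------------------
  vt <- list()
  if (config$n_genes > 0) {
    gene_of_variant <- rep(genes, nv_gene)
    p_gene <- length(gene_of_variant)
    is_rare <- runif(p_gene) < config$rare_fraction
    maf <- ifelse(is_rare,
                  10^runif(p_gene, -4, log10(0.01)),
                  runif(p_gene, 0.01, 0.05))
    cons_pool <- c("synonymous", "missense", "stop_gained", "frameshift",
                   "splice_acceptor", "splice_donor", "inframe_insertion",
                   "inframe_deletion")
    cons_prob <- c(0.30, 0.45, 0.06, 0.06, 0.03, 0.03, 0.035, 0.035)
    consequence <- sample(cons_pool, p_gene, replace = TRUE, prob = cons_prob)
    condel <- ifelse(consequence == "missense",
                     sample(c("damaging", "benign"), p_gene, replace = TRUE,
                            prob = c(0.4, 0.6)),
                     "not_applicable")
    vt$gene_vars <- data.frame(
      chrom = as.character(rep_len(1:22, p_gene)),
      pos = 1e6 + seq_len(p_gene) * 1000L,
      ref = sample(c("A", "C", "G", "T"), p_gene, replace = TRUE),
      alt = "T", gene = gene_of_variant, maf = maf,
      consequence = consequence, condel_label = condel,
      is_indel = consequence %in% c("frameshift", "inframe_insertion",
                                    "inframe_deletion"),
      is_common_snv = FALSE, chrom_x = FALSE, stringsAsFactors = FALSE)
  }
  if (config$common_snv_count > 0) {
    pc <- config$common_snv_count
    vt$common <- data.frame(
      chrom = as.character(rep_len(1:22, pc)),
      pos = 5e7 + seq_len(pc) * 1000L,
      ref = "A", alt = "G", gene = "", maf = runif(pc, 0.2, 0.5),
      consequence = "synonymous", condel_label = "not_applicable",
      is_indel = FALSE, is_common_snv = TRUE, chrom_x = FALSE,
      stringsAsFactors = FALSE)
  }
  if (config$x_snv_count > 0) {
    px <- config$x_snv_count
    vt$xblock <- data.frame(
      chrom = "X", pos = 1e6 + seq_len(px) * 1000L,
      ref = "A", alt = "G", gene = "", maf = runif(px, 0.2, 0.5),
      consequence = "synonymous", condel_label = "not_applicable",
      is_indel = FALSE, is_common_snv = TRUE, chrom_x = TRUE,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vt)
  if (is.null(variants)) stop("config generates no variants at all")
  variants$ref[variants$ref == variants$alt] <- "C"
  variants$variant_key <- variant_key(variants$chrom, variants$pos,
                                      variants$ref, variants$alt)
  variants$tranche <- round(runif(nrow(variants), 90, 98.9), 2)
  variants$alignability <- 1
  variants$repeat_distance <- 1000L
  rownames(variants) <- NULL

  # --- genotypes -----------------------------------------------------------
  p <- nrow(variants)
  geno <- matrix(0L, nrow = n, ncol = p,
                 dimnames = list(sample_id, variants$variant_key))
  male <- true_sex == "M"
  for (j in seq_len(p)) {
    f <- variants$maf[j]
    if (variants$chrom_x[j]) {
      g <- integer(n)
      g[male] <- 2L * rbinom(sum(male), 1, f)
      g[!male] <- rbinom(sum(!male), 2, f)
      geno[, j] <- g
    } else {
      geno[, j] <- rbinom(n, 2, f)
    }
  }

  # --- planted signals -----------------------------------------------------
  truth <- list(planted = list(), failures = list(),
                true_maf = setNames(variants$maf, variants$variant_key))
  is_case <- status == "case"
  for (ps in config$planted_signals) {
    cons <- switch(ps$variant_class, "stop_gained", "splice_acceptor", "missense")
    condel <- if (ps$variant_class == 3L) "benign" else "not_applicable"
    if (ps$mode == "exact_counts") {
      carriers <- c(sample(which(is_case), ps$case_carriers),
                    sample(which(!is_case), ps$control_carriers))
      w <- ps$weights
    } else {
      c0 <- ps$carrier_freq
      c1 <- ps$rr * c0 / (1 - c0 + ps$rr * c0)
      if (c1 >= 1) stop("relative risk too large for the given carrier frequency")
      carriers <- c(which(is_case)[runif(config$n_case) < c1],
                    which(!is_case)[runif(config$n_control) < c0])
      w <- rep(1L, length(carriers))
    }
    newpos <- max(variants$pos) + 1000L * (length(truth$planted) + 1L)
    key <- variant_key("1", newpos, "A", "T")
    newv <- data.frame(
      chrom = "1", pos = newpos, ref = "A", alt = "T", gene = ps$gene,
      maf = length(carriers) / (2 * n), consequence = cons,
      condel_label = condel, is_indel = FALSE, is_common_snv = FALSE,
      chrom_x = FALSE, variant_key = key, tranche = 95, alignability = 1,
      repeat_distance = 1000L, stringsAsFactors = FALSE)
    variants <- rbind(variants, newv)
    gcol <- integer(n)
    gcol[carriers] <- as.integer(w)
    geno <- cbind(geno, setNames(list(gcol), key)[[1]])
    colnames(geno)[ncol(geno)] <- key
    truth$true_maf[key] <- sum(w) / (2 * n)
    truth$planted[[length(truth$planted) + 1L]] <- list(
      gene = ps$gene, variant_key = key, class = ps$variant_class,
      carriers = sample_id[carriers], weights = as.integer(w))
  }

  # baseline missingness; planted columns are exempt so that exact_counts
  # signals realize exactly the requested carrier configuration
  planted_keys <- vapply(truth$planted, function(x) x$variant_key, character(1))
  if (config$baseline_missingness > 0) {
    open_cols <- which(!colnames(geno) %in% planted_keys)
    cells <- length(open_cols) * n
    nmiss <- rbinom(1, cells, config$baseline_missingness)
    if (nmiss > 0) {
      hit <- sample(cells, nmiss)
      geno[cbind((hit - 1L) %% n + 1L, open_cols[(hit - 1L) %/% n + 1L])] <- NA_integer_
    }
  }

  # --- genotype metadata ---------------------------------------------------
  depth <- matrix(pmax(rnbinom(n * ncol(geno), mu = config$depth_mu,
                               size = config$depth_size), 1L),
                  nrow = n)
  het <- !is.na(geno) & geno == 1L
  homalt <- !is.na(geno) & geno == 2L
  ad_alt <- matrix(0L, n, ncol(geno))
  ad_alt[het] <- rbinom(sum(het), depth[het], 0.5)
  if (config$imbalanced_het_rate > 0) {
    imb <- het & matrix(runif(length(het)) < config$imbalanced_het_rate,
                        nrow = n)
    ad_alt[imb] <- rbinom(sum(imb), depth[imb], 0.1)
    truth$failures$imbalanced_het <- which(imb, arr.ind = TRUE)
  }
  ad_alt[homalt] <- depth[homalt]
  gq <- matrix(sample(30:99, n * ncol(geno), replace = TRUE), nrow = n)
  if (config$low_gq_rate > 0) {
    low <- matrix(runif(length(gq)) < config$low_gq_rate, nrow = n)
    gq[low] <- sample(2:29, sum(low), replace = TRUE)
  }
  dimnames(gq) <- dimnames(depth) <- dimnames(ad_alt) <-
    list(sample_id, colnames(geno))
  # planted calls are given unambiguous support (deep, balanced, high GQ) so
  # they survive every genotype-level filter
  if (length(planted_keys)) {
    for (key in planted_keys) {
      carr <- !is.na(geno[, key]) & geno[, key] > 0L
      depth[carr, key] <- pmax(depth[carr, key], 20L)
      ad_alt[carr, key] <- ifelse(geno[carr, key] == 2L, depth[carr, key],
                                  depth[carr, key] %/% 2L)
      gq[carr, key] <- 60L
    }
  }
  ad_ref <- depth - ad_alt
  dimnames(ad_ref) <- dimnames(gq)
  if (config$low_gq_rate > 0)
    truth$failures$low_gq <- which(gq < 30L & !is.na(geno) & geno > 0L,
                                   arr.ind = TRUE)

  cohort <- list(geno = geno, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt,
                 samples = samples, variants = variants,
                 annotations = variants[, c("variant_key", "gene",
                                            "consequence", "condel_label",
                                            "alignability", "repeat_distance",
                                            "tranche", "is_indel")],
                 truth = truth, config = config)
  class(cohort) <- "rv_cohort"
  if (config$n_missingness_outliers > 0 || config$n_het_outliers > 0 ||
      config$n_duplicate_pairs > 0 || config$n_sex_mismatch > 0 ||
      config$n_hwe_sites > 0 || config$n_repeat_sites > 0) {
    cohort <- inject_qc_failures(cohort, config)
  }
  cohort
}

#' Inject quality-control failure modes into a cohort
#'
#' Applies the configured failure modes so that each is recoverable by the
#' corresponding QC operation: samples with elevated missingness or
#' heterozygosity over the common-SNV subset, duplicate sample pairs
#' (near-identical genotypes, the copy carrying extra missingness),
#' reported-sex flips, sites violating Hardy-Weinberg equilibrium (all
#' carriers homozygous alternate), and repeat-proximal sites. The injected
#' roster is appended to `cohort$truth$failures`.
#'
#' @param cohort an `rv_cohort` from [simulate_cohort()].
#' @param config the [sim_config()] carrying the injection counts.
#' @return the modified cohort.
#' @export
inject_qc_failures <- function(cohort, config) {
  stopifnot(inherits(cohort, "rv_cohort"))
  set.seed(config$seed + 1L)
  n <- nrow(cohort$geno)
  common <- cohort$variants$variant_key[cohort$variants$is_common_snv &
                                          !cohort$variants$chrom_x]
  taken <- integer(0)
  pick <- function(k) {
    avail <- setdiff(seq_len(n), taken)
    out <- sample(avail, k)
    taken <<- c(taken, out)
    out
  }
  fr <- cohort$truth$failures

  if (config$n_missingness_outliers > 0) {
    idx <- pick(config$n_missingness_outliers)
    for (i in idx) {
      hit <- runif(length(common)) < config$missingness_outlier_rate
      cohort$geno[i, common[hit]] <- NA_integer_
    }
    fr$missingness_outlier <- rownames(cohort$geno)[idx]
  }
  if (config$n_het_outliers > 0) {
    idx <- pick(config$n_het_outliers)
    for (i in idx) {
      hom <- common[!is.na(cohort$geno[i, common]) &
                      cohort$geno[i, common] != 1L]
      flipn <- ceiling(length(hom) * 0.3)
      cohort$geno[i, sample(hom, flipn)] <- 1L
    }
    fr$het_outlier <- rownames(cohort$geno)[idx]
  }
  if (config$n_duplicate_pairs > 0) {
    if (2L * config$n_duplicate_pairs > n - length(taken))
      stop("not enough unflagged samples for the requested duplicate pairs")
    pairs <- matrix(pick(2L * config$n_duplicate_pairs), ncol = 2)
    for (r in seq_len(nrow(pairs))) {
      src <- pairs[r, 1]; dst <- pairs[r, 2]
      cohort$geno[dst, ] <- cohort$geno[src, ]
      # the copy carries a little extra missingness so exclusion is determinate
      extra <- sample(ncol(cohort$geno), max(5L, ncol(cohort$geno) %/% 200L))
      cohort$geno[dst, extra] <- NA_integer_
    }
    fr$duplicate_pair <- data.frame(
      sample1 = rownames(cohort$geno)[pairs[, 1]],
      sample2 = rownames(cohort$geno)[pairs[, 2]], stringsAsFactors = FALSE)
  }
  if (config$n_sex_mismatch > 0) {
    idx <- pick(config$n_sex_mismatch)
    flip <- c(M = "F", F = "M")
    cohort$samples$reported_sex[idx] <- flip[cohort$samples$reported_sex[idx]]
    fr$sex_mismatch <- cohort$samples$sample_id[idx]
  }
  if (config$n_hwe_sites > 0) {
    keys <- character(config$n_hwe_sites)
    for (s in seq_len(config$n_hwe_sites)) {
      newpos <- max(cohort$variants$pos) + 1000L
      key <- variant_key("2", newpos, "A", "T")
      carriers <- sample(n, 12)
      gcol <- integer(n); gcol[carriers] <- 2L
      cohort <- add_variant(cohort, key, chrom = "2", pos = newpos,
                            gene = "", consequence = "synonymous",
                            geno_col = gcol)
      keys[s] <- key
    }
    fr$hwe_site <- keys
  }
  if (config$n_repeat_sites > 0) {
    gene_keys <- cohort$variants$variant_key[!cohort$variants$is_common_snv]
    idx <- sample(gene_keys, min(config$n_repeat_sites, length(gene_keys)))
    row <- match(idx, cohort$variants$variant_key)
    cohort$variants$repeat_distance[row] <- sample(0:10, length(row), replace = TRUE)
    arow <- match(idx, cohort$annotations$variant_key)
    cohort$annotations$repeat_distance[arow] <- cohort$variants$repeat_distance[row]
    fr$repeat_site <- idx
  }
  cohort$truth$failures <- fr
  cohort
}

# append one variant column plus metadata to a cohort
add_variant <- function(cohort, key, chrom, pos, gene, consequence, geno_col,
                        condel = "not_applicable", is_indel = FALSE) {
  n <- nrow(cohort$geno)
  newv <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                     gene = gene, maf = sum(geno_col, na.rm = TRUE) / (2 * n),
                     consequence = consequence, condel_label = condel,
                     is_indel = is_indel, is_common_snv = FALSE,
                     chrom_x = FALSE, variant_key = key, tranche = 95,
                     alignability = 1, repeat_distance = 1000L,
                     stringsAsFactors = FALSE)
  cohort$variants <- rbind(cohort$variants, newv)
  cohort$annotations <- rbind(cohort$annotations,
                              newv[, names(cohort$annotations)])
  depth <- pmax(rnbinom(n, mu = cohort$config$depth_mu,
                        size = cohort$config$depth_size), 1L)
  ad_alt <- integer(n)
  het <- !is.na(geno_col) & geno_col == 1L
  ad_alt[het] <- rbinom(sum(het), depth[het], 0.5)
  ad_alt[!is.na(geno_col) & geno_col == 2L] <- depth[!is.na(geno_col) & geno_col == 2L]
  cohort$geno <- cbind(cohort$geno, geno_col)
  cohort$gq <- cbind(cohort$gq, sample(30:99, n, replace = TRUE))
  cohort$ad_alt <- cbind(cohort$ad_alt, ad_alt)
  cohort$ad_ref <- cbind(cohort$ad_ref, depth - ad_alt)
  for (m in c("geno", "gq", "ad_alt", "ad_ref"))
    colnames(cohort[[m]])[ncol(cohort[[m]])] <- key
  cohort$truth$true_maf[key] <- newv$maf
  cohort
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat(sprintf("rv_cohort: %d samples (%d cases / %d controls), %d variants\n",
              nrow(x$geno), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), ncol(x$geno)))
  cat(sprintf("  genes: %d; common SNVs: %d; X sites: %d; planted signals: %d\n",
              length(unique(x$variants$gene[x$variants$gene != ""])),
              sum(x$variants$is_common_snv & !x$variants$chrom_x),
              sum(x$variants$chrom_x), length(x$truth$planted)))
  invisible(x)
}
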