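test_that("genotype-support filter enforces GQ, alt-depth and tranche bounds", {
  keys <- sprintf("1:%d:A:T", 1:6)
  geno <- matrix(1L, 1, 6, dimnames = list("S1", keys))
  gq <- matrix(c(30, 29, 50, 50, 50, 50), 1)
  ad <- matrix(c(4, 10, 3, 4, 4, 4), 1)
  tranche <- c(99.0, 95, 95, 99.5, 98.9, 99.0)
  is_indel <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  out <- genotype_support_filter(geno, gq, ad, tranche, is_indel)
  # GQ=30, depth 4, SNV tranche 99.0 passes; GQ=29 fails; depth 3 fails
  # (strict); SNV tranche 99.5 fails; indel tranche 98.9 passes, 99.0 fails
  expect_equal(as.vector(out), c(1L, NA, NA, NA, 1L, NA))
  # hom-ref calls are untouched
  geno0 <- matrix(0L, 1, 6, dimnames = list("S1", keys))
  expect_equal(as.vector(genotype_support_filter(geno0, gq, ad, tranche, is_indel)),
               rep(0L, 6))
  # missing metadata: call dropped with a warning
  gq[1] <- NA
  expect_warning(out2 <- genotype_support_filter(geno, gq, ad, tranche, is_indel),
                 "lack GQ/AD")
  expect_true(is.na(out2[1, 1]))
})

test_that("sample missingness and heterozygosity match direct recounts", {
  set.seed(2)
  co <- small_cohort()
  common <- co$variants$variant_key[co$variants$is_common_snv & !co$variants$chrom_x]
  miss <- sample_missingness(co$geno, common)
  het <- sample_heterozygosity(co$geno, common)
  sub <- co$geno[, common]
  for (i in sample(nrow(sub), 10)) {
    expect_equal(miss[[i]], sum(is.na(sub[i, ])) / length(common))
    expect_equal(het[[i]], sum(sub[i, ] == 1, na.rm = TRUE) / sum(!is.na(sub[i, ])))
  }
  expect_equal(unname(sample_missingness(
    matrix(c(NA, rep(0L, 99)), 1, dimnames = list("a", sprintf("k%d", 1:100))),
    sprintf("k%d", 1:100))), 0.01)
  expect_error(sample_missingness(co$geno, character(0)), "empty")
})

test_that("3-SD outlier rule uses the one-pass population SD", {
  vals <- c(rep(0.01, 99), 0.5)
  flags <- flag_outliers_3sd(vals)
  mu <- mean(vals); sdev <- sqrt(mean((vals - mu)^2))
  expect_identical(flags, vals > mu + 3 * sdev)
  expect_identical(which(flags), 100L)
  expect_false(any(flag_outliers_3sd(rep(0.3, 50))))
  # k = 0 flags everything strictly above the mean
  expect_identical(flag_outliers_3sd(c(1, 2, 3), k = 0), c(FALSE, FALSE, TRUE))
})

test_that("sex inference from X heterozygosity flags discrepancies only when determined", {
  set.seed(6)
  n <- 60
  truth_male <- rep(c(TRUE, FALSE), each = n / 2)
  af <- runif(200, 0.2, 0.5)
  xg <- t(vapply(seq_len(n), function(i) {
    if (truth_male[i]) 2L * rbinom(200, 1, af) else rbinom(200, 2, af)
  }, integer(200)))
  reported <- ifelse(truth_male, "M", "F")
  res <- sex_check(xg, reported)
  expect_false(any(res$discrepancy))
  expect_equal(res$inferred_sex, reported)
  # an all-homozygous sample reported female is discrepant; reported male passes
  res2 <- sex_check(xg, replace(reported, 1, "F"))
  expect_true(res2$discrepancy[1])
  # unknown reported sex is never flagged
  res3 <- sex_check(xg, rep("unknown", n))
  expect_false(any(res3$discrepancy))
  # no X variants: undetermined, no flags
  res4 <- sex_check(NULL, reported)
  expect_true(all(res4$inferred_sex == "undetermined"))
  expect_false(any(res4$discrepancy))
})

test_that("duplicate detection finds planted pairs and nothing else", {
  set.seed(17)
  n <- 80
  keys <- sprintf("1:%d:A:G", 1:400)
  af <- runif(400, 0.2, 0.5)
  g <- t(vapply(seq_len(n), function(i) rbinom(400, 2, af), integer(400)))
  dimnames(g) <- list(sprintf("S%03d", 1:n), keys)
  g[2, ] <- g[1, ]          # exact duplicate
  g[2, 1:5] <- NA           # copy has higher missingness
  dups <- detect_duplicates(g, keys, threshold = 0.95)
  expect_equal(nrow(dups), 1)
  expect_setequal(c(dups$sample1, dups$sample2), c("S001", "S002"))
  expect_equal(dups$exclude, "S002")
  # unrelated pairs stay below threshold
  dups2 <- detect_duplicates(g[3:n, ], keys, threshold = 0.95)
  expect_equal(nrow(dups2), 0)
})

test_that("HWE exact test matches full enumeration and handles edge cases", {
  # independent enumeration oracle over heterozygote counts
  hwe_oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb
    na <- 2 * bb + ab
    rare <- min(na, 2 * n - na)
    if (rare == 0) return(1)
    hets <- seq(rare %% 2, rare, 2)
    pr <- vapply(hets, function(h) {
      hom_r <- (rare - h) / 2
      hom_c <- n - hom_r - h
      exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
            h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
            lfactorial(2 * n))
    }, 1)
    sum(pr[pr <= pr[hets == ab] * (1 + 1e-10)])
  }
  expect_equal(hwe_exact_test(100, 0, 0), 1)      # monomorphic
  expect_lt(hwe_exact_test(0, 100, 0), 1e-8)
  expect_equal(hwe_exact_test(0, 100, 0), hwe_oracle(0, 100, 0), tolerance = 1e-10)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25), tolerance = 1e-10)
  set.seed(30)
  for (i in 1:30) {
    cnts <- c(sample(0:40, 1), sample(0:40, 1), sample(0:10, 1))
    expect_equal(hwe_exact_test(cnts[1], cnts[2], cnts[3]),
                 hwe_oracle(cnts[1], cnts[2], cnts[3]), tolerance = 1e-9)
  }
  expect_equal(hwe_exact_test(0, 0, 0), 1)
  # chi-square option agrees with the asymptotic formula
  p_alt <- (2 * 5 + 20) / (2 * 100)
  ex <- 100 * c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2)
  x2 <- sum((c(75, 20, 5) - ex)^2 / ex)
  expect_equal(hwe_exact_test(75, 20, 5, method = "chisq"),
               pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("all-homozygous-alternate carrier sites fail HWE decisively", {
  # the HWE failure mode the generator injects: carriers only as hom-alt
  for (k in c(8, 12, 20)) {
    p <- hwe_exact_test(500 - k, 0, k)
    expect_lt(p, 1e-8)
  }
})

test_that("allele-balance chi-square matches the survival function", {
  r <- allele_balance_test(10, 10)
  expect_equal(r$p, 1)
  expect_false(r$exclude)
  r2 <- allele_balance_test(30, 2)
  expect_equal(r2$x2, 24.5)
  expect_equal(r2$p, pchisq(24.5, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(r2$exclude)
  r3 <- allele_balance_test(12, 8)
  expect_equal(r3$x2, 0.8)
  expect_false(r3$exclude)
  expect_true(allele_balance_test(0, 0)$exclude)
})

test_that("differential-missingness Fisher test flags capture artefacts", {
  expect_equal(differential_missingness_test(400, 0, 1560, 0), 1)
  expect_equal(differential_missingness_test(100, 10, 300, 30), 1)
  p <- differential_missingness_test(400, 113, 1560, 9)
  expect_lt(p, 1e-5)
  expect_equal(p, stats::fisher.test(
    matrix(c(113, 400, 9, 1560), 2, byrow = TRUE))$p.value, tolerance = 1e-10)
})

test_that("single-variant track QC applies each discard rule at its boundary", {
  set.seed(55)
  n <- 200
  is_case <- rep(c(TRUE, FALSE), each = 100)
  keys <- sprintf("1:%d:A:T", 1:5)
  g <- matrix(rbinom(n * 5, 2, 0.2), n, dimnames = list(NULL, keys))
  ann <- do.call(rbind, lapply(keys, ann_row))
  ann$alignability[2] <- 0.5
  ann$repeat_distance[3] <- 10   # inclusive: fails
  ann$repeat_distance[4] <- 11   # just outside: passes
  # variant 5: no-call rate 0.031 in controls
  g[sample(which(!is_case), ceiling(0.031 * 100)), 5] <- NA
  qc <- single_variant_qc(g, is_case, ann)
  expect_true(qc$pass[1])
  expect_false(qc$pass[2]); expect_true(qc$fail_alignability[2])
  expect_false(qc$pass[3]); expect_true(qc$fail_repeat[3])
  expect_false(qc$fail_repeat[4])
  expect_false(qc$pass[5]); expect_true(qc$fail_nocall[5])
  expect_error(single_variant_qc(g, is_case, ann[, 1:2]), "required columns")
})

test_that("gene-centric QC uses combined HWE and the inclusive no-call bound", {
  n <- 400
  is_case <- rep(c(TRUE, FALSE), each = 200)
  keys <- sprintf("1:%d:A:T", 1:3)
  g <- matrix(rbinom(n * 3, 2, 0.1), n, dimnames = list(NULL, keys))
  ann <- do.call(rbind, lapply(keys, ann_row))
  # variant 2: exactly 25% no-call in cases -> fails (inclusive)
  g[1:50, 2] <- NA
  # variant 3: all carriers homozygous alternate -> combined HWE << 1e-8
  g[, 3] <- 0L; g[sample(n, 15), 3] <- 2L
  qc <- gene_centric_qc(g, is_case, ann)
  expect_true(qc$pass[1])
  expect_false(qc$pass[2]); expect_true(qc$fail_nocall[2])
  expect_false(qc$pass[3]); expect_true(qc$fail_hwe[3])
  # a variant at combined HWE P ~ 1e-7 passes the 1e-8 gene-centric bound
  expect_false(qc$fail_hwe[1])
})

test_that("sample QC bookkeeping: excluded iff at least one flag", {
  co <- small_cohort(seed = 77, n_missingness_outliers = 3, n_het_outliers = 2,
                     n_duplicate_pairs = 1, n_sex_mismatch = 2)
  common <- co$variants$variant_key[co$variants$is_common_snv & !co$variants$chrom_x]
  xk <- co$variants$variant_key[co$variants$chrom_x]
  sqc <- sample_qc(co$geno, co$samples, common, xk)
  flags <- sqc[, c("sex_discrepancy", "high_missingness", "high_heterozygosity",
                   "ancestry_excluded", "duplicate")]
  expect_identical(sqc$excluded, rowSums(flags) > 0)
  expect_equal(sum(sqc$excluded), sum(rowSums(flags) > 0))
  expect_true(all(nzchar(sqc$reason[sqc$excluded])))
  expect_true(all(sqc$reason[!sqc$excluded] == ""))
  # every planted failure is recovered
  fr <- co$truth$failures
  expect_true(all(fr$missingness_outlier %in%
                    sqc$sample_id[sqc$high_missingness]))
  expect_true(all(fr$het_outlier %in% sqc$sample_id[sqc$high_heterozygosity]))
  expect_true(all(fr$sex_mismatch %in% sqc$sample_id[sqc$sex_discrepancy]))
  dup_found <- attr(sqc, "duplicates")
  for (r in seq_len(nrow(fr$duplicate_pair))) {
    expect_true(any(
      (dup_found$sample1 == fr$duplicate_pair$sample1[r] &
         dup_found$sample2 == fr$duplicate_pair$sample2[r]) |
        (dup_found$sample2 == fr$duplicate_pair$sample1[r] &
           dup_found$sample1 == fr$duplicate_pair$sample2[r])))
  }
  # ancestry exclusions are merged from the input list
  sqc2 <- sample_qc(co$geno, co$samples, common, xk,
                    ancestry_excluded = co$samples$sample_id[1:3])
  expect_true(all(sqc2$ancestry_excluded[1:3]))
})

test_that("sample QC flags are invariant to sample order", {
  co <- small_cohort(seed = 78, n_missingness_outliers = 2)
  common <- co$variants$variant_key[co$variants$is_common_snv & !co$variants$chrom_x]
  perm <- sample(nrow(co$geno))
  sqc1 <- sample_qc(co$geno, co$samples, common)
  sqc2 <- sample_qc(co$geno[perm, ], co$samples[perm, ], common)
  sqc2 <- sqc2[match(sqc1$sample_id, sqc2$sample_id), ]
  expect_equal(sqc1$excluded, sqc2$excluded)
  expect_equal(sqc1$high_missingness, sqc2$high_missingness)
})
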