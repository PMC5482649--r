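test_that("exact mid-P reproduces published carrier configurations at 513/1569", {
  # printed one-sided permutation P-values for weight-1 carrier configs
  configs <- list(
    list(ca = 6, co = 0, printed = 1.1e-4),
    list(ca = 5, co = 0, printed = 4.5e-4),
    list(ca = 5, co = 1, printed = 2.2e-3),
    list(ca = 7, co = 2, printed = 6.4e-4),
    list(ca = 2, co = 2, printed = 1.5e-1),
    list(ca = 16, co = 7, printed = 3.6e-6))
  for (cf in configs) {
    p <- exact_permutation_midp(rep(1, cf$ca + cf$co), cf$ca,
                                n_case = 513, n_control = 1569)
    expect_equal(signif(p, 2), cf$printed,
                 label = sprintf("config (%d,%d)", cf$ca, cf$co))
  }
})

test_that("exact permutation path equals full enumeration on micro-cohorts", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    n_case <- sample(2:(n - 2), 1)
    w_all <- sample(0:3, n, replace = TRUE)
    is_case <- seq_len(n) %in% sample(n, n_case)
    oracle <- enum_midp_oracle(w_all, is_case)
    pn <- perm_null(w_all[w_all > 0], n_case, n - n_case)
    p <- exact_permutation_midp(pn, sum(w_all[is_case]))
    expect_equal(p, oracle, tolerance = 1e-12)
  }
})

test_that("weight-1 convolution path agrees with the hypergeometric closed form", {
  pn <- perm_null(rep(1L, 23), 513, 1569)
  expect_equal(pn$prob, dhyper(0:23, 513, 1569, 23), tolerance = 1e-12)
  expect_equal(sum(pn$prob), 1, tolerance = 1e-12)
  # forcing the DP route with a dummy weight-2 carrier removed again
  pn2 <- perm_null(c(rep(1L, 22), 1L), 513, 1569)
  expect_equal(pn2$support, 0:23)
})

test_that("unequal-weight null matches weighted subset enumeration", {
  # seven carriers, weights (2,2,1,1,1,1,1): compare against direct
  # enumeration over the 2^7 carrier label assignments
  w <- c(2, 2, 1, 1, 1, 1, 1)
  K <- 7; N <- 2082; ncs <- 513
  p_gt <- 0; p_eq <- 0
  for (mask in 0:(2^K - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(K - 1))) > 0)
    s <- sum(w[idx])
    pr <- exp(lchoose(N - K, ncs - length(idx)) - lchoose(N, ncs))
    if (s > 8) p_gt <- p_gt + pr
    if (s == 8) p_eq <- p_eq + pr
  }
  oracle <- p_gt + 0.5 * p_eq
  p <- exact_permutation_midp(perm_null(w, 513, 1569), 8)
  expect_equal(p, oracle, tolerance = 1e-10)
  expect_equal(signif(p, 2), 4.7e-4)
})

test_that("mid-P and tail conventions relate correctly and handle the floor", {
  pn <- perm_null(rep(1, 5), 50, 150)
  for (s in 0:5) {
    midp <- exact_permutation_midp(pn, s)
    tail <- exact_permutation_midp(pn, s, convention = "tail")
    expect_lt(midp, tail)
    expect_equal(tail - midp, 0.5 * dhyper(s, 50, 150, 5), tolerance = 1e-12)
  }
  # at S_obs = 0 the mid-P is 1 - Pr(S = 0) / 2
  expect_equal(exact_permutation_midp(pn, 0),
               1 - 0.5 * dhyper(0, 50, 150, 5), tolerance = 1e-12)
})

test_that("Monte-Carlo permutation agrees with the exact path", {
  set.seed(33)
  worst <- 0
  for (i in 1:50) {
    K <- sample(3:12, 1)
    w <- sample(1:3, K, replace = TRUE)
    s_obs <- sum(w[runif(K) < 0.4])
    ex <- exact_permutation_midp(perm_null(w, 40, 160), s_obs)
    mc <- monte_carlo_permutation_midp(w, s_obs, 40, 160, B = 1e5, seed = i)
    expect_lt(abs(mc$p - ex), 3 * max(mc$se, 5e-4))
  }
  # degenerate grouping: every sample a case makes S constant, mid-P = 1/2
  mc <- monte_carlo_permutation_midp(rep(1, 4), 4, n_case = 10, n_control = 0,
                                     B = 1e3, seed = 1)
  expect_equal(mc$p, 0.5)
  expect_error(monte_carlo_permutation_midp(rep(1, 4), 2, 10, 10, B = 100),
               "at least 1000")
})

test_that("collapse_gene summarizes carrier configurations and weights", {
  # 16 case carriers + 7 control carriers, one allele each
  g <- micro_geno(100, list(c(1:16, 51:57)))
  is_case <- c(rep(TRUE, 50), rep(FALSE, 50))
  cf <- collapse_gene(g, colnames(g), is_case)
  expect_equal(cf$s_obs, 16)
  expect_equal(length(cf$weights), 23)
  expect_equal(cf$case_carriers, 16)
  expect_equal(cf$control_carriers, 7)
  # a sample carrying two distinct qualifying variants contributes weight 2
  g2 <- cbind(micro_geno(10, list(1:2), key = "1:1:A:T"),
              micro_geno(10, list(1), key = "1:2:A:T"))
  cf2 <- collapse_gene(g2, colnames(g2), rep(c(TRUE, FALSE), each = 5))
  expect_equal(sort(cf2$weights), c(1, 2))
  expect_equal(cf2$s_obs, 3)
  # no case carriers
  g3 <- micro_geno(10, list(8:9))
  cf3 <- collapse_gene(g3, colnames(g3), rep(c(TRUE, FALSE), each = 5))
  expect_equal(cf3$s_obs, 0)
  expect_null(collapse_gene(g3, character(0), rep(TRUE, 10)))
})

test_that("burden_scan admits genes on Class 3 carriers and orders by min P", {
  n <- 200
  is_case <- rep(c(TRUE, FALSE), each = 100)
  keys <- c("1:1:A:T", "1:2:A:T", "1:3:A:T")
  g <- cbind(micro_geno(n, list(1:9), keys[1]),        # gene A: 9 carriers
             micro_geno(n, list(c(1:8, 101:104)), keys[2]),  # gene B class 1
             micro_geno(n, list(105), keys[3]))              # gene B class 3 extra
  colnames(g) <- keys
  cs <- rbind(
    data.frame(gene = "GA", class_id = 3L, variant_key = keys[1]),
    data.frame(gene = "GB", class_id = 1L, variant_key = keys[2]),
    data.frame(gene = "GB", class_id = 2L, variant_key = keys[2]),
    data.frame(gene = "GB", class_id = 3L, variant_key = c(keys[2], keys[3])))
  res <- burden_scan(g, cs, is_case, min_samples = 10)
  # gene A has 9 Class 3 carriers: not tested
  expect_false("GA" %in% res$gene)
  expect_equal(sort(unique(res$class_id[res$gene == "GB"])), 1:3)
  # carriers nest across classes
  c3 <- res[res$gene == "GB" & res$class_id == 3, ]
  c1 <- res[res$gene == "GB" & res$class_id == 1, ]
  expect_gte(c3$case_samples, c1$case_samples)
  expect_gte(c3$control_samples, c1$control_samples)
  # threshold = alpha / number of computed tests
  expect_equal(attr(res, "exome_wide_threshold"), 0.05 / nrow(res))
})

test_that("panel test applies the list-sized Bonferroni threshold", {
  res <- data.frame(gene = c("A", "B"), class_id = c(3L, 3L),
                    P = c(1e-5, 0.2), stringsAsFactors = FALSE)
  panel <- csg_panel_test(res, c("A", "C"), alpha = 0.05)
  expect_equal(panel$threshold, 0.025)
  expect_equal(panel$untested, "C")
  expect_true(panel$results$significant[panel$results$gene == "A"])
  # a 114-gene panel yields the 4.4e-4 threshold
  expect_equal(signif(suppressWarnings(
    csg_panel_test(res, sprintf("G%03d", 1:114)))$threshold, 2), 4.4e-4)
  single <- csg_panel_test(res, "A")
  expect_equal(single$threshold, 0.05)
  expect_warning(csg_panel_test(res, "ZZZ"), "none of the listed genes")
})

test_that("LOH binomial test matches direct tail summation", {
  expect_equal(loh_binomial_test(14, 0), 1)
  expect_equal(loh_binomial_test(14, 14), 2^-14)
  expect_equal(loh_binomial_test(14, 9), sum(dbinom(9:14, 14, 0.5)),
               tolerance = 1e-12)
  expect_error(loh_binomial_test(14, 15), "exceed")
})

test_that("Bonferroni thresholds reproduce the published values", {
  expect_equal(signif(bonferroni_threshold(0.05, 24752), 3), 2.02e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 15358), 2), 3.3e-6)
  expect_equal(signif(bonferroni_threshold(0.05, 114), 2), 4.4e-4)
})
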