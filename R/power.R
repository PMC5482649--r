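#' Simulated discovery power for a single variant
#'
#' For a variant of given minor allele frequency and per-allele relative
#' risk, draws `B` replicate case/control allele counts and reports the
#' fraction reaching `P <= alpha` under the two-sided Fisher exact test.
#' The control allele frequency is the population MAF `p0`; the case
#' frequency follows the rare-disease relative-risk mapping
#' `p1 = rr * p0 / (1 - p0 + rr * p0)`.
#'
#' @param maf population minor allele frequency, in (0, 0.5].
#' @param rr per-allele relative risk (>= 0).
#' @param n_case,n_control sample sizes (alleles drawn are twice these).
#' @param alpha significance level per test.
#' @param B replicate draws.
#' @param seed RNG seed.
#' @return list of class `power_point`: `power`, `mc_se`, plus the inputs.
#' @export
single_variant_power <- function(maf, rr, n_case = 513, n_control = 1569,
                                 alpha = 2.02e-6, B = 10000, seed = 1L) {
  stopifnot(maf > 0, maf <= 0.5, rr >= 0, B >= 1)
  p0 <- maf
  p1 <- rr_to_freq(p0, rr)
  if (p1 >= 1) stop("relative risk too large for the given MAF")
  if (!is.null(seed)) set.seed(seed)
  a <- rbinom(B, 2L * n_case, p1)
  c_ <- rbinom(B, 2L * n_control, p0)
  p <- fisher_two_sided_p(a, 2L * n_case - a, c_, 2L * n_control - c_)
  finish_power_point(mean(p <= alpha), B, freq = maf, rr = rr,
                     n_case = n_case, n_control = n_control, alpha = alpha)
}

#' Simulated discovery power for a gene burden test
#'
#' As [single_variant_power()], but the unit is the carrier: the frequency
#' argument is the fraction of the population carrying a qualifying variant
#' in the gene of interest, replicate carrier counts are drawn binomially,
#' and each replicate is evaluated with the exact one-sided mid-P burden
#' test (all carrier weights 1).
#'
#' @param carrier_freq population carrier fraction, in (0, 1).
#' @inheritParams single_variant_power
#' @export
burden_power <- function(carrier_freq, rr, n_case = 513, n_control = 1569,
                         alpha = 3.3e-6, B = 10000, seed = 1L) {
  stopifnot(carrier_freq > 0, carrier_freq < 1, rr >= 0, B >= 1)
  c0 <- carrier_freq
  c1 <- rr_to_freq(c0, rr)
  if (c1 >= 1) stop("relative risk too large for the given carrier frequency")
  if (!is.null(seed)) set.seed(seed)
  x1 <- rbinom(B, n_case, c1)
  x0 <- rbinom(B, n_control, c0)
  K <- x1 + x0
  # weight-1 exact mid-P, vectorized over replicates
  p <- phyper(x1, n_case, n_control, K, lower.tail = FALSE) +
    0.5 * dhyper(x1, n_case, n_control, K)
  finish_power_point(mean(p <= alpha), B, freq = carrier_freq, rr = rr,
                     n_case = n_case, n_control = n_control, alpha = alpha)
}

# rare-disease per-carrier relative-risk mapping from control to case frequency
rr_to_freq <- function(p0, rr) rr * p0 / (1 - p0 + rr * p0)

finish_power_point <- function(power, B, ...) {
  out <- c(list(power = power,
                mc_se = sqrt(max(power, 1 / B) * (1 - min(power, 1 - 1 / B)) / B),
                B = B), list(...))
  class(out) <- "power_point"
  out
}

#' @export
print.power_point <- function(x, ...) {
  cat(sprintf("power %.4f (MC se %.4f) at freq=%g rr=%g alpha=%g, n=%d/%d, B=%d\n",
              x$power, x$mc_se, x$freq, x$rr, x$alpha, x$n_case, x$n_control,
              x$B))
  invisible(x)
}

#' Evaluate a power grid
#'
#' Cartesian product of frequency and relative-risk grids, each cell
#' evaluated by [single_variant_power()] or [burden_power()]. Each cell uses
#' a seed derived deterministically from `seed` and the cell index.
#'
#' @param freq_list,rr_list non-empty numeric grids.
#' @param kind `"single"` or `"burden"`.
#' @param ... passed to the per-cell power function.
#' @param seed base RNG seed.
#' @return data.frame with one row per (freq, rr) cell.
#' @export
power_grid <- function(freq_list, rr_list, kind = c("single", "burden"),
                       ..., seed = 1L) {
  kind <- match.arg(kind)
  if (length(freq_list) == 0L || length(rr_list) == 0L)
    stop("grids must be non-empty")
  cells <- expand.grid(freq = freq_list, rr = rr_list,
                       KEEP.OUT.ATTRS = FALSE)
  fn <- if (kind == "single") {
    function(f, r, s) single_variant_power(maf = f, rr = r, seed = s, ...)
  } else {
    function(f, r, s) burden_power(carrier_freq = f, rr = r, seed = s, ...)
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    pp <- fn(cells$freq[i], cells$rr[i], (seed * 1000L + i) %% .Machine$integer.max)
    data.frame(freq = cells$freq[i], rr = cells$rr[i], power = pp$power,
               mc_se = pp$mc_se, B = pp$B)
  })
  do.call(rbind, res)
}
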