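# shared fixtures, all generated in code

# full enumeration of the one-sided mid-P over every case/control label split
# (independent oracle for the exact permutation path; feasible for n <= 12)
enum_midp_oracle <- function(weights_all, is_case) {
  n <- length(weights_all)
  n_case <- sum(is_case)
  s_obs <- sum(weights_all[is_case])
  splits <- combn(n, n_case)
  S <- apply(splits, 2, function(ix) sum(weights_all[ix]))
  mean(S > s_obs) + 0.5 * mean(S == s_obs)
}

# tiny deterministic genotype matrix builder: carriers get genotype `g`
micro_geno <- function(n, carrier_rows, key = "1:100:A:T", g = 1L) {
  m <- matrix(0L, nrow = n, ncol = length(key),
              dimnames = list(sprintf("S%03d", 1:n), key))
  for (j in seq_along(key)) m[carrier_rows[[j]], j] <- g
  m
}

# small clean cohort reused across files
small_cohort <- function(seed = 101, ...) {
  simulate_cohort(sim_config(n_case = 60, n_control = 140, n_genes = 20,
                             common_snv_count = 300, x_snv_count = 60,
                             seed = seed, ...))
}

# annotation row factory
ann_row <- function(variant_key, gene = "G1", consequence = "missense",
                    condel_label = "not_applicable", alignability = 1,
                    repeat_distance = 1000, tranche = 95, is_indel = FALSE) {
  data.frame(variant_key = variant_key, gene = gene,
             consequence = consequence, condel_label = condel_label,
             alignability = alignability, repeat_distance = repeat_distance,
             tranche = tranche, is_indel = is_indel,
             stringsAsFactors = FALSE)
}
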