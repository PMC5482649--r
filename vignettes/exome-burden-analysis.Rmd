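---
title: "Rare-variant case-control exome analysis: QC, burden testing, and power"
author: "exomeburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant case-control exome analysis: QC, burden testing, and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeburden)
```

## Scope

`exomeburden` implements the statistical core of a rare-variant case-control
exome study: quality control at the sample, genotype and variant level; a
single-variant Fisher exact association scan with pruning of unpowered
variants; a gene-level collapsing burden test (the T1/CMC family) over nested
functional severity classes, evaluated against an exact one-sided permutation
null; a candidate-gene panel assessment; and simulation-based power analysis.
A synthetic cohort generator produces case-control exomes with the
statistical structure the analysis assumes, so the entire pipeline is
testable end to end without access to controlled sequencing data.

The defaults throughout emulate a study of 513 cases against 1,569 controls
(2,082 samples after quality exclusions), the configuration used in all
worked examples and calibration checks below.

## The collapsing burden model

For a gene $g$ and a set $Q_g$ of qualifying variants (rare, functional;
see the class definitions below), each sample $i$ receives a burden weight

$$w_i = \sum_{v \in Q_g} g_{iv},$$

the count of qualifying alternate alleles it carries ($g_{iv} \in \{0,1,2\}$;
missing genotypes contribute 0). The test statistic is the case allele total

$$S = \sum_{i \,\in\, \text{cases}} w_i .$$

Under the null hypothesis that case/control labels are exchangeable, the
distribution of $S$ is obtained by permuting labels with the group sizes
fixed. Only carriers ($w_i > 0$) matter: with $K$ carriers of weights
$w_1,\dots,w_K$ among $N$ samples of which $n_1$ are cases, the number $J$
of carriers landing in the case group is hypergeometric, and conditional on
$J = j$ the carriers in cases are a uniform random $j$-subset. When all
weights are 1, $S = J$ exactly, and the null is the hypergeometric law
$S \sim \mathrm{Hyper}(N, K, n_1)$. With unequal weights the package counts,
for every $(j, s)$, the number $N_j(s)$ of $j$-subsets of carriers with
weight sum $s$ (a subset-sum dynamic programme run in log space to avoid
overflow at large $K$), and mixes over the hypergeometric law of $J$:

$$\Pr(S = s) \;=\; \sum_j \frac{\binom{N-K}{\,n_1-j\,}}{\binom{N}{n_1}}\, N_j(s).$$

This path is exact for any carrier configuration and is used up to
$K \le 500$ carriers; beyond that a seeded Monte-Carlo permutation
(default $B = 10^6$) takes over. Both paths are validated in the test suite
against brute-force enumeration of every label split on micro-cohorts.

### The mid-P convention

The one-sided P-value reported by default is the mid-P,

$$P \;=\; \Pr(S > S_{\mathrm{obs}}) + \tfrac12 \Pr(S = S_{\mathrm{obs}}),$$

which removes most of the conservatism that plain tail probabilities
($\Pr(S \ge S_{\mathrm{obs}})$) suffer on heavily discrete supports —
important here because rare-variant carrier counts are small. Published
per-gene values for this design (e.g. $1.1\times10^{-4}$ for a 6-case/0-control
configuration, $3.6\times10^{-6}$ for 16/7 at $n = 513/1{,}569$) are
reproduced by the mid-P convention and not by the plain tail; the plain tail
remains available via `convention = "tail"`.

```{r}
# six case carriers, none in controls, one qualifying allele each
exact_permutation_midp(rep(1, 6), 6, n_case = 513, n_control = 1569)
# the 16/7 configuration
exact_permutation_midp(rep(1, 23), 16, n_case = 513, n_control = 1569)
```

## Nested variant severity classes

Variants are assigned a single worst consequence per gene under the
hierarchy stop gained > frameshift > splice acceptor/donor > inframe
insertion/deletion > missense > synonymous, then grouped into three nested
classes:

* **Class 1, "disruptive"** — stop gained, frameshift;
* **Class 2, "predicted damaging"** — Class 1 plus splice acceptor/donor
  and missense calls labelled damaging by a CONDEL-style classifier;
* **Class 3, "all non-synonymous"** — Class 2 plus every remaining
  non-synonymous variant (benign/unscored missense, inframe indels).

Inframe indels sit above missense in the severity hierarchy but are not
named in any class definition narrower than "non-synonymous"; they are
placed in Class 3 rather than guessed into Class 2. Qualifying variants must
also be rare: combined-cohort MAF (over called alleles of cases and controls
together) strictly below 1% by default, with an optional external reference
frequency column applied at the same threshold when present. A gene enters
the scan when its Class 3 (widest) carrier count reaches 10 samples; all
three class tests are then computed, since published per-class results
include classes with fewer than 10 carriers in admitted genes. The
exome-wide significance threshold is `alpha` divided by the number of
(gene, class) tests actually computed.

## Quality control

Two tracks mirror the two analyses.

**Genotype support** (both tracks): a non-reference call is kept only if
GQ $\ge$ 30, alternate read depth $> 3$ (strict), and the site's truth
tranche sensitivity is below 99.5 (SNVs) or 99 (indels); failing calls
become missing.

**Sample QC** operates on a designated panel of high-confidence common SNVs
(default 6,100 autosomal sites): missingness and heterozygosity outliers are
flagged above mean $+ 3$ SD (population SD, single pass, candidates
included); sex is inferred from an X-chromosome inbreeding-style statistic
($F > 0.8$ male, $F < 0.2$ female, otherwise undetermined and never
excluded); duplicates are pairs with genotype concordance above 0.95 over at
least 200 mutually called panel sites (the pair member with higher
missingness is dropped); ancestry exclusions are consumed from an input list
(no PCA is performed). A sample is excluded when any flag fires, and the
report lists every reason.

**Single-variant track**: discard a variant if alignability $\ne 1$, it lies
within 10 bp of a simple repeat (inclusive; 0 means inside), the
Hardy-Weinberg exact P is below $10^{-5}$ in cases *or* in controls (tested
separately), the case/control no-call rates differ at Fisher
$P < 10^{-5}$, or the no-call rate exceeds 0.03 in either group.
Additionally, each variant's *minimum possible* P — the two-sided Fisher P
it would attain if every one of its minor alleles were in cases — is
computed, and variants that cannot reach the Bonferroni threshold implied by
their own inclusion are pruned by fixed-point iteration
($t = \alpha/|\text{retained}|$, drop $p_{\min} > t$, repeat).

**Gene-centric track**: per (sample, variant) call, heterozygotes with
unbalanced ref/alt read support ($\chi^2_1$ P below $10^{-4}$, where
$X^2 = (\mathrm{ref}-\mathrm{alt})^2/(\mathrm{ref}+\mathrm{alt})$) are set
missing; per variant, discard on alignability, repeat proximity, *combined*
cases-plus-controls HWE exact $P < 10^{-8}$, or a no-call rate of 25% or
more (inclusive) in either group.

The HWE test is the exact conditional test (probabilities of heterozygote
counts no more probable than observed, given allele counts), with a
chi-square option exposed; the exact form is the default because the
thresholds in use ($10^{-5}$, $10^{-8}$) sit deep in the tail where the
asymptotic test misbehaves at rare-variant counts.

## Single-variant scan and the inflation diagnostic

Association is tested on allele counts (two per called diploid genotype;
missing genotypes contribute nothing to the margins) with the two-sided
Fisher exact test under the probability-mass rule — the sum of
probabilities of all tables, at fixed margins, no more probable than the
observed one (with a $10^{-7}$ relative guard against floating-point ties).
This matches the default of the standard R implementation, which serves as
the independent cross-check in the test suite. Odds ratios are the
cross-product ratio on allele counts, reported as infinite when the
denominator is empty and the numerator is not.

The calibration diagnostic is a trimmed genomic inflation factor: drop the
smallest 10% of P-values (the putative signals), map the remainder to
1-df chi-square quantiles, and divide their median by the corresponding
truncated-null median — the 45th percentile of $\chi^2_1$, since the
surviving null P-values are uniform on $(0.1, 1]$ with median 0.55. This
convention is stated explicitly because "the highest 90% of P-values" does
not fix a unique normalization.

Two properties of this diagnostic matter for interpreting results on
simulated data. First, Fisher's exact test is mildly conservative, so the
null expectation of $\lambda$ on a clean cohort is slightly below 1
(around 0.92–0.95 at the default cohort shape, dominated by the common-SNV
panel; P-values of very rare variants are so discrete that a $\lambda$
computed on them alone would be meaningless, which is why the calibration
check runs the all-MAF scan). Second, a single cohort's $\lambda$ is one
sample quantile over a few thousand partly discrete P-values and has a
sampling SD near 0.05; the acceptance check therefore reports the median
over five replicate cohorts, which measures systematic mis-calibration
rather than single-draw noise.

## Power analysis

Discovery power is estimated by simulation, by default with $B = 10{,}000$
replicate draws. For a single variant of population MAF $p_0$ and
per-allele relative risk $R$, the case allele frequency follows the
rare-disease mapping

$$p_1 = \frac{R\,p_0}{1 - p_0 + R\,p_0},$$

replicate case/control allele counts are binomial, and power is the
fraction of replicates reaching the chosen $\alpha$ under the two-sided
Fisher test. The gene-level analogue replaces alleles by carriers (the
fraction of the population carrying a qualifying variant in the gene) and
evaluates each replicate with the exact mid-P burden test. The mapping is
isolated in one internal function (`rr_to_freq`) so an odds-ratio mapping
can be substituted; note that it yields $p_1 < 1$ for every finite relative
risk, so the "relative risk too large" guard can only trigger under a
substituted mapping.

At the study's scale, a variant at MAF 1% with relative risk 4.0 is
detected at the exome-wide threshold $\alpha = 2.02\times10^{-6}$ in about
80% of replicates (0.799 by exact summation over the binomial lattice;
crude normal approximations that ignore the alternative-hypothesis variance
overstate this as >0.9). At relative risk 1 the rejection rate is
indistinguishable from $\alpha$.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
consumes, not sequencing reads:

* **Cohort shape** — 513 cases / 1,569 controls by default.
* **Frequency spectrum** — 80% of gene variants with population MAF below
  1% (log-uniform on $[10^{-4}, 0.01)$), the rest uniform on
  $[0.01, 0.05]$; genotypes drawn from Hardy-Weinberg proportions
  identically for cases and controls, so every unplanted gene is null by
  construction.
* **Common-SNV panel** — 6,100 autosomal sites at MAF 0.2–0.5 for sample
  QC, plus a small X block (200 sites) in which simulated males are never
  heterozygous, enabling the sex check without full X modelling.
* **Genotype metadata** — read depth per call is negative binomial
  (mean 50, size 10); heterozygote alternate reads are binomial(depth, ½)
  except designated imbalanced calls (probability 0.1); GQ is discrete with
  3% of calls below 30. These choices exist to exercise every
  genotype-level filter, not to model a particular sequencing platform.
* **Planted signals** — `exact_counts` mode realizes a requested
  case/control carrier configuration exactly (planted calls are exempt from
  baseline missingness and given unambiguous support so they survive every
  filter — without this the planted configuration would be eroded and the
  test would measure attrition, not recovery); `relative_risk` mode draws
  carriers binomially at the mapped case frequency. At most one qualifying
  allele is planted per carrier unless weights say otherwise, matching
  designs where carrier and allele counts coincide.
* **Injected failures** — missingness outliers (10$\times$ baseline
  no-call rate), heterozygosity outliers, near-identical duplicate pairs
  (the copy carries slightly more missingness so the exclusion choice is
  determinate), reported-sex flips, Hardy-Weinberg-violating sites (all
  carriers homozygous alternate), and repeat-proximal sites. Each injection
  is logged in a truth roster and must be recovered by the corresponding QC
  operation.

What the generator deliberately omits: linkage disequilibrium and haplotype
structure, population stratification, capture-kit differences between
groups (differential missingness is exercised by injection instead), and
read-level error processes. Passing tests on synthetic cohorts therefore
demonstrate the correctness and calibration of the statistics, not
robustness to those real-data complications.

## Numerical and design notes

* Positions are 1-based VCF coordinates throughout; the variant key is
  `chrom:pos:ref:alt` and multi-allelic records must be split upstream.
* The weighted permutation DP runs in log space with a `logsumexp`
  update; the weight-1 closed form and the DP agree to $10^{-12}$.
* Burden results are ordered by per-gene minimum P with ties broken by
  gene symbol, for deterministic output.
* The null-calibration check uses one P-value per gene (the widest class):
  the three class tests of a gene share variants and are strongly
  positively dependent, so pooling them across classes cannot be uniform
  even under a perfect null.
* Monte-Carlo permutation P-values and all power estimates are
  deterministic given their seed arguments.
* Calibration and recovery checks in the test suite run at the default
  cohort shape with 500 genes (calibration), 60 genes (signal recovery),
  and micro-cohorts of at most 12 samples (enumeration oracles).

## Limitations

* The multiple-testing denominator for the exome-wide threshold is the
  number of tests actually computed, which depends on the data; a published
  denominator from a particular study is not reproducible from counts
  alone.
* The gene admission rule (Class 3 carriers $\ge$ 10) is evaluated on the
  widest class by design; a per-class rule would silently drop sparse
  Class 1/2 tests that published tables do report.
* LOH analysis is represented only by its summary statistic (a one-sided
  binomial test for preferential wild-type loss among informative pairs);
  segmentation of tumor/normal coverage is out of scope.
* Ancestry handling is consumption of an exclusion list; no PCA is run.
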