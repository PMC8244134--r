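---
title: "Validating reference genes for RT-qPCR and RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating reference genes for RT-qPCR and RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification of gene expression by RT-qPCR divides a target
gene's signal by that of one or more *reference* (housekeeping) genes,
assumed to be expressed at a constant level in every sample. When a
reference gene's expression itself depends on the experimental groups —
for example on gestational or postnatal age in developmental cohorts —
normalization silently transfers that dependence onto every target gene,
producing *systematic bias*: spurious "regulation" of targets, or true
regulation cancelled away. `refstab` implements the standard validation
toolbox used to detect this situation before it damages a study: three
published stability algorithms, consensus ranking, normalization-factor
(NF) construction and vetting, explicit intergroup bias testing, and an
RNA-seq screening procedure for discovering better reference candidates.

Cycle-threshold (ct) values are treated as the primary data. A ct value is
approximately $-\log_2$ of input template amount, so a difference of one
cycle corresponds to a two-fold expression difference. Relative quantities
use the classic $2^{-\Delta ct}$ conversion with 100% amplification
efficiency; each gene is calibrated to its most-expressed sample (minimum
ct), a convention that affects nothing downstream because every reported
statistic is calibrator-invariant (this is property-tested). An
efficiency-corrected mode ($E^{-\Delta ct}$ with per-gene $E$) exists but is
off by default: per-gene efficiencies are carried as metadata only.

## The three stability algorithms

**BestKeeper** (`bestkeeper_rank()`) is purely descriptive. Per gene it
reports the sample standard deviation of ct (cycles) and the Pearson
correlation $r$ (and $r^2$) of the gene's ct with the *BestKeeper index*,
the per-sample geometric mean of all candidate genes' ct values (the
candidate being ranked is included in its own index, matching the original
tool). A gene with SD above one cycle varies more than two-fold in starting
template and is demoted below every gene with SD $\le 1$ regardless of its
correlation; the boundary is strict (`> 1`). Within the two blocks genes
are ordered by descending $r^2$, ties broken by ascending SD, then label.

**NormFinder** (`normfinder_stability()`) is model-based. Working on the ct
scale (valid because all of its statistics are sign-symmetric, and ct is
$-\log_2$ expression up to a gene constant), it first centres each sample
across genes — removing shared loading/RNA-input effects — and then
decomposes each gene's centred values into intergroup variation $d_{ig}$
(group mean minus gene mean, summing to zero over groups) and intragroup
variance $\gamma^2_{ig}$. Because a noisy gene produces spuriously large
$d$ estimates, $d$ is shrunk toward zero by
$c_{ig} = \max\!\big(0,\, 1 - \tfrac{\gamma^2_{ig}/n_g}{\sum_g d_{ig}^2/(G-1)}\big)$
before entering the stability value
$\rho_i = \tfrac1G \sum_g \big(|c_{ig} d_{ig}| + \sqrt{\gamma^2_{ig}/n_g}\big)$,
in cycles, lower = more stable. This shrinkage has the same contract as the
original method's bias correction (suppress noise-driven intergroup
estimates) but is a documented in-package definition rather than a
reproduction of the original spreadsheet's constants; likewise $\gamma^2$
is the plain within-cell sample variance without the original's cross-gene
correction term. Rankings are validated by simulation, not by agreement
with the legacy add-in. For a single-group design $\rho_i$ reduces to
$\sqrt{\gamma^2_{i}}$. The greedy NF search (`normfinder_select_nf()`)
starts from the most stable gene and keeps adding the candidate that most
reduces the NF stability
$\rho_S = \tfrac1G\sum_g\big(|\overline{c d}_{\cdot g}| + \sqrt{\sum_{i\in S}\gamma^2_{ig}/(|S|^2 n_g)}\big)$,
stopping when no addition strictly helps — genes with opposite-signed group
biases cancel, which is exactly the mechanism worth exploiting.

**GeNorm** (`genorm_rank()`, `genorm_v()`) works on relative quantities.
The stability measure $M_j$ is the mean over partner genes $k$ of the
standard deviation across samples of $\log_2(q_j/q_k)$; perfectly
co-regulated genes have constant ratios and $M = 0$. The gene with the
highest $M$ is removed and $M$ recomputed until two genes remain; those two
cannot be ordered by a pairwise measure and share rank 1, and their
reported $M$ is taken from the last informative stage (three genes
remaining). Ties on the maximum $M$ remove the later gene in input order — a
deterministic, documented choice. The pairwise-variation analysis builds
normalization factors $NF_n$ from the $n$ most stable genes and computes
$V_{n,n+1} = \mathrm{SD}\big(\log_2(NF_n/NF_{n+1})\big)$ across the whole
sample set; the smallest $n$ with $V < 0.15$ (a configurable default, not a
hard-coded constant) is the recommended NF size, and when nothing passes
the result is flagged with the best available $n$. The SD uses the $n-1$
denominator everywhere in the package.

## Consensus, NF vetting and the co-regulation guard

`mean_rank()` aggregates the three per-algorithm rankings by arithmetic
mean rank; ties break by NormFinder's $\rho$ (the only model-based metric),
then label. `evaluate_nf_candidate()` encodes the decision rule for a
multi-gene NF: accept only if its stability value is *strictly* lower than
that of the best single gene, on the same algorithm's scale (NormFinder
$\rho$ by convention). `run_validation()` chains everything per analysis
step (a configurable subset of groups, supporting two-step designs such as
"neonatal groups only, then all groups"), applies the co-regulation guard —
if GeNorm's top pair belongs to one gene family (e.g. two ribosomal
proteins, whose shared regulation mutually deflates their $M$), the member
with the worse consensus rank is excluded and GeNorm re-run without it —
and attaches per-gene bias flags. The guard applies to GeNorm only; the
other algorithms always see the full candidate set.

## Bias assessment

`assess_bias()` reports, per candidate (or per NF), group fold changes
relative to a baseline group and an omnibus p-value for any intergroup
difference, flagging the gene "biased" when $p < \alpha$ (default 0.05, no
multiplicity correction — the flag is a descriptive screen, not a
confirmatory test). The test is a per-gene one-way fixed-effects ANOVA:
a genes-by-groups two-way layout is unsuitable for a per-gene verdict
because genes live on very different scales, so the per-gene one-way test
is the deliberate design here. It is applied to $\log_2$ expression, where
qPCR noise is closest to homoscedastic normal; fold changes are reported on
the linear scale as arithmetic group means scaled so the baseline mean
equals 1, matching the common plotting convention. Degenerate inputs are
resolved explicitly (all values equal: $p = 1$; zero residual variance with
different group means: $p = 0$). Categorical cohort characteristics use
Pearson's chi-square *without* continuity correction (`chi_square()`) — the
convention that reproduces standard clinical-table software; all-zero
categories are dropped before computing degrees of freedom. Metric
characteristics use Welch's two-tailed t-test (`welch_t_test()`), the
variance-robust default.

## RNA-seq screening

`uq_normalize()` scales each sample by the 75th percentile of its nonzero
counts (linear-interpolation quantile, R type 7), divided by the geometric
mean of all samples' upper quartiles so that the matrix keeps its overall
scale and normalization is idempotent. `screen_candidates()` filters genes
on $L = \log_2(UQ + 1)$ — the pseudocount of 1 is configurable and reported
with the result — keeping genes with (i) mean $L > 5$ (strict), (ii)
SD $< 1$ (strict), and (iii) no sample deviating from the gene's mean by 2
or more (a deviation of exactly 2 fails). Passing genes are ranked by
ascending coefficient of variation CV = SD/mean of $L$; a flag switches the
CV to the linear scale, where it is exactly invariant to global rescaling.
`intersect_screens()` implements two-dataset designs: genes passing in both
datasets are re-screened and re-ranked against the column-concatenated,
re-normalized combined matrix, with an empty intersection returned (with a
warning) rather than an error.

## Synthetic data: what it emulates and what it does not

`simulate_ct()` draws
$ct_{igj} = \mathrm{baseline}_i + \mathrm{shift}_{ig} + b_j + \varepsilon_{igj}$
with a shared per-sample loading offset $b_j \sim N(0, \sigma_b^2)$ and
gene-specific Gaussian noise. The **`"paper-like"`** preset encodes the
cohort structure this package targets: 8 whole-blood reference-gene
candidates with baselines spanning 15.6–29.6 cycles, three groups of 10
(preterm and full-term neonatal cord blood, adult peripheral blood), an
age-dependent expression increase — small heterogeneous full-term shifts
(−0.25 to +0.10 cycles) and adult shifts of −0.42 to −0.90 cycles
(1.3–1.9-fold), with RPLP0 flattest and HPRT most age-responsive — plus
per-gene noise of 0.12–0.30 cycles (largest for the least-expressed gene,
GUSB) and a 0.45-cycle loading SD. The **`"null"`** preset (8 generic
genes, no group effects, equal noise) provides the calibration baseline: on
it, no gene is truly better than any other and the intergroup ANOVA must
reject at its nominal level. `simulate_counts()` draws negative-binomial
counts with log-normal size factors and group log2-fold effects; the
**`"screen-bench"`** preset emulates a two-group cord-blood RNA-seq design
(8 vs 8) with 2000 genes of which exactly 10 are planted to pass the screen
filters with margin, 20 are strongly development-regulated high-dispersion
distractors, and the rest sit below the abundance filter. It is a stylized
benchmark: real transcriptomes have a continuum of mid-expressed,
moderately variable genes whose pass/fail status is genuinely borderline,
so exact recovery on the benchmark does not promise exact candidate counts
on real data — it verifies the filter logic, not transcriptome realism.
Generators are pure functions of (scenario, seed); tests assert statistics,
never stream internals, so reimplementations may diverge bitwise.

The simulated data also omit other features of real qPCR and RNA-seq:
plate/batch effects, efficiency differences between genes, non-Gaussian
outliers, and count overdispersion structure beyond a single NB dispersion
per gene. Passing the recovery benchmarks therefore demonstrates that the
algorithms respond correctly to the modelled effect types at realistic
magnitudes, not that any particular real cohort will behave identically.

### Design of the perturbation-recovery benchmark

The headline recovery experiment plants two perturbations into the
paper-like cohort: one gene (HPRT) shifted by +1 cycle in the full-term
group, and one gene (GUSB) with its noise SD tripled. Each algorithm is
scored on the subset of groups in which its target perturbation is the only
designed instability: NormFinder and the bias flag on all three groups, and
BestKeeper on the preterm + adult subset. The reason is instructive: on the
full dataset the two planted genes *duel* for last place in both
algorithms — a +1-cycle group shift inflates a gene's raw ct SD and lowers
its index correlation (so the shifted gene competes for BestKeeper's last
rank), while a tripled noise SD produces heavy-tailed spurious intergroup
estimates (so the noisy gene competes for NormFinder's last rank even after
shrinkage, whose tail decays only like $e^{-X/2}$ in the group-mean
chi-square). Scored jointly, the benchmark would measure the outcome of
that duel rather than each algorithm's own sensitivity; scored on the
isolating subsets, each event cleanly measures what it names. This mirrors
practice, where validation is run per group subset anyway (two-step
designs).

## Numerical choices and degenerate inputs

* ct values must be finite and in (0, 45] cycles (a 40-cycle protocol with
  headroom); violations are reported with sample and gene names.
* Technical replicates are collapsed by the arithmetic mean of ct at load
  time; collapsing is order-invariant.
* Missing ct cells are an error by default; `drop_incomplete_samples =
  TRUE` removes affected samples instead, because every algorithm needs a
  complete sample × gene block.
* A constant-ct gene makes the BestKeeper correlation undefined; the error
  names the gene so the caller can exclude it.
* GeNorm refuses fewer than 3 genes ("ranking undefined"); NormFinder
  requires every group to have at least 2 samples; NF selection requires at
  least 2 groups, and single-group validation steps skip NF selection and
  bias testing with a warning.
* All stochastic benchmarks in the tests and the acceptance script use
  moderate problem sizes — 100 random tables for oracle agreement, 100
  simulated cohorts for recovery, 1000 cohorts for ANOVA calibration,
  10^4 replicates for the Welch type-I error, 50 matrices for the screen —
  chosen so the whole suite runs in well under a minute while leaving the
  Monte-Carlo error far from every decision boundary.

## Known limitations

* NormFinder numbers are not interchangeable with the legacy Excel add-in's
  output (different shrinkage constants); rankings and decisions are the
  supported interface.
* The BestKeeper "SD" is the sample standard deviation of ct. The original
  BestKeeper publication used the mean absolute deviation; the SD-based
  definition implemented here follows the validation-study convention this
  package reproduces.
* V values are computed across the whole sample set of a step, not within
  groups.
* The screen's absolute abundance filter (mean log2 > 5) makes the passing
  set depend on sequencing depth conventions; only the CV ordering is
  scale-free. Reported candidate counts from published datasets depend on
  their exact upper-quartile and pseudocount conventions and are not
  reproduced here.
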