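# refstab

Reference-gene stability validation for RT-qPCR and RNA-seq.

Relative gene expression by RT-qPCR is normalized to *reference*
(housekeeping) genes assumed stable across all samples. When a reference
gene's expression actually depends on the experimental groups — a common
situation in developmental cohorts, where most housekeeping genes gain
expression with age — every normalized target inherits that dependence as
systematic bias. `refstab` is for researchers who need to choose and defend
their normalization strategy: it ranks candidate reference genes for
stability, builds and vets multi-gene normalization factors, quantifies
residual intergroup bias, and screens RNA-seq count matrices for better
candidates. Everything is testable end-to-end on built-in synthetic cohorts
with known ground truth.

## What it computes

For a samples × genes cycle-threshold (ct) table with a group design:

* **BestKeeper** — per-gene ct standard deviation (cycles) and correlation
  r² with the BestKeeper index (per-sample geometric mean of candidate ct
  values); genes with SD > 1 (more than two-fold template variation) are
  demoted below all SD ≤ 1 genes, the rest ranked by descending r².
* **NormFinder** — variance decomposition of per-sample-centred ct into
  intergroup variation d (shrunk toward zero when noise-driven) and
  intragroup variance γ², combined into the stability value
  ρ = meanᵍ(|d·c| + √(γ²/n_g)); greedy selection of a normalization-factor
  gene set exploiting cancellation of opposite-signed biases.
* **GeNorm** — M value (mean SD of pairwise log₂ expression ratios) with
  iterative elimination, and pairwise variation
  V(n, n+1) = SD(log₂(NFₙ/NFₙ₊₁)) to choose how many genes a normalization
  factor needs (default threshold V < 0.15).
* **Consensus and vetting** — mean-rank aggregation of the three rankings; a
  multi-gene NF is accepted only if strictly more stable than the best
  single gene; a co-regulation guard excludes one member of a same-family
  GeNorm top pair and re-runs.
* **Bias assessment** — per-gene fold changes vs a baseline group with a
  one-way ANOVA flag on log₂ expression; Pearson chi-square (no continuity
  correction) and Welch t-tests for cohort characteristics.
* **RNA-seq screening** — upper-quartile normalization, the
  mean log₂(UQ) > 5 / SD < 1 / max deviation < 2 filters, CV ranking, and
  two-dataset intersection re-analysis.

## Worked example

Simulate a realistic three-group cohort (10 preterm, 10 full-term, 10
adult samples; 8 candidate genes with an age-dependent expression increase)
and run the full two-step validation:

```r
library(refstab)

scenario <- ct_scenario_preset("paper-like")
cohort <- simulate_ct(scenario, seed = 2024)

report <- run_validation(
  cohort$ct,
  steps = list(neonates = c("preterm", "fullterm"),
               all_groups = c("preterm", "fullterm", "adult")),
  family_map = c(RPLP0 = "ribosomal", RPL13 = "ribosomal"))

print(report$all_groups)
```

```
== validation step: all_groups (groups: preterm, fullterm, adult ) ==
consensus (mean rank, most stable first):
  gene bestkeeper normfinder genorm mean_rank consensus_rank
 GAPDH          2          2      1      1.67              1
  ACTB          1          3      1      1.67              2
  PPIB          3          1      3      2.33              3
 RPL13          4          4      4      4.00              4
   B2M          5          5      5      5.00              5
 RPLP0          6          6      6      6.00              6
  HPRT          7          8      7      7.33              7
  GUSB          8          7      8      7.67              8
NF candidate PPIB/GAPDH: rho = 0.02691 vs best single PPIB rho = 0.03751 -> accept
V series: V2:3=0.054, V3:4=0.043, V4:5=0.039, V5:6=0.038, V6:7=0.037, V7:8=0.036
bias flags:
  gene fc_preterm fc_fullterm fc_adult  p_value   flag
  ACTB          1        1.46     1.78 0.006230 biased
   B2M          1        1.64     1.89 0.001813 biased
 GAPDH          1        1.52     1.65 0.024150 biased
  GUSB          1        1.46     1.42 0.041637 biased
  HPRT          1        1.24     1.92 0.000328 biased
  PPIB          1        1.48     1.65 0.014486 biased
 RPLP0          1        1.39     1.42 0.120053 stable
 RPL13          1        1.61     1.77 0.003575 biased
```

Reading the output: the three algorithms agree that GAPDH, ACTB and PPIB
are the most stable candidates; the NormFinder-selected pair PPIB/GAPDH is
*accepted* as a normalization factor because its stability value (0.027
cycles) strictly beats the best single gene (0.038); V(2:3) = 0.054 < 0.15
confirms two genes suffice. The bias table shows why validation matters:
almost every candidate — including the genes inside the chosen NF — is
significantly more expressed in adults than in preterm neonates
(fold changes 1.4–1.9), while RPLP0 is the only candidate without a
significant intergroup difference. A practitioner would report
group-dependent targets against the NF and cross-check age-sensitive
conclusions against RPLP0 alone.

Real data enter through `read_ct_table("ct.csv", "design.tsv")` (samples in
rows, genes in columns, plus a `sample_id`/`group` design file) and
`read_count_matrix("counts.tsv", "design.tsv")` for RNA-seq screening via
`uq_normalize()`, `screen_candidates()` and `intersect_screens()`.

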