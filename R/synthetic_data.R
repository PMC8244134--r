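#' Define a synthetic qPCR ct scenario
#'
#' A ct scenario fixes the generative truth for [simulate_ct()]:
#' `ct[sample j of group g, gene i] = baseline_i + shift[i, g] + b_j +
#' eps_ij`, where `b_j ~ N(0, sample_effect_sd^2)` is a loading/RNA-input
#' offset shared by all genes of a sample and `eps_ij ~ N(0, noise_sd_i^2)`
#' is gene-specific technical/biological noise (all in cycles).
#'
#' @param n_groups Number of groups.
#' @param n_per_group Samples per group (scalar or vector).
#' @param baseline Per-gene baseline ct, in cycles; must lie in [15, 30]
#'   (the observed range for common reference genes in whole blood).
#' @param shift Genes x groups matrix of group-level ct shifts (cycles);
#'   negative = higher expression in that group. Default all zero.
#' @param noise_sd Per-gene noise SD (cycles, >= 0).
#' @param sample_effect_sd SD of the shared per-sample loading offset
#'   (cycles, >= 0).
#' @param gene_names,group_names Optional labels.
#' @return A `ct_scenario` list.
#' @seealso [ct_scenario_preset()] for ready-made scenarios.
#' @export
ct_scenario <- function(n_groups, n_per_group, baseline, shift = NULL,
                        noise_sd, sample_effect_sd, gene_names = NULL,
                        group_names = NULL) {
  n_genes <- length(baseline)
  if (n_genes == 0L) stop("scenario needs >= 1 gene")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n_genes))
  if (is.null(group_names)) group_names <- paste0("g", seq_len(n_groups))
  stopifnot(length(gene_names) == n_genes, length(group_names) == n_groups)
  n_per_group <- rep_len(as.integer(n_per_group), n_groups)
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  if (any(baseline < 15 | baseline > 30)) {
    stop("baseline ct must lie in [15, 30] cycles")
  }
  noise_sd <- rep_len(noise_sd, n_genes)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (sample_effect_sd < 0) stop("sample_effect_sd must be >= 0")
  if (is.null(shift)) shift <- matrix(0, n_genes, n_groups)
  shift <- as.matrix(shift)
  stopifnot(nrow(shift) == n_genes, ncol(shift) == n_groups)
  dimnames(shift) <- list(gene_names, group_names)
  structure(list(n_groups = n_groups, n_per_group = n_per_group,
                 baseline = stats::setNames(baseline, gene_names),
                 shift = shift,
                 noise_sd = stats::setNames(noise_sd, gene_names),
                 sample_effect_sd = sample_effect_sd,
                 gene_names = gene_names, group_names = group_names),
            class = "ct_scenario")
}

#' Ready-made ct scenarios
#'
#' Two presets are shipped:
#' \describe{
#'   \item{`"null"`}{8 genes, 3 groups of 10, no group shifts, equal noise
#'     (0.5 cycles) and a 0.5-cycle loading effect. Under this scenario no
#'     gene is truly more stable than any other.}
#'   \item{`"paper-like"`}{8 whole-blood reference-gene candidates (ACTB,
#'     B2M, GAPDH, GUSB, HPRT, PPIB, RPLP0, RPL13) with baselines spanning
#'     15.6-29.6 cycles and three groups of 10 (preterm, fullterm, adult).
#'     All genes gain expression with age: small heterogeneous full-term
#'     shifts (-0.25 to +0.10 cycles) and adult shifts of -0.42 to -0.90
#'     cycles (1.3-1.9 fold), with RPLP0 the flattest and HPRT the most
#'     age-responsive. Gene-specific noise is 0.12-0.30 cycles (noisier for
#'     the low-expressed GUSB) on top of a 0.45-cycle shared loading
#'     effect.}
#' }
#'
#' @param name `"null"` or `"paper-like"`.
#' @return A [ct_scenario()].
#' @export
ct_scenario_preset <- function(name = c("null", "paper-like")) {
  name <- match.arg(name)
  if (name == "null") {
    return(ct_scenario(
      n_groups = 3, n_per_group = 10,
      baseline = seq(16, 30, by = 2),
      noise_sd = 0.5, sample_effect_sd = 0.5))
  }
  genes <- c("ACTB", "B2M", "GAPDH", "GUSB", "HPRT", "PPIB", "RPLP0", "RPL13")
  baseline <- c(15.6, 17.5, 18.4, 29.6, 26.5, 22.8, 21.2, 19.8)
  fullterm <- c(-0.10, -0.25, -0.15, -0.20, 0.10, -0.12, -0.05, -0.18)
  adult <- -c(0.69, 0.81, 0.63, 0.72, 0.90, 0.60, 0.42, 0.66)
  shift <- cbind(preterm = 0, fullterm = fullterm, adult = adult)
  ct_scenario(n_groups = 3, n_per_group = 10, baseline = baseline,
              shift = shift,
              noise_sd = c(0.12, 0.16, 0.12, 0.30, 0.14, 0.14, 0.20, 0.15),
              sample_effect_sd = 0.45,
              gene_names = genes,
              group_names = c("preterm", "fullterm", "adult"))
}

#' Modify a ct scenario's truth for benchmarking
#'
#' `scenario_shift_gene()` adds a ct shift to one gene in one group (a
#' designed-unstable gene); `scenario_scale_noise()` multiplies one gene's
#' noise SD (a designed-noisy gene).
#'
#' @param scenario A [ct_scenario()].
#' @param gene Gene label.
#' @param group Group label.
#' @param delta Cycles to add to that gene's shift in that group.
#' @return The modified scenario.
#' @export
scenario_shift_gene <- function(scenario, gene, group, delta) {
  stopifnot(inherits(scenario, "ct_scenario"),
            gene %in% scenario$gene_names, group %in% scenario$group_names)
  scenario$shift[gene, group] <- scenario$shift[gene, group] + delta
  scenario
}

#' @rdname scenario_shift_gene
#' @param factor Multiplier for that gene's noise SD.
#' @export
scenario_scale_noise <- function(scenario, gene, factor) {
  stopifnot(inherits(scenario, "ct_scenario"),
            gene %in% scenario$gene_names, factor >= 0)
  scenario$noise_sd[gene] <- scenario$noise_sd[gene] * factor
  scenario
}

#' Simulate a ct table from a scenario
#'
#' Pure function of `(scenario, seed)`: the same pair always yields an
#' identical table.
#'
#' @param scenario A [ct_scenario()].
#' @param seed Integer seed.
#' @return List with `ct` (a [ct_table()]) and `truth` (the scenario's
#'   shifts and noise, plus the drawn per-sample loading offsets).
#' @export
simulate_ct <- function(scenario, seed) {
  stopifnot(inherits(scenario, "ct_scenario"))
  set.seed(seed)
  n <- sum(scenario$n_per_group)
  grp <- rep(scenario$group_names, scenario$n_per_group)
  sample_id <- paste0("s", formatC(seq_len(n), width = nchar(n), flag = "0"))
  b <- stats::rnorm(n, 0, scenario$sample_effect_sd)
  ngenes <- length(scenario$baseline)
  eps <- matrix(stats::rnorm(n * ngenes), n, ngenes)
  eps <- sweep(eps, 2, scenario$noise_sd, "*")
  m <- matrix(rep(scenario$baseline, each = n), n, ngenes) +
    t(scenario$shift[, grp, drop = FALSE]) + b + eps
  dimnames(m) <- list(sample_id, scenario$gene_names)
  ct <- ct_table(m, group_design(sample_id, grp))
  list(ct = ct,
       truth = list(shift = scenario$shift, noise_sd = scenario$noise_sd,
                    sample_effect_sd = scenario$sample_effect_sd,
                    sample_effects = stats::setNames(b, sample_id)))
}

#' Define a synthetic RNA-seq count scenario
#'
#' Counts are drawn as
#' `count[i, j] ~ NegBin(mu = mean_i * sf_j * 2^effect[i, g(j)],
#' size = 1/dispersion_i)` with log-normal per-sample size factors
#' `sf_j` (median 1).
#'
#' @param n_per_group Samples per group (scalar or vector).
#' @param mean Per-gene expected counts (> 0).
#' @param dispersion Per-gene negative-binomial dispersion (> 0; variance
#'   `mu + dispersion * mu^2`).
#' @param effect Genes x groups matrix of group log2-fold effects (default
#'   zero).
#' @param size_factor_sd SD of log(size factor) (>= 0).
#' @param planted Indices (or labels) of genes designed to pass the
#'   reference-gene screen; their parameters must satisfy the filter margins
#'   (`log2(mean + 1) > 5`, approximate SD of log2 counts < 1, no effect).
#' @param gene_names,group_names Optional labels.
#' @return A `count_scenario` list.
#' @export
count_scenario <- function(n_per_group, mean, dispersion, effect = NULL,
                           size_factor_sd = 0, planted = integer(0),
                           gene_names = NULL, group_names = NULL) {
  n_genes <- length(mean)
  if (n_genes == 0L) stop("scenario needs >= 1 gene")
  if (any(mean <= 0)) stop("means must be > 0")
  dispersion <- rep_len(dispersion, n_genes)
  if (any(dispersion <= 0)) stop("dispersions must be > 0")
  if (size_factor_sd < 0) stop("size_factor_sd must be >= 0")
  if (is.null(gene_names)) {
    gene_names <- paste0("gene", formatC(seq_len(n_genes),
                                         width = nchar(n_genes), flag = "0"))
  }
  n_groups <- length(n_per_group)
  if (is.null(group_names)) group_names <- paste0("g", seq_len(n_groups))
  stopifnot(length(group_names) == n_groups)
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  if (is.null(effect)) effect <- matrix(0, n_genes, n_groups)
  effect <- as.matrix(effect)
  stopifnot(nrow(effect) == n_genes, ncol(effect) == n_groups)
  dimnames(effect) <- list(gene_names, group_names)
  if (is.character(planted)) planted <- match(planted, gene_names)
  planted <- as.integer(planted)
  if (length(planted) > 0L) {
    if (anyNA(planted) || any(planted < 1L | planted > n_genes)) {
      stop("invalid planted gene indices")
    }
    ## planted genes must satisfy the screen filters by construction
    approx_sd_log2 <- sqrt(log1p(dispersion[planted] + 1 / mean[planted])) /
      log(2)
    if (any(log2(mean[planted] + 1) <= 5) || any(approx_sd_log2 >= 1) ||
        any(effect[planted, ] != 0)) {
      stop("planted genes must satisfy mean_log > 5, sd_log < 1 and no group effect")
    }
  }
  structure(list(n_per_group = n_per_group, mean = stats::setNames(mean, gene_names),
                 dispersion = stats::setNames(dispersion, gene_names),
                 effect = effect, size_factor_sd = size_factor_sd,
                 planted = gene_names[planted],
                 gene_names = gene_names, group_names = group_names),
            class = "count_scenario")
}

#' Ready-made RNA-seq screening benchmark scenario
#'
#' The `"screen-bench"` preset emulates a two-group cord-blood comparison
#' (8 preterm vs 8 full-term samples) with 2000 genes: 10 planted
#' reference-gene candidates (high expression, near-Poisson dispersion, no
#' group effect — designed to pass all three screen filters with margin),
#' 20 strongly development-regulated distractors (high expression, large
#' opposite group effects and high dispersion — designed to fail the SD and
#' max-deviation filters), and 1970 low-expressed genes below the abundance
#' filter. Size factors have 0.15 log-SD.
#'
#' @param name Currently only `"screen-bench"`.
#' @return A [count_scenario()].
#' @export
count_scenario_preset <- function(name = "screen-bench") {
  name <- match.arg(name)
  n_genes <- 2000L
  n_planted <- 10L
  n_wild <- 20L
  n_low <- n_genes - n_planted - n_wild
  mean <- c(exp(seq(log(400), log(4000), length.out = n_planted)),
            exp(seq(log(300), log(2000), length.out = n_wild)),
            exp(seq(log(0.5), log(12), length.out = n_low)))
  dispersion <- c(rep(0.005, n_planted), rep(0.3, n_wild), rep(0.3, n_low))
  effect <- matrix(0, n_genes, 2)
  effect[n_planted + seq_len(n_wild), 1] <- rep(c(-2.5, 2.5),
                                                length.out = n_wild)
  effect[n_planted + seq_len(n_wild), 2] <- -effect[n_planted + seq_len(n_wild), 1]
  gene_names <- c(paste0("REFCAND", formatC(seq_len(n_planted), width = 2, flag = "0")),
                  paste0("DEVREG", formatC(seq_len(n_wild), width = 2, flag = "0")),
                  paste0("LOWEXP", formatC(seq_len(n_low), width = 4, flag = "0")))
  count_scenario(n_per_group = c(8L, 8L), mean = mean,
                 dispersion = dispersion, effect = effect,
                 size_factor_sd = 0.15, planted = seq_len(n_planted),
                 gene_names = gene_names,
                 group_names = c("preterm", "fullterm"))
}

#' Simulate an RNA-seq count matrix from a scenario
#'
#' Pure function of `(scenario, seed)`.
#'
#' @param scenario A [count_scenario()].
#' @param seed Integer seed.
#' @return List with `counts` (a [count_matrix()]) and `truth` (planted
#'   reference genes, effects, size factors).
#' @export
simulate_counts <- function(scenario, seed) {
  stopifnot(inherits(scenario, "count_scenario"))
  set.seed(seed)
  n <- sum(scenario$n_per_group)
  grp <- rep(scenario$group_names, scenario$n_per_group)
  sample_id <- paste0("s", formatC(seq_len(n), width = nchar(n), flag = "0"))
  sf <- stats::rlnorm(n, 0, scenario$size_factor_sd)
  ngenes <- length(scenario$mean)
  mu <- outer(scenario$mean, sf) * 2^scenario$effect[, grp, drop = FALSE]
  m <- matrix(stats::rnbinom(ngenes * n, mu = mu,
                             size = rep(1 / scenario$dispersion, n)),
              ngenes, n, dimnames = list(scenario$gene_names, sample_id))
  cm <- count_matrix(m, group_design(sample_id, grp))
  list(counts = cm,
       truth = list(planted = scenario$planted, effect = scenario$effect,
                    size_factors = stats::setNames(sf, sample_id)))
}
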