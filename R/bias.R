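#' One-way intergroup ANOVA on per-sample expression values
#'
#' Fixed-effects one-way ANOVA F-test for any expression difference between
#' groups. Used to flag candidate reference genes whose expression depends
#' on group membership (systematic bias); expression values are usually
#' supplied on the log2 scale, where qPCR noise is closest to homoscedastic
#' normal.
#'
#' @param values Numeric vector of per-sample expression values.
#' @param groups Group label per value (character/factor), or a
#'   [group_design()] whose `sample_id` matches `names(values)`.
#' @return The omnibus p-value. Degenerate inputs are handled explicitly:
#'   all values identical gives p = 1; zero within-group variance with
#'   differing group means gives p = 0.
#' @export
intergroup_test <- function(values, groups) {
  if (inherits(groups, "group_design") || is.data.frame(groups)) {
    if (is.null(names(values))) {
      stop("values must be named when groups is a design")
    }
    groups <- design_group_of(groups, names(values))
  }
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (anyNA(values) || anyNA(groups)) stop("values/groups may not contain NA")
  n_g <- table(groups)
  if (length(n_g) < 2L) stop("intergroup test requires >= 2 groups")
  if (any(n_g < 2L)) stop("every group needs >= 2 samples")
  gm <- tapply(values, groups, mean)
  ssb <- sum(n_g * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0) return(if (ssb == 0) 1 else 0)   # degenerate: F undefined
  stats::oneway.test(values ~ factor(groups), var.equal = TRUE)$p.value
}

#' Pearson chi-square test on a group x category contingency table
#'
#' Pearson chi-square without continuity correction (matching the convention
#' of standard clinical-table software); all-zero categories are dropped
#' before testing, and degrees of freedom are computed on the reduced table.
#'
#' @param table A [contingency_table()] or plain non-negative integer matrix
#'   (groups x categories).
#' @return List with `statistic`, `df` and `p_value`.
#' @examples
#' chi_square(rbind(c(4, 6), c(10, 0)))  # p ~ 0.003
#' @export
chi_square <- function(table) {
  m <- unclass(as.matrix(table))
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    stop("contingency counts must be non-negative integers")
  }
  if (nrow(m) < 2L) stop("chi-square requires >= 2 groups (rows)")
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2L) stop("chi-square requires >= 2 non-zero categories")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Welch two-sample t-test p-value
#'
#' Two-tailed Welch t-test (unequal variances); used for metric group
#' characteristics. Degenerate inputs with zero variance in both samples are
#' resolved by comparing means directly.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @return Two-tailed p-value.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need >= 2 values")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Flag candidate reference genes for systematic intergroup bias
#'
#' For each gene (optionally after normalization by an
#' [normalization_factor()]), computes per-group fold changes versus the
#' baseline group and a one-way intergroup ANOVA on log2 expression; a gene
#' is flagged `"biased"` when the omnibus p-value falls below `alpha`,
#' `"stable"` otherwise.
#'
#' @param expr An `expression_table`.
#' @param baseline_group Group used as fold-change baseline (default: first
#'   group in the design).
#' @param alpha Significance level (default 0.05; no multiplicity
#'   correction, matching common practice for this descriptive check).
#' @param genes Optional subset of genes to assess.
#' @param normalizer `"none"` (assess non-normalized relative expression) or
#'   an `nf_vector`.
#' @return data.frame with one row per gene: fold-change columns
#'   `fc_<group>` (baseline = 1), `p_value` and `flag`.
#' @export
assess_bias <- function(expr, baseline_group = NULL, alpha = 0.05,
                        genes = NULL, normalizer = "none") {
  stopifnot(inherits(expr, "expression_table"))
  if (is.null(genes)) genes <- colnames(expr$q)
  grp_levels <- unique(expr$design$group)
  if (is.null(baseline_group)) baseline_group <- grp_levels[1]
  grp <- expr$design$group[match(rownames(expr$q), expr$design$sample_id)]
  rows <- lapply(genes, function(g) {
    fc <- normalize_and_compare(expr, g, normalizer = normalizer,
                                baseline_group = baseline_group)
    p <- intergroup_test(log2(fc$samples$value), fc$samples$group)
    fcs <- stats::setNames(fc$groups$fold_change,
                           paste0("fc_", fc$groups$group))
    c(list(gene = g), as.list(fcs[paste0("fc_", grp_levels)]),
      list(p_value = p, flag = if (p < alpha) "biased" else "stable"))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
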