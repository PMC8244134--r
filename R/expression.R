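#' Convert ct values to linear relative quantities (2^-dct)
#'
#' Each gene is calibrated to its own most-expressed sample (minimum ct), so
#' relative quantities lie in (0, 1] with the calibrator at 1:
#' `q = E^(ct_min - ct)`, with amplification efficiency `E = 2` (100%) by
#' default. Downstream stability metrics and fold changes are invariant to
#' the choice of calibrator.
#'
#' @param ct A [ct_table()].
#' @param efficiency Amplification base; 2 corresponds to the classic
#'   2^-dct convention. Per-gene efficiencies (e.g. from standard curves) can
#'   be supplied as a named vector for an efficiency-corrected conversion.
#' @return An `expression_table` (list with `q`: samples x genes matrix of
#'   relative quantities, and `design`).
#' @examples
#' ctm <- matrix(c(20, 21, 23, 18, 18, 18), nrow = 3,
#'               dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
#' d <- group_design(rownames(ctm), c("g1", "g1", "g2"))
#' relative_quantities(ct_table(ctm, d))$q
#' @export
relative_quantities <- function(ct, efficiency = 2) {
  stopifnot(inherits(ct, "ct_table"))
  m <- ct$ct
  if (is.null(names(efficiency))) {
    eff <- rep_len(as.numeric(efficiency), ncol(m))
  } else {
    if (!all(colnames(m) %in% names(efficiency))) {
      stop("efficiency vector must name every gene")
    }
    eff <- as.numeric(efficiency[colnames(m)])
  }
  if (any(!is.finite(eff) | eff <= 1)) stop("efficiency must be > 1")
  cal <- apply(m, 2, min)                      # per-gene calibrator ct
  q <- vapply(seq_len(ncol(m)),
              function(j) eff[j]^(cal[j] - m[, j]),
              numeric(nrow(m)))
  dimnames(q) <- dimnames(m)
  structure(list(q = q, design = ct$design), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression table:", nrow(x$q), "samples x", ncol(x$q),
      "genes (relative quantities)\n")
  invisible(x)
}

geometric_mean_rows <- function(m) exp(rowMeans(log(m)))

#' Geometric-mean normalization factor over a reference-gene set
#'
#' The normalization factor (NF) for a sample is the geometric mean of the
#' relative quantities of the chosen reference genes in that sample.
#'
#' @param expr An [relative_quantities()] result.
#' @param gene_set Non-empty character vector of gene labels in `expr`.
#' @return An `nf_vector` (list with `gene_set` and `nf`, a named per-sample
#'   vector, all > 0).
#' @export
normalization_factor <- function(expr, gene_set) {
  stopifnot(inherits(expr, "expression_table"))
  gene_set <- as.character(gene_set)
  if (length(gene_set) == 0L) stop("gene_set must be non-empty")
  unknown <- setdiff(gene_set, colnames(expr$q))
  if (length(unknown) > 0L) {
    stop("unknown gene(s) in gene_set: ", paste(unknown, collapse = ", "))
  }
  nf <- geometric_mean_rows(expr$q[, gene_set, drop = FALSE])
  structure(list(gene_set = gene_set, nf = nf), class = "nf_vector")
}

#' @export
print.nf_vector <- function(x, ...) {
  cat("normalization factor over {", paste(x$gene_set, collapse = ", "),
      "} for", length(x$nf), "samples\n")
  invisible(x)
}

#' Normalize a target gene and compare expression between groups
#'
#' Divides the target gene's relative quantities by a normalization factor
#' (or leaves them non-normalized), rescales so that the baseline group's
#' mean is 1, and reports per-group arithmetic means and fold changes versus
#' the baseline. Calling this once per candidate normalizer exposes
#' normalization-induced bias: a normalizer sharing the target's group effect
#' abolishes the true fold change.
#'
#' @param expr An `expression_table`.
#' @param target Gene label to normalize.
#' @param normalizer An [normalization_factor()] result, or `"none"` for
#'   non-normalized relative expression.
#' @param baseline_group Group whose mean is scaled to 1.
#' @return A `fold_change_table`: list with `target`, `baseline_group`,
#'   `samples` (per-sample normalized values, baseline mean = 1) and `groups`
#'   (per-group mean expression and fold change vs baseline).
#' @export
normalize_and_compare <- function(expr, target, normalizer = "none",
                                  baseline_group) {
  stopifnot(inherits(expr, "expression_table"))
  if (!target %in% colnames(expr$q)) stop("unknown target gene: ", target)
  if (!baseline_group %in% expr$design$group) {
    stop("unknown baseline group: ", baseline_group)
  }
  v <- expr$q[, target]
  if (!identical(normalizer, "none")) {
    if (!inherits(normalizer, "nf_vector")) {
      stop("normalizer must be an nf_vector or \"none\"")
    }
    if (!setequal(names(normalizer$nf), rownames(expr$q))) {
      stop("normalizer samples do not match expression samples")
    }
    v <- v / normalizer$nf[rownames(expr$q)]
  }
  grp <- expr$design$group[match(rownames(expr$q), expr$design$sample_id)]
  base_mean <- mean(v[grp == baseline_group])
  v <- v / base_mean
  gm <- tapply(v, grp, mean)
  groups <- data.frame(group = names(gm),
                       mean_expression = as.numeric(gm),
                       fold_change = as.numeric(gm),  # baseline mean is 1
                       stringsAsFactors = FALSE, row.names = NULL)
  samples <- data.frame(sample_id = rownames(expr$q), group = grp,
                        value = as.numeric(v),
                        stringsAsFactors = FALSE)
  structure(list(target = target, baseline_group = baseline_group,
                 normalizer = if (identical(normalizer, "none")) "none"
                              else normalizer$gene_set,
                 samples = samples, groups = groups),
            class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat("fold changes for", x$target, "vs baseline", x$baseline_group,
      "(normalizer:",
      if (identical(x$normalizer, "none")) "none"
      else paste(x$normalizer, collapse = "/"), ")\n")
  print(x$groups, row.names = FALSE)
  invisible(x)
}
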