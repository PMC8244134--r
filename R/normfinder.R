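#' NormFinder-style model-based stability analysis
#'
#' Decomposes candidate-gene variation into intergroup bias and intragroup
#' noise on the ct scale (ct is proportional to -log2 expression; all
#' statistics used are sign-symmetric, so operating on ct directly is
#' equivalent).
#'
#' Writing `y` for ct, the model-based decomposition is:
#' \enumerate{
#'   \item per-sample centering: `z = y - (cross-gene mean of the sample)`,
#'     which removes shared loading/RNA-input effects;
#'   \item intergroup variation `d[i, g]` = group mean of `z` minus the
#'     gene's unweighted mean over groups (so `d` sums to zero per gene);
#'   \item intragroup variance `gamma2[i, g]` = sample variance of `z`
#'     within gene and group;
#'   \item shrinkage of noisy intergroup estimates toward zero:
#'     `d_shrunk = d * c` with
#'     `c = max(0, 1 - (gamma2/n_g) / (sum_g d^2 / (G - 1)))`
#'     (and `c = 0` when all `d` vanish);
#'   \item stability value
#'     `rho_i = mean_g( |d_shrunk[i, g]| + sqrt(gamma2[i, g] / n_g) )`,
#'     in cycles; lower is more stable.
#' }
#' For a single-group design `rho_i = sqrt(gamma2_i)` (pure intragroup
#' noise).
#'
#' @param ct A [ct_table()]; every group must contain >= 2 samples and >= 2
#'   genes are required (>= 3 recommended).
#' @param genes Optional candidate subset.
#' @param max_nf_genes Cap on the greedy normalization-factor search (see
#'   [normfinder_select_nf()]); `Inf` means unrestricted.
#' @return A list with components `decomposition` (a
#'   `normfinder_decomposition`: matrices `d`, `d_shrunk`, `gamma2` of size
#'   genes x groups, and `n_g`) and `result` (a `normfinder_result`:
#'   data.frame of gene, rho, rank, plus `nf_genes`/`nf_rho` when >= 2
#'   groups are present).
#' @examples
#' sc <- ct_scenario_preset("paper-like")
#' nf <- normfinder_stability(simulate_ct(sc, seed = 1)$ct)
#' nf$result$summary
#' @export
normfinder_stability <- function(ct, genes = NULL, max_nf_genes = Inf) {
  stopifnot(inherits(ct, "ct_table"))
  if (!is.null(genes)) ct <- ct_subset(ct, genes = genes)
  m <- ct$ct
  if (ncol(m) < 2L) stop("NormFinder requires >= 2 genes")
  grp <- design_group_of(ct$design, rownames(m))
  groups <- unique(grp)
  n_g <- vapply(groups, function(g) sum(grp == g), integer(1))
  if (any(n_g < 2L)) {
    stop("every group needs >= 2 samples (offending: ",
         paste(groups[n_g < 2L], collapse = ", "), ")")
  }
  G <- length(groups)
  z <- m - rowMeans(m)                        # per-sample centering
  ngenes <- ncol(m)
  a <- matrix(NA_real_, ngenes, G, dimnames = list(colnames(m), groups))
  gamma2 <- a
  for (g in seq_len(G)) {
    zg <- z[grp == groups[g], , drop = FALSE]
    a[, g] <- colMeans(zg)
    gamma2[, g] <- apply(zg, 2, stats::var)
  }
  d <- a - rowMeans(a)
  if (G > 1L) {
    ssd <- rowSums(d^2) / (G - 1)
    cc <- 1 - sweep(gamma2, 2, n_g, "/") / ssd
    cc[!is.finite(cc) | ssd == 0] <- 0
    cc <- pmax(cc, 0)
    d_shrunk <- d * cc
    rho <- rowMeans(abs(d_shrunk) + sqrt(sweep(gamma2, 2, n_g, "/")))
  } else {
    d_shrunk <- d                             # all zero
    rho <- sqrt(gamma2[, 1])
  }
  decomp <- structure(list(d = d, d_shrunk = d_shrunk, gamma2 = gamma2,
                           n_g = stats::setNames(n_g, groups)),
                      class = "normfinder_decomposition")
  summary <- data.frame(gene = colnames(m), rho = as.numeric(rho),
                        stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(summary$rho, summary$gene)
  summary$rank <- NA_integer_
  summary$rank[ord] <- seq_len(nrow(summary))
  result <- structure(list(summary = summary, nf_genes = NULL, nf_rho = NULL),
                      class = "normfinder_result")
  if (G > 1L) {
    sel <- normfinder_select_nf(decomp, max_genes = max_nf_genes)
    result$nf_genes <- sel$nf_genes
    result$nf_rho <- sel$nf_rho
  }
  list(decomposition = decomp, result = result)
}

nf_set_rho <- function(decomp, set) {
  G <- ncol(decomp$d)
  dbar <- colMeans(decomp$d_shrunk[set, , drop = FALSE])
  noise <- sqrt(colSums(decomp$gamma2[set, , drop = FALSE]) /
                  (length(set)^2 * decomp$n_g))
  mean(abs(dbar) + noise)
}

#' Greedy NormFinder gene-set selection for a normalization factor
#'
#' Starting from the most stable single gene, repeatedly adds the candidate
#' that most reduces the stability of the combined normalization factor,
#' `rho_S = mean_g( |mean_{i in S} d_shrunk[i, g]| +
#' sqrt(sum_{i in S} gamma2[i, g] / (|S|^2 n_g)) )`, and stops as soon as no
#' addition strictly reduces it. Genes with opposite-signed intergroup biases
#' can cancel, which is the mechanism this search exploits.
#'
#' @param decomp A `normfinder_decomposition` from [normfinder_stability()];
#'   needs >= 2 groups.
#' @param max_genes Cap on the selected set size.
#' @return List with `nf_genes` (character) and `nf_rho` (numeric).
#' @export
normfinder_select_nf <- function(decomp, max_genes = Inf) {
  stopifnot(inherits(decomp, "normfinder_decomposition"))
  if (ncol(decomp$d) < 2L) stop("NF selection requires >= 2 groups")
  genes <- rownames(decomp$d)
  singles <- vapply(genes, function(g) nf_set_rho(decomp, g), numeric(1))
  set <- genes[which.min(singles)]
  best <- min(singles)
  repeat {
    rest <- setdiff(genes, set)
    if (length(rest) == 0L || length(set) >= max_genes) break
    cand <- vapply(rest, function(g) nf_set_rho(decomp, c(set, g)), numeric(1))
    if (min(cand) < best) {
      best <- min(cand)
      set <- c(set, rest[which.min(cand)])
    } else break
  }
  list(nf_genes = set, nf_rho = best)
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability (rho, cycles; rank 1 = most stable):\n")
  print(x$summary[order(x$summary$rank), ], row.names = FALSE, digits = 4)
  if (!is.null(x$nf_genes)) {
    cat("NF gene set:", paste(x$nf_genes, collapse = "/"),
        sprintf("(rho = %.4g)\n", x$nf_rho))
  }
  invisible(x)
}

#' @export
stability_ranks.normfinder_result <- function(x) {
  stats::setNames(x$summary$rank, x$summary$gene)
}
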