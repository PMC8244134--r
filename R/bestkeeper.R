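#' BestKeeper-style descriptive stability ranking
#'
#' Computes, per candidate gene, the sample standard deviation of its ct
#' values (cycles), the coefficient of variation of ct, and the Pearson
#' correlation of its ct values with the BestKeeper index — the per-sample
#' geometric mean of all candidate genes' ct values. A ct standard deviation
#' above 1 cycle indicates more than two-fold variation of starting template,
#' so such genes are demoted below every gene with SD <= 1 regardless of
#' their correlation; within each of the two blocks genes are ordered by
#' descending coefficient of determination (r^2), with ties broken by
#' ascending SD and then label.
#'
#' @param ct A [ct_table()].
#' @param genes Optional subset of candidate genes (default: all).
#' @return A `bestkeeper_result`: list with `summary` (data.frame: gene,
#'   sd_ct, cv_ct, r, r2, rank) and `index` (per-sample BestKeeper index,
#'   cycles).
#' @examples
#' sc <- ct_scenario_preset("null")
#' bk <- bestkeeper_rank(simulate_ct(sc, seed = 1)$ct)
#' bk$summary
#' @export
bestkeeper_rank <- function(ct, genes = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  if (!is.null(genes)) ct <- ct_subset(ct, genes = genes)
  m <- ct$ct
  if (nrow(m) < 2L) stop("BestKeeper requires >= 2 samples")
  if (ncol(m) < 2L) stop("BestKeeper requires >= 2 genes")
  sds <- apply(m, 2, stats::sd)
  const <- names(sds)[sds == 0]
  if (length(const) > 0L) {
    stop("undefined correlation: gene(s) with constant ct: ",
         paste(const, collapse = ", "))
  }
  index <- geometric_mean_rows(m)            # self-inclusive candidate set
  r <- apply(m, 2, stats::cor, y = index)
  res <- data.frame(gene = colnames(m),
                    sd_ct = sds,
                    cv_ct = 100 * sds / colMeans(m),
                    r = r,
                    r2 = r^2,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(res$sd_ct > 1, -res$r2, res$sd_ct, res$gene)
  res$rank <- NA_integer_
  res$rank[ord] <- seq_len(nrow(res))
  structure(list(summary = res, index = index), class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper stability (rank 1 = most stable):\n")
  s <- x$summary[order(x$summary$rank), ]
  print(s, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Extract a named rank vector from a stability result
#'
#' @param x A `bestkeeper_result`, `normfinder_result` or `genorm_result`.
#' @return Named integer vector of ranks (1 = most stable).
#' @export
stability_ranks <- function(x) UseMethod("stability_ranks")

#' @export
stability_ranks.bestkeeper_result <- function(x) {
  stats::setNames(x$summary$rank, x$summary$gene)
}
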