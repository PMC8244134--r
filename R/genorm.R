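#' GeNorm-style stability ranking by pairwise variation
#'
#' For each pair of genes (j, k), the log2 expression ratio
#' `A_jk = log2(q_j / q_k)` is computed per sample; the gene-stability
#' measure `M_j` is the mean, over all other genes k, of the standard
#' deviation of `A_jk` across samples. Perfectly co-regulated genes have a
#' constant ratio and hence contribute 0. The gene with the highest M is
#' removed, M is recomputed on the remaining set, and so on until two genes
#' remain; those two share rank 1 (a single pair cannot be ordered by a
#' pairwise measure).
#'
#' @param expr An `expression_table` from [relative_quantities()] (all
#'   quantities must be > 0); >= 3 genes and >= 2 samples required.
#' @param genes Optional candidate subset (supports re-running after
#'   excluding, say, one member of a co-regulated gene family).
#' @return A `genorm_result`: list with `summary` (data.frame: gene, M at
#'   elimination, elimination_step — step 1 is the first gene removed, NA for
#'   the final pair — and rank), `stability_order` (most to least stable;
#'   final pair first, in input order), and empty `v_series`/`recommended_n`
#'   slots filled by [genorm_v()].
#' @examples
#' q <- cbind(G1 = c(1, 2, 4, 8), G2 = 2 * c(1, 2, 4, 8), G3 = rep(1, 4))
#' rownames(q) <- paste0("s", 1:4)
#' expr <- structure(list(q = q,
#'                        design = group_design(rownames(q), rep("a", 4))),
#'                   class = "expression_table")
#' genorm_rank(expr)$summary
#' @export
genorm_rank <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  q <- expr$q
  if (!is.null(genes)) {
    unknown <- setdiff(genes, colnames(q))
    if (length(unknown) > 0L) {
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    q <- q[, genes, drop = FALSE]
  }
  if (any(q <= 0)) stop("all relative quantities must be > 0")
  if (ncol(q) < 3L) stop("ranking undefined: GeNorm requires >= 3 genes")
  if (nrow(q) < 2L) stop("GeNorm requires >= 2 samples")
  lq <- log2(q)
  input_order <- colnames(q)
  active <- input_order
  n <- length(active)
  M_at_removal <- stats::setNames(rep(NA_real_, n), input_order)
  step_at_removal <- stats::setNames(rep(NA_integer_, n), input_order)
  rank <- stats::setNames(rep(NA_integer_, n), input_order)
  step <- 0L
  last_informative_M <- NULL           # M at the 3-gene stage
  while (length(active) > 2L) {
    M <- genorm_m(lq[, active, drop = FALSE])
    if (length(active) == 3L) last_informative_M <- M
    worst <- max(M)
    ## tie on max M: remove the later gene in input order
    drop_gene <- active[max(which(M == worst))]
    step <- step + 1L
    M_at_removal[drop_gene] <- worst
    step_at_removal[drop_gene] <- step
    rank[drop_gene] <- length(active)
    active <- setdiff(active, drop_gene)
  }
  ## the final pair is never eliminated; report its M from the last stage at
  ## which M is informative (with only two genes every pairwise SD is shared)
  M_at_removal[active] <- last_informative_M[active]
  rank[active] <- 1L
  summary <- data.frame(gene = input_order,
                        M = as.numeric(M_at_removal),
                        elimination_step = as.integer(step_at_removal),
                        rank = as.integer(rank),
                        stringsAsFactors = FALSE, row.names = NULL)
  eliminated <- input_order[order(step_at_removal[input_order],
                                  decreasing = TRUE, na.last = FALSE)]
  stability_order <- c(active, setdiff(eliminated, active))
  stability_order <- stability_order[!duplicated(stability_order)]
  structure(list(summary = summary, stability_order = stability_order,
                 v_series = NULL, recommended_n = NULL, threshold = NULL),
            class = "genorm_result")
}

## mean over partner genes of SD(log2 ratio), per gene, on a log2 matrix
genorm_m <- function(lq) {
  n <- ncol(lq)
  vapply(seq_len(n), function(j) {
    sds <- vapply(setdiff(seq_len(n), j),
                  function(k) stats::sd(lq[, j] - lq[, k]), numeric(1))
    mean(sds)
  }, numeric(1)) |> stats::setNames(colnames(lq))
}

#' GeNorm pairwise-variation (V) analysis for normalization-factor size
#'
#' Builds normalization factors `NF_n` from the n most stable genes (GeNorm
#' order) for n = 2, ..., n_genes and computes
#' `V_{n,n+1} = SD_samples(log2(NF_n / NF_{n+1}))`. A small V means adding
#' the (n+1)-th gene hardly changes the normalization factor, so n genes
#' suffice; conventionally V < 0.15 is taken as sufficient stability.
#'
#' @inheritParams genorm_rank
#' @param ranking Optional `genorm_result` from [genorm_rank()] (computed if
#'   omitted).
#' @param threshold V threshold below which adding a gene is deemed
#'   unnecessary (default 0.15).
#' @return The `genorm_result` with `v_series` (named `V2:3`, `V3:4`, ...)
#'   and `recommended_n` filled; `recommended_n` is `NA` with attribute
#'   `flag = "none below threshold"` when no V passes.
#' @export
genorm_v <- function(expr, ranking = NULL, threshold = 0.15, genes = NULL) {
  stopifnot(inherits(expr, "expression_table"))
  if (is.null(ranking)) ranking <- genorm_rank(expr, genes = genes)
  ord <- ranking$stability_order
  q <- expr$q[, ord, drop = FALSE]
  n <- length(ord)
  if (n < 3L) stop("V analysis requires >= 3 genes")
  v <- numeric(n - 2L)
  names(v) <- paste0("V", 2:(n - 1), ":", 3:n)
  for (k in 2:(n - 1)) {
    nf_k <- geometric_mean_rows(q[, 1:k, drop = FALSE])
    nf_k1 <- geometric_mean_rows(q[, 1:(k + 1), drop = FALSE])
    v[k - 1L] <- stats::sd(log2(nf_k / nf_k1))
  }
  ranking$v_series <- v
  ranking$threshold <- threshold
  ranking$recommended_n <- recommended_nf_size(v, threshold)
  ranking
}

#' Smallest normalization-factor size with pairwise variation below threshold
#'
#' @param v_series Numeric vector of V values for n = 2, 3, ... (the first
#'   element compares the 2-gene with the 3-gene normalization factor).
#' @param threshold Acceptance threshold (default 0.15).
#' @return Integer n, or `NA` with attribute `flag = "none below threshold"`
#'   (callers should then report the n with the smallest V as best
#'   available).
#' @export
recommended_nf_size <- function(v_series, threshold = 0.15) {
  stopifnot(is.numeric(v_series), length(v_series) >= 1L, all(v_series >= 0))
  hit <- which(v_series < threshold)
  if (length(hit) == 0L) {
    return(structure(NA_integer_, flag = "none below threshold",
                     best_available_n = as.integer(which.min(v_series) + 1L)))
  }
  as.integer(hit[1] + 1L)
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("GeNorm stability (M at elimination; final pair shares rank 1):\n")
  print(x$summary[order(x$summary$rank, x$summary$gene), ],
        row.names = FALSE, digits = 4)
  if (!is.null(x$v_series)) {
    cat("pairwise variation:\n")
    print(round(x$v_series, 4))
    if (is.na(x$recommended_n)) {
      cat("no NF size below threshold", x$threshold, "- best available n =",
          attr(x$recommended_n, "best_available_n"), "\n")
    } else {
      cat("recommended NF size:", x$recommended_n,
          "(threshold", paste0(x$threshold, ")"), "\n")
    }
  }
  invisible(x)
}

#' @export
stability_ranks.genorm_result <- function(x) {
  stats::setNames(x$summary$rank, x$summary$gene)
}
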