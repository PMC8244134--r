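#' Upper-quartile normalization of an RNA-seq count matrix
#'
#' Each sample is scaled by its upper quartile — the 75th percentile (linear
#' interpolation, R quantile type 7) of its nonzero counts — divided by the
#' geometric mean of all samples' upper quartiles, so the overall scale of
#' the matrix is preserved and normalizing twice is a no-op.
#'
#' @param counts A [count_matrix()] or plain genes x samples numeric matrix;
#'   every sample must have at least one nonzero count.
#' @return Numeric matrix of UQ-normalized values (same dimnames), with the
#'   per-sample scale factors in attribute `"scale_factors"`.
#' @export
uq_normalize <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative")
  uq <- apply(m, 2, function(x) {
    x <- x[x > 0]
    if (length(x) == 0L) return(NA_real_)
    stats::quantile(x, 0.75, names = FALSE, type = 7)
  })
  if (anyNA(uq)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[is.na(uq)], collapse = ", "))
  }
  scale <- uq / exp(mean(log(uq)))
  out <- sweep(m, 2, scale, "/")
  attr(out, "scale_factors") <- stats::setNames(scale, colnames(m))
  out
}

#' Screen UQ-normalized RNA-seq data for reference-gene candidates
#'
#' Applies three filters on `L = log2(UQ + pseudocount)` per gene:
#' (i) mean(L) strictly greater than `mean_log_min`;
#' (ii) SD(L) strictly less than `sd_log_max`;
#' (iii) no single sample deviating from the gene's mean by
#' `max_dev_limit` or more (a deviation equal to the limit fails).
#' Passing genes are ranked by ascending coefficient of variation
#' CV = SD(L)/mean(L) (a config flag switches the CV to the linear UQ
#' scale).
#'
#' @param uq Matrix of UQ-normalized values from [uq_normalize()] (genes x
#'   samples).
#' @param mean_log_min,sd_log_max,max_dev_limit Filter thresholds; defaults
#'   5, 1 and 2 log2 units.
#' @param pseudocount Added before the log2 transform (default 1).
#' @param cv_scale `"log"` (default; the filters are defined on that scale)
#'   or `"linear"`.
#' @return A `screen_result`: data.frame with per-gene `mean_log`, `sd_log`,
#'   `max_dev`, `cv`, `pass` and `rank` (among passing genes; NA otherwise),
#'   with attributes `n_pass` and `thresholds`.
#' @export
screen_candidates <- function(uq, mean_log_min = 5, sd_log_max = 1,
                              max_dev_limit = 2, pseudocount = 1,
                              cv_scale = c("log", "linear")) {
  cv_scale <- match.arg(cv_scale)
  m <- if (inherits(uq, "count_matrix")) uq$counts else as.matrix(uq)
  if (any(m < 0) || anyNA(m)) stop("UQ values must be non-negative")
  L <- log2(m + pseudocount)
  mean_log <- rowMeans(L)
  sd_log <- apply(L, 1, stats::sd)
  max_dev <- apply(abs(L - mean_log), 1, max)
  cv <- if (cv_scale == "log") {
    ifelse(mean_log > 0, sd_log / mean_log, NA_real_)
  } else {
    apply(m, 1, stats::sd) / rowMeans(m)
  }
  pass <- mean_log > mean_log_min & sd_log < sd_log_max &
    max_dev < max_dev_limit
  res <- data.frame(gene = rownames(m), mean_log = mean_log,
                    sd_log = sd_log, max_dev = max_dev, cv = cv,
                    pass = pass, stringsAsFactors = FALSE, row.names = NULL)
  res$rank <- rep(NA_integer_, nrow(res))
  if (any(pass)) {
    ord <- order(res$cv[pass], res$gene[pass])
    res$rank[which(pass)[ord]] <- seq_len(sum(pass))
  }
  structure(res, class = c("screen_result", "data.frame"),
            n_pass = sum(pass),
            thresholds = list(mean_log_min = mean_log_min,
                              sd_log_max = sd_log_max,
                              max_dev_limit = max_dev_limit,
                              pseudocount = pseudocount,
                              cv_scale = cv_scale))
}

#' @export
print.screen_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "RNA-seq reference-gene screen: %d/%d genes pass (mean log2 > %g, SD < %g, max dev < %g, pseudocount %g)\n",
    attr(x, "n_pass"), nrow(x), th$mean_log_min, th$sd_log_max,
    th$max_dev_limit, th$pseudocount))
  top <- x[!is.na(x$rank) & x$rank <= 10, ]
  if (nrow(top) > 0L) {
    cat("top candidates by CV:\n")
    print(as.data.frame(top[order(top$rank), ]), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Genes passing a screen
#' @param x A `screen_result`.
#' @return Character vector of passing gene labels.
#' @export
passing_genes <- function(x) {
  stopifnot(inherits(x, "screen_result"))
  x$gene[x$pass]
}

#' Column-bind two count matrices on their shared gene set
#'
#' @param a,b [count_matrix()] objects with overlapping genes and disjoint
#'   sample labels.
#' @return A combined [count_matrix()].
#' @export
combine_counts <- function(a, b) {
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  shared <- intersect(rownames(a$counts), rownames(b$counts))
  if (length(shared) == 0L) stop("no shared genes between datasets")
  m <- cbind(a$counts[shared, , drop = FALSE], b$counts[shared, , drop = FALSE])
  count_matrix(m, group_design(c(a$design$sample_id, b$design$sample_id),
                               c(a$design$group, b$design$group)))
}

#' Intersect two screens and re-rank on a combined dataset
#'
#' Takes the genes that pass the screen in both dataset A and dataset B,
#' UQ-normalizes the combined count matrix, and re-screens/re-ranks that
#' intersection against it.
#'
#' @param result_a,result_b `screen_result` objects from two independent
#'   datasets.
#' @param combined The combined [count_matrix()] (e.g. from
#'   [combine_counts()]); must contain the intersection genes.
#' @param ... Thresholds passed on to [screen_candidates()].
#' @return A `screen_result` restricted to the intersection genes (empty,
#'   with a warning, when the passing sets are disjoint).
#' @export
intersect_screens <- function(result_a, result_b, combined, ...) {
  stopifnot(inherits(result_a, "screen_result"),
            inherits(result_b, "screen_result"))
  cand <- intersect(passing_genes(result_a), passing_genes(result_b))
  if (length(cand) == 0L) {
    warning("no gene passes in both datasets; returning empty result")
  }
  uq <- uq_normalize(combined)
  missing_genes <- setdiff(cand, rownames(uq))
  if (length(missing_genes) > 0L) {
    stop("intersection genes absent from combined matrix: ",
         paste(missing_genes, collapse = ", "))
  }
  screen_candidates(uq[cand, , drop = FALSE], ...)
}
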