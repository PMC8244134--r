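#' Group design for a sample set
#'
#' A group design assigns every sample to exactly one experimental group
#' (e.g. `"preterm"`, `"fullterm"`, `"adult"`) and optionally carries further
#' categorical covariates (e.g. birth mode).
#'
#' @param sample_id Character vector of unique sample labels.
#' @param group Character vector (same length) of group labels; at least one
#'   group must be present.
#' @param covariates Optional data.frame (or list coercible to one) of extra
#'   per-sample columns.
#' @return A `group_design` data.frame with columns `sample_id`, `group`, and
#'   any covariates.
#' @examples
#' group_design(c("s1", "s2"), c("preterm", "adult"))
#' @export
group_design <- function(sample_id, group, covariates = NULL) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) == 0L) stop("design must contain at least one sample")
  if (length(group) != length(sample_id)) {
    stop("'sample_id' and 'group' must have the same length")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (anyNA(sample_id) || anyNA(group)) stop("design may not contain NA")
  out <- data.frame(sample_id = sample_id, group = group,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != nrow(out)) {
      stop("covariates must have one row per sample")
    }
    out <- cbind(out, covariates)
  }
  class(out) <- c("group_design", "data.frame")
  out
}

#' @export
print.group_design <- function(x, ...) {
  cat("Group design:", nrow(x), "samples in",
      length(unique(x$group)), "group(s)\n")
  print(table(x$group))
  invisible(x)
}

design_groups <- function(design) unique(design$group)

## look up the group of each sample label, in order
design_group_of <- function(design, samples) {
  design$group[match(samples, design$sample_id)]
}

#' Construct a validated ct table
#'
#' A ct table holds qPCR cycle-threshold values, samples in rows and genes in
#' columns, together with a [group_design()]. All downstream stability
#' algorithms operate on complete ct tables.
#'
#' @param ct Numeric matrix, samples x genes, with row and column names.
#'   Values must be finite and in (0, 45] cycles (the upper bound leaves
#'   headroom over a standard 40-cycle protocol).
#' @param design A [group_design()] covering all rows of `ct`.
#' @param gene_meta Optional data.frame of per-gene annotation (e.g. amplicon
#'   length, primer efficiency); informational only, never used in
#'   computations.
#' @return A `ct_table` object (list with elements `ct`, `design`,
#'   `gene_meta`).
#' @seealso [read_ct_table()], [simulate_ct()]
#' @export
ct_table <- function(ct, design, gene_meta = NULL) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("ct matrix must have sample rownames and gene colnames")
  }
  if (ncol(ct) == 0L) stop("ct table contains no genes")
  if (nrow(ct) == 0L) stop("ct table contains no samples")
  if (anyDuplicated(colnames(ct))) {
    stop("duplicate gene label: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(ct))) {
    stop("duplicate sample label: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  }
  bad <- which(!is.finite(ct) | ct <= 0 | ct > 45, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid ct value %s at sample '%s', gene '%s' (must be finite and in (0, 45])",
      format(ct[bad[1, 1], bad[1, 2]]),
      rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]]))
  }
  if (!inherits(design, "group_design")) {
    design <- group_design(design$sample_id, design$group)
  }
  missing_design <- setdiff(rownames(ct), design$sample_id)
  if (length(missing_design) > 0L) {
    stop("samples missing from design: ", paste(missing_design, collapse = ", "))
  }
  design <- design[match(rownames(ct), design$sample_id), , drop = FALSE]
  class(design) <- c("group_design", "data.frame")
  structure(list(ct = ct, design = design, gene_meta = gene_meta),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct table:", nrow(x$ct), "samples x", ncol(x$ct), "genes\n")
  cat("genes:", paste(colnames(x$ct), collapse = ", "), "\n")
  print(table(x$design$group))
  invisible(x)
}

#' @rdname ct_table
#' @param x A `ct_table`.
#' @export
ct_genes <- function(x) colnames(x$ct)

#' @rdname ct_table
#' @export
ct_samples <- function(x) rownames(x$ct)

#' Subset a ct table by samples, genes or groups
#'
#' @param x A [ct_table()].
#' @param samples,genes,groups Optional character vectors selecting what to
#'   keep; `groups` selects all samples of those design groups.
#' @return A validated `ct_table` restricted to the selection.
#' @export
ct_subset <- function(x, samples = NULL, genes = NULL, groups = NULL) {
  stopifnot(inherits(x, "ct_table"))
  keep_s <- rownames(x$ct)
  if (!is.null(groups)) {
    unknown <- setdiff(groups, design_groups(x$design))
    if (length(unknown) > 0L) {
      stop("unknown group(s): ", paste(unknown, collapse = ", "))
    }
    keep_s <- keep_s[design_group_of(x$design, keep_s) %in% groups]
  }
  if (!is.null(samples)) keep_s <- intersect(keep_s, samples)
  keep_g <- if (is.null(genes)) colnames(x$ct) else {
    unknown <- setdiff(genes, colnames(x$ct))
    if (length(unknown) > 0L) {
      stop("unknown gene(s): ", paste(unknown, collapse = ", "))
    }
    genes
  }
  meta <- x$gene_meta
  if (!is.null(meta) && !is.null(rownames(meta))) {
    meta <- meta[intersect(rownames(meta), keep_g), , drop = FALSE]
  }
  ct_table(x$ct[keep_s, keep_g, drop = FALSE],
           x$design[x$design$sample_id %in% keep_s, , drop = FALSE],
           gene_meta = meta)
}

read_design_file <- function(design_path) {
  d <- utils::read.table(design_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         comment.char = "")
  need <- c("sample_id", "group")
  if (!all(need %in% names(d))) {
    stop("design file must have columns 'sample_id' and 'group'")
  }
  covars <- setdiff(names(d), need)
  group_design(d$sample_id, d$group,
               covariates = if (length(covars)) d[covars] else NULL)
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a ct table with its group design
#'
#' Reads a CSV/TSV file of cycle-threshold values (header row of gene labels,
#' first column of sample labels) and a tab-separated design file with
#' columns `sample_id` and `group` (plus optional covariates). Technical
#' replicates — repeated sample labels, optionally distinguished by a
#' `replicate` column — are collapsed by the arithmetic mean of their ct
#' values.
#'
#' @param path Path to the ct file (`.csv` comma-separated, anything else
#'   tab-separated).
#' @param design_path Path to the design TSV.
#' @param drop_incomplete_samples If `TRUE`, samples with any missing ct are
#'   removed instead of raising an error (all stability algorithms require
#'   complete sample x gene blocks).
#' @return A validated [ct_table()].
#' @export
read_ct_table <- function(path, design_path, drop_incomplete_samples = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (ncol(raw) < 2L) stop("ct file must contain sample labels plus >= 1 gene")
  sample_col <- names(raw)[1]
  raw[[sample_col]] <- as.character(raw[[sample_col]])
  raw[["replicate"]] <- NULL                 # well id, only marks replicates
  gene_cols <- names(raw)[-1]
  if (anyDuplicated(gene_cols)) {
    stop("duplicate gene label in header: ",
         paste(unique(gene_cols[duplicated(gene_cols)]), collapse = ", "))
  }
  for (g in gene_cols) {
    v <- raw[[g]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric ct '%s' at sample '%s', gene '%s'",
                   v[bad[1]], raw[[sample_col]][bad[1]], g))
    }
    bad <- which(!is.na(num) & (num <= 0 | num > 45))
    if (length(bad) > 0L) {
      stop(sprintf("ct value %s out of (0, 45] at sample '%s', gene '%s'",
                   format(num[bad[1]]), raw[[sample_col]][bad[1]], g))
    }
    raw[[g]] <- num
  }
  ## collapse technical replicates by arithmetic mean of ct
  agg <- stats::aggregate(raw[gene_cols], by = list(sample_id = raw[[sample_col]]),
                          FUN = mean)
  ## aggregate() sorts by sample id; restore first-appearance order
  agg <- agg[match(unique(raw[[sample_col]]), agg$sample_id), , drop = FALSE]
  m <- as.matrix(agg[gene_cols])
  rownames(m) <- agg$sample_id
  if (anyNA(m)) {
    if (drop_incomplete_samples) {
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) == 0L) stop("all samples dropped as incomplete")
    } else {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "missing ct at sample '%s', gene '%s' (set drop_incomplete_samples = TRUE to drop)",
        rownames(m)[idx[1]], colnames(m)[idx[2]]))
    }
  }
  design <- read_design_file(design_path)
  ct_table(m, design)
}

#' Write a ct table (and optionally its design) to disk
#'
#' @param x A [ct_table()].
#' @param path Output path (`.csv` comma-separated, else tab-separated).
#' @param design_path Optional path for the design TSV.
#' @return Invisibly, `x`.
#' @export
write_ct_table <- function(x, path, design_path = NULL) {
  stopifnot(inherits(x, "ct_table"))
  df <- data.frame(sample_id = rownames(x$ct), x$ct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design_path)) {
    utils::write.table(as.data.frame(x$design), design_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Construct a validated RNA-seq count matrix
#'
#' @param counts Numeric matrix of non-negative integer read counts, genes in
#'   rows and samples in columns (the conventional count-matrix layout), with
#'   dimnames.
#' @param design A [group_design()] covering all columns; groups may be
#'   timepoints (e.g. day of life 0/1/3/7).
#' @return A `count_matrix` object (list with elements `counts`, `design`).
#' @seealso [read_count_matrix()], [uq_normalize()], [simulate_counts()]
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have gene rownames and sample colnames")
  }
  if (nrow(counts) == 0L) stop("count matrix contains no genes")
  if (ncol(counts) == 0L) stop("count matrix contains no samples")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene label")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample label")
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts must be finite")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("count %s at gene '%s', sample '%s' is not a non-negative integer",
                 format(counts[bad[1, 1], bad[1, 2]]),
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (!inherits(design, "group_design")) {
    design <- group_design(design$sample_id, design$group)
  }
  missing_design <- setdiff(colnames(counts), design$sample_id)
  if (length(missing_design) > 0L) {
    stop("samples missing from design: ", paste(missing_design, collapse = ", "))
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  class(design) <- c("group_design", "data.frame")
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(x$design$group))
  invisible(x)
}

#' Read an RNA-seq count matrix with its group design
#'
#' Expects a tab-separated file with a `gene_id` first column and one column
#' of integer counts per sample, plus a design TSV (`sample_id`, `group`).
#'
#' @inheritParams read_ct_table
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, design_path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (ncol(raw) < 2L) stop("count file must contain gene ids plus >= 1 sample")
  if (nrow(raw) == 0L) stop("count file contains no genes")
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) stop("non-numeric count in count file")
  rownames(m) <- genes
  count_matrix(m, read_design_file(design_path))
}

#' Construct a contingency table of group x category counts
#'
#' Used for categorical group comparisons (e.g. receipt of antenatal
#' corticosteroids by gestational-age group). All-zero categories are dropped
#' by [chi_square()] before testing.
#'
#' @param counts Non-negative integer matrix, groups in rows, categories in
#'   columns.
#' @param row_labels,col_labels Optional dimnames.
#' @return A `contingency_table` matrix.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers")
  }
  if (nrow(counts) < 2L) stop("contingency table needs >= 2 groups (rows)")
  if (sum(colSums(counts) > 0) < 2L) {
    stop("contingency table needs >= 2 non-zero categories")
  }
  structure(counts, class = c("contingency_table", class(counts)))
}
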