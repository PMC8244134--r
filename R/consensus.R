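#' Consensus gene ordering by mean rank across algorithms
#'
#' Aggregates per-algorithm rank assignments by the arithmetic mean rank of
#' each gene; genes are ordered by ascending mean rank. Ties are broken by
#' the supplied tiebreak statistic (by convention the NormFinder stability
#' value, the only model-based metric), then by gene label.
#'
#' @param rankings A list of named rank vectors (e.g. from
#'   [stability_ranks()]), all covering the same gene set.
#' @param tiebreak Optional named numeric vector (lower wins) used to break
#'   mean-rank ties.
#' @return data.frame with columns `gene`, one rank column per input
#'   ranking, `mean_rank`, and `consensus_rank`, ordered most stable first.
#' @examples
#' mean_rank(list(bk = c(X = 1, Y = 2), nf = c(X = 1, Y = 4),
#'                gn = c(X = 3, Y = 1)))
#' @export
mean_rank <- function(rankings, tiebreak = NULL) {
  stopifnot(is.list(rankings), length(rankings) >= 1L)
  genes <- names(rankings[[1]])
  if (is.null(genes)) stop("rankings must be named vectors")
  for (r in rankings) {
    if (!setequal(names(r), genes)) {
      stop("all rankings must cover the same gene set")
    }
  }
  mat <- vapply(rankings, function(r) as.numeric(r[genes]),
                numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, names(rankings)))
  mr <- rowMeans(mat)
  tb <- if (is.null(tiebreak)) rep(0, length(genes)) else {
    if (!all(genes %in% names(tiebreak))) {
      stop("tiebreak must name every gene")
    }
    as.numeric(tiebreak[genes])
  }
  ord <- order(mr, tb, genes)
  out <- data.frame(gene = genes, mat, mean_rank = mr,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out <- out[ord, , drop = FALSE]
  out$consensus_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Accept or reject a multi-gene normalization factor
#'
#' A combined normalization factor is only worth using if it is more stable
#' than the best single reference gene; with stability values where lower is
#' better, the candidate is accepted iff strictly
#' `nf_stability < best_single_stability`.
#'
#' @param nf_stability Stability value of the candidate normalization factor
#'   (>= 0; NormFinder rho scale by convention).
#' @param best_single_stability Stability value of the best-ranked single
#'   gene, on the same scale.
#' @return `"accept"` or `"reject"`.
#' @examples
#' evaluate_nf_candidate(0.123, 0.207)  # accept
#' evaluate_nf_candidate(0.062, 0.057)  # reject
#' @export
evaluate_nf_candidate <- function(nf_stability, best_single_stability) {
  stopifnot(is.numeric(nf_stability), is.numeric(best_single_stability),
            length(nf_stability) == 1L, length(best_single_stability) == 1L,
            nf_stability >= 0, best_single_stability >= 0)
  if (nf_stability < best_single_stability) "accept" else "reject"
}

#' Run the full multi-step reference-gene validation workflow
#'
#' For each configured step (a subset of design groups), runs all three
#' stability algorithms, aggregates them by mean rank, vets the
#' NormFinder-selected normalization factor against the best single gene,
#' applies the GeNorm co-regulation guard (if the top GeNorm pair belongs to
#' one gene family, the member with the worse consensus rank is excluded and
#' GeNorm re-run without it — co-regulated family members mutually inflate
#' each other's apparent stability), computes the pairwise-variation series,
#' and attaches per-gene intergroup bias flags.
#'
#' @param ct A [ct_table()].
#' @param steps Named list of character vectors of group labels, e.g.
#'   `list(neonates = c("preterm", "fullterm"), all = c("preterm",
#'   "fullterm", "adult"))`.
#' @param family_map Optional named character vector mapping gene label ->
#'   family label (e.g. `c(RPLP0 = "ribosomal", RPL13 = "ribosomal")`).
#' @param v_threshold GeNorm V threshold (default 0.15).
#' @param max_nf_genes Cap for the NormFinder NF search.
#' @param alpha Significance level for bias flags (default 0.05).
#' @return A list of `validation_report` objects, one per step, each with
#'   per-algorithm results, the consensus table, the NF decision, the V
#'   series, bias flags and any excluded genes.
#' @export
run_validation <- function(ct, steps, family_map = NULL, v_threshold = 0.15,
                           max_nf_genes = Inf, alpha = 0.05) {
  stopifnot(inherits(ct, "ct_table"), is.list(steps), length(steps) >= 1L)
  if (is.null(names(steps)) || any(names(steps) == "")) {
    names(steps) <- vapply(steps, paste, character(1), collapse = "+")
  }
  if (!is.null(family_map)) {
    extra <- setdiff(names(family_map), ct_genes(ct))
    if (length(extra) > 0L) {
      stop("family_map labels not among candidates: ",
           paste(extra, collapse = ", "))
    }
  }
  lapply(stats::setNames(names(steps), names(steps)), function(step_name) {
    grps <- steps[[step_name]]
    sub <- ct_subset(ct, groups = grps)
    bk <- bestkeeper_rank(sub)
    nf <- normfinder_stability(sub, max_nf_genes = max_nf_genes)
    expr <- relative_quantities(sub)
    gn <- genorm_v(expr, threshold = v_threshold)
    rho <- stats::setNames(nf$result$summary$rho, nf$result$summary$gene)
    consensus <- mean_rank(list(bestkeeper = stability_ranks(bk),
                                normfinder = stability_ranks(nf$result),
                                genorm = stability_ranks(gn)),
                           tiebreak = rho)
    excluded <- data.frame(gene = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
    gn_final <- gn
    if (!is.null(family_map)) {
      top_pair <- gn$stability_order[1:2]
      fam <- family_map[top_pair]
      if (!anyNA(fam) && fam[1] == fam[2] && ncol(sub$ct) > 3L) {
        cr <- stats::setNames(consensus$consensus_rank, consensus$gene)
        drop_gene <- top_pair[which.max(cr[top_pair])]
        excluded <- data.frame(
          gene = drop_gene,
          reason = sprintf("co-regulated family '%s' with %s", fam[1],
                           setdiff(top_pair, drop_gene)),
          stringsAsFactors = FALSE)
        gn_final <- genorm_v(expr, threshold = v_threshold,
                             genes = setdiff(colnames(expr$q), drop_gene))
      }
    }
    nf_decision <- NULL
    if (length(grps) >= 2L) {
      best_single <- nf$result$summary$gene[which.min(nf$result$summary$rho)]
      nf_decision <- list(
        genes = nf$result$nf_genes,
        nf_stability = nf$result$nf_rho,
        best_single = best_single,
        best_single_stability = min(nf$result$summary$rho),
        verdict = evaluate_nf_candidate(nf$result$nf_rho,
                                        min(nf$result$summary$rho)))
    } else {
      warning("step '", step_name,
              "' has < 2 groups: NormFinder NF selection skipped")
    }
    bias <- if (length(grps) >= 2L) {
      assess_bias(expr, baseline_group = grps[1], alpha = alpha)
    } else NULL
    structure(list(step = step_name, groups = grps,
                   bestkeeper = bk, normfinder = nf,
                   genorm = gn, genorm_final = gn_final,
                   consensus = consensus, nf_decision = nf_decision,
                   v_series = gn_final$v_series,
                   recommended_n = gn_final$recommended_n,
                   bias = bias, excluded_genes = excluded),
              class = "validation_report")
  })
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== validation step:", x$step, "(groups:",
      paste(x$groups, collapse = ", "), ") ==\n")
  cat("consensus (mean rank, most stable first):\n")
  print(x$consensus, row.names = FALSE, digits = 3)
  if (!is.null(x$nf_decision)) {
    cat(sprintf("NF candidate %s: rho = %.4g vs best single %s rho = %.4g -> %s\n",
                paste(x$nf_decision$genes, collapse = "/"),
                x$nf_decision$nf_stability, x$nf_decision$best_single,
                x$nf_decision$best_single_stability, x$nf_decision$verdict))
  }
  if (nrow(x$excluded_genes) > 0L) {
    cat("excluded from GeNorm:",
        paste(x$excluded_genes$gene, collapse = ", "), "\n")
  }
  if (!is.null(x$v_series)) {
    cat("V series:", paste(sprintf("%s=%.3f", names(x$v_series), x$v_series),
                           collapse = ", "), "\n")
  }
  if (!is.null(x$bias)) {
    cat("bias flags:\n")
    print(x$bias, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a validation report as TSV (consensus) plus a JSON summary
#'
#' @param report A `validation_report` from [run_validation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0("validation_", gsub("[^A-Za-z0-9_.-]", "_",
                                                    report$step)))
  tsv <- paste0(base, "_consensus.tsv")
  utils::write.table(report$consensus, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  btsv <- paste0(base, "_bias.tsv")
  utils::write.table(report$bias, btsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- paste0(base, ".json")
  jsonlite::write_json(
    list(step = report$step, groups = report$groups,
         consensus_order = report$consensus$gene,
         nf_decision = report$nf_decision,
         v_series = as.list(report$v_series),
         recommended_n = report$recommended_n,
         excluded_genes = report$excluded_genes),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(tsv, btsv, js))
}
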