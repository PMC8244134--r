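# Independent brute-force oracles, written as direct loop transcriptions of
# the algorithm definitions. Deliberately naive and separate from the package
# code paths.

oracle_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_geomean <- function(x) prod(x)^(1 / length(x))

## GeNorm M: per gene, mean over partners of SD of per-sample log2 ratios
oracle_genorm_m <- function(q) {
  ngene <- ncol(q)
  m <- numeric(ngene)
  for (j in seq_len(ngene)) {
    sds <- c()
    for (k in seq_len(ngene)) {
      if (k == j) next
      a <- log2(q[, j] / q[, k])
      sds <- c(sds, oracle_sd(a))
    }
    m[j] <- mean(sds)
  }
  names(m) <- colnames(q)
  m
}

## full GeNorm elimination by recomputation from scratch at every step
oracle_genorm_elimination <- function(q) {
  active <- colnames(q)
  out <- character(0)
  while (length(active) > 2) {
    m <- oracle_genorm_m(q[, active, drop = FALSE])
    worst <- active[m == max(m)]
    drop_gene <- worst[length(worst)]      # later gene in input order on ties
    out <- c(out, drop_gene)
    active <- setdiff(active, drop_gene)
  }
  list(eliminated = out, final_pair = active)
}

## BestKeeper: sd, cv, r, r2 against the geometric-mean index
oracle_bestkeeper <- function(ctmat) {
  idx <- apply(ctmat, 1, oracle_geomean)
  genes <- colnames(ctmat)
  data.frame(
    gene = genes,
    sd_ct = vapply(genes, function(g) oracle_sd(ctmat[, g]), numeric(1)),
    cv_ct = vapply(genes, function(g) {
      100 * oracle_sd(ctmat[, g]) / mean(ctmat[, g])
    }, numeric(1)),
    r = vapply(genes, function(g) oracle_pearson(ctmat[, g], idx), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

## NormFinder decomposition and stability value, spreadsheet-style
oracle_normfinder <- function(ctmat, groups) {
  glev <- unique(groups)
  G <- length(glev)
  genes <- colnames(ctmat)
  z <- ctmat
  for (j in seq_len(nrow(ctmat))) z[j, ] <- ctmat[j, ] - mean(ctmat[j, ])
  d <- gamma2 <- matrix(0, length(genes), G, dimnames = list(genes, glev))
  n_g <- numeric(G)
  for (g in seq_len(G)) {
    rows <- which(groups == glev[g])
    n_g[g] <- length(rows)
    for (i in seq_along(genes)) {
      zi <- z[rows, i]
      d[i, g] <- mean(zi)
      gamma2[i, g] <- sum((zi - mean(zi))^2) / (length(zi) - 1)
    }
  }
  for (i in seq_along(genes)) d[i, ] <- d[i, ] - mean(d[i, ])
  d_shrunk <- d
  rho <- numeric(length(genes))
  for (i in seq_along(genes)) {
    ssd <- sum(d[i, ]^2) / (G - 1)
    for (g in seq_len(G)) {
      cc <- if (ssd == 0) 0 else max(0, 1 - (gamma2[i, g] / n_g[g]) / ssd)
      d_shrunk[i, g] <- d[i, g] * cc
    }
    rho[i] <- mean(abs(d_shrunk[i, ]) + sqrt(gamma2[i, ] / n_g))
  }
  list(d = d, gamma2 = gamma2, d_shrunk = d_shrunk,
       rho = setNames(rho, genes))
}

## Pearson chi-square on a 2x2 table, closed form
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

## random complete ct table within the valid cycle range
random_ct_table <- function(n_samples, n_genes, seed,
                            groups = rep("g1", n_samples)) {
  set.seed(seed)
  m <- matrix(runif(n_samples * n_genes, 18, 32), n_samples, n_genes,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("G", seq_len(n_genes))))
  ct_table(m, group_design(rownames(m), groups))
}
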