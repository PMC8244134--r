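make_ct <- function(m, groups) {
  ct_table(m, group_design(rownames(m), groups))
}

test_that("perfectly co-varying genes have zero stability value", {
  base <- c(20, 21, 22, 20.5, 21.5, 19, 23, 24)
  m <- cbind(A = base, B = base + 3)
  rownames(m) <- paste0("s", 1:8)
  nf <- normfinder_stability(make_ct(m, rep(c("x", "y"), each = 4)))
  expect_equal(nf$result$summary$rho, c(0, 0))
})

test_that("stability values are invariant to per-gene constant offsets", {
  sim <- simulate_ct(ct_scenario_preset("null"), seed = 3)
  nf1 <- normfinder_stability(sim$ct)
  ct2 <- sim$ct
  ct2$ct[, "G4"] <- ct2$ct[, "G4"] - 5
  nf2 <- normfinder_stability(ct2)
  expect_equal(nf1$result$summary$rho, nf2$result$summary$rho,
               tolerance = 1e-12)
})

test_that("the variance decomposition matches a step-by-step oracle", {
  set.seed(77)
  m <- matrix(rnorm(40, 25, 1), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("G", 1:4)))
  groups <- rep(c("a", "b"), each = 5)
  out <- normfinder_stability(make_ct(m, groups))
  oracle <- oracle_normfinder(m, groups)
  expect_equal(out$decomposition$d, oracle$d, tolerance = 1e-10)
  expect_equal(out$decomposition$gamma2, oracle$gamma2, tolerance = 1e-10)
  expect_equal(out$decomposition$d_shrunk, oracle$d_shrunk, tolerance = 1e-10)
  expect_equal(stats::setNames(out$result$summary$rho, out$result$summary$gene),
               oracle$rho, tolerance = 1e-10)
  ## structural invariants: d sums to zero per gene, shrinkage never grows d
  expect_equal(rowSums(out$decomposition$d), rep(0, 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(abs(out$decomposition$d_shrunk) <=
                    abs(out$decomposition$d) + 1e-12))
})

test_that("single-group stability reduces to intragroup noise and NF selection refuses", {
  set.seed(12)
  m <- matrix(rnorm(30, 24, 0.5), 10, 3,
              dimnames = list(paste0("s", 1:10), paste0("G", 1:3)))
  out <- normfinder_stability(make_ct(m, rep("only", 10)))
  expect_equal(out$result$summary$rho,
               sqrt(out$decomposition$gamma2[, 1]),
               ignore_attr = TRUE)
  expect_error(normfinder_select_nf(out$decomposition), ">= 2 groups")
})

test_that("undersized groups and gene sets are rejected", {
  m <- matrix(rnorm(9, 24, 0.5), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("G", 1:3)))
  expect_error(normfinder_stability(make_ct(m, c("a", "a", "b"))),
               ">= 2 samples")
  m2 <- m[, 1, drop = FALSE]
  expect_error(normfinder_stability(make_ct(m2, c("a", "a", "a"))),
               ">= 2 genes")
})

test_that("genes with opposite intergroup biases are selected together", {
  ## two-gene case: by construction d_A = -d_B after centering, so the pair's
  ## intergroup term vanishes and the pair beats either single gene
  set.seed(1)
  grp <- rep(c("x", "y"), each = 6)
  a <- 22 + 0.8 * (grp == "y") + rnorm(12, 0, 0.1)
  b <- 25 - 0.8 * (grp == "y") + rnorm(12, 0, 0.1)
  m <- cbind(A = a, B = b)
  rownames(m) <- paste0("s", 1:12)
  out <- normfinder_stability(make_ct(m, grp))
  expect_equal(out$decomposition$d["A", ], -out$decomposition$d["B", ])
  expect_setequal(out$result$nf_genes, c("A", "B"))
  expect_lt(out$result$nf_rho, min(out$result$summary$rho))

  ## six-gene panel where every gene is group-dependent: the two mildest
  ## opposite-signed biases (A, B) are both the best singles and each
  ## other's best complement, so the greedy search should settle on them
  picked <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    n <- 10
    grp <- rep(c("x", "y"), each = n)
    load <- rnorm(2 * n, 0, 0.5)
    mk <- function(shift, noise = 0.15) 24 + load + shift * (grp == "y") +
      rnorm(2 * n, 0, noise)
    m <- cbind(A = mk(0.5), B = mk(-0.5), C = mk(0.9),
               D = mk(-1.1), E = mk(1.2), F = mk(-0.8))
    rownames(m) <- paste0("s", seq_len(2 * n))
    out <- normfinder_stability(make_ct(m, grp))
    if (setequal(out$result$nf_genes, c("A", "B"))) picked <- picked + 1L
  }
  expect_gte(picked, 38L)                      # >= 95% of seeds
})

test_that("NF search stops at one gene when no addition helps", {
  base <- c(20, 21, 22, 23, 20, 24, 21, 25)
  m <- cbind(A = base, B = base, C = base)
  rownames(m) <- paste0("s", 1:8)
  out <- normfinder_stability(make_ct(m, rep(c("x", "y"), each = 4)))
  expect_length(out$result$nf_genes, 1L)
  expect_equal(out$result$nf_rho, 0)
})

test_that("an artificial group shift strictly increases a gene's rho", {
  for (seed in 1:15) {
    sim <- simulate_ct(ct_scenario_preset("null"), seed = 500 + seed)
    rho0 <- normfinder_stability(sim$ct)$result$summary
    ct2 <- sim$ct
    shift_rows <- ct2$design$sample_id[ct2$design$group == "g2"]
    ct2$ct[shift_rows, "G3"] <- ct2$ct[shift_rows, "G3"] + 1
    rho1 <- normfinder_stability(ct2)$result$summary
    expect_gt(rho1$rho[rho1$gene == "G3"], rho0$rho[rho0$gene == "G3"])
  }
})

test_that("gene order does not influence the results", {
  sim <- simulate_ct(ct_scenario_preset("paper-like"), seed = 9)
  out1 <- normfinder_stability(sim$ct)
  perm <- rev(ct_genes(sim$ct))
  out2 <- normfinder_stability(ct_subset(sim$ct, genes = perm))
  s1 <- out1$result$summary
  s2 <- out2$result$summary
  expect_equal(stats::setNames(s2$rho, s2$gene)[s1$gene],
               stats::setNames(s1$rho, s1$gene), tolerance = 1e-12)
  expect_setequal(out1$result$nf_genes, out2$result$nf_genes)
})
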