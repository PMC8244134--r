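test_that("mean rank aggregates, is idempotent and symmetric in its inputs", {
  r <- list(bk = c(X = 1, Y = 2), nf = c(X = 1, Y = 4), gn = c(X = 3, Y = 1))
  cons <- mean_rank(r)
  expect_equal(cons$gene, c("X", "Y"))
  expect_equal(cons$mean_rank, c(5 / 3, 7 / 3), tolerance = 1e-12)

  same <- c(A = 2, B = 1, C = 3)
  cons2 <- mean_rank(list(same, same, same))
  expect_equal(cons2$gene, c("B", "A", "C"))
  expect_equal(cons2$mean_rank, c(1, 2, 3))

  perm <- mean_rank(r[c(3, 1, 2)])
  expect_equal(perm$gene, cons$gene)
  expect_equal(perm$mean_rank, cons$mean_rank)

  expect_error(mean_rank(list(c(X = 1), c(Y = 1))), "same gene set")
})

test_that("mean-rank ties break by the model-based stability value", {
  r <- list(a = c(X = 1, Y = 2), b = c(X = 2, Y = 1))
  cons <- mean_rank(r, tiebreak = c(X = 0.3, Y = 0.1))
  expect_equal(cons$gene, c("Y", "X"))
})

test_that("NF candidates are accepted only on strict improvement", {
  expect_equal(evaluate_nf_candidate(0.062, 0.057), "reject")
  expect_equal(evaluate_nf_candidate(0.123, 0.207), "accept")
  expect_equal(evaluate_nf_candidate(0.1, 0.1), "reject")
  expect_error(evaluate_nf_candidate(-0.1, 0.2))
})

test_that("run_validation produces self-consistent two-step reports", {
  sim <- simulate_ct(ct_scenario_preset("paper-like"), seed = 14)
  steps <- list(neonates = c("preterm", "fullterm"),
                all = c("preterm", "fullterm", "adult"))
  reports <- run_validation(sim$ct, steps)
  expect_named(reports, c("neonates", "all"))
  for (rep in reports) {
    expect_s3_class(rep, "validation_report")
    ## every rank cited in the consensus equals the algorithm's own rank
    for (alg in c("bestkeeper", "genorm")) {
      ranks <- stability_ranks(rep[[alg]])
      expect_equal(rep$consensus[[alg]],
                   unname(ranks[rep$consensus$gene]))
    }
    expect_equal(rep$consensus$normfinder,
                 unname(stability_ranks(rep$normfinder$result)[rep$consensus$gene]))
    expect_false(is.unsorted(rep$consensus$mean_rank))
    expect_equal(rep$nf_decision$verdict,
                 evaluate_nf_candidate(rep$nf_decision$nf_stability,
                                       rep$nf_decision$best_single_stability))
    expect_length(rep$v_series, 6L)
    expect_equal(nrow(rep$bias), 8L)
  }
  ## byte-identical determinism
  reports2 <- run_validation(sim$ct, steps)
  expect_identical(reports, reports2)
  expect_error(run_validation(sim$ct, list(c("preterm", "nosuch"))),
               "unknown group")
})

test_that("the co-regulation guard excludes one family member and re-runs GeNorm", {
  ## build a table whose GeNorm top pair is the two ribosomal genes: they
  ## share a dedicated co-regulation component
  set.seed(33)
  n <- 12
  grp <- rep(c("a", "b"), each = n / 2)
  load <- rnorm(n, 0, 0.5)
  ribo <- rnorm(n, 0, 0.3)
  m <- cbind(RPLP0 = 22 + load + ribo + rnorm(n, 0, 0.05),
             RPL13 = 20 + load + ribo + rnorm(n, 0, 0.05),
             ACTB = 16 + load + rnorm(n, 0, 0.2),
             B2M = 18 + load + rnorm(n, 0, 0.25),
             HPRT = 26 + load + rnorm(n, 0, 0.3))
  rownames(m) <- paste0("s", seq_len(n))
  ct <- ct_table(m, group_design(rownames(m), grp))
  fam <- c(RPLP0 = "ribosomal", RPL13 = "ribosomal")
  rep1 <- run_validation(ct, list(both = c("a", "b")), family_map = fam)$both
  expect_setequal(rep1$genorm$stability_order[1:2], c("RPLP0", "RPL13"))
  expect_equal(nrow(rep1$excluded_genes), 1L)
  dropped <- rep1$excluded_genes$gene
  expect_true(dropped %in% c("RPLP0", "RPL13"))
  expect_false(dropped %in% rep1$genorm_final$summary$gene)
  expect_equal(sort(rep1$genorm_final$summary$gene),
               sort(setdiff(colnames(m), dropped)))
})

test_that("a strongly shifted gene lands last in the consensus", {
  sc <- scenario_shift_gene(ct_scenario_preset("null"), "G5", "g2", +2)
  hits <- 0L
  for (seed in 1:25) {
    sim <- simulate_ct(sc, seed = 900 + seed)
    rep <- run_validation(sim$ct, list(all = c("g1", "g2", "g3")))$all
    if (rep$consensus$gene[nrow(rep$consensus)] == "G5") hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})

test_that("single-group steps skip NF selection with a warning", {
  sim <- simulate_ct(ct_scenario_preset("null"), seed = 5)
  expect_warning(rep <- run_validation(sim$ct, list(solo = "g1"))$solo,
                 "NF selection skipped")
  expect_null(rep$nf_decision)
})

test_that("reports serialize to TSV + JSON", {
  sim <- simulate_ct(ct_scenario_preset("paper-like"), seed = 3)
  rep <- run_validation(sim$ct, list(all = c("preterm", "fullterm", "adult")))$all
  dir <- tempfile()
  paths <- write_validation_report(rep, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[3])
  expect_equal(unlist(js$consensus_order), rep$consensus$gene)
})
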