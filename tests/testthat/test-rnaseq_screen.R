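test_that("upper-quartile normalization removes per-sample scale", {
  set.seed(3)
  a <- rpois(50, 40)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- paste0("g", 1:50)
  uq <- uq_normalize(m)
  expect_equal(uq[, "s1"], uq[, "s2"], ignore_attr = TRUE)

  single <- m[, 1, drop = FALSE]
  expect_equal(uq_normalize(single), single, ignore_attr = TRUE)

  ## after normalization every sample has the same 75th percentile of its
  ## nonzero values (the common geometric mean)
  set.seed(4)
  m2 <- matrix(rnbinom(400, mu = 60, size = 2), 100, 4,
               dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  uq2 <- uq_normalize(m2)
  q75 <- apply(uq2, 2, function(x) quantile(x[x > 0], 0.75, names = FALSE))
  expect_equal(q75, rep(q75[1], 4), ignore_attr = TRUE, tolerance = 1e-12)
  ## idempotence
  expect_equal(uq_normalize(uq2), uq2, ignore_attr = TRUE, tolerance = 1e-12)

  m3 <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(m3) <- c("g1", "g2")
  expect_error(uq_normalize(m3), "all-zero sample.*s2")
})

test_that("screen filters apply the stated strict/inclusive boundaries", {
  n <- 8
  dev_gene <- rep(6, n); dev_gene[1] <- 8.5               # one outlying sample
  sd1 <- rep(c(5, 7), each = n / 2)                       # sd just above 1
  uq <- rbind(good = 2^6 - 1,
              mean5 = 2^5 - 1,                            # mean_log exactly 5
              mean49 = 2^4.9 - 1,
              sdhigh = 2^sd1 - 1,
              devhit = 2^dev_gene - 1)
  colnames(uq) <- paste0("s", 1:n)
  res <- screen_candidates(uq, pseudocount = 1)
  expect_equal(stats::setNames(res$pass, res$gene),
               c(good = TRUE, mean5 = FALSE, mean49 = FALSE,
                 sdhigh = FALSE, devhit = FALSE))
  expect_equal(res$sd_log[res$gene == "sdhigh"], sd(sd1))
  expect_lt(res$sd_log[res$gene == "devhit"], 1)          # fails only on dev
  expect_equal(res$max_dev[res$gene == "devhit"], 2.5 - 2.5 / n)
  expect_equal(res$cv[res$gene == "good"], 0)
  expect_equal(res$rank[res$gene == "good"], 1L)
  expect_equal(attr(res, "n_pass"), 1L)
})

test_that("a sample deviating by exactly 2 log2 units fails filter iii", {
  n <- 9                                                   # mean of (8x6, 1x?)
  x <- c(rep(6, n - 1), 6 + 2 * n / (n - 1))               # dev from mean = 2.0
  uq <- rbind(boundary = 2^x - 1, good = rep(2^6 - 1, n))
  colnames(uq) <- paste0("s", 1:n)
  res <- screen_candidates(uq)
  expect_equal(res$max_dev[res$gene == "boundary"], 2, tolerance = 1e-12)
  expect_false(res$pass[res$gene == "boundary"])
})

test_that("linear-scale cv ranking is invariant to global rescaling", {
  sim <- simulate_counts(count_scenario_preset("screen-bench"), seed = 8)
  m <- sim$counts$counts
  ## UQ normalization commutes with a global rescale
  expect_equal(unname(uq_normalize(m * 4)), unname(4 * uq_normalize(m)),
               tolerance = 1e-12)
  ## linear CV is scale-free, so the ordering of any genes passing under
  ## both scalings is preserved (the abundance filter itself is absolute,
  ## by design, so the passing sets may differ)
  r1 <- screen_candidates(uq_normalize(m), cv_scale = "linear")
  r2 <- screen_candidates(uq_normalize(m * 4), cv_scale = "linear")
  common <- intersect(passing_genes(r1), passing_genes(r2))
  expect_gte(length(common), 10L)
  cv1 <- stats::setNames(r1$cv, r1$gene)[common]
  cv2 <- stats::setNames(r2$cv, r2$gene)[common]
  expect_equal(order(cv1), order(cv2))
  expect_equal(unname(cv1), unname(cv2), tolerance = 1e-10)
})

test_that("screens intersect and re-rank on the combined dataset", {
  sc <- count_scenario_preset("screen-bench")
  simA <- simulate_counts(sc, seed = 21)
  simB <- simulate_counts(sc, seed = 22)
  b <- simB$counts
  b$design$sample_id <- colnames(b$counts) <- paste0("B", colnames(b$counts))
  resA <- screen_candidates(uq_normalize(simA$counts))
  resB <- screen_candidates(uq_normalize(b))
  combined <- combine_counts(simA$counts, b)
  inter <- intersect_screens(resA, resB, combined)
  expect_setequal(inter$gene,
                  intersect(passing_genes(resA), passing_genes(resB)))
  ## same dataset twice: intersection is just A's passing set
  self <- intersect_screens(resA, resA, simA$counts)
  expect_setequal(self$gene, passing_genes(resA))

  ## disjoint passing sets: empty result with a warning
  resEmpty <- resB
  resEmpty$pass <- FALSE
  expect_warning(none <- intersect_screens(resA, resEmpty, combined),
                 "no gene passes")
  expect_equal(nrow(none), 0L)
})
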