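test_that("fisher_overlap_p closed forms and edge cases", {
  # overlap of 0 leaves the whole tail: p = 1
  expect_equal(fisher_overlap_p(5, 0, 10, 100), 1)
  # all 5 of 5 drawn in top 5 from 100: 1 / C(100,5)
  expect_equal(fisher_overlap_p(5, 5, 5, 100), 1 / choose(100, 5),
               tolerance = 1e-12)
  expect_error(fisher_overlap_p(5, 6, 5, 100), "impossible")
  expect_error(fisher_overlap_p(50, 0, 10, 30), "universe")
})

test_that("fisher_overlap_p agrees with exhaustive enumeration", {
  set.seed(71)
  for (i in 1:200) {
    N <- sample(5:30, 1)
    m <- sample.int(N, 1)
    k <- sample.int(N, 1)
    x <- sample(0:min(k, m), 1)
    expect_equal(fisher_overlap_p(k, x, m, N),
                 hyper_tail_oracle(k, x, m, N), tolerance = 1e-12)
  }
})

test_that("running_min_p handles empty overlap and perfect top-ranking", {
  ranked <- sprintf("g%04d", 1:1000)
  expect_equal(running_min_p(c("absent1", "absent2"), ranked, 1000), 1)
  expect_equal(running_min_p(character(), ranked, 1000), 1)
  expect_equal(running_min_p(c("a"), character(), 1000), 1)
  # signature = the top 10 of the ranked list: min-p at k=10 is
  # C(10,10)C(990,0)/C(1000,10), times at most 10+1 scan points
  p <- running_min_p(ranked[1:10], ranked, 1000)
  expect_lt(p, 1e-15)
  expect_gte(p, 1 / choose(1000, 10))
})

test_that("scan correction respects Bonferroni bounds", {
  set.seed(72)
  for (i in 1:50) {
    N <- 500
    ranked <- sprintf("g%04d", sample.int(N, 100))
    sig <- sample(sprintf("g%04d", 1:N), 20)
    hits <- which(ranked %in% sig)
    scan <- sort(unique(c(hits, length(ranked))))
    minp <- min(vapply(scan, function(k)
      fisher_overlap_p(k, sum(hits <= k), length(sig), N), numeric(1)))
    p <- running_min_p(sig, ranked, N)
    expect_gte(p, minp - 1e-15)
    expect_lte(p, min(1, minp * length(scan)) + 1e-15)
  }
})

test_that("a bioset identical to the signature classifies as activated", {
  set.seed(73)
  sig <- random_signature(n_up = 20, n_down = 5, universe = 1000)
  b <- self_bioset(sig, universe = 1000)
  r <- rf_compare(sig, b)
  expect_identical(r$direction, 1L)
  expect_lt(r$p_value, 1e-4)
  expect_gt(r$signed_score, 4)
  expect_setequal(r$overlap, c(sig$up$gene, sig$down$gene))
})

test_that("sign-flip antisymmetry holds exactly over random biosets", {
  set.seed(74)
  sig <- random_signature(n_up = 25, n_down = 6, universe = 2000)
  for (i in 1:100) {
    b <- random_bioset(n = sample(20:120, 1), universe = 2000)
    r1 <- rf_compare(sig, b)
    r2 <- rf_compare(sig, flip_bioset(b))
    expect_identical(r2$direction, -r1$direction)
    expect_identical(r2$p_value, r1$p_value)
    expect_identical(r2$signed_score, -r1$signed_score)
  }
})

test_that("compare is invariant to bioset record order", {
  set.seed(75)
  sig <- random_signature(n_up = 15, n_down = 5, universe = 500)
  b <- random_bioset(n = 60, universe = 500)
  shuf <- b$records[sample.int(60), ]
  b2 <- bioset(shuf, metadata = b$metadata, universe_size = 500)
  r1 <- rf_compare(sig, b)
  r2 <- rf_compare(sig, b2)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$direction, r2$direction)
})

test_that("empty and degenerate inputs follow the declared semantics", {
  sig <- random_signature(n_up = 5, n_down = 2, universe = 100, seed = 76)
  empty <- bioset(data.frame(gene = character(), fold_change = numeric(),
                             adj_p = numeric()), universe_size = 100)
  r <- rf_compare(sig, empty)
  expect_identical(r$direction, 0L)
  expect_equal(r$p_value, 1)
  # up-only signature evaluates only two pairs
  sig_up_only <- gene_signature(up = data.frame(gene = sprintf("g%05d", 1:5),
                                                avg_fold_change = 2),
                                name = "UP")
  b <- random_bioset(n = 30, universe = 100, seed = 77)
  r2 <- rf_compare(sig_up_only, b)
  expect_equal(unname(r2$pair_pvalues[c("down_down", "down_up")]), c(1, 1))
})

test_that("signed score grows with the planted concordant fraction", {
  set.seed(78)
  universe <- 2000
  genes <- sprintf("g%05d", 1:universe)
  sig <- random_signature(n_up = 40, n_down = 10, universe = universe)
  sig_genes <- c(sig$up$gene, sig$down$gene)
  sig_fc <- c(sig$up$avg_fold_change, sig$down$avg_fold_change)
  mean_scores <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(f) {
    mean(replicate(50, {
      n_echo <- round(f * length(sig_genes))
      idx <- sample.int(length(sig_genes), n_echo)
      fillers <- sample(setdiff(genes, sig_genes), 100 - n_echo)
      rec <- data.frame(
        gene = c(sig_genes[idx], fillers),
        fold_change = c(sign(sig_fc[idx]) * runif(n_echo, 4, 8),
                        sample(c(-1, 1), 100 - n_echo, TRUE) *
                          2^runif(100 - n_echo, 0.3, 1.5)),
        adj_p = 0.001)
      rf_compare(sig, bioset(rec, universe_size = universe))$signed_score
    }))
  }, numeric(1))
  expect_true(all(diff(mean_scores) > 0))
})

test_that("intersection universe policy restricts both sides", {
  sig <- random_signature(n_up = 10, n_down = 3, universe = 200, seed = 79)
  b <- random_bioset(n = 50, universe = 200, seed = 80)
  platform <- sprintf("g%05d", 1:150)
  r <- rf_compare(sig, b, universe_policy = "intersection",
                  platform_genes = platform)
  expect_true(all(r$overlap %in% platform))
  r2 <- rf_compare(sig, b, universe_policy = "fixed", fixed_universe = 5000)
  expect_s3_class(r2, "running_fisher_result")
})
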