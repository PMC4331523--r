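# Builds a full-universe contrast table from sparse specifications; genes
# not mentioned are null (fc +1.01, adj_p 1).
contrast_fixture <- function(universe, sig = list()) {
  tab <- data.frame(gene = universe, fold_change = 1.01, adj_p = 1,
                    stringsAsFactors = FALSE)
  for (g in names(sig)) {
    tab$fold_change[tab$gene == g] <- sig[[g]][1]
    tab$adj_p[tab$gene == g] <- sig[[g]][2]
  }
  tab
}

test_that("knockout-anchoring criteria admit and exclude correctly", {
  u <- c("a", "b", "c", "d")
  exp <- chemical_experiment(
    "chem1",
    wt_treated_vs_ctrl = contrast_fixture(u, list(
      a = c(2.0, 0.001),    # up in WT
      b = c(2.0, 0.001),    # up in WT
      c = c(2.0, 0.001),    # up in WT
      d = c(-3.0, 0.001))), # down in WT
    null_treated_vs_ctrl = contrast_fixture(u, list(
      a = c(1.8, 0.001),    # also significantly up in null -> excluded
      b = c(-1.8, 0.001))), # significantly DOWN in null -> not disqualifying
    wt_treated_vs_null_treated = contrast_fixture(u, list(
      a = c(2.0, 0.001),
      b = c(2.0, 0.001),
      d = c(-2.5, 0.001))))  # c lacks the wt-vs-null contrast -> excluded
  dep <- dependent_genes_for_chemical(exp)
  expect_setequal(dep$gene, c("b", "d"))
  expect_identical(dep$direction[dep$gene == "b"], 1L)
  expect_identical(dep$direction[dep$gene == "d"], -1L)
})

test_that("chemical_experiment rejects mismatched universes", {
  u <- c("a", "b")
  expect_error(chemical_experiment(
    "x",
    wt_treated_vs_ctrl = contrast_fixture(u),
    null_treated_vs_ctrl = contrast_fixture(c("a", "zzz")),
    wt_treated_vs_null_treated = contrast_fixture(u)), "mismatch")
})

dep_tab <- function(genes, dirs, fcs) {
  data.frame(gene = genes, direction = as.integer(dirs),
             wt_fold_change = fcs, stringsAsFactors = FALSE)
}

test_that("combine_signature applies support, direction and magnitude rules", {
  per_chem <- list(
    dep_tab(c("a", "b", "c", "e"), c(1, 1, 1, 1), c(1.6, 2.0, 1.4, 1.45)),
    dep_tab(c("a", "b", "d", "e"), c(1, -1, -1, 1), c(1.7, -2.0, -1.8, 1.45)),
    dep_tab(c("c", "d"), c(1, -1), c(1.5, -2.0)))
  sig <- combine_signature(per_chem, builder_config())
  # a: up in 2/3, avg (1.6+1.7)/2 = 1.65 -> retained
  expect_true("a" %in% sig$up$gene)
  expect_equal(sig$up$avg_fold_change[sig$up$gene == "a"], 1.65)
  # b: direction conflict between chemicals -> dropped
  expect_false("b" %in% c(sig$up$gene, sig$down$gene))
  # c: support 2, avg (1.4+1.5)/2 = 1.45 < 1.5 -> dropped
  expect_false("c" %in% sig$up$gene)
  # d: down in 2 chemicals, avg -1.9 -> retained in down half
  expect_true("d" %in% sig$down$gene)
  # e: avg 1.45 < 1.5 despite support 2 -> dropped
  expect_false("e" %in% sig$up$gene)
})

test_that("exclusion signatures drop same-direction members only", {
  per_chem <- list(dep_tab(c("a", "b"), c(1, 1), c(2, 2)),
                   dep_tab(c("a", "b"), c(1, 1), c(2, 2)))
  excl_same <- gene_signature(up = data.frame(gene = "a",
                                              avg_fold_change = 3),
                              name = "EXCL")
  excl_opp <- gene_signature(up = data.frame(gene = "zz",
                                             avg_fold_change = 2),
                             down = data.frame(gene = "a",
                                               avg_fold_change = -3),
                             name = "EXCL2")
  sig1 <- combine_signature(per_chem,
                            builder_config(exclusion_signatures = list(excl_same)))
  expect_false("a" %in% sig1$up$gene)   # same direction -> dropped
  expect_true("b" %in% sig1$up$gene)
  sig2 <- combine_signature(per_chem,
                            builder_config(exclusion_signatures = list(excl_opp)))
  expect_true("a" %in% sig2$up$gene)    # opposite direction -> retained
})

test_that("probe collapsing requires direction agreement", {
  per_chem <- list(dep_tab(c("p1", "p2", "p3"), c(1, 1, -1), c(2, 2.4, -2)),
                   dep_tab(c("p1", "p2", "p3"), c(1, 1, -1), c(2, 2.4, -2)))
  map <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE2")
  sig <- combine_signature(per_chem, probe_to_gene = map)
  expect_setequal(sig$up$gene, "GENE1")
  expect_equal(sig$up$avg_fold_change, 2.2)    # mean over agreeing probes
  # now make GENE1's probes disagree
  per_chem2 <- list(dep_tab(c("p1", "p2"), c(1, -1), c(2, -2)),
                    dep_tab(c("p1", "p2"), c(1, -1), c(2, -2)))
  expect_message(
    sig2 <- combine_signature(per_chem2, probe_to_gene = c(p1 = "GENE1",
                                                           p2 = "GENE1")),
    "direction-conflicting")
  expect_identical(signature_size(sig2), 0L)
})

test_that("signature is invariant to chemical order and monotone in support", {
  set.seed(51)
  per_chem <- lapply(1:3, function(i) {
    n <- 30
    g <- sprintf("g%03d", sample.int(60, n))
    dep_tab(g, sample(c(1L, -1L), n, TRUE) ,
            sample(c(1, -1), n, TRUE) * runif(n, 1.2, 3))
  })
  # keep direction/fc consistent within each table
  per_chem <- lapply(per_chem, function(t) {
    t$wt_fold_change <- abs(t$wt_fold_change) * t$direction
    t
  })
  s123 <- combine_signature(per_chem, builder_config())
  s321 <- combine_signature(rev(per_chem), builder_config())
  expect_equal(s123$up, s321$up)
  expect_equal(s123$down, s321$down)
  s_all <- combine_signature(per_chem,
                             builder_config(min_chemical_support = 3))
  expect_true(all(c(s_all$up$gene, s_all$down$gene) %in%
                    c(s123$up$gene, s123$down$gene)))
})

test_that("builder recovers a strongly planted program and rejects
           genotype-independent responders", {
  cfg <- sim_config(n_genes = 2000, n_program = 131, n_independent = 30,
                    effect_log2fc = c(2, 2.5),   # |FC| >= 4: strong effects
                    chemical_presence_prob = 1, seed = 61)
  sim <- simulate_ko_experiments(cfg)
  sig <- build_signature_from_matrices(sim$matrices)
  got <- c(sig$up$gene, sig$down$gene)
  program <- c(sim$truth$program_up, sim$truth$program_down)
  expect_gte(mean(got %in% program), 0.95)            # precision
  expect_gte(mean(program %in% got), 0.90)            # recall
  expect_gte(mean(!sim$truth$independent %in% got), 0.95)
})
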