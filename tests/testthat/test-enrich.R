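# brute-force hypergeometric right tail by direct enumeration
fisher_enum <- function(x, K, n, N) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

test_that("right-tailed Fisher p matches enumeration on worked cases", {
  expect_equal(fisher_right_tail(0, 5, 4, 10), 1)
  expect_equal(fisher_right_tail(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(fisher_right_tail(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    x <- sample(max(0, n + K - N):min(K, n), 1)
    expect_close(fisher_right_tail(x, K, n, N), fisher_enum(x, K, n, N), 1e-10)
  }
  # monotone nonincreasing in the overlap count
  p_seq <- fisher_right_tail(0:5, 8, 5, 30)
  expect_true(all(diff(p_seq) <= 0))
  expect_error(fisher_right_tail(6, 5, 10, 20), "bounds")
  expect_error(fisher_right_tail(1, 25, 10, 20), "bounds")
})

test_that("collection restriction enforces the universe and drops empty sets", {
  coll <- gene_set_collection(
    list(A = c("g1", "g2", "gX"), B = c("gY", "gZ"), C = c("g3")),
    universe = c("g1", "g2", "g3", "g4"))
  expect_equal(names(coll$sets), c("A", "C"))
  expect_equal(coll$sets$A, c("g1", "g2"))
  expect_equal(attr(coll, "n_dropped"), 1L)
  expect_error(gene_set_collection(list(A = "g"), character(0)), "empty universe")
})

test_that("ORA handles disjoint, degenerate and empty-stratum inputs", {
  coll <- gene_set_collection(
    list(S1 = c("g1", "g2", "g3"), S2 = c("g7", "g8")),
    universe = sprintf("g%d", 1:10))
  res <- run_ora(list(all = c("g1", "g2", "g4"), positive = character(0)), coll)
  s2 <- res[res$set == "S2" & res$stratum == "all", ]
  expect_equal(s2$x, 0L)
  expect_equal(s2$p, 1)
  s1 <- res[res$set == "S1" & res$stratum == "all", ]
  expect_equal(s1$x, 2L)
  expect_equal(s1$ratio, 2 / 3)
  expect_close(s1$p, fisher_enum(2, 3, 3, 10), 1e-12)
  pos <- res[res$stratum == "positive", ]
  expect_true(all(pos$not_applicable))
  expect_true(all(is.na(pos$p)))
  # input list equal to the universe: overlap is forced, p = 1, flagged
  deg <- run_ora(list(all = sprintf("g%d", 1:10)), coll)
  expect_true(all(deg$degenerate))
  expect_true(all(deg$p == 1))
  expect_true(all(deg$x == deg$K))
})

test_that("permutation FDR obeys the add-one floor, ceiling and determinism", {
  genes <- sprintf("g%03d", 1:60)
  coll <- gene_set_collection(
    list(hit = genes[1:10], whole = genes, null1 = genes[31:40]),
    universe = genes)
  obs <- run_ora(list(all = genes[1:12]), coll)
  pf1 <- permutation_fdr(obs, coll, B = 200, seed = 9)
  pf2 <- permutation_fdr(obs, coll, B = 200, seed = 9)
  expect_identical(pf1, pf2)
  # the 'hit' set overlaps the input in all 10 members: no random list of 12
  # from 60 genes beats that in 200 draws
  expect_equal(pf1$perm_fdr[pf1$set == "hit"], 1 / 201)
  # a set equal to the universe always has p = 1: FDR = 1
  expect_equal(pf1$perm_fdr[pf1$set == "whole"], 1)
  expect_error(permutation_fdr(obs, coll, B = 50), "at least 100")
  expect_error(permutation_fdr(obs, coll, n_input = 100, B = 200), "universe")
})

test_that("direction composition partitions each set's genes", {
  coll <- gene_set_collection(list(S = c("g1", "g2", "g3", "g4")),
                              universe = sprintf("g%d", 1:8))
  gr <- data.frame(gene = c("g1", "g2", "g3"),
                   direction_class = c("positive", "positive", "negative"))
  comp <- direction_composition("S", coll, gr)
  expect_equal(unname(comp), c(2, 1, 1) / 4)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
  allpos <- direction_composition(
    "S", coll, data.frame(gene = sprintf("g%d", 1:4),
                          direction_class = "positive"))
  expect_equal(unname(allpos), c(1, 0, 0))
  expect_error(direction_composition("nope", coll, gr), "unknown set")
})

test_that("enrichment table mirrors the per-stratum report layout", {
  coll <- gene_set_collection(
    list(S1 = sprintf("g%d", 1:6), S2 = sprintf("g%d", 7:12)),
    universe = sprintf("g%d", 1:20))
  strata <- list(all = sprintf("g%d", c(1:4, 7)),
                 positive = sprintf("g%d", 1:4),
                 negative = "g7")
  tab <- enrichment_table(run_ora(strata, coll))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_all[tab$set == "S1"], 4L)
  expect_equal(tab$n_positive[tab$set == "S1"], 4L)
  expect_equal(tab$n_negative[tab$set == "S1"], 0L)
  expect_equal(tab$n_negative[tab$set == "S2"], 1L)
  expect_equal(tab$ratio[tab$set == "S1"], 4 / 6)
})

test_that("planted-enriched sets attain smaller ORA p-values than null sets", {
  obj <- tiny_pipeline_objects(seed = 41, n_samples_per_cohort = c(250L, 250L),
                               n_probes = 500L, n_genes = 400L,
                               effect_size_sd = 0.4,
                               reticulocyte_block_size = 0L)
  # the set seed must differ from the simulation seed: sharing one RNG
  # stream would correlate "null" set membership with the planted genes
  sets <- generate_gene_sets(obj$gs$truth, n_sets = 15,
                             set_size_range = c(10L, 25L), n_enriched = 4,
                             seed = 541)
  universe <- unique(obj$gs$studies[[1]]$annotation$gene)
  coll <- gene_set_collection(sets$sets, universe)
  ora <- run_ora(list(all = obj$genes$gene), coll)
  planted_p <- ora$p[sets$enriched[ora$set]]
  null_p <- ora$p[!sets$enriched[ora$set]]
  expect_lt(max(planted_p), min(null_p))
})
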