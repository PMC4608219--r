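test_that("signed z conversion matches the inverse-normal oracle", {
  expect_equal(z_from_assoc(1.5, 0.05), 1.959964, tolerance = 1e-6)
  expect_equal(z_from_assoc(-1.5, 0.05), -1.959964, tolerance = 1e-6)
  expect_equal(z_from_assoc(2, 1), 0)
  expect_equal(z_from_assoc(0, 0.05), 0)  # sign(0) carries no direction
  expect_error(z_from_assoc(1, 0), "\\(0, 1\\]")
  expect_error(z_from_assoc(Inf, 0.5), "finite")
})

test_that("sample-size-weighted z combination follows the closed form", {
  # equal-n case: (10*2 + 10*2)/sqrt(200)
  expect_equal(stouffer(c(2, 2), c(100, 100))$z_meta, 40 / sqrt(200),
               tolerance = 1e-12)
  r <- stouffer(c(2, -2), c(100, 100))
  expect_equal(r$z_meta, 0)
  expect_equal(r$p_meta, 1)
  # (10*2 + 20*3)/sqrt(500)
  expect_equal(stouffer(c(2, 3), c(100, 400))$z_meta, 80 / sqrt(500),
               tolerance = 1e-12)
  expect_equal(stouffer(c(2, 3), c(100, 400))$z_meta, 3.57771,
               tolerance = 1e-5)
  # single study: identity
  expect_equal(stouffer(1.7, 250)$z_meta, 1.7)
  expect_equal(stouffer(1.7, 250)$p_meta, 2 * pnorm(-1.7))
  expect_error(stouffer(c(1, 2), c(10, 0)), "positive")
  expect_error(stouffer(c(1, 2), 10), "equal length")
})

test_that("BH step-up matches hand computation and the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.05)),
               c(0.004, 0.02, 0.04, 0.05))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:300, 1))^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    expect_close(bh_adjust(p), p.adjust(p, "BH"), 1e-12)
  }
  # q-values are monotone in sorted p and bounded below by p
  p <- sort(runif(100))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("meta_analyze combines cohorts per the weighted-z scheme", {
  mk <- function(id, beta, p, n) data.frame(
    probe_id = c("pA", "pB"), cohort = id, beta = beta, se = abs(beta) / 2,
    t = 2, p = p, n = n, df = n - 2, degenerate = FALSE, model = "base")
  a <- mk("c1", c(0.2, -0.1), c(0.001, 0.6), 100)
  b <- mk("c2", c(0.3, -0.2), c(0.002, 0.4), 400)
  m <- meta_analyze(list(a, b), q_threshold = 0.05)
  z1 <- z_from_assoc(c(0.2, -0.1), c(0.001, 0.6))
  z2 <- z_from_assoc(c(0.3, -0.2), c(0.002, 0.4))
  exp_z <- (sqrt(100) * z1 + sqrt(400) * z2) / sqrt(500)
  expect_close(m$z_meta, exp_z, 1e-12)
  expect_close(m$p_meta, 2 * pnorm(-abs(exp_z)), 1e-12)
  expect_equal(m$q, bh_adjust(m$p_meta))
  expect_equal(m$direction, sign(exp_z))
  expect_close(m$beta_meta, (100 * c(0.2, -0.1) + 400 * c(0.3, -0.2)) / 500, 1e-12)
  expect_equal(m$n_meta, c(500, 500))
  # single cohort: meta reduces to the cohort's own z and p
  m1 <- meta_analyze(list(a))
  expect_close(m1$z_meta, z1, 1e-12)
  expect_close(m1$p_meta, pmax(2 * pnorm(-abs(z1)), 1e-300), 1e-12)
})

test_that("gene collapsing picks the min-p probe and classifies directions", {
  meta <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    p_meta = c(0.01, 0.001, 1e-6, 1e-6, 0.5, 1e-4),
    q = c(0.009, 0.0009, 1e-5, 1e-5, 0.6, 1e-3),
    z_meta = c(3, 4, 5, -5, 0.5, -4),
    direction = c(1, 1, 1, -1, 1, -1))
  ann <- data.frame(probe_id = paste0("p", 1:6),
                    gene = c("G1", "G1", "G2", "G2", "G3", "G4"))
  g <- collapse_genes(meta, ann, q_threshold = 0.01)
  g1 <- g[g$gene == "G1", ]
  expect_equal(g1$probe_id, "p2")          # smallest p among G1's probes
  expect_equal(g1$direction_class, "positive")
  expect_equal(g1$n_probes, 2L)
  g2 <- g[g$gene == "G2", ]
  expect_equal(g2$direction_class, "inconsistent")  # significant +, - probes
  expect_equal(g2$probe_id, "p3")          # p tie broken lexicographically
  expect_false("G3" %in% g$gene)           # no significant probe -> absent
  expect_equal(g[g$gene == "G4", "direction_class"], "negative")
})

test_that("direction summary reproduces percentage arithmetic", {
  s <- direction_summary(c(positive = 1, negative = 0, inconsistent = 0))
  expect_equal(s$percent, c(100, 0, 0))
  g <- data.frame(direction_class = c(rep("positive", 2), "negative"))
  s2 <- direction_summary(g)
  expect_equal(s2$count, c(2L, 1L, 0L))
  expect_equal(s2$percent, c(66.7, 33.3, 0))
  expect_error(direction_summary(g[0, , drop = FALSE]), "no genes")
})

test_that("with strong coherent planted effects no gene is classified inconsistent", {
  obj <- tiny_pipeline_objects(seed = 31, n_samples_per_cohort = c(250L, 250L),
                               n_probes = 400L, n_genes = 300L,
                               effect_size_sd = 0.5,
                               reticulocyte_block_size = 0L)
  expect_gt(nrow(obj$genes), 0)
  expect_false(any(obj$genes$direction_class == "inconsistent"))
  # recovered directions agree with the planted truth
  tr <- merge(obj$genes, obj$gs$truth$gene_truth, by = "gene")
  planted <- tr$direction_true != "null"
  expect_true(all(tr$direction_class[planted] == tr$direction_true[planted]))
})
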