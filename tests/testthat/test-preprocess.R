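make_study <- function(n = 10, probes = 4, rin = NULL, bmi = NULL) {
  set.seed(99)
  cov <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                    bmi = if (is.null(bmi)) rnorm(n, 28, 4) else bmi,
                    age = rnorm(n, 60, 8),
                    rin = if (is.null(rin)) rep(9, n) else rin)
  m <- matrix(runif(probes * n, 10, 1000), nrow = probes,
              dimnames = list(sprintf("p%d", seq_len(probes)), cov$sample_id))
  dp <- matrix(runif(probes * n), nrow = probes, dimnames = dimnames(m))
  expression_study(m, dp, cov, "c1",
                   data.frame(probe_id = rownames(m), gene = rownames(m)))
}

test_that("sample QC retains clean samples and drops low-RIN ones strictly below 7", {
  s <- make_study(n = 10)
  expect_identical(filter_samples(s)$covariates, s$covariates)

  rin <- rep(9, 10); rin[4] <- 6.9
  s2 <- make_study(n = 10, rin = rin)
  f2 <- filter_samples(s2)
  expect_equal(ncol(f2$intensities), 9)
  expect_false("s04" %in% f2$covariates$sample_id)
  # boundary: RIN exactly 7 is retained
  rin[4] <- 7
  expect_equal(ncol(filter_samples(make_study(n = 10, rin = rin))$intensities), 10)
  expect_error(filter_samples(make_study(n = 3, rin = rep(2, 3))), "RIN")
})

test_that("samples with missing BMI are excluded (5 of 988 leaves 983)", {
  bmi <- rnorm(988, 28.9, 4.5)
  bmi[c(10, 200, 300, 400, 988)] <- NA
  s <- make_study(n = 988, bmi = bmi)
  f <- filter_samples(s)
  expect_equal(nrow(f$covariates), 983)
  log <- attr(f, "qc_log")
  expect_equal(log$n[log$reason == "missing_values"], 5)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)
  set.seed(1)
  r <- matrix(rexp(600), nrow = 100)
  qn <- quantile_normalize(r)
  ref <- sort(qn[, 1])
  for (j in 2:6) expect_equal(sort(qn[, j]), ref)
  expect_equal(dim(qn), dim(r))
})

test_that("quantile normalization is idempotent and sample-permutation equivariant", {
  set.seed(2)
  m <- matrix(rlnorm(500), nrow = 50,
              dimnames = list(NULL, sprintf("s%d", 1:10)))
  q1 <- quantile_normalize(m)
  expect_lt(max(abs(quantile_normalize(q1) - q1)), 1e-12)
  perm <- sample(10)
  expect_equal(quantile_normalize(m[, perm]), q1[, perm])
  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), "fewer than 2")
  expect_error(quantile_normalize(matrix(c(1, NA), 1)), "missing")
})

test_that("log2 transform with clipping floor", {
  expect_equal(log2_transform(matrix(8)), matrix(3))
  expect_equal(log2_transform(matrix(1)), matrix(0))
  expect_equal(log2_transform(matrix(0.5)), matrix(-1))
  expect_warning(out <- log2_transform(matrix(c(-2, 0, 4), 1)), "clipped")
  expect_equal(out, matrix(c(0, 0, 2), 1))
  expect_warning(out2 <- log2_transform(matrix(-1), floor = 0.5))
  expect_equal(out2, matrix(-1))
})

test_that("detection filter applies the strict both-cohort above-50% rule", {
  mk <- function(dp, id) {
    n <- ncol(dp)
    cov <- data.frame(sample_id = sprintf("%s_s%d", id, 1:n),
                      bmi = rnorm(n, 28), rin = rep(9, n))
    colnames(dp) <- cov$sample_id
    m <- matrix(100, nrow(dp), n, dimnames = dimnames(dp))
    expression_study(m, dp, cov, id,
                     data.frame(probe_id = rownames(dp), gene = rownames(dp)))
  }
  # probe detection p [0.01, 0.2, 0.01, 0.04] -> rate 0.75, passes
  dpA <- rbind(p1 = c(0.01, 0.2, 0.01, 0.04),   # 0.75
               p2 = c(0.01, 0.01, 0.2, 0.3),    # 0.50 exactly -> fail
               p3 = c(0.01, 0.01, 0.01, 0.01))  # 1.00
  dpB <- rbind(p1 = c(0.01, 0.01, 0.01, 0.2),   # 0.75
               p2 = c(0.01, 0.01, 0.01, 0.01),
               p3 = c(0.2, 0.3, 0.4, 0.01))     # 0.25 -> fails cohort B
  res <- detection_filter(list(mk(dpA, "A"), mk(dpB, "B")))
  expect_equal(res$probes, "p1")
  sm <- res$summary
  expect_equal(sm$detection_rate[sm$probe_id == "p1" & sm$cohort == "A"], 0.75)
  expect_false(sm$pass[sm$probe_id == "p2" & sm$cohort == "A"])   # 0.5 strict
  # boundary on the detection call itself: p = 0.05 is not a detection
  dpC <- rbind(p1 = rep(0.05, 4))
  expect_equal(detection_filter(list(mk(dpC, "C")))$summary$detection_rate, 0)
  # lowering the threshold never removes a passing probe
  loose <- detection_filter(list(mk(dpA, "A"), mk(dpB, "B")), threshold = 0.2)
  expect_true(all(res$probes %in% loose$probes))
  # disjoint probe universes are an error
  dpD <- rbind(q1 = rep(0.01, 4))
  expect_error(detection_filter(list(mk(dpA, "A"), mk(dpD, "D"))), "disjoint")
})
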