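test_that("K = 1 pins the whole genome to the single component", {
  gm <- make_gm(matrix(sample(0:2, 60, replace = TRUE), nrow = 3,
                       dimnames = list(c("a", "b", "c"), NULL)))
  panel <- matrix(runif(20, 0.1, 0.9), ncol = 1,
                  dimnames = list(variant_ids(gm), "AFR"))
  anc <- estimate_ancestry(gm, panel)
  expect_equal(unname(anc$Q[, 1]), c(1, 1, 1))
})

test_that("an all-heterozygous genome between opposite panels lands at 50/50", {
  M <- 50L
  gm <- make_gm(matrix(1L, 1, M, dimnames = list("het", NULL)))
  panel <- cbind(c1 = rep(0.999999, M), c2 = rep(0.000001, M))
  rownames(panel) <- variant_ids(gm)
  anc <- estimate_ancestry(gm, panel)
  expect_equal(unname(anc$Q["het", ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("EM log-likelihood never decreases across iterations", {
  st <- simulate_study(tiny_cfg(M = 400L, n = 15L, seed = 41L))
  anc <- estimate_ancestry(st$gm, st$panel$freq, trace = TRUE)
  tr <- attr(anc, "trace")                # iterations x individuals
  expect_true(all(diff(tr) > -1e-8))
  expect_true(all(anc$converged))
  expect_true(all(abs(rowSums(anc$Q) - 1) < 1e-8))
})

test_that("supervised EM recovers simulated ancestry fractions", {
  st <- simulate_study(tiny_cfg(M = 1500L, n = 15L, seed = 43L))
  anc <- estimate_ancestry(st$gm, st$panel$freq)
  mae <- mean(abs(anc$Q[rownames(st$truth), ] - st$truth))
  expect_lt(mae, 0.05)
})

test_that("recovery error shrinks as the panel becomes more informative", {
  mae_at <- function(f) {
    st <- simulate_study(tiny_cfg(M = 1500L, n = 15L, seed = 47L, diff = f))
    anc <- estimate_ancestry(st$gm, st$panel$freq)
    mean(abs(anc$Q[rownames(st$truth), ] - st$truth))
  }
  expect_lt(mae_at(0.2), mae_at(0.05))
})

test_that("too few shared variants is an error", {
  gm <- make_gm(matrix(1L, 2, 5, dimnames = list(c("a", "b"), NULL)))
  panel <- matrix(0.5, 5, 2, dimnames = list(variant_ids(gm), c("x", "y")))
  expect_error(estimate_ancestry(gm, panel), "need >= 10")
})

test_that("association OLS matches the hand-computed oracle", {
  gm <- make_gm(matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1,
                       dimnames = list(paste0("s", 1:6), NULL)))
  q <- matrix(c(0.1, 0.2, 0.4, 0.5, 0.7, 0.8), ncol = 1,
              dimnames = list(paste0("s", 1:6), "AFR"))
  out <- ancestry_association(gm, q)
  # beta = Sxy/Sxx = 1.2/4; SSE = 0.015; SE = sqrt(0.015/4/4); df = 4
  expect_equal(out$beta, 0.3, tolerance = 1e-12)
  expect_equal(out$se, sqrt(0.015 / 4 / 4), tolerance = 1e-12)
  expect_equal(out$t, 0.3 / sqrt(0.015 / 4 / 4), tolerance = 1e-10)
  expect_equal(out$t, 9.798, tolerance = 1e-4)
  expect_equal(out$p, 2 * pt(-out$t, df = 4), tolerance = 1e-12)
  expect_equal(out$n, 6L)
})

test_that("association agrees with lm() across random data with missingness", {
  set.seed(53)
  n <- 30L
  d <- matrix(sample(c(0:2, NA), n * 5, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), nrow = n,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  gm <- make_gm(d)
  q <- matrix(runif(n), ncol = 1, dimnames = list(rownames(d), "EUR"))
  out <- ancestry_association(gm, q)
  for (j in seq_len(5)) {
    x <- d[, j]; y <- q[, 1]
    fit <- summary(lm(y ~ x))
    expect_equal(out$beta[j], unname(coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(out$se[j], unname(coef(fit)[2, 2]), tolerance = 1e-10)
    expect_equal(out$p[j], unname(coef(fit)[2, 4]), tolerance = 1e-10)
    expect_equal(out$n[j], sum(!is.na(x)))
  }
})

test_that("degenerate regressions are flagged, not divided by zero", {
  gm <- make_gm(matrix(c(0L, 1L, 2L, 1L), ncol = 1,
                       dimnames = list(paste0("s", 1:4), NULL)))
  flat <- matrix(0.4, 4, 1, dimnames = list(paste0("s", 1:4), "AFR"))
  out <- ancestry_association(gm, flat)
  expect_equal(out$beta, 0)
  expect_equal(out$p, 1)
  expect_identical(out$flag, "constant_y")

  perfect <- matrix(0.1 * gm$dosage[, 1] + 0.2, ncol = 1,
                    dimnames = list(paste0("s", 1:4), "AFR"))
  out2 <- ancestry_association(gm, perfect)
  expect_equal(out2$beta, 0.1, tolerance = 1e-12)
  expect_equal(out2$p, 0)
  expect_identical(out2$flag, "degenerate_fit")

  const_x <- make_gm(matrix(1L, 4, 1, dimnames = list(paste0("s", 1:4), NULL)))
  out3 <- ancestry_association(const_x, matrix(runif(4), 4, 1,
    dimnames = list(paste0("s", 1:4), "AFR")))
  expect_identical(out3$flag, "constant_x")
  expect_true(is.na(out3$beta))
})

test_that("per-variant slopes over all components sum to zero", {
  st <- simulate_study(tiny_cfg(M = 50L, n = 30L, seed = 59L))
  out <- ancestry_association(st$gm, st$truth)
  sums <- tapply(out$beta, out$id, sum)
  expect_true(all(abs(sums) < 1e-10, na.rm = TRUE))
})

test_that("an African-enriched effect allele yields a positive African slope", {
  st <- simulate_study(sim_config(M = 50L, seed = 61L))   # 200 individuals
  set.seed(62)
  f_special <- c(0.9, 0.1, 0.1)
  p <- st$truth %*% f_special
  g <- matrix(rbinom(length(p), 2L, p), ncol = 1,
              dimnames = list(rownames(st$truth), NULL))
  gm <- make_gm(g, ids = "rs_special")
  out <- ancestry_association(gm, st$truth, component = "AFR")
  expect_gt(out$beta, 0)
  expect_lt(out$p, 0.01)
})

test_that("benjamini-hochberg q-values are optional and per component", {
  st <- simulate_study(tiny_cfg(M = 40L, n = 20L, seed = 67L))
  plain <- ancestry_association(st$gm, st$truth)
  expect_false("q" %in% names(plain))
  adj <- ancestry_association(st$gm, st$truth, adjust = TRUE)
  for (comp in unique(adj$component)) {
    rows <- adj$component == comp
    expect_equal(adj$q[rows], p.adjust(adj$p[rows], "BH"))
  }
})
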