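test_that("effect-allele frequencies are plain dosage sums over non-missing calls", {
  gm <- make_gm(rbind(a = c(1L, 0L, 2L), b = c(2L, 0L, NA), c = c(0L, 1L, 1L)))
  man <- make_manifest(c("a", "b", "c"), c("pop1", "pop1", "pop2"))
  f <- effect_allele_frequencies(gm, man, c("pop1", "pop2"))
  expect_equal(f$f_pop1, c(3 / 4, 0, 1))
  expect_equal(f$n1, c(2, 2, 1))
  expect_equal(f$f_pop2, c(0, 0.5, 0.5))
  expect_error(effect_allele_frequencies(gm, man, c("pop1", "nowhere")),
               "absent from manifest")
})

test_that("divergence arithmetic matches direct computation on published frequencies", {
  d <- divergence(c(0.81, 0.18), c(0.32, 0.05),
                  ids = c("rs776746", "rs4149056"))
  expect_equal(d$delta, c(0.49, 0.13), tolerance = 1e-12)
  expect_equal(d$log2_ratio, c(log2(0.81 / 0.32), log2(0.18 / 0.05)),
               tolerance = 1e-12)
  expect_equal(d$log2_ratio, c(1.3399, 1.8480), tolerance = 1e-4)
  expect_equal(d$euclidean,
               sqrt(d$log2_ratio^2 + d$delta^2), tolerance = 1e-12)
  expect_equal(d$euclidean, c(1.4267, 1.8526), tolerance = 1e-4)
  expect_identical(d$direction, c("pop1", "pop1"))
})

test_that("equal frequencies sit at the origin", {
  d <- divergence(0.4, 0.4)
  expect_equal(unlist(d[c("log2_ratio", "delta", "euclidean")]),
               c(log2_ratio = 0, delta = 0, euclidean = 0))
  expect_identical(d$direction, "equal")
})

test_that("divergence is antisymmetric under population swap", {
  set.seed(3)
  f1 <- runif(20, 0.02, 0.98); f2 <- runif(20, 0.02, 0.98)
  fwd <- divergence(f1, f2)
  rev <- divergence(f2, f1)
  expect_equal(rev$log2_ratio, -fwd$log2_ratio, tolerance = 1e-12)
  expect_equal(rev$delta, -fwd$delta, tolerance = 1e-12)
  expect_equal(rev$euclidean, fwd$euclidean, tolerance = 1e-12)
  expect_identical(rev$direction,
                   ifelse(fwd$direction == "pop1", "pop2",
                          ifelse(fwd$direction == "pop2", "pop1", "equal")))
})

test_that("the composite is monotone in each coordinate's magnitude", {
  r <- 0.8
  deltas <- seq(0, 1, by = 0.05)
  e_by_delta <- sqrt(r^2 + deltas^2)
  expect_true(all(diff(e_by_delta) >= 0))
  expect_true(all(e_by_delta >= r))
  d <- divergence(c(0.6, 0.7), c(0.4, 0.3))
  expect_true(all(d$euclidean >= pmax(abs(d$log2_ratio), abs(d$delta))))
})

test_that("continuity correction touches only boundary frequencies", {
  set.seed(5)
  f1 <- runif(30, 0.01, 0.99); f2 <- runif(30, 0.01, 0.99)
  corrected <- divergence(f1, f2, n1 = 50, n2 = 50)
  raw <- data.frame(log2_ratio = log2(f1 / f2), delta = f1 - f2)
  expect_equal(corrected$log2_ratio, raw$log2_ratio, tolerance = 1e-12)
  expect_equal(corrected$delta, raw$delta, tolerance = 1e-12)

  # a population-private allele: f2 = 0 gets half an allele count
  edge <- divergence(0.3, 0, n1 = 40, n2 = 40)
  expect_equal(edge$log2_ratio, log2(0.3 / (0.5 / 81)), tolerance = 1e-12)
  expect_equal(edge$delta, 0.3, tolerance = 1e-12)
  expect_true(is.finite(edge$euclidean))

  full <- divergence(1, 0.5, n1 = 40, n2 = 40)
  expect_equal(full$log2_ratio, log2((80.5 / 81) / 0.5), tolerance = 1e-12)

  expect_error(divergence(0, 0.5), "sample sizes needed")
  inf <- divergence(0, 0.5, continuity_correct = FALSE)
  expect_identical(inf$log2_ratio, -Inf)
})

test_that("the screen filters on evidence, strict threshold, and ranks by E", {
  recs <- divergence(
    f_pop1 = c(0.9, 0.6, 0.5, 0.52, 0.8, 0.3, 0.45, 0.9, 0.2, 0.35),
    f_pop2 = c(0.1, 0.4, 0.5, 0.48, 0.3, 0.7, 0.55, 0.5, 0.6, 0.35),
    ids = sprintf("rs%02d", 1:10))
  ann <- make_ann(sprintf("rs%02d", 1:10),
                  effect = rep("A", 10), non_effect = rep("G", 10),
                  evidence = c("1A", "2B", "1A", "1B", "3", "2A", "1A", "1B",
                               "2B", "4"))
  got <- suppressMessages(screen_of_interest(recs, ann))

  # independent brute-force filter
  keep <- ann$evidence_level %in% c("1A", "1B", "2A", "2B") &
    recs$euclidean > 0.5
  expect_setequal(got$id, recs$id[keep])
  expect_true(all(diff(got$euclidean) <= 0))

  # E exactly at the threshold is excluded
  at_thr <- recs; at_thr$euclidean <- rep(0.5, 10)
  expect_equal(nrow(suppressMessages(screen_of_interest(at_thr, ann))), 0L)

  # unjoined records are excluded and logged
  recs2 <- recs; recs2$id[1] <- "rs_orphan"
  expect_message(out <- screen_of_interest(recs2, ann), "without annotation")
  expect_identical(attr(out, "unjoined"), "rs_orphan")
  expect_false("rs_orphan" %in% out$id)
})

test_that("equal-E ties rank lexicographically by rsID", {
  recs <- divergence(c(0.9, 0.9), c(0.1, 0.1), ids = c("rsB", "rsA"))
  ann <- make_ann(c("rsB", "rsA"), effect = c("A", "A"),
                  non_effect = c("G", "G"))
  got <- screen_of_interest(recs, ann)
  expect_identical(got$id, c("rsA", "rsB"))
})

test_that("cohort effect-allele frequencies match the admixture expectation", {
  st <- simulate_study(tiny_cfg(M = 600L, n = 100L, seed = 71L))
  f <- effect_allele_frequencies(st$gm, st$manifest, c("antioquia", "choco"))
  for (pop in c("antioquia", "choco")) {
    rows <- grep(paste0("^", pop), rownames(st$truth))
    expected <- colMeans(st$truth[rows, ] %*% t(st$panel$freq))
    observed <- if (pop == "antioquia") f$f_pop1 else f$f_pop2
    se <- sqrt(expected * (1 - expected) / (2 * length(rows)))
    expect_lt(mean(abs(observed - expected)), 3 * mean(se))
  }
})
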