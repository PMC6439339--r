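test_that("MAF folds the counted-allele frequency and skips missing calls", {
  gm <- make_gm(matrix(c(0L, 1L, 2L,
                         2L, 2L, 2L,
                         2L, 1L, NA), nrow = 3))
  maf <- compute_maf(gm)
  expect_equal(maf$freq, c(0.5, 1, 0.75))
  expect_equal(maf$maf, c(0.5, 0, 0.25))
  expect_equal(maf$n_used, c(3L, 3L, 2L))

  all_missing <- make_gm(matrix(NA_integer_, 2, 1))
  out <- compute_maf(all_missing)
  expect_false(out$defined)
  expect_true(is.na(out$maf))
})

test_that("Wright's F_ST matches direct arithmetic of the variance formula", {
  expect_equal(compute_fst(c(0.3, 0.3, 0.3))$fst, 0, tolerance = 1e-12)
  expect_equal(compute_fst(c(0, 1))$fst, 1, tolerance = 1e-12)
  # pbar = 0.3, sigma2 = 0.01 (divide by N), denominator 0.21
  expect_equal(compute_fst(c(0.2, 0.4))$fst, 0.01 / 0.21, tolerance = 1e-12)
  # sample-variance convention doubles sigma2 for two populations
  expect_equal(compute_fst(c(0.2, 0.4), var_method = "sample")$fst,
               0.02 / 0.21, tolerance = 1e-12)
})

test_that("F_ST is invariant to population relabeling and allele complementation", {
  set.seed(4)
  f <- matrix(runif(60, 0.05, 0.95), nrow = 12)
  base <- compute_fst(f)$fst
  expect_equal(compute_fst(f[, sample(ncol(f))])$fst, base, tolerance = 1e-12)
  expect_equal(compute_fst(1 - f)$fst, base, tolerance = 1e-12)
})

test_that("F_ST is undefined for monomorphic variants and single populations", {
  expect_error(compute_fst(matrix(0.4, 3, 1)), "at least 2 populations")
  out <- compute_fst(rbind(c(0, 0, 0), c(1, 1, 1), c(0.2, 0.4, 0.6)))
  expect_true(all(is.na(out$fst[1:2])))
  expect_identical(out$defined, c(FALSE, FALSE, TRUE))
  expect_equal(mean_fst(out), out$fst[3])
})

test_that("mean F_ST between pure-component cohorts rises with Balding-Nichols F", {
  fst_at <- function(f) {
    cfg <- sim_config(M = 2000L, cohorts = list(
      list(name = "pop1", n = 60L, alpha = c(500, 0.01, 0.01), role = "study"),
      list(name = "pop2", n = 60L, alpha = c(0.01, 500, 0.01), role = "study")
    ), diff = f, seed = 19L)
    st <- simulate_study(cfg)
    freqs <- allele_freq_by_pop(st$gm, st$manifest)
    mean_fst(compute_fst(freqs))
  }
  vals <- vapply(c(0.01, 0.05, 0.2), fst_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("LD pruning keeps singletons and resolves duplicates deterministically", {
  single <- make_gm(matrix(c(0L, 1L, 2L, 1L), ncol = 1))
  expect_identical(ld_prune(single), variant_ids(single))

  # identical columns: r2 = 1, equal MAF -> tie broken to the later position
  x <- c(0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L)
  dup <- make_gm(cbind(x, x))
  expect_identical(ld_prune(dup), "rs0001")

  # strongly correlated pair with unequal MAF -> lower-MAF member pruned
  a <- rep(c(0L, 1L, 2L, 0L), 4)            # MAF 0.375
  b <- a; b[4] <- 2L                         # MAF 0.4375, r2 ~ 0.70 with a
  stopifnot(cor(a, b)^2 > 0.5)
  gm <- make_gm(cbind(a, b))
  expect_identical(ld_prune(gm), "rs0002")
})

test_that("windowed pruning matches a brute-force greedy oracle on a small instance", {
  set.seed(99)
  n <- 30L
  d <- matrix(sample(0:2, n * 60, replace = TRUE), nrow = n)
  base <- d[, 10]
  for (j in 11:12) {                      # correlated triple, pairwise r2 ~ 0.9
    col <- base
    flip <- sample(n, 2)
    col[flip] <- sample(0:2, 2, replace = TRUE)
    d[, j] <- col
  }
  gm <- make_gm(d)
  maf <- compute_maf(gm)$maf

  greedy_oracle <- function(d, maf, thr) {
    alive <- rep(TRUE, ncol(d))
    repeat {
      idx <- which(alive)
      r2 <- suppressWarnings(cor(d[, idx, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0; diag(r2) <- 0
      if (max(r2) <= thr) break
      hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      a <- idx[hit[1]]; b <- idx[hit[2]]
      drop_v <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
      alive[drop_v] <- FALSE
    }
    which(alive)
  }
  expect_identical(ld_prune(gm, 0.5, window = 50L, step = 5L),
                   variant_ids(gm)[greedy_oracle(d, maf, 0.5)])
})

test_that("zero-variance variants never trigger pruning", {
  d <- cbind(rep(1L, 6), c(0L, 1L, 2L, 0L, 1L, 2L))
  gm <- make_gm(d)
  expect_identical(ld_prune(gm), c("rs0001", "rs0002"))
})

test_that("IBS distance matches allelic Hamming counts", {
  gm <- make_gm(rbind(a = c(0L, 1L, 2L), b = c(1L, 1L, 0L), c = c(0L, 1L, 2L)))
  dm <- ibs_distance(gm)
  expect_equal(diag(dm), c(a = 0, b = 0, c = 0))
  expect_equal(dm["a", "b"], (1 + 0 + 2) / 6)
  expect_equal(dm["a", "c"], 0)
  expect_equal(dm, t(dm))

  maximal <- make_gm(rbind(a = c(0L, 0L), b = c(2L, 2L)))
  expect_equal(ibs_distance(maximal)["a", "b"], 1)
})

test_that("IBS uses pairwise-complete variants and rejects empty overlap", {
  gm <- make_gm(rbind(a = c(0L, 1L, 2L, NA), b = c(1L, 1L, 0L, 2L)))
  expect_equal(ibs_distance(gm)["a", "b"], (1 + 0 + 2) / 6)
  disjoint <- make_gm(rbind(a = c(NA, 0L), b = c(1L, NA)))
  expect_error(ibs_distance(disjoint), "no shared non-missing")
})

test_that("classical MDS reproduces embeddable distance matrices", {
  # all-zero distances -> all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(suppressWarnings(classical_mds(z)) == 0))

  # equilateral triangle: recovered pairwise distances equal 1
  tri <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(tri) <- 0
  coords <- classical_mds(tri)
  rec <- as.matrix(dist(coords))
  expect_equal(rec[upper.tri(rec)], rep(1, 3), tolerance = 1e-9)

  # any 2-D Euclidean configuration is recovered exactly (up to rigid motion)
  set.seed(8)
  pts <- matrix(rnorm(12), ncol = 2, dimnames = list(paste0("p", 1:6), NULL))
  dm <- as.matrix(dist(pts))
  rec2 <- as.matrix(dist(classical_mds(dm)))
  expect_equal(rec2, dm, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("MDS sign convention makes coordinates deterministic", {
  set.seed(15)
  pts <- matrix(rnorm(20), ncol = 2, dimnames = list(paste0("p", 1:10), NULL))
  dm <- as.matrix(dist(pts))
  c1 <- classical_mds(dm)
  c2 <- classical_mds(dm)
  expect_identical(c1, c2)
  expect_true(all(apply(c1, 2, function(ax) ax[which(abs(ax) > 1e-12)[1]] > 0)))
})

test_that("MDS separates simulated cohorts (positive silhouette)", {
  cfg <- sim_config(M = 1000L, cohorts = list(
    list(name = "pop1", n = 30L, alpha = c(500, 0.01, 0.01), role = "study"),
    list(name = "pop2", n = 30L, alpha = c(0.01, 500, 0.01), role = "study")
  ), diff = 0.1, seed = 23L)
  st <- simulate_study(cfg)
  dm <- ibs_distance(st$gm)
  coords <- suppressWarnings(classical_mds(dm))
  labels <- as.integer(factor(st$manifest$population[
    match(rownames(coords), st$manifest$sample)]))
  sil <- cluster::silhouette(labels, dist(coords))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("allele frequency table assembles per-population frequencies with F_ST", {
  st <- simulate_study(tiny_cfg(M = 200L, n = 25L, seed = 29L))
  aft <- allele_frequency_table(st$gm, st$manifest)
  expect_identical(names(aft),
                   c("id", "antioquia", "choco", "maf", "pbar", "sigma2", "fst"))
  expect_equal(aft$pbar, (aft$antioquia + aft$choco) / 2, tolerance = 1e-12)
  expect_true(all(aft$maf <= 0.5 + 1e-12, na.rm = TRUE))
  expect_true(all(aft$fst >= 0 & aft$fst <= 1, na.rm = TRUE))
})
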