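test_that("composite r2 matches the hand-derived value for identical loci", {
  # identical HW dosage vectors {0,1,1,2}: raw Delta = 0.25, denominator
  # 0.0625; the S/(S-1) Burrows correction at S = 4 scales Delta by 4/3
  g <- make_geno(cbind(c(0L, 1L, 1L, 2L), c(0L, 1L, 1L, 2L)))
  b <- burrows_r2(g)
  expect_equal(b$pairs$r2, (4 / 3)^2 * 0.25^2 / 0.0625, tolerance = 1e-12)
  expect_equal(b$pairs$s, 4)
})

test_that("pairs with a fixed locus are excluded and missing data are pairwise-complete", {
  d <- cbind(c(0L, 1L, 1L, 2L, 0L), rep(1L, 5), c(0L, 0L, 0L, 0L, 0L))
  g <- make_geno(d)
  b <- burrows_r2(g)
  # locus_3 fixed: only the (1,2) pair remains
  expect_equal(nrow(b$pairs), 1)
  expect_setequal(c(b$pairs$locus1, b$pairs$locus2), c("locus_1", "locus_2"))
  d2 <- cbind(c(0L, 1L, 1L, 2L, NA), c(0L, 1L, 2L, NA, 1L))
  b2 <- burrows_r2(make_geno(d2))
  expect_equal(b2$pairs$s, 3) # individuals complete at both loci
})

test_that("mean r2 of independent loci matches the sampling expectation", {
  # 6 replicate panels of 60 independent loci at S = 1000; the Monte-Carlo
  # SE of the replicate mean is ~1.7e-5, so 5e-5 is a 3-SE band
  set.seed(101)
  m <- replicate(6, {
    p <- runif(60, 0.2, 0.8)
    burrows_r2(make_geno(sapply(p, function(pp) rbinom(1000, 2, pp))))$mean_r2
  })
  expect_lt(abs(mean(m) - (1 / 1000 + 3.19 / 1000^2)), 5e-5)
})

test_that("the drift-to-Ne inversion matches its closed form and the INF rule", {
  # r2_drift = 0.02 in the S >= 30 regime
  expect_equal(popgenmon:::ne_from_drift(0.02, 40),
               (1 / 3 + sqrt(1 / 9 - 2.76 * 0.02)) / 0.04, tolerance = 1e-12)
  expect_equal(round(popgenmon:::ne_from_drift(0.02, 40), 2), 14.24)
  expect_identical(popgenmon:::ne_from_drift(0, 40), Inf)
  expect_identical(popgenmon:::ne_from_drift(-0.001, 40), Inf)
  expect_identical(popgenmon:::ne_from_drift(-0.001, 10), Inf)
})

test_that("ld_ne is monotone: more disequilibrium means smaller Ne", {
  # two samples from Wright-Fisher populations of different size
  sim_small <- simulate_wright_fisher(30, n_loci = 120, generations = 20,
    schedule = tibble::tibble(generation = 20, deme = 1, size = 30),
    mode = "individual", seed = 201)
  sim_big <- simulate_wright_fisher(300, n_loci = 120, generations = 20,
    schedule = tibble::tibble(generation = 20, deme = 1, size = 30),
    mode = "individual", seed = 202)
  e_small <- ld_ne(sim_small$genotypes, ci = "none")
  e_big <- ld_ne(sim_big$genotypes, ci = "none")
  expect_gt(e_small[["mean_r2"]], e_big[["mean_r2"]])
  expect_lt(e_small$ne, e_big$ne)
})

test_that("ld_ne is invariant to locus order and allele-label swaps", {
  sim <- simulate_wright_fisher(50, n_loci = 60, generations = 15,
    schedule = tibble::tibble(generation = 15, deme = 1, size = 25),
    mode = "individual", seed = 301)
  g <- sim$genotypes
  base <- ld_ne(g, ci = "none")
  shuffled <- gm_subset(g, loci = sample(n_loci(g)))
  flip <- geno_matrix(2L - g$dosages, samples = g$samples)
  expect_equal(ld_ne(shuffled, ci = "none")$ne, base$ne, tolerance = 1e-10)
  expect_equal(ld_ne(flip, ci = "none")$ne, base$ne, tolerance = 1e-10)
})

test_that("jackknife CI brackets the point estimate", {
  sim <- simulate_wright_fisher(50, n_loci = 80, generations = 15,
    schedule = tibble::tibble(generation = 15, deme = 1, size = 25),
    mode = "individual", seed = 401)
  est <- ld_ne(sim$genotypes, ci = "jackknife")
  expect_lte(est$lower, est$ne)
  expect_gte(est$upper, est$ne)
})

test_that("jackknife CIs cover the simulated truth at close to nominal rate", {
  covered <- vapply(1:50, function(r) {
    sim <- simulate_wright_fisher(50, n_loci = 100, generations = 20,
      schedule = tibble::tibble(generation = 20, deme = 1, size = 30),
      mode = "individual", seed = 40000 + r)
    est <- ld_ne(sim$genotypes, ci = "jackknife")
    est$lower <= 50 && est$upper >= 50
  }, logical(1))
  expect_gte(sum(covered), 40) # >= 80% of 50 at nominal 95%
})

test_that("temporal F statistic matches hand values and symmetry", {
  # x = (0.5, 0.5), y = (0.7, 0.3): both allele terms are 0.16
  fc_pair <- function(x, y) {
    xs <- c(x, 1 - x); ys <- c(y, 1 - y)
    mean((xs - ys)^2 / ((xs + ys) / 2 - xs * ys))
  }
  expect_equal(fc_pair(0.5, 0.7), 0.16, tolerance = 1e-12)
  # via genotype matrices: g0 with p = 0.5 (n=5), gt with p = 0.7 (n=5)
  g0 <- make_geno(matrix(c(2L, 2L, 1L, 0L, 0L), 5, 1))
  gt <- make_geno(matrix(c(2L, 2L, 2L, 1L, 0L), 5, 1))
  fc <- temporal_fc(g0, gt)
  expect_equal(fc$fc_mean, 0.16, tolerance = 1e-12)
  # symmetry in the two samples
  expect_equal(temporal_fc(gt, g0)$fc_mean, fc$fc_mean, tolerance = 1e-12)
  # identical frequencies -> 0
  expect_equal(temporal_fc(g0, g0)$fc_mean, 0)
  # both samples fixed for the same allele -> locus skipped
  fix0 <- make_geno(matrix(2L, 4, 2))
  fix1 <- make_geno(cbind(rep(2L, 4), c(2L, 2L, 1L, 2L)))
  out <- temporal_fc(fix0, fix1)
  expect_true(is.na(out$per_locus$fc[1]))
  expect_equal(out$df, 1)
})

test_that("temporal Ne matches the plan-II moment formula and the INF rule", {
  est <- temporal_ne(0.16, s0 = 25, st = 25, t = 4)
  expect_equal(est$ne, 4 / (2 * (0.16 - 0.02 - 0.02)), tolerance = 1e-12)
  expect_equal(round(est$ne, 2), 16.67)
  # sampling correction at least as large as Fc -> infinite
  inf <- temporal_ne(0.03, s0 = 25, st = 25, t = 4)
  expect_identical(inf$ne, Inf)
  expect_error(temporal_ne(0.1, s0 = 25, st = 25, t = 0), "t")
  # Ne increases with t at fixed Fc
  expect_gt(temporal_ne(0.16, 25, 25, t = 8)$ne,
            temporal_ne(0.16, 25, 25, t = 4)$ne)
})

test_that("drift-free samples yield infinite or effectively unbounded Ne", {
  # large independent draws from fixed frequencies: the drift signal is 0,
  # so estimates are infinite or orders of magnitude beyond the sample
  set.seed(77)
  ld <- tmp <- numeric(6)
  for (r in 1:6) {
    p <- runif(150, 0.2, 0.8)
    g0 <- make_geno(sapply(p, function(pp) rbinom(400, 2, pp)))
    gt <- make_geno(sapply(p, function(pp) rbinom(400, 2, pp)))
    ld[r] <- ld_ne(g0, ci = "none")$ne
    tmp[r] <- ne_temporal(g0, gt, t = 5)$ne
  }
  expect_true(all(ld > 2000))
  expect_true(all(tmp > 2000))
  expect_true(any(is.infinite(ld)))
  expect_true(any(is.infinite(tmp)))
})

test_that("Ne/Na ratios reproduce the published worked examples", {
  expect_equal(ne_na_ratio(ne_temporal = 254, na = 1317)$ratio, 0.19)
  r <- ne_na_ratio(ne_ld = 10, na = 50)
  expect_equal(r$ratio, 0.20)
  expect_equal(r$method_used, "LD")
  expect_equal(ne_na_ratio(ne_ld = 80, na = 80)$ratio, 1.0)
  # temporal preferred when finite
  expect_equal(ne_na_ratio(ne_ld = 10, ne_temporal = 20, na = 100)$ratio, 0.2)
  expect_equal(ne_na_ratio(ne_ld = 10, ne_temporal = Inf, na = 100)$ratio, 0.1)
  expect_error(ne_na_ratio(ne_ld = Inf, na = 100), "undefined|finite")
})

test_that("tidy() returns the one-row estimate summary", {
  est <- temporal_ne(0.16, s0 = 25, st = 25, t = 4, df = 100)
  out <- tidy(est)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$method, "temporal")
  expect_lt(out$ci_lower, est$ne)
  expect_gt(out$ci_upper, est$ne)
})
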