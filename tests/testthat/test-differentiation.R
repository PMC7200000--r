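test_that("theta is 1 for populations fixed for opposite alleles", {
  g <- make_two_pop(matrix(2L, 10, 3), matrix(0L, 10, 3))
  expect_equal(wc_theta(g)$theta, 1)
})

test_that("theta is non-positive for one population split under two labels", {
  set.seed(13)
  d <- sapply(runif(40, 0.2, 0.8), function(p) rbinom(30, 2, p))
  g <- make_geno(d, populations = rep(c("A", "B"), 15))
  expect_lte(wc_theta(g)$theta, 0.02)
})

test_that("vectorized theta matches the per-locus component oracle to 1e-12", {
  # the spec's 2-population toy plus randomized multi-locus cases with
  # missing data and three populations
  d1 <- matrix(c(2L, 2L, 1L, 1L, 0L), 5, 1)
  d2 <- matrix(c(0L, 0L, 0L, 1L, 1L), 5, 1)
  g <- make_two_pop(d1, d2)
  comp <- wc_theta(g)$components
  oracle <- wc_oracle_locus(list(d1[, 1], d2[, 1]))
  expect_equal(comp$a, unname(oracle["a"]), tolerance = 1e-12)
  expect_equal(comp$b, unname(oracle["b"]), tolerance = 1e-12)
  expect_equal(comp$c, unname(oracle["c"]), tolerance = 1e-12)
  expect_equal(wc_theta(g)$theta,
               oracle["a"] / sum(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(31)
  for (rep in 1:5) {
    pops <- rep(c("A", "B", "C"), times = c(8, 11, 6))
    d <- sapply(runif(12, 0.1, 0.9), function(p) rbinom(25, 2, p))
    d[sample(length(d), 20)] <- NA
    g <- make_geno(d, populations = pops)
    fit <- wc_theta(g)
    for (k in seq_len(nrow(fit$components))) {
      loc <- fit$components$locus_id[k]
      dl <- g$dosages[, loc]
      oracle <- wc_oracle_locus(split(dl, pops))
      expect_equal(fit$components$a[k], unname(oracle["a"]), tolerance = 1e-12)
      expect_equal(fit$components$b[k], unname(oracle["b"]), tolerance = 1e-12)
      expect_equal(fit$components$c[k], unname(oracle["c"]), tolerance = 1e-12)
    }
  }
})

test_that("theta is invariant to allele-label swap and individual order", {
  set.seed(17)
  d <- sapply(runif(20, 0.1, 0.9), function(p) rbinom(24, 2, p))
  pops <- rep(c("A", "B"), each = 12)
  g <- make_geno(d, populations = pops)
  swapped <- make_geno(2L - d, populations = pops)
  perm <- sample(24)
  reordered <- make_geno(d[perm, ], populations = pops[perm])
  base <- wc_theta(g)$theta
  expect_equal(wc_theta(swapped)$theta, base, tolerance = 1e-12)
  expect_equal(wc_theta(reordered)$theta, base, tolerance = 1e-12)
})

test_that("ratio-of-sums theta reduces to the single-locus value when only one locus is polymorphic", {
  d1 <- cbind(c(2L, 2L, 1L, 1L, 0L), rep(1L, 5), rep(0L, 5))
  d2 <- cbind(c(0L, 0L, 0L, 1L, 1L), rep(1L, 5), rep(0L, 5))
  # loci 2-3 are monomorphic across populations or carry no among-pop signal:
  # locus 3 is monomorphic everywhere and must be skipped
  g_multi <- make_two_pop(d1, d2)
  g_single <- make_two_pop(d1[, 1, drop = FALSE], d2[, 1, drop = FALSE])
  skip_set <- wc_theta(g_multi)$components$locus_id
  expect_false("locus_3" %in% skip_set)
  g_only <- make_two_pop(cbind(d1[, 1], rep(0L, 5)), cbind(d2[, 1], rep(0L, 5)))
  expect_equal(wc_theta(g_only)$theta, wc_theta(g_single)$theta)
})

test_that("theta decreases with migration in a two-deme island model", {
  thetas <- vapply(c(0.002, 0.02, 0.2), function(m) {
    sim <- simulate_wright_fisher(c(100, 100), n_loci = 300,
                                  generations = 150, migration = m,
                                  seed = 71)
    wc_theta(sim$genotypes)$theta
  }, numeric(1))
  expect_true(all(diff(thetas) < 0))
  expect_gt(thetas[1], 0.1)
  expect_lt(thetas[3], 0.05)
})

test_that("permutation p-values follow the add-one rule", {
  g <- make_two_pop(matrix(2L, 8, 4), matrix(0L, 8, 4))
  expect_equal(theta_permutation_test(g, c("A", "B"), n_perm = 999, seed = 1),
               1 / 1000)
  expect_gte(theta_permutation_test(g, c("A", "B"), n_perm = 99, seed = 1),
             0.01)
  expect_error(theta_permutation_test(g, c("A", "B"), n_perm = 50), "99")
})

test_that("Bonferroni correction divides the familywise level", {
  expect_equal(bonferroni_alpha(36, 0.05), 0.05 / 36)
  expect_equal(round(bonferroni_alpha(36, 0.05), 5), 0.00139)
  expect_equal(bonferroni_alpha(1, 0.05), 0.05)
  expect_equal(round(bonferroni_alpha(28, 0.05), 5), 0.00179)
})

test_that("theta_matrix assembles symmetric pairwise estimates", {
  set.seed(19)
  d <- sapply(runif(25, 0.2, 0.8), function(p) rbinom(30, 2, p))
  g <- make_geno(d, populations = rep(c("A", "B", "C"), each = 10))
  tm <- theta_matrix(g)
  expect_equal(tm$matrix, t(tm$matrix))
  expect_equal(nrow(tm$pairs), 3)
  expect_equal(tm$alpha_bonferroni, 0.05 / 3)
})

test_that("Mantel test recovers perfect positive and negative association", {
  sites <- tibble::tibble(site = c("a", "b", "c", "d"),
                          longitude = c(0, 0.05, 0.1, 0.2),
                          latitude = c(0, 0.02, 0.05, 0.1))
  geo <- geo_dist_km(sites)
  up <- mantel_test(geo, geo, n_perm = 99, seed = 1)
  expect_equal(up$r, 1, tolerance = 1e-10)
  neg <- mantel_test(max(geo) - geo - diag(max(geo), 4), geo,
                     n_perm = 99, seed = 1)
  expect_equal(neg$r, -1, tolerance = 1e-10)
  expect_error(mantel_test(geo[1:2, 1:2], geo[1:2, 1:2]), "3")
  asym <- geo
  asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(asym, geo), "symmetric")
})

test_that("great-circle distances are plausible", {
  sites <- tibble::tibble(site = c("x", "y"),
                          longitude = c(-122.42, -122.42),
                          latitude = c(37.60, 37.564))
  # 0.036 degrees of latitude is almost exactly 4 km
  expect_equal(geo_dist_km(sites)["x", "y"], 4.0, tolerance = 0.01)
})
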