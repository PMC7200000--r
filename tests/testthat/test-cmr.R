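test_that("augmentation bookkeeping is exact", {
  ds <- make_captures(rbind(c(1, 0), c(0, 1), c(1, 1)))
  aug <- build_augmented_data(ds, 10)
  expect_equal(aug$m_total, 10)
  expect_equal(nrow(aug$y), 10)
  expect_equal(sum(rowSums(aug$y) > 0), 3)
  expect_true(all(aug$y[4:10, ] == 0))
  expect_true(all(is.na(aug$male[4:10])))
  expect_true(all(is.na(aug$site[4:10])))
  # zero pseudo rows allowed
  expect_equal(nrow(build_augmented_data(ds, 3)$y), 3)
  expect_error(build_augmented_data(ds, 2), "smaller")
})

test_that("the behavioural covariate lags observed captures by one occasion", {
  ds <- make_captures(rbind(c(1, 0, 1), c(0, 1, 1)))
  aug <- build_augmented_data(ds, 4)
  expect_equal(aug$behav[1, ], c(0, 1, 0))
  expect_equal(aug$behav[2, ], c(0, 0, 1))
  expect_true(all(aug$behav[, 1] == 0))
})

test_that("covariate standardization uses the observed-data mean and SD", {
  ds <- make_captures(rbind(c(1, 0), c(1, 1)), svl = c(300, 500),
                      temps = c(10, 20))
  aug <- build_augmented_data(ds, 5)
  expect_equal(mean(aug$svl_std[1:2]), 0)
  expect_equal(sd(aug$svl_std[1:2]), 1)
  expect_equal(mean(aug$temp_std[1, ]), 0)
})

test_that("posterior mode picks the most frequent value, ties to the smaller", {
  expect_equal(posterior_mode(c(2, 2, 3)), 2L)
  expect_equal(posterior_mode(rep(7, 10)), 7L)
  expect_equal(posterior_mode(c(1, 1, 2, 2)), 1L)
})

test_that("the HPDI is the shortest window holding the target mass", {
  expect_equal(hpdi(rep(3, 25)), c(3, 3))
  h <- hpdi(1:100, 0.95)
  expect_equal(h[2] - h[1], 94)
  # contains the mode of a unimodal sample
  set.seed(1)
  draws <- round(rnorm(2000, 50, 5))
  h2 <- hpdi(draws)
  m <- posterior_mode(draws)
  expect_true(h2[1] <= m && m <= h2[2])
  expect_error(hpdi(1:5), "20")
})

test_that("covariate evidence summarises the sign of the posterior", {
  expect_equal(covariate_evidence(rep(0.5, 10))$prob_sign, 1)
  ev <- covariate_evidence(c(rep(1, 90), rep(-1, 10)))
  expect_equal(ev$prob_sign, 0.9)
  expect_true(ev$strong)
  sym <- covariate_evidence(c(-(1:50), 1:50))
  expect_lt(abs(sym$prob_sign - 0.5), 0.02)
  expect_false(sym$strong)
})

test_that("sampler posterior matches exhaustive enumeration on a tiny pool", {
  # M = 6, D = 2, fixed p: the inclusion indicators of the 3 pseudo rows
  # are the only latent variables; psi integrates to a Beta function
  p_fix <- 0.4
  ds <- make_captures(rbind(c(1, 0), c(1, 1), c(0, 1)))
  aug <- build_augmented_data(ds, 6)
  exact <- vapply(0:3, function(k) {
    choose(3, k) * beta(3 + k + 1, 6 - 3 - k + 1) * ((1 - p_fix)^2)^k
  }, numeric(1))
  exact <- exact / sum(exact)
  fit <- fit_cmr(aug, cmr_config(chains = 2, n_iter = 15000, burnin = 500,
                                 thin = 1, adapt = 500, seed = 11,
                                 fixed_p = p_fix))
  post <- as.numeric(table(factor(fit$n_draws[, 1], levels = 3:6))) /
    nrow(fit$n_draws)
  expect_lt(max(abs(post - exact)), 0.02)
})

test_that("with uninformative observations the pool prior is recovered", {
  # a second enumeration instance: one observed animal, p fixed, M = 12;
  # checks the induced augmentation prior (binomial thinning of the pool)
  p_fix <- 0.3
  ds <- make_captures(matrix(c(1, 0), 1, 2))
  aug <- build_augmented_data(ds, 12)
  k <- 0:11
  exact <- choose(11, k) * beta(1 + k + 1, 12 - 1 - k + 1) *
    ((1 - p_fix)^2)^k
  exact <- exact / sum(exact)
  fit <- fit_cmr(aug, cmr_config(chains = 2, n_iter = 15000, burnin = 500,
                                 thin = 1, adapt = 500, seed = 13,
                                 fixed_p = p_fix))
  post <- as.numeric(table(factor(fit$n_draws[, 1], levels = 1:12))) /
    nrow(fit$n_draws)
  expect_lt(max(abs(post - exact)), 0.02)
})

test_that("abundance draws respect the structural bounds", {
  sim <- simulate_capture_histories(c(A = 40, B = 30), 6, mean_p = 0.3,
                                    seed = 5)
  aug <- build_augmented_data(sim$data, 150)
  fit <- fit_cmr(aug, cmr_config(chains = 1, n_iter = 1500, burnin = 300,
                                 thin = 1, adapt = 300, seed = 2,
                                 covariates = "sex", random = character(0)))
  obs <- fit$n_observed_by_site
  expect_true(all(fit$n_draws[, "A"] >= obs["A"]))
  expect_true(all(fit$n_draws[, "B"] >= obs["B"]))
  expect_true(all(rowSums(fit$n_draws) <= 150))
  # tidy/glance structure
  td <- tidy(fit)
  expect_true(all(c("parameter", "estimate", "hpdi_lower", "hpdi_upper")
                  %in% names(td)))
  expect_equal(glance(fit)$sites, 2)
})

test_that("a single-site fit recovers a known simulated abundance", {
  sim <- simulate_capture_histories(c(A = 100), 10, mean_p = 0.2, seed = 71)
  aug <- build_augmented_data(sim$data, 300)
  fit <- fit_cmr(aug, cmr_config(chains = 1, n_iter = 3000, burnin = 500,
                                 thin = 1, adapt = 300, seed = 7,
                                 covariates = character(0),
                                 random = character(0)))
  n <- fit$n_draws[, 1]
  h <- hpdi(n)
  expect_true(h[1] <= 100 && 100 <= h[2])
  expect_lt(abs(posterior_mode(n) - 100), 20)
})

test_that("complete detection collapses the posterior onto the observed count", {
  sim <- simulate_capture_histories(c(A = 30), 6, mean_p = 0.9999999,
                                    seed = 9)
  aug <- build_augmented_data(sim$data, 60)
  fit <- fit_cmr(aug, cmr_config(chains = 1, n_iter = 1000, burnin = 200,
                                 thin = 1, adapt = 200, seed = 3,
                                 fixed_p = 0.9999))
  expect_true(all(fit$n_draws[, 1] == 30))
})

test_that("flat data give centred coefficients with weak sign evidence", {
  # the sign-evidence of any single null dataset is roughly uniform on
  # [0.5, 1], so the no-signal property is asserted on the average over
  # replicate datasets
  stats <- vapply(1:3, function(r) {
    sim <- simulate_capture_histories(c(A = 60), 8, mean_p = 0.3,
                                      seed = 17 + r)
    aug <- build_augmented_data(sim$data, 140)
    fit <- fit_cmr(aug, cmr_config(chains = 1, n_iter = 1500, burnin = 400,
                                   thin = 1, adapt = 300, seed = 4 + r,
                                   covariates = "temp",
                                   random = character(0)))
    b <- as.matrix(fit$draws[[1]])[, "beta_temp"]
    c(mean(b), covariate_evidence(b)$prob_sign)
  }, numeric(2))
  expect_lt(mean(abs(stats[1, ])), 0.5)
  expect_lt(mean(stats[2, ]), 0.92)
})

test_that("sex-ratio posterior flags a strongly male-biased population", {
  sim <- simulate_capture_histories(c(A = 150), 10, mean_p = 0.3,
                                    prop_male = 0.75, seed = 23)
  aug <- build_augmented_data(sim$data, 300)
  fit <- fit_cmr(aug, cmr_config(chains = 1, n_iter = 2500, burnin = 500,
                                 thin = 1, adapt = 300, seed = 6,
                                 covariates = "sex", random = character(0)))
  sr <- sex_ratio_posterior(fit, "A")
  expect_true(sr$biased)
  expect_gt(sr$hpdi[1], 1)
  expect_lt(sr$frac_undefined, 0.01)
})

test_that("Huggins fit obeys the Horvitz-Thompson identity and detection limits", {
  sim <- simulate_capture_histories(c(A = 200), 15, mean_p = 0.25,
                                    beta_sex = -0.8, seed = 3)
  fit <- huggins_fit(sim$data)
  expect_equal(fit$n_hat, sum(1 / fit$p_star), tolerance = 1e-9)
  expect_lt(abs(fit$n_hat - 200) / 200, 0.25)
  # p -> 1: estimate collapses to the observed count
  sim1 <- simulate_capture_histories(c(A = 25), 6, mean_p = 0.95, seed = 4)
  fit1 <- huggins_fit(sim1$data, effects = "occasion")
  expect_equal(fit1$n_hat, nrow(sim1$data$individuals), tolerance = 0.5)
  # an occasion with zero captures drops its free effect with a warning
  h <- rbind(c(1, 0, 1), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1))
  expect_warning(huggins_fit(make_captures(h), effects = "occasion"),
                 "zero captures")
})

test_that("sex-ratio regression handles collinear, flat and excluded inputs", {
  exact <- tibble::tibble(site = letters[1:4], na_modal = c(10, 20, 30, 40),
                          sex_ratio = c(1, 2, 3, 4))
  fit <- suppressWarnings(na_sexratio_regression(exact)) # perfect-fit note
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
  set.seed(2)
  flat <- tibble::tibble(site = letters[1:6], na_modal = 1:6 * 10,
                         sex_ratio = 1 + rnorm(6, 0, 1e-3))
  ffit <- na_sexratio_regression(flat)
  expect_lt(abs(ffit$slope), 0.01)
  expect_gt(ffit$p_value, 0.1)
  excl <- suppressWarnings(na_sexratio_regression(exact, exclude = "d"))
  expect_equal(excl$n_sites, 3)
  expect_error(na_sexratio_regression(exact, exclude = c("a", "b")), "3")
})
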