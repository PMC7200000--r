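#' Configuration for the Bayesian capture-mark-recapture model
#'
#' Defaults follow the monitoring study design this package implements:
#' 5 chains of 200,000 sampling iterations after 10,000 burn-in, thinned by
#' 10; Uniform(0,1) priors on mean capture probability and the inclusion
#' probability, Normal(0, 3.16) priors on covariate effects, and
#' half-Cauchy(1) priors on random-effect standard deviations. Simulation
#' studies and tests pass much shorter chains explicitly.
#'
#' @param chains number of MCMC chains.
#' @param n_iter sampling iterations per chain (after burn-in).
#' @param burnin burn-in iterations discarded per chain.
#' @param thin thinning interval.
#' @param adapt JAGS adaptation iterations.
#' @param seed integer seed (drives per-chain RNG).
#' @param covariates character subset of
#'   `c("temp", "sex", "svl", "behavior")` to include as fixed effects.
#' @param random character subset of `c("site", "date", "ind")`; the site
#'   effect only applies to multi-site pools.
#' @param fixed_p if non-`NULL`, capture probability is fixed at this value
#'   and all covariates/random effects are dropped (used for exact-oracle
#'   checks and prior-predictive tests).
#' @param beta_sd prior SD for covariate effects.
#' @param sigma_scale half-Cauchy scale for random-effect SDs.
#' @return a list of class `cmr_config`.
#' @export
cmr_config <- function(chains = 5, n_iter = 200000, burnin = 10000,
                       thin = 10, adapt = 1000, seed = 1,
                       covariates = c("temp", "sex", "svl", "behavior"),
                       random = c("date", "ind", "site"),
                       fixed_p = NULL, beta_sd = 3.16, sigma_scale = 1) {
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates, c("temp", "sex", "svl", "behavior"),
                            several.ok = TRUE)
  }
  if (length(random) > 0) {
    random <- match.arg(random, c("date", "ind", "site"), several.ok = TRUE)
  }
  structure(list(chains = chains, n_iter = n_iter, burnin = burnin,
                 thin = thin, adapt = adapt, seed = seed,
                 covariates = covariates, random = random, fixed_p = fixed_p,
                 beta_sd = beta_sd, sigma_scale = sigma_scale),
            class = "cmr_config")
}

# assemble the JAGS model string for a given augmented dataset + config
build_jags_model <- function(aug, config) {
  multi <- length(aug$site_levels) > 1
  cov <- if (is.null(config$fixed_p)) config$covariates else character()
  ran <- if (is.null(config$fixed_p)) config$random else character()
  if (!multi) ran <- setdiff(ran, "site")
  tau_beta <- 1 / config$beta_sd^2

  lp <- c("lp_bar")
  if (multi && "site" %in% ran) lp <- c(lp, "a[g[i]]")
  if ("date" %in% ran) lp <- c(lp, "b[g[i], d]")
  if ("ind" %in% ran) lp <- c(lp, "e[i]")
  if ("temp" %in% cov) lp <- c(lp, "beta_temp * temp[g[i], d]")
  if ("sex" %in% cov) lp <- c(lp, "beta_sex * male[i]")
  if ("svl" %in% cov) lp <- c(lp, "beta_svl * svl[i]")
  if ("behavior" %in% cov) lp <- c(lp, "beta_behav * behav[i, d]")

  lines <- c("model {", "  psi ~ dunif(0, 1)")
  if (is.null(config$fixed_p)) {
    lines <- c(lines, "  pbar ~ dunif(0, 1)", "  lp_bar <- logit(pbar)")
  }
  if (multi) {
    lines <- c(lines,
      "  pi[1:S] ~ ddirch(alpha[])")
  }
  sex_model <- "sex" %in% cov || aug_has_missing_sex(aug)
  if (sex_model) {
    lines <- c(lines, "  for (s in 1:S) { rho[s] ~ dunif(0, 1) }")
  }
  for (bt in intersect(cov, c("temp", "sex", "svl", "behavior"))) {
    nm <- c(temp = "beta_temp", sex = "beta_sex", svl = "beta_svl",
            behavior = "beta_behav")[[bt]]
    lines <- c(lines, sprintf("  %s ~ dnorm(0, %.6f)", nm, tau_beta))
  }
  hc <- sprintf("dt(0, %.6f, 1) T(0,)", 1 / config$sigma_scale^2)
  if (multi && "site" %in% ran) {
    lines <- c(lines,
      sprintf("  sigma_site ~ %s", hc),
      "  tau_site <- pow(sigma_site, -2)",
      "  for (s in 1:S) { a[s] ~ dnorm(0, tau_site) }")
  }
  if ("date" %in% ran) {
    lines <- c(lines,
      sprintf("  sigma_date ~ %s", hc),
      "  tau_date <- pow(sigma_date, -2)",
      "  for (s in 1:S) { for (d in 1:D) { b[s, d] ~ dnorm(0, tau_date) } }")
  }
  if ("ind" %in% ran) {
    lines <- c(lines,
      sprintf("  sigma_ind ~ %s", hc),
      "  tau_ind <- pow(sigma_ind, -2)",
      "  for (i in 1:M) { e[i] ~ dnorm(0, tau_ind) }")
  }
  lines <- c(lines, "  for (i in 1:M) {", "    z[i] ~ dbern(psi)")
  if (multi) lines <- c(lines, "    g[i] ~ dcat(pi[])")
  if (sex_model) lines <- c(lines, "    male[i] ~ dbern(rho[g[i]])")
  if ("svl" %in% cov) lines <- c(lines, "    svl[i] ~ dnorm(0, 1)")
  if (is.null(config$fixed_p)) {
    lines <- c(lines,
      "    for (d in 1:D) {",
      sprintf("      logit(p[i, d]) <- %s", paste(lp, collapse = " + ")),
      "      y[i, d] ~ dbern(z[i] * p[i, d] * active[g[i], d])",
      "    }")
  } else {
    lines <- c(lines,
      "    for (d in 1:D) {",
      sprintf("      y[i, d] ~ dbern(z[i] * %.8f * active[g[i], d])",
              config$fixed_p),
      "    }")
  }
  lines <- c(lines, "  }",
    "  for (s in 1:S) {",
    "    for (i in 1:M) { zs[i, s] <- z[i] * equals(g[i], s) }",
    "    N[s] <- sum(zs[, s])")
  if (sex_model) {
    lines <- c(lines,
      "    for (i in 1:M) { zms[i, s] <- z[i] * equals(g[i], s) * male[i] }",
      "    Nmale[s] <- sum(zms[, s])")
  }
  lines <- c(lines, "  }", "}")
  paste(lines, collapse = "\n")
}

aug_has_missing_sex <- function(aug) anyNA(aug$male)

#' Fit the Bayesian data-augmentation abundance model
#'
#' Closed-population multinomial N-mixture model fitted by MCMC (JAGS):
#' each pool member has a latent inclusion indicator `z_i ~ Bern(psi)` and,
#' in multi-site pools, a latent site `g_i ~ Cat(pi)` with a flat Dirichlet
#' prior; capture probability is modelled on the logit scale with fixed
#' effects of standardized air temperature, sex, standardized SVL and a
#' behavioural response to capture on the previous day, plus site, nested
#' site-by-date and individual normal random effects (half-Cauchy SD
#' priors). Unknown sexes are imputed from a per-site Bernoulli with a
#' uniform prior and missing standardized SVL from a standard normal.
#' Per-site abundance is `N_s = sum_i z_i [g_i = s]`.
#'
#' Convergence is summarised with the potential scale reduction factor and
#' effective sample size; a warning is raised if any monitored parameter
#' has PSRF > 1.1. If the posterior piles up at the pool capacity the fit
#' aborts with advice to raise `m_total`.
#'
#' @param aug an [build_augmented_data()] object.
#' @param config a [cmr_config()].
#' @param quiet suppress JAGS progress output.
#' @return object of class `cmr_posterior`: `draws` (coda `mcmc.list`),
#'   `n_draws` (matrix of per-site abundance draws), `nmale_draws`,
#'   `site_levels`, `diagnostics` (tibble), `config`.
#' @export
fit_cmr <- function(aug, config = cmr_config(), quiet = TRUE) {
  stopifnot(inherits(aug, "augmented_data"))
  d_per_site <- rowSums(aug$active)
  if (any(d_per_site < 2)) abort("every site needs at least 2 occasions")
  multi <- length(aug$site_levels) > 1
  model_str <- build_jags_model(aug, config)
  cov <- if (is.null(config$fixed_p)) config$covariates else character()
  ran <- if (is.null(config$fixed_p)) config$random else character()
  if (!multi) ran <- setdiff(ran, "site")
  sex_model <- "sex" %in% cov || aug_has_missing_sex(aug)

  data <- list(y = aug$y, M = aug$m_total, D = ncol(aug$y),
               S = length(aug$site_levels), active = aug$active)
  if (multi) {
    data$g <- aug$site
    data$alpha <- rep(1, length(aug$site_levels))
  } else {
    data$g <- rep(1L, aug$m_total)
  }
  if (sex_model) data$male <- aug$male
  if ("svl" %in% cov) data$svl <- aug$svl_std
  if ("temp" %in% cov) data$temp <- aug$temp_std
  if ("behavior" %in% cov) data$behav <- aug$behav
  if (!multi && !sex_model) {
    # g is wholly observed constant; JAGS treats it as data either way
  }

  monitors <- c("N", "psi")
  if (is.null(config$fixed_p)) monitors <- c(monitors, "pbar")
  cov_beta <- intersect(cov, c("temp", "sex", "svl"))
  monitors <- c(monitors,
                if (length(cov_beta) > 0) paste0("beta_", cov_beta),
                if ("behavior" %in% cov) "beta_behav",
                if (multi && "site" %in% ran) "sigma_site",
                if ("date" %in% ran) "sigma_date",
                if ("ind" %in% ran) "sigma_ind",
                if (sex_model) c("rho", "Nmale"))

  inits <- function(chain) {
    out <- list(z = rep(1L, aug$m_total),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = config$seed * 1000 + chain)
    out
  }
  jm <- rjags::jags.model(
    textConnection(model_str), data = data,
    inits = lapply(seq_len(config$chains), inits),
    n.chains = config$chains, n.adapt = config$adapt, quiet = quiet)
  if (config$burnin > 0) {
    update(jm, config$burnin, progress.bar = if (quiet) "none" else "text")
  }
  draws <- rjags::coda.samples(
    jm, monitors, n.iter = config$n_iter, thin = config$thin,
    progress.bar = if (quiet) "none" else "text")

  all_mat <- do.call(rbind, lapply(draws, as.matrix))
  n_cols <- grep("^N\\[", colnames(all_mat))
  if (length(n_cols) == 0) n_cols <- which(colnames(all_mat) == "N")
  n_draws <- all_mat[, n_cols, drop = FALSE]
  colnames(n_draws) <- aug$site_levels
  nm_cols <- grep("^Nmale", colnames(all_mat))
  nmale_draws <- if (length(nm_cols)) {
    nm <- all_mat[, nm_cols, drop = FALSE]
    colnames(nm) <- aug$site_levels
    nm
  } else NULL

  n_total <- rowSums(n_draws)
  if (posterior_mode(n_total) >= aug$m_total &&
      mean(n_total >= aug$m_total) > 0.02) {
    abort(paste("posterior abundance is piling up at the pool capacity;",
                "rebuild the augmented data with a larger m_total"))
  }

  diagnostics <- cmr_diagnostics(draws)
  bad <- diagnostics$psrf > 1.1 & !is.na(diagnostics$psrf)
  if (any(bad)) {
    warn(sprintf("PSRF > 1.1 for: %s; chains have not converged",
                 paste(diagnostics$parameter[bad], collapse = ", ")))
  }
  structure(list(draws = draws, n_draws = n_draws,
                 nmale_draws = nmale_draws, site_levels = aug$site_levels,
                 n_observed_by_site = site_observed_counts(aug),
                 diagnostics = diagnostics, config = config),
            class = "cmr_posterior")
}

site_observed_counts <- function(aug) {
  obs_site <- aug$site[seq_len(aug$n_observed)]
  counts <- tabulate(obs_site, nbins = length(aug$site_levels))
  setNames(counts, aug$site_levels)
}

cmr_diagnostics <- function(draws) {
  params <- colnames(as.matrix(draws[[1]]))
  psrf <- rep(NA_real_, length(params))
  if (length(draws) >= 2) {
    gd <- tryCatch(
      coda::gelman.diag(draws, autoburnin = FALSE, multivariate = FALSE),
      error = function(e) NULL)
    if (!is.null(gd)) psrf <- gd$psrf[params, 1]
  }
  ess <- tryCatch(coda::effectiveSize(draws)[params],
                  error = function(e) rep(NA_real_, length(params)))
  tibble::tibble(parameter = params, psrf = unname(psrf), ess = unname(ess))
}

#' @export
print.cmr_posterior <- function(x, ...) {
  cat(sprintf("<cmr_posterior> %d site(s), %d draws x %d chains\n",
              length(x$site_levels), nrow(x$n_draws) / length(x$draws),
              length(x$draws)))
  for (s in x$site_levels) {
    h <- hpdi(x$n_draws[, s])
    cat(sprintf("  %s: N mode = %d, 95%% HPDI [%d, %d]\n", s,
                posterior_mode(x$n_draws[, s]), h[1], h[2]))
  }
  invisible(x)
}

#' Posterior mode of integer draws
#'
#' Most frequent integer value; ties are broken toward the smaller value.
#'
#' @param draws numeric vector of integer-valued posterior draws.
#' @return integer scalar.
#' @export
posterior_mode <- function(draws) {
  if (length(draws) < 1) abort("need at least one draw")
  tab <- table(as.integer(draws))
  vals <- as.integer(names(tab))
  min(vals[tab == max(tab)])
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted draws containing
#' `ceiling(level * n)` draws.
#'
#' @param draws numeric vector of posterior draws (>= 20).
#' @param level posterior mass to cover.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, level = 0.95) {
  if (length(draws) < 20) abort("need at least 20 draws for an HPDI")
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(level * n)
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- starts[which.min(widths)]
  c(s[i], s[i + m - 1])
}

#' Posterior evidence for the sign of a coefficient
#'
#' Fraction of draws sharing the sign of the posterior median; evidence for
#' a directional effect is called strong when that fraction is at least
#' `threshold`.
#'
#' @param draws numeric vector of posterior draws of a coefficient.
#' @param threshold strong-evidence cut-off.
#' @return one-row tibble: `direction`, `prob_sign`, `strong`.
#' @export
covariate_evidence <- function(draws, threshold = 0.9) {
  if (length(draws) < 1) abort("need at least one draw")
  med <- median(draws)
  dir <- if (med >= 0) "positive" else "negative"
  prob <- if (med >= 0) mean(draws >= 0) else mean(draws < 0)
  tibble::tibble(direction = dir, prob_sign = prob,
                 strong = prob >= threshold)
}

#' Posterior sex-ratio (males/females) at a site
#'
#' Per-draw ratio of included males to included females (imputed sexes of
#' pseudo-individuals included). Draws with zero females are recorded as
#' missing and reported as a fraction. The ratio is called biased when the
#' 95% HPDI of the defined draws excludes 1.
#'
#' @param fit a `cmr_posterior` with the sex model enabled.
#' @param site site label (default: first site).
#' @param level HPDI level for the bias call.
#' @return list of class `sex_ratio_posterior`: `draws` (ratio, `NA` where
#'   undefined), `frac_undefined`, `hpdi`, `biased`.
#' @export
sex_ratio_posterior <- function(fit, site = NULL, level = 0.95) {
  if (is.null(fit$nmale_draws)) abort("fit has no sex model; enable the sex covariate or supply unknown sexes")
  site <- site %||% fit$site_levels[1]
  nm <- fit$nmale_draws[, site]
  nf <- fit$n_draws[, site] - nm
  ratio <- ifelse(nf > 0, nm / nf, NA_real_)
  ok <- ratio[!is.na(ratio)]
  h <- if (length(ok) >= 20) hpdi(ok, level) else c(NA_real_, NA_real_)
  structure(list(
    draws = ratio, frac_undefined = mean(is.na(ratio)),
    hpdi = h, biased = !is.na(h[1]) && (h[1] > 1 || h[2] < 1),
    site = site
  ), class = "sex_ratio_posterior")
}

#' @export
print.sex_ratio_posterior <- function(x, ...) {
  cat(sprintf("sex ratio (M/F) at %s: median %.2f, HPDI [%.2f, %.2f]%s\n",
              x$site, median(x$draws, na.rm = TRUE), x$hpdi[1], x$hpdi[2],
              if (x$biased) " [biased]" else ""))
  invisible(x)
}

#' Tidy posterior summaries for a fitted CMR model
#'
#' @param x a `cmr_posterior`.
#' @param level HPDI level.
#' @param ... unused.
#' @return tibble with one row per monitored parameter: `parameter`,
#'   `estimate` (posterior mode for abundance, mean otherwise), `hpdi_lower`,
#'   `hpdi_upper`, `psrf`, `ess`.
#' @export
tidy.cmr_posterior <- function(x, level = 0.95, ...) {
  mat <- do.call(rbind, lapply(x$draws, as.matrix))
  purrr::map_dfr(colnames(mat), function(par) {
    v <- mat[, par]
    h <- hpdi(v, level)
    is_n <- grepl("^N", par)
    tibble::tibble(parameter = par,
                   estimate = if (is_n) posterior_mode(v) else mean(v),
                   hpdi_lower = h[1], hpdi_upper = h[2])
  }) |>
    dplyr::left_join(x$diagnostics, by = "parameter")
}

#' @rdname tidy.cmr_posterior
#' @export
glance.cmr_posterior <- function(x, ...) {
  tibble::tibble(
    chains = length(x$draws),
    draws = nrow(x$n_draws),
    max_psrf = suppressWarnings(max(x$diagnostics$psrf, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
    sites = length(x$site_levels)
  )
}

#' Posterior abundance histograms
#'
#' @param object a `cmr_posterior`.
#' @param ... unused.
#' @return a ggplot: per-site histogram of the abundance posterior with the
#'   posterior mode marked.
#' @export
autoplot.cmr_posterior <- function(object, ...) {
  df <- tibble::as_tibble(object$n_draws) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "site",
                        values_to = "N")
  modes <- df |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(mode = posterior_mode(.data$N), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$N)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(data = modes,
                        ggplot2::aes(xintercept = .data$mode),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~site, scales = "free") +
    ggplot2::labs(x = "Abundance (N)", y = "Posterior draws") +
    ggplot2::theme_minimal()
}

#' Regression of sex ratio on modal abundance across sites
#'
#' Ordinary least squares of per-site sex ratio on modal adult abundance,
#' with optional exclusion of outlier sites; reports the slope, adjusted
#' R-squared (which may be negative) and the two-sided slope p-value.
#'
#' @param df tibble with columns `site`, `na_modal`, `sex_ratio`.
#' @param exclude character vector of sites to drop before fitting.
#' @return one-row tibble: `slope`, `adj_r_squared`, `p_value`, `n_sites`.
#' @export
na_sexratio_regression <- function(df, exclude = NULL) {
  df <- df[!df$site %in% exclude, ]
  if (nrow(df) < 3) abort("need at least 3 sites after exclusion")
  fit <- lm(sex_ratio ~ na_modal, data = df)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    adj_r_squared = sm$adj.r.squared,
    p_value = sm$coefficients[2, 4],
    n_sites = nrow(df)
  )
}
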