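#' Wright-Fisher forward simulation of biallelic SNP panels
#'
#' Simulates drift at unlinked biallelic loci and draws genotype samples on
#' a schedule, producing the [geno_matrix()] substrate the genetic analyses
#' expect. Two modes:
#'
#' * `"frequency"` (default): per-deme allele frequencies evolve by
#'   symmetric island-model migration followed by binomial resampling of
#'   `2N` gene copies; sampled genotypes are assembled under Hardy-Weinberg
#'   (optionally with an inbreeding excess of homozygotes) from the deme
#'   frequencies. Loci are fully independent -- appropriate for drift,
#'   temporal-change and differentiation analyses.
#' * `"individual"`: a single deme of `N` diploids reproduces by random
#'   union of gametes with Mendelian transmission and free recombination.
#'   This generates the physical inter-locus disequilibrium that drift
#'   induces in a finite population, which the LD effective-size estimator
#'   measures; the frequency mode, having independent loci, carries no such
#'   signal by construction.
#'
#' @param n_diploid diploid deme size(s); one value per deme (individual
#'   mode supports exactly one deme).
#' @param n_loci number of unlinked biallelic loci.
#' @param generations number of generations to run.
#' @param migration symmetric per-generation migration rate in `[0, 1)`
#'   (frequency mode only).
#' @param init_freq initial alternate-allele frequencies; default drawn
#'   uniformly on `[0.05, 0.95]`.
#' @param schedule tibble with columns `generation`, `deme` (1-based),
#'   `size` -- the samples to draw. Defaults to sampling every deme fully at
#'   the final generation.
#' @param missing_rate fraction of genotypes set missing at random.
#' @param inbreeding within-deme excess homozygosity in `[0, 1]` applied at
#'   genotype assembly (frequency mode).
#' @param mode `"frequency"` or `"individual"` (see above).
#' @param seed integer seed (required: runs must be reproducible).
#' @return list of class `wf_sim`: `genotypes` (a single [geno_matrix()]
#'   with `population = deme label`, `period = "gen<g>"`), `truth` (list
#'   with `init_freq` and `freq` -- deme frequencies at each scheduled
#'   generation), and the call parameters.
#' @export
simulate_wright_fisher <- function(n_diploid, n_loci, generations,
                                   migration = 0, init_freq = NULL,
                                   schedule = NULL, missing_rate = 0,
                                   inbreeding = 0,
                                   mode = c("frequency", "individual"),
                                   seed) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is required for reproducibility")
  if (migration < 0 || migration >= 1) abort("`migration` must be in [0, 1)")
  set.seed(seed)
  n_demes <- length(n_diploid)
  if (mode == "individual" && n_demes != 1) {
    abort("individual mode supports a single deme")
  }
  init_freq <- init_freq %||% runif(n_loci, 0.05, 0.95)
  if (length(init_freq) != n_loci) abort("init_freq must have n_loci entries")
  if (is.null(schedule)) {
    schedule <- tibble::tibble(generation = generations,
                               deme = seq_len(n_demes), size = n_diploid)
  }
  schedule <- tibble::as_tibble(schedule)
  if (any(schedule$size > n_diploid[schedule$deme])) {
    abort("sample size exceeds deme size")
  }
  if (any(schedule$generation > generations)) {
    abort("schedule beyond the simulated generations")
  }
  locus_ids <- paste0("locus_", seq_len(n_loci))

  if (mode == "frequency") {
    out <- wf_frequency_run(n_diploid, n_loci, generations, migration,
                            init_freq, schedule, missing_rate, inbreeding,
                            locus_ids)
  } else {
    out <- wf_individual_run(n_diploid, n_loci, generations, init_freq,
                             schedule, missing_rate, locus_ids)
  }
  fixed <- vapply(out$freq, function(f) all(f %in% c(0, 1)), logical(1))
  if (any(fixed)) {
    warn("all loci fixed before at least one scheduled sample; monomorphic loci retained")
  }
  structure(list(
    genotypes = out$genotypes,
    truth = list(init_freq = init_freq, freq = out$freq),
    n_diploid = n_diploid, migration = migration, generations = generations,
    mode = mode, seed = seed
  ), class = "wf_sim")
}

wf_frequency_run <- function(n_diploid, n_loci, generations, migration,
                             init_freq, schedule, missing_rate, inbreeding,
                             locus_ids) {
  n_demes <- length(n_diploid)
  p <- matrix(rep(init_freq, n_demes), n_loci, n_demes)
  samples <- vector("list", nrow(schedule))
  freqs <- vector("list", nrow(schedule))
  take <- function(gen) {
    rows <- which(schedule$generation == gen)
    for (k in rows) {
      d <- schedule$deme[k]
      samples[[k]] <<- hw_genotypes(p[, d], schedule$size[k], inbreeding)
      freqs[[k]] <<- p[, d]
      names(freqs)[k] <<- sprintf("deme%d_gen%d", d, gen)
    }
  }
  take(0)
  for (gen in seq_len(generations)) {
    if (migration > 0 && n_demes > 1) {
      pbar <- rowMeans(p)
      # island model: migrants drawn from the pooled other demes
      p_others <- (pbar * n_demes - p) / (n_demes - 1)
      p <- (1 - migration) * p + migration * p_others
    }
    for (d in seq_len(n_demes)) {
      p[, d] <- rbinom(n_loci, 2 * n_diploid[d], p[, d]) / (2 * n_diploid[d])
    }
    take(gen)
  }
  list(genotypes = assemble_samples(samples, schedule, locus_ids,
                                    missing_rate),
       freq = freqs[!vapply(freqs, is.null, logical(1))])
}

# HW (optionally inbred) genotype dosages for one sample
hw_genotypes <- function(p, size, inbreeding = 0) {
  n_loci <- length(p)
  if (inbreeding > 0) {
    auto <- matrix(rbinom(size * n_loci, 1, inbreeding), size, n_loci,
                   byrow = FALSE)
    g_auto <- 2 * matrix(rbinom(size * n_loci, 1, rep(p, each = size)),
                         size, n_loci)
    g_out <- matrix(rbinom(size * n_loci, 2, rep(p, each = size)),
                    size, n_loci)
    auto * g_auto + (1 - auto) * g_out
  } else {
    matrix(rbinom(size * n_loci, 2, rep(p, each = size)), size, n_loci)
  }
}

wf_individual_run <- function(n_diploid, n_loci, generations, init_freq,
                              schedule, missing_rate, locus_ids) {
  n <- n_diploid[1]
  # genotype dosages of the living population; founders in HW proportions
  pop <- hw_genotypes(init_freq, n, 0)
  samples <- vector("list", nrow(schedule))
  freqs <- vector("list", nrow(schedule))
  take <- function(gen) {
    rows <- which(schedule$generation == gen)
    for (k in rows) {
      idx <- sample.int(n, schedule$size[k]) # without replacement
      samples[[k]] <<- pop[idx, , drop = FALSE]
      freqs[[k]] <<- colSums(pop) / (2 * n)
      names(freqs)[k] <<- sprintf("deme1_gen%d", gen)
    }
  }
  take(0)
  for (gen in seq_len(generations)) {
    p1 <- pop[sample.int(n, n, replace = TRUE), , drop = FALSE]
    p2 <- pop[sample.int(n, n, replace = TRUE), , drop = FALSE]
    # Mendelian transmission at unlinked loci: each gamete carries the
    # alternate allele with probability dosage/2, independently per locus
    gam1 <- matrix(rbinom(n * n_loci, 1, p1 / 2), n, n_loci)
    gam2 <- matrix(rbinom(n * n_loci, 1, p2 / 2), n, n_loci)
    pop <- gam1 + gam2
    take(gen)
  }
  list(genotypes = assemble_samples(samples, schedule, locus_ids,
                                    missing_rate),
       freq = freqs[!vapply(freqs, is.null, logical(1))])
}

assemble_samples <- function(samples, schedule, locus_ids, missing_rate) {
  taken <- which(!vapply(samples, is.null, logical(1)))
  mats <- list()
  meta <- list()
  for (k in taken) {
    m <- samples[[k]]
    ids <- sprintf("d%d_g%d_i%d", schedule$deme[k], schedule$generation[k],
                   seq_len(nrow(m)))
    rownames(m) <- ids
    mats[[length(mats) + 1]] <- m
    meta[[length(meta) + 1]] <- tibble::tibble(
      sample_id = ids,
      population = paste0("deme", schedule$deme[k]),
      period = paste0("gen", schedule$generation[k]))
  }
  dos <- do.call(rbind, mats)
  colnames(dos) <- locus_ids
  if (missing_rate > 0) {
    drop <- matrix(runif(length(dos)) < missing_rate, nrow(dos))
    dos[drop] <- NA_integer_
  }
  geno_matrix(dos, samples = dplyr::bind_rows(meta))
}

#' Simulate daily capture histories with known truth
#'
#' Generates a closed population of `n_true` individuals per site, assigns
#' sex and snout-vent length, and simulates daily Bernoulli captures with
#' the same linear predictor as the abundance model ([fit_cmr()]): logit
#' capture probability = intercept + date and individual random effects +
#' temperature, sex, SVL and previous-day-capture effects. Individuals
#' never captured are absent from the returned dataset but present in the
#' truth record.
#'
#' @param n_true true abundance per site (named vector; names become site
#'   labels, default `site1`, ...).
#' @param n_occasions daily occasions per site.
#' @param mean_p capture probability at covariate means (intercept on the
#'   probability scale).
#' @param beta_temp,beta_sex,beta_svl,beta_behav fixed effects on the logit
#'   scale (standardized temperature / male indicator / standardized SVL /
#'   previous-day capture).
#' @param sigma_date,sigma_ind random-effect SDs on the logit scale.
#' @param prop_male expected proportion of males.
#' @param svl_mean,svl_sd snout-vent length distribution (mm).
#' @param temp_mean,temp_sd daily air-temperature distribution (deg C).
#' @param seed integer seed (required).
#' @return list of class `capture_sim`: `data` (a [capture_dataset()] of
#'   the observed individuals), `truth` (tibble of all individuals with
#'   `site`, `sex`, `svl_mm`, `detected`), `n_true`.
#' @export
simulate_capture_histories <- function(n_true, n_occasions, mean_p = 0.2,
                                       beta_temp = 0, beta_sex = 0,
                                       beta_svl = 0, beta_behav = 0,
                                       sigma_date = 0, sigma_ind = 0,
                                       prop_male = 0.5, svl_mean = 450,
                                       svl_sd = 80, temp_mean = 15,
                                       temp_sd = 4, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility")
  set.seed(seed)
  sites <- names(n_true) %||% paste0("site", seq_along(n_true))
  if (any(n_true < 1) || n_occasions < 2) {
    abort("need n_true >= 1 and n_occasions >= 2")
  }
  all_ind <- list()
  all_hist <- list()
  occasions <- list()
  truth <- list()
  for (s in seq_along(sites)) {
    n <- n_true[s]
    temps <- rnorm(n_occasions, temp_mean, temp_sd)
    t_std <- as.numeric(scale(temps))
    if (any(!is.finite(t_std))) t_std <- rep(0, n_occasions)
    male <- rbinom(n, 1, prop_male)
    svl <- pmax(rnorm(n, svl_mean, svl_sd), 1)
    svl_std <- as.numeric(scale(svl))
    if (any(!is.finite(svl_std))) svl_std <- rep(0, n)
    b_d <- rnorm(n_occasions, 0, sigma_date)
    e_i <- rnorm(n, 0, sigma_ind)
    y <- matrix(0L, n, n_occasions)
    prev <- rep(0L, n)
    for (d in seq_len(n_occasions)) {
      lp <- qlogis(mean_p) + b_d[d] + e_i + beta_temp * t_std[d] +
        beta_sex * male + beta_svl * svl_std + beta_behav * prev
      y[, d] <- rbinom(n, 1, plogis(lp))
      prev <- y[, d]
    }
    detected <- rowSums(y) > 0
    ids <- sprintf("%s_ind%03d", sites[s], seq_len(n))
    truth[[s]] <- tibble::tibble(
      id = ids, site = sites[s], sex = ifelse(male == 1, "M", "F"),
      svl_mm = svl, detected = detected)
    if (any(detected)) {
      all_ind[[s]] <- tibble::tibble(
        id = ids[detected], site = sites[s],
        sex = ifelse(male[detected] == 1, "M", "F"),
        svl_mm = svl[detected])
      all_hist[[s]] <- y[detected, , drop = FALSE]
    }
    occasions[[s]] <- tibble::tibble(
      site = sites[s], occasion = seq_len(n_occasions), air_temp_c = temps)
  }
  truth <- dplyr::bind_rows(truth)
  occ <- dplyr::bind_rows(occasions)
  data <- if (length(all_ind) > 0) {
    capture_dataset(dplyr::bind_rows(all_ind), do.call(rbind, all_hist), occ)
  } else NULL
  structure(list(data = data, truth = truth,
                 n_true = setNames(n_true, sites), occasions = occ,
                 seed = seed),
            class = "capture_sim")
}
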