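#' Composite (Burrows) linkage disequilibrium r-squared between locus pairs
#'
#' For every pair of loci, the composite disequilibrium is estimated from
#' unphased dosages as `Delta = (S/(S-1)) * [(1/(2S)) * sum(x_i * y_i) -
#' 2 * p * q]`, with `x`, `y` the alternate-allele dosages, `p`, `q` the
#' alternate-allele frequencies over the `S` individuals complete for that
#' pair, and `r2 = Delta^2 / (p(1-p) q(1-q))`. The `S/(S-1)` factor is the
#' standard small-sample correction of the Burrows estimator used by the
#' LD effective-size software this method mirrors; without it the mean
#' r-squared of independent loci falls below the `1/S + 3.19/S^2` sampling
#' expectation that the downstream bias correction assumes. Pairs where
#' either locus is monomorphic among the complete individuals are excluded.
#' Individuals missing at either locus are excluded pairwise.
#'
#' @param g a [geno_matrix()].
#' @param population optional single population label.
#' @return list of class `burrows_r2`: `pairs` (tibble: `locus1`, `locus2`,
#'   `r2`, `s`), `mean_r2` (weighted by pair sample size), `s_harmonic`
#'   (harmonic mean pair sample size), `n_loci`, `n_pairs`.
#' @export
burrows_r2 <- function(g, population = NULL) {
  if (!is.null(population)) g <- gm_subset(g, population = population)
  d <- g$dosages
  if (ncol(d) < 2) abort("need at least 2 loci")
  pres <- (!is.na(d)) * 1
  x <- ifelse(is.na(d), 0, d)

  s_pair <- crossprod(pres)            # complete individuals per pair
  sum_xy <- crossprod(x)               # sum x_i y_i over complete pairs
  sum_x <- crossprod(x, pres)          # [j,k]: sum of x at j over complete(j,k)
  # alternate-allele frequency at locus j among individuals complete for (j,k)
  p_jk <- sum_x / (2 * pmax(s_pair, 1))
  q_jk <- t(p_jk)

  delta <- (s_pair / pmax(s_pair - 1, 1)) *
    (sum_xy / (2 * pmax(s_pair, 1)) - 2 * p_jk * q_jk)
  denom <- p_jk * (1 - p_jk) * q_jk * (1 - q_jk)
  r2 <- delta^2 / denom

  up <- upper.tri(s_pair)
  ok <- up & denom > 0 & s_pair >= 2
  if (!any(ok)) abort("no usable polymorphic locus pairs")
  idx <- which(ok, arr.ind = TRUE)
  pairs <- tibble::tibble(
    locus1 = colnames(d)[idx[, 1]], locus2 = colnames(d)[idx[, 2]],
    r2 = r2[ok], s = s_pair[ok]
  )
  structure(list(
    pairs = pairs,
    mean_r2 = sum(pairs$r2 * pairs$s) / sum(pairs$s),
    s_harmonic = harmonic_mean(pairs$s),
    n_loci = ncol(d), n_pairs = nrow(pairs)
  ), class = "burrows_r2")
}

# expected sampling contribution to mean r2 under random mating
# (NeEstimator / LDNe random-mating coefficients, separate small-S regime)
expected_r2_sample <- function(s) {
  if (s >= 30) 1 / s + 3.19 / s^2 else 0.0018 + 0.907 / s + 4.44 / s^2
}

# invert the drift r2 to Ne; non-positive drift signal maps to infinity
ne_from_drift <- function(r2_drift, s) {
  if (is.na(r2_drift) || r2_drift <= 0) return(Inf)
  if (s >= 30) {
    disc <- max(1 / 9 - 2.76 * r2_drift, 0)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- max(0.618^2 - 5.24 * r2_drift, 0)
    (0.618 + sqrt(disc)) / (2 * r2_drift)
  }
}

#' Linkage-disequilibrium (single-sample) effective population size
#'
#' Implements the LD method for unphased diploid SNPs under random mating:
#' mean composite r-squared across locus pairs, bias-corrected by the
#' expected sampling contribution (`1/S + 3.19/S^2` for harmonic-mean sample
#' size `S >= 30`, `0.0018 + 0.907/S + 4.44/S^2` below 30), then inverted to
#' `Ne` with the matching quadratic solution. A non-positive drift signal
#' yields `Ne = Inf`. Confidence intervals come from a delete-one-individual
#' jackknife on the drift r-squared scale.
#'
#' @param g a [geno_matrix()].
#' @param population single population label (default: all individuals).
#' @param pcrit minor-allele-frequency screen applied within the population
#'   before estimation (see [screen_maf()]).
#' @param ci `"jackknife"` for delete-one-individual 95% intervals, or
#'   `"none"`.
#' @param level confidence level for the jackknife interval.
#' @return an object of class `ne_estimate`; see [tidy.ne_estimate()].
#' @export
ld_ne <- function(g, population = NULL, pcrit = 0.05,
                  ci = c("jackknife", "none"), level = 0.95) {
  ci <- match.arg(ci)
  if (!is.null(population)) g <- gm_subset(g, population = population)
  g <- screen_maf(g, pcrit = pcrit, scope = "pooled")
  if (n_loci(g) < 2) abort("fewer than 2 usable loci after MAF screening")

  drift_of <- function(gm) {
    b <- burrows_r2(gm)
    list(drift = b$mean_r2 - expected_r2_sample(b$s_harmonic), b = b)
  }
  full <- drift_of(g)
  point <- ne_from_drift(full$drift, full$b$s_harmonic)

  lower <- upper <- NA_real_
  if (ci == "jackknife") {
    n <- n_samples(g)
    if (n < 5) abort("jackknife CI needs at least 5 individuals")
    loo <- purrr::map_dbl(seq_len(n), function(i) {
      tryCatch(drift_of(gm_subset(g, samples = -i))$drift,
               error = function(e) {
                 warn(sprintf("leave-one-out subset %d skipped: %s",
                              i, conditionMessage(e)))
                 NA_real_
               })
    })
    loo <- loo[!is.na(loo)]
    m <- length(loo)
    jk_var <- (m - 1) / m * sum((loo - mean(loo))^2)
    z <- qnorm(1 - (1 - level) / 2)
    d_lo <- full$drift - z * sqrt(jk_var)
    d_hi <- full$drift + z * sqrt(jk_var)
    # Ne is decreasing in the drift signal: upper Ne from the lower bound
    lower <- ne_from_drift(d_hi, full$b$s_harmonic)
    upper <- ne_from_drift(d_lo, full$b$s_harmonic)
  }
  new_ne_estimate(
    method = "LD", ne = point, lower = lower, upper = upper,
    pcrit = pcrit, s = full$b$s_harmonic, n_loci = full$b$n_loci,
    n_pairs = full$b$n_pairs,
    extra = list(mean_r2 = full$b$mean_r2, r2_drift = full$drift,
                 level = level)
  )
}

#' Temporal moment F-statistic between two samples
#'
#' Per-locus standardized variance of allele-frequency change
#' (Nei & Tajima's Fc): `Fc = (1/K) * sum_a (x_a - y_a)^2 /
#' ((x_a + y_a)/2 - x_a y_a)` over the `K = 2` alleles, with `x`, `y` the
#' allele frequencies in the earlier and later sample. Loci fixed for the
#' same allele in both samples are skipped (the denominator vanishes).
#' The multi-locus mean weights each locus by its independent allele count
#' (`K - 1`, so equally for biallelic loci).
#'
#' @param g0,gt [geno_matrix()] objects for the earlier and later sample,
#'   sharing locus identifiers.
#' @return list of class `temporal_fc`: `per_locus` (tibble: `locus_id`,
#'   `fc`, `n0`, `nt`), `fc_mean`, `df` (independent alleles used),
#'   `s0_harmonic`, `st_harmonic`.
#' @export
temporal_fc <- function(g0, gt) {
  shared <- intersect(colnames(g0$dosages), colnames(gt$dosages))
  if (length(shared) == 0) abort("no shared loci between the two samples")
  a0 <- allele_freqs(gm_subset(g0, loci = shared))
  at <- allele_freqs(gm_subset(gt, loci = shared))
  fc_one <- function(x, y) {
    xs <- c(x, 1 - x)
    ys <- c(y, 1 - y)
    den <- (xs + ys) / 2 - xs * ys
    if (all(den <= 0)) return(NA_real_)
    mean((xs - ys)^2 / den)
  }
  fc <- purrr::map2_dbl(a0$p_alt, at$p_alt, fc_one)
  per_locus <- tibble::tibble(locus_id = shared, fc = fc,
                              n0 = a0$n, nt = at$n)
  usable <- per_locus[!is.na(per_locus$fc), ]
  if (nrow(usable) == 0) abort("no usable loci for the temporal F statistic")
  structure(list(
    per_locus = per_locus, fc_mean = mean(usable$fc), df = nrow(usable),
    s0_harmonic = harmonic_mean(usable$n0),
    st_harmonic = harmonic_mean(usable$nt)
  ), class = "temporal_fc")
}

#' Temporal (two-sample) effective population size
#'
#' Moment-based temporal method under sampling plan II:
#' `Ne = t / (2 * (Fc - 1/(2*S0) - 1/(2*St)))` with `t` the elapsed
#' generations and `S0`, `St` the (harmonic mean) sample sizes in
#' individuals. A non-positive corrected drift signal yields `Ne = Inf`.
#' The confidence interval treats `df * Fc / Fc_true` as chi-squared with
#' `df` = number of independent alleles.
#'
#' @param fc mean temporal F statistic (or a [temporal_fc()] object, in
#'   which case `s0`, `st` and `df` default to its values).
#' @param s0,st sample sizes (diploid individuals) of the two samples.
#' @param t elapsed generations between samples (> 0); the generation time
#'   is study knowledge the caller must supply.
#' @param df independent alleles behind `fc`, for the chi-squared interval.
#' @param level confidence level.
#' @param plan temporal sampling plan; only plan II (sampling without
#'   replacement before reproduction) is implemented.
#' @return an object of class `ne_estimate`.
#' @export
temporal_ne <- function(fc, s0 = NULL, st = NULL, t, df = NULL,
                        level = 0.95, plan = "II") {
  if (!identical(plan, "II")) abort("only sampling plan II is implemented")
  if (inherits(fc, "temporal_fc")) {
    s0 <- s0 %||% fc$s0_harmonic
    st <- st %||% fc$st_harmonic
    df <- df %||% fc$df
    fc <- fc$fc_mean
  }
  if (is.null(s0) || is.null(st)) abort("`s0` and `st` are required")
  if (!is.numeric(t) || length(t) != 1 || t <= 0) abort("`t` must be > 0")
  if (s0 < 2 || st < 2) abort("sample sizes must be at least 2")
  ne_of <- function(f) {
    drift <- f - 1 / (2 * s0) - 1 / (2 * st)
    if (drift <= 0) Inf else t / (2 * drift)
  }
  point <- ne_of(fc)
  lower <- upper <- NA_real_
  if (!is.null(df)) {
    alpha <- 1 - level
    fc_hi <- df * fc / qchisq(alpha / 2, df)
    fc_lo <- df * fc / qchisq(1 - alpha / 2, df)
    lower <- ne_of(fc_hi)
    upper <- ne_of(fc_lo)
  }
  new_ne_estimate(
    method = "temporal", ne = point, lower = lower, upper = upper,
    pcrit = NA_real_, s = harmonic_mean(c(s0, st)), n_loci = df,
    n_pairs = NA_integer_,
    extra = list(fc = fc, s0 = s0, st = st, t = t, level = level)
  )
}

#' Temporal Ne from two genotype samples
#'
#' Convenience wrapper: screens rare alleles over the pooled pair of
#' samples, computes the temporal F statistic and converts it to `Ne`.
#'
#' @inheritParams temporal_fc
#' @inheritParams temporal_ne
#' @param pcrit minor-allele-frequency screen over the pooled samples.
#' @return an object of class `ne_estimate`.
#' @export
ne_temporal <- function(g0, gt, t, pcrit = 0.05, level = 0.95) {
  shared <- intersect(colnames(g0$dosages), colnames(gt$dosages))
  if (length(shared) == 0) abort("no shared loci between the two samples")
  g0 <- gm_subset(g0, loci = shared)
  gt <- gm_subset(gt, loci = shared)
  pooled <- geno_matrix(
    rbind(g0$dosages,
          `rownames<-`(gt$dosages, paste0("t_", rownames(gt$dosages)))),
    samples = tibble::tibble(
      sample_id = c(rownames(g0$dosages), paste0("t_", rownames(gt$dosages))),
      population = "pooled",
      period = rep(c("t0", "t1"), c(n_samples(g0), n_samples(gt))))
  )
  keep <- colnames(screen_maf(pooled, pcrit = pcrit, scope = "pooled")$dosages)
  fc <- temporal_fc(gm_subset(g0, loci = keep), gm_subset(gt, loci = keep))
  est <- temporal_ne(fc, t = t, level = level)
  est$pcrit <- pcrit
  est
}

new_ne_estimate <- function(method, ne, lower, upper, pcrit, s, n_loci,
                            n_pairs, extra = list()) {
  structure(c(list(
    method = method, ne = ne, lower = lower, upper = upper, pcrit = pcrit,
    s = s, n_loci = n_loci, n_pairs = n_pairs
  ), extra), class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v)) "NA" else if (is.infinite(v)) "INF" else sprintf("%.1f", v)
  }
  cat(sprintf("Ne (%s method) = %s [%s, %s]\n", x$method, fmt(x$ne),
              fmt(x$lower), fmt(x$upper)))
  cat(sprintf("  S = %.1f, loci = %s%s\n", x$s,
              x$n_loci %||% NA,
              if (!is.na(x$n_pairs %||% NA_integer_))
                sprintf(", pairs = %d", x$n_pairs) else ""))
  invisible(x)
}

#' Tidy an effective-size estimate
#'
#' @param x an `ne_estimate` from [ld_ne()] or [temporal_ne()].
#' @param ... unused.
#' @return one-row tibble with `method`, `ne`, `ci_lower`, `ci_upper`,
#'   `pcrit`, `s`, `n_loci`, `n_pairs`.
#' @export
tidy.ne_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, ne = x$ne, ci_lower = x$lower, ci_upper = x$upper,
    pcrit = x$pcrit, s = x$s,
    n_loci = as.integer(x$n_loci %||% NA_integer_),
    n_pairs = as.integer(x$n_pairs %||% NA_integer_)
  )
}

#' Effective-to-adult population size ratio
#'
#' `Ne/Na` using the temporal point estimate when it is available and
#' finite, otherwise the LD estimate; reported rounded to 2 decimals.
#'
#' @param ne_ld,ne_temporal `ne_estimate` objects or plain numbers (either
#'   may be `NULL`/`NA`).
#' @param na modal adult abundance (> 0).
#' @param digits rounding for the reported ratio.
#' @return list: `ratio` (rounded, half away from zero), `ne_used`,
#'   `method_used`.
#' @export
ne_na_ratio <- function(ne_ld = NULL, ne_temporal = NULL, na, digits = 2) {
  if (!is.numeric(na) || length(na) != 1 || is.na(na) || na <= 0) {
    abort("`na` must be a positive number")
  }
  pt <- function(x) {
    if (is.null(x)) return(NA_real_)
    if (inherits(x, "ne_estimate")) x$ne else as.numeric(x)
  }
  ne_t <- pt(ne_temporal)
  ne_l <- pt(ne_ld)
  if (!is.na(ne_t) && is.finite(ne_t)) {
    used <- ne_t; method <- "temporal"
  } else if (!is.na(ne_l) && is.finite(ne_l)) {
    used <- ne_l; method <- "LD"
  } else {
    abort("no finite Ne estimate available; ratio undefined")
  }
  list(ratio = round_half_up(used / na, digits), ne_used = used,
       method_used = method)
}
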