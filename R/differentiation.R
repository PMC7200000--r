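#' Weir-Cockerham theta (FST) from diploid genotypes
#'
#' Computes the Weir & Cockerham (1984) variance components per locus --
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) -- and combines loci as a ratio of sums:
#' `theta = sum(a) / sum(a + b + c)`. Loci monomorphic across the chosen
#' populations are skipped. Sample sizes may differ per locus through
#' missing data. Negative estimates are reported as computed, not truncated.
#'
#' @param g a [geno_matrix()].
#' @param populations character vector of two or more population labels
#'   (default: all populations present).
#' @return list of class `wc_theta`: `theta` (multi-locus estimate),
#'   `components` (tibble: `locus_id`, `a`, `b`, `c`), `populations`.
#' @export
wc_theta <- function(g, populations = NULL) {
  populations <- populations %||% unique(g$samples$population)
  if (length(populations) < 2) abort("need at least 2 populations")
  g <- gm_subset(g, population = populations)
  comp <- wc_components(g$dosages, g$samples$population)
  usable <- !is.na(comp$a)
  if (!any(usable)) abort("no shared polymorphic loci between populations")
  comp <- comp[usable, ]
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  structure(list(theta = theta, components = comp, populations = populations),
            class = "wc_theta")
}

#' @export
print.wc_theta <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.4f over %d polymorphic loci (%s)\n",
              x$theta, nrow(x$components), paste(x$populations, collapse = ", ")))
  invisible(x)
}

# vectorized WC 1984 components for all loci at once; pop is a factor-able
# label vector aligned with rows of the dosage matrix. Returns NA components
# for loci monomorphic (or unusable) across the populations.
wc_components <- function(dosages, pop) {
  pop <- as.factor(pop)
  r_levels <- levels(pop)
  ind <- outer(pop, r_levels, "==") * 1 # n x r indicator
  present <- !is.na(dosages)
  d0 <- ifelse(present, dosages, 0)
  het <- ifelse(present, dosages == 1, 0)

  n_i <- crossprod(ind, present)          # r x L: sample size per pop/locus
  alt_i <- crossprod(ind, d0)             # alt copies per pop/locus
  het_i <- crossprod(ind, het)            # het counts per pop/locus

  ok_pop <- n_i > 0
  r_eff <- colSums(ok_pop)                # populations represented per locus
  p_i <- ifelse(ok_pop, alt_i / (2 * pmax(n_i, 1)), 0)
  h_i <- ifelse(ok_pop, het_i / pmax(n_i, 1), 0)

  nbar <- colSums(n_i) / r_eff
  nc <- (colSums(n_i) - colSums(n_i^2) / colSums(n_i)) / (r_eff - 1)
  pbar <- colSums(n_i * p_i) / (r_eff * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = nrow(n_i)))^2 * ok_pop) /
    ((r_eff - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r_eff * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r_eff - 1) / r_eff) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r_eff - 1) / r_eff) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  poly <- pbar > 0 & pbar < 1
  ok <- poly & r_eff >= 2 & colSums(n_i) > r_eff # need nbar > 1
  a[!ok] <- NA_real_
  b[!ok] <- NA_real_
  cc[!ok] <- NA_real_
  tibble::tibble(locus_id = colnames(dosages), a = as.numeric(a),
                 b = as.numeric(b), c = as.numeric(cc))
}

#' Pairwise theta matrix with permutation significance
#'
#' All pairwise Weir-Cockerham theta estimates between populations, optional
#' permutation p-values, the Bonferroni-corrected alpha for the number of
#' pairs, and the global multi-population theta.
#'
#' @param g a [geno_matrix()].
#' @param n_perm permutations per pair (0 = no test).
#' @param alpha nominal significance level before Bonferroni correction.
#' @param seed integer seed for the permutation streams.
#' @return list of class `theta_matrix`: `pairs` (tibble: `pop1`, `pop2`,
#'   `theta`, `p_value`), `theta_global`, `alpha_bonferroni`, `n_perm`,
#'   and `matrix` (symmetric numeric matrix of theta).
#' @export
theta_matrix <- function(g, n_perm = 0, alpha = 0.05, seed = 1) {
  pops <- unique(g$samples$population)
  if (length(pops) < 2) abort("need at least 2 populations")
  pairs <- utils::combn(pops, 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    pair <- pairs[, k]
    th <- wc_theta(g, pair)$theta
    p <- if (n_perm > 0) {
      theta_permutation_test(g, pair, n_perm = n_perm, seed = seed + k)
    } else NA_real_
    tibble::tibble(pop1 = pair[1], pop2 = pair[2], theta = th, p_value = p)
  }) |> dplyr::bind_rows()
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (k in seq_len(nrow(res))) {
    m[res$pop1[k], res$pop2[k]] <- m[res$pop2[k], res$pop1[k]] <- res$theta[k]
  }
  structure(list(
    pairs = res, theta_global = wc_theta(g)$theta,
    alpha_bonferroni = bonferroni_alpha(nrow(res), alpha),
    n_perm = n_perm, matrix = m
  ), class = "theta_matrix")
}

#' @export
print.theta_matrix <- function(x, ...) {
  cat(sprintf("global theta = %.4f; %d pairs; Bonferroni alpha = %.5f\n",
              x$theta_global, nrow(x$pairs), x$alpha_bonferroni))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Permutation test for pairwise theta
#'
#' Permutes individual population labels within the pair and recomputes the
#' multi-locus theta. The p-value uses the add-one rule
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' @param g a [geno_matrix()].
#' @param pair two population labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
theta_permutation_test <- function(g, pair, n_perm = 999, seed = 1) {
  if (length(pair) != 2) abort("`pair` must name two populations")
  if (n_perm < 99) abort("`n_perm` must be at least 99")
  g <- gm_subset(g, population = pair)
  obs <- wc_theta(g, pair)$theta
  labels <- g$samples$population
  d <- g$dosages
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(labels)
    comp <- wc_components(d, perm)
    comp <- comp[!is.na(comp$a), ]
    th <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
    if (!is.na(th) && th >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

#' Bonferroni-corrected significance level
#'
#' @param n_tests number of simultaneous tests (>= 1).
#' @param alpha familywise level.
#' @return per-test level `alpha / n_tests`.
#' @export
bonferroni_alpha <- function(n_tests, alpha = 0.05) {
  n_tests <- assert_count(n_tests, "n_tests")
  alpha / n_tests
}

#' Great-circle distance matrix between sites (km)
#'
#' @param sites tibble with `site`, `longitude`, `latitude` (decimal degrees).
#' @return symmetric matrix of haversine distances in kilometres.
#' @export
geo_dist_km <- function(sites) {
  coords <- as.matrix(sites[c("longitude", "latitude")])
  n <- nrow(coords)
  m <- matrix(0, n, n, dimnames = list(sites$site, sites$site))
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(coords[i, , drop = FALSE], coords) / 1000
  }
  (m + t(m)) / 2
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between pairwise genetic distances (theta, as
#' plotted, not theta/(1-theta)) and great-circle geographic distances in
#' km, with significance from joint row/column permutations.
#'
#' @param gen_dist,geo_dist symmetric matrices with zero diagonals and
#'   matching dimensions (>= 3 populations).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list of class `ibd_result`: `r`, `r_squared`, `p_value`,
#'   `n_perm`, and `pairs` (tibble of the off-diagonal pairs).
#' @export
mantel_test <- function(gen_dist, geo_dist, n_perm = 1000, seed = 1) {
  gen_dist <- as.matrix(gen_dist)
  geo_dist <- as.matrix(geo_dist)
  if (!all(dim(gen_dist) == dim(geo_dist))) abort("matrices must match in shape")
  if (nrow(gen_dist) < 3) abort("need at least 3 populations")
  check_sym <- function(m, nm) {
    if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-12)) {
      abort(sprintf("`%s` must be symmetric with a zero diagonal", nm))
    }
  }
  check_sym(gen_dist, "gen_dist")
  check_sym(geo_dist, "geo_dist")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(gen_dist), stats::as.dist(geo_dist),
                       method = "pearson", permutations = n_perm)
  idx <- which(upper.tri(gen_dist), arr.ind = TRUE)
  labels <- rownames(gen_dist) %||% as.character(seq_len(nrow(gen_dist)))
  pairs <- tibble::tibble(
    pop1 = labels[idx[, 1]], pop2 = labels[idx[, 2]],
    gen_dist = gen_dist[idx], geo_dist_km = geo_dist[idx]
  )
  structure(list(
    r = unname(fit$statistic), r_squared = unname(fit$statistic)^2,
    p_value = fit$signif, n_perm = n_perm, pairs = pairs
  ), class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f (R^2 = %.3f), p = %.4g [%d permutations]\n",
              x$r, x$r_squared, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname mantel_test
#' @param x an `ibd_result`.
#' @param ... unused.
#' @export
glance.ibd_result <- function(x, ...) {
  tibble::tibble(r = x$r, r_squared = x$r_squared, p_value = x$p_value,
                 n_perm = x$n_perm, n_pairs = nrow(x$pairs))
}

#' Scatterplot of isolation by distance
#'
#' @param object an `ibd_result` from [mantel_test()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ibd_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$geo_dist_km, y = .data$gen_dist)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.4) +
    ggplot2::labs(x = "Geographic distance (km)",
                  y = expression("Genetic differentiation" ~ (theta)),
                  subtitle = sprintf("Mantel r = %.3f, p = %.3g",
                                     object$r, object$p_value)) +
    ggplot2::theme_minimal()
}
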