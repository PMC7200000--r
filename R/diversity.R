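#' Per-locus diversity statistics within one population
#'
#' `observed_heterozygosity()` is the fraction of heterozygous genotypes per
#' locus among non-missing individuals. `expected_heterozygosity()` is the
#' plug-in estimator `1 - p^2 - q^2` from non-missing gene copies.
#' `nucleotide_diversity()` is the unbiased pairwise-difference estimator at
#' a variant site, `(2n/(2n-1)) * (1 - p^2 - q^2)` with `2n` the non-missing
#' gene copies, and therefore always `>= He` on the same sample.
#'
#' @param g a [geno_matrix()].
#' @param population single population label (default: all individuals).
#' @return tibble with `locus_id`, `n` (non-missing individuals), and the
#'   statistic column (`ho`, `he` or `pi`).
#' @export
observed_heterozygosity <- function(g, population = NULL) {
  if (!is.null(population)) g <- gm_subset(g, population = population)
  d <- g$dosages
  n <- unname(colSums(!is.na(d)))
  if (any(n == 0)) abort("locus with no non-missing genotypes; filter first")
  ho <- unname(colSums(d == 1, na.rm = TRUE)) / n
  tibble::tibble(locus_id = colnames(d), n = as.integer(n), ho = ho)
}

#' @rdname observed_heterozygosity
#' @export
expected_heterozygosity <- function(g, population = NULL) {
  if (!is.null(population)) g <- gm_subset(g, population = population)
  af <- allele_freqs(g)
  if (any(af$n == 0)) abort("locus with no non-missing genotypes; filter first")
  tibble::tibble(locus_id = af$locus_id, n = af$n,
                 he = 2 * af$p_alt * (1 - af$p_alt))
}

#' @rdname observed_heterozygosity
#' @export
nucleotide_diversity <- function(g, population = NULL) {
  if (!is.null(population)) g <- gm_subset(g, population = population)
  af <- allele_freqs(g)
  copies <- 2 * af$n
  if (any(copies < 2)) {
    warn(sprintf("skipping %d locus/loci with fewer than 2 gene copies",
                 sum(copies < 2)))
  }
  keep <- copies >= 2
  he <- 2 * af$p_alt[keep] * (1 - af$p_alt[keep])
  tibble::tibble(locus_id = af$locus_id[keep], n = af$n[keep],
                 pi = copies[keep] / (copies[keep] - 1) * he)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles per locus in a random subsample of
#' `g_copies` gene copies, by hypergeometric rarefaction:
#' `Ar = sum_a (1 - choose(2n - n_a, g) / choose(2n, g))` where `n_a` is the
#' observed count of allele `a` among the `2n` non-missing copies. At
#' `g_copies = 2n` this is the observed allele count; a monomorphic locus has
#' `Ar = 1` at any rarefaction depth.
#'
#' @param g a [geno_matrix()].
#' @param population single population label (default: all individuals).
#' @param g_copies rarefaction depth in gene copies; must be at least 2 and
#'   no larger than the smallest number of non-missing copies at any locus.
#' @return tibble with `locus_id`, `n`, `ar`.
#' @export
rarefied_allelic_richness <- function(g, population = NULL, g_copies) {
  if (!is.null(population)) g <- gm_subset(g, population = population)
  g_copies <- assert_count(g_copies, "g_copies", min = 2)
  af <- allele_freqs(g)
  copies <- 2 * af$n
  if (g_copies > min(copies)) {
    abort(sprintf(
      "g_copies (%d) exceeds the smallest non-missing copy count (%d)",
      g_copies, min(copies)))
  }
  n_alt <- round(af$p_alt * copies)
  ar_one <- function(total, count) {
    # P(allele seen in subsample) = 1 - C(total - count, g)/C(total, g)
    counts <- c(count, total - count)
    counts <- counts[counts > 0]
    sum(1 - exp(lchoose(total - counts, g_copies) - lchoose(total, g_copies)))
  }
  ar <- mapply(ar_one, copies, n_alt)
  tibble::tibble(locus_id = af$locus_id, n = af$n, ar = ar)
}

#' Diversity summary table by population (and period)
#'
#' One row per population x period with the column set of a standard SNP
#' diversity table: `n` (mean non-missing individuals per locus), rarefied
#' allelic richness `ar`, mean observed (`ho`) and expected (`he`)
#' heterozygosity, and mean nucleotide diversity `pi`. Loci entirely missing
#' within a group are excluded from that group's means.
#'
#' @param g a [geno_matrix()].
#' @param g_copies rarefaction depth in gene copies; default is the smallest
#'   number of non-missing copies over all groups and loci ("rarefied by
#'   lowest number of gene copies per site").
#' @param by grouping columns of the sample table.
#' @return tibble with columns `population`, `period`, `n`, `ar`, `ho`,
#'   `he`, `pi`.
#' @export
diversity_table <- function(g, g_copies = NULL, by = c("population", "period")) {
  groups <- dplyr::distinct(g$samples[by])
  subsets <- purrr::pmap(groups, function(...) {
    sel <- list(...)
    keep <- rep(TRUE, n_samples(g))
    for (col in names(sel)) keep <- keep & g$samples[[col]] == sel[[col]]
    sub <- gm_subset(g, samples = which(keep))
    typed <- colSums(!is.na(sub$dosages)) > 0
    gm_subset(sub, loci = which(typed))
  })
  if (is.null(g_copies)) {
    g_copies <- min(purrr::map_int(subsets, function(s) {
      min(2L * colSums(!is.na(s$dosages)))
    }))
  }
  stats <- purrr::map(subsets, function(sub) {
    ho <- observed_heterozygosity(sub)
    he <- expected_heterozygosity(sub)
    pi <- nucleotide_diversity(sub)
    ar <- rarefied_allelic_richness(sub, g_copies = g_copies)
    tibble::tibble(n = mean(ho$n), ar = mean(ar$ar), ho = mean(ho$ho),
                   he = mean(he$he), pi = mean(pi$pi))
  })
  dplyr::bind_cols(groups, dplyr::bind_rows(stats))
}
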