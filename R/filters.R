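#' Filter loci by genotyping presence within every population
#'
#' Retains exactly the loci genotyped in at least `min_fraction` of the
#' individuals of every population (the per-site "80% presence" rule used
#' for RAD SNP panels). The boundary is inclusive: a locus typed in exactly
#' `min_fraction` of individuals is kept. Individuals are never removed.
#'
#' @param g a [geno_matrix()].
#' @param min_fraction required fraction of genotyped individuals per
#'   population, in (0, 1].
#' @param per_population if `FALSE`, the fraction is computed over the
#'   pooled sample instead of within every population.
#' @return a [geno_matrix()] with the retained loci.
#' @export
filter_by_presence <- function(g, min_fraction = 0.8, per_population = TRUE) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1]")
  }
  present <- !is.na(g$dosages)
  if (per_population) {
    pops <- unique(g$samples$population)
    keep <- rep(TRUE, n_loci(g))
    for (pop in pops) {
      idx <- g$samples$population == pop
      if (!any(idx)) abort(sprintf("population '%s' has no individuals", pop))
      frac <- colMeans(present[idx, , drop = FALSE])
      # tolerance guards against 8/10 < 0.8 under binary floating point
      keep <- keep & (frac >= min_fraction - 1e-12)
    }
  } else {
    keep <- colMeans(present) >= min_fraction - 1e-12
  }
  if (!any(keep)) abort("no loci pass the presence filter")
  gm_subset(g, loci = which(keep))
}

#' Screen out low minor-allele-frequency loci
#'
#' Removes loci whose minor-allele frequency, computed over non-missing gene
#' copies, is strictly below `pcrit`. A frequency exactly equal to `pcrit`
#' is retained (the "exclude alleles with frequency < Pcrit" convention of
#' effective-size estimation software). Used ahead of the Ne estimators
#' with the conventional `pcrit = 0.05`.
#'
#' @param g a [geno_matrix()].
#' @param pcrit critical minor-allele frequency in `[0, 0.5)`.
#' @param scope `"pooled"` computes MAF over all individuals; `"population"`
#'   drops a locus if its MAF falls below `pcrit` in any population.
#' @return a [geno_matrix()] with the retained loci.
#' @export
screen_maf <- function(g, pcrit = 0.05, scope = c("pooled", "population")) {
  scope <- match.arg(scope)
  if (!is.numeric(pcrit) || length(pcrit) != 1 || pcrit < 0 || pcrit >= 0.5) {
    abort("`pcrit` must be in [0, 0.5)")
  }
  maf_of <- function(sub) {
    af <- allele_freqs(sub)
    pmin(af$p_alt, 1 - af$p_alt)
  }
  if (scope == "pooled") {
    maf <- maf_of(g)
    keep <- is.na(maf) | maf >= pcrit - 1e-12
  } else {
    keep <- rep(TRUE, n_loci(g))
    for (pop in unique(g$samples$population)) {
      maf <- maf_of(gm_subset(g, population = pop))
      keep <- keep & (is.na(maf) | maf >= pcrit - 1e-12)
    }
  }
  if (!any(keep)) abort("no loci pass the MAF screen")
  gm_subset(g, loci = which(keep))
}
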