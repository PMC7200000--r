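#' SNP genotype matrix with population and period labels
#'
#' `geno_matrix()` builds the shared genotype container used by all genetic
#' analyses in the package: an individuals x loci matrix of alternate-allele
#' dosages (0, 1, 2 or `NA` for missing) plus a sample table carrying the
#' site ("population") and sampling-period label of every individual. The
#' design mirrors matrix-backed genotype containers such as adegenet's
#' `genind`: the dosage matrix stays a matrix, and [tidy()] gives the long
#' tibble view.
#'
#' @param dosages integer matrix, individuals x loci, values in
#'   `{0, 1, 2, NA}` counting copies of the alternate allele.
#' @param samples data frame with one row per individual: columns
#'   `sample_id`, `population`, `period`. Defaults to single-population,
#'   single-period labels.
#' @param sample_ids,locus_ids identifiers; default to the dimnames of
#'   `dosages` or generated names.
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (named integer matrix) and `samples` (tibble).
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 1L, 2L), 2, 2))
#' n_samples(g)
geno_matrix <- function(dosages, samples = NULL, sample_ids = NULL,
                        locus_ids = NULL) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "dosage outside {0,1,2,NA} at row %d, column %d", idx[1], idx[2]))
  }
  if (is.null(sample_ids) && is.null(rownames(dosages)) &&
      is.data.frame(samples) && "sample_id" %in% names(samples) &&
      nrow(samples) == nrow(dosages)) {
    sample_ids <- samples$sample_id # row order of `samples` names the rows
  }
  sample_ids <- sample_ids %||% rownames(dosages) %||%
    paste0("ind_", seq_len(nrow(dosages)))
  locus_ids <- locus_ids %||% colnames(dosages) %||%
    paste0("locus_", seq_len(ncol(dosages)))
  if (anyDuplicated(locus_ids)) abort("locus_ids must be unique")
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique")
  dimnames(dosages) <- list(sample_ids, locus_ids)

  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sample_ids,
                              population = "pop1", period = "all")
  } else {
    samples <- tibble::as_tibble(samples)
    if (!all(c("sample_id", "population", "period") %in% names(samples))) {
      if (!"sample_id" %in% names(samples)) samples$sample_id <- sample_ids
      if (!"period" %in% names(samples)) samples$period <- "all"
    }
    samples <- samples[match(sample_ids, samples$sample_id), ]
    if (anyNA(samples$sample_id)) abort("samples table does not cover all sample_ids")
  }
  if (any(!nzchar(samples$population)) || anyNA(samples$population)) {
    abort("population labels must be non-empty")
  }
  if (any(!nzchar(samples$period)) || anyNA(samples$period)) {
    abort("period labels must be non-empty")
  }
  structure(list(dosages = dosages, samples = samples), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d loci\n",
              nrow(x$dosages), ncol(x$dosages)))
  pops <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of individuals / loci in a genotype matrix
#' @param g a [geno_matrix()].
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$dosages)

#' Subset a genotype matrix
#'
#' @param g a [geno_matrix()].
#' @param samples sample ids or logical/integer index over individuals.
#' @param loci locus ids or index over loci.
#' @param population,period optional label filters applied before `samples`.
#' @return a [geno_matrix()].
#' @export
gm_subset <- function(g, samples = NULL, loci = NULL, population = NULL,
                      period = NULL) {
  keep <- rep(TRUE, n_samples(g))
  if (!is.null(population)) keep <- keep & g$samples$population %in% population
  if (!is.null(period)) keep <- keep & g$samples$period %in% period
  idx <- which(keep)
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) {
      intersect(idx, match(samples, g$samples$sample_id))
    } else intersect(idx, seq_len(n_samples(g))[samples])
  }
  if (length(idx) == 0) abort("subset selects no individuals")
  loci <- loci %||% seq_len(n_loci(g))
  geno_matrix(g$dosages[idx, loci, drop = FALSE],
              samples = g$samples[idx, ])
}

#' Per-locus alternate-allele frequencies
#'
#' Frequencies are computed over non-missing gene copies (2 per genotyped
#' individual), either pooled or within one population.
#'
#' @param g a [geno_matrix()].
#' @param population optional single population label.
#' @return tibble with `locus_id`, `n` (non-missing individuals), `p_alt`.
#' @export
allele_freqs <- function(g, population = NULL) {
  if (!is.null(population)) g <- gm_subset(g, population = population)
  d <- g$dosages
  n <- unname(colSums(!is.na(d)))
  p <- ifelse(n > 0, unname(colSums(d, na.rm = TRUE)) / (2 * n), NA_real_)
  tibble::tibble(locus_id = colnames(d), n = as.integer(n), p_alt = p)
}

#' Tidy a genotype matrix into long form
#'
#' @param x a [geno_matrix()].
#' @param ... unused.
#' @return tibble with one row per individual x locus:
#'   `sample_id`, `population`, `period`, `locus_id`, `dosage`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$dosages), times = ncol(x$dosages)),
    locus_id = rep(colnames(x$dosages), each = nrow(x$dosages)),
    dosage = as.integer(x$dosages)
  ) |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::select("sample_id", "population", "period", "locus_id", "dosage")
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance
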