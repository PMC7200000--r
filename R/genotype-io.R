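#' Read diploid biallelic genotypes from a VCF file
#'
#' Parses a VCF into the package's [geno_matrix()] dosage form. Only diploid
#' biallelic SNP records are usable; multi-allelic records are skipped (with
#' a warning) or rejected depending on `multiallelic`. Missing calls
#' (`./.` or `.`) become `NA`.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param samples optional sample table (`sample_id`, `population`, `period`)
#'   to attach; defaults to a single population.
#' @param multiallelic `"skip"` (drop records with >1 ALT allele, warning) or
#'   `"error"`.
#' @return a [geno_matrix()]; sample order is the VCF column order.
#' @export
read_vcf <- function(path, samples = NULL, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF: ", conditionMessage(e)))
  )
  if (nrow(vcf@fix) == 0) abort("VCF contains no records")
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt)
  if (any(multi)) {
    if (multiallelic == "error") {
      abort(sprintf("multi-allelic record at %s:%s",
                    vcf@fix[which(multi)[1], "CHROM"],
                    vcf@fix[which(multi)[1], "POS"]))
    }
    warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
  }
  if (nrow(vcf@fix) == 0) abort("no biallelic records left after filtering")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- unname(vcf@fix[, "ID"])
  locus_ids <- ifelse(is.na(ids) | ids == ".",
                      paste0(unname(vcf@fix[, "CHROM"]), "_",
                             unname(vcf@fix[, "POS"])), ids)
  rownames(gt) <- locus_ids

  # validate ploidy before translating: every non-missing call must have
  # exactly one separator, i.e. two alleles
  sep_count <- lengths(regmatches(gt, gregexpr("[|/]", gt)))
  nonmiss <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  bad <- nonmiss & sep_count != 1
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("non-diploid call '%s' at record %s",
                  gt[idx[1], idx[2]], rownames(gt)[idx[1]]))
  }
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  ok <- nonmiss & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  part <- nonmiss & xor(a1 == ".", a2 == ".")
  if (any(nonmiss & !ok & !part)) {
    idx <- which(nonmiss & !ok & !part, arr.ind = TRUE)[1, ]
    abort(sprintf("unsupported genotype '%s' at record %s",
                  gt[idx[1], idx[2]], rownames(gt)[idx[1]]))
  }
  val <- matrix(NA_integer_, nrow(gt), ncol(gt))
  val[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  dos[] <- t(val)
  geno_matrix(dos, samples = samples)
}

#' Read / write the package's TSV genotype dialect
#'
#' The TSV dialect is one row per individual with columns `sample_id`,
#' `population`, `period`, then one column per locus holding dosages 0/1/2
#' or `NA`. `write_genotype_tsv()` and `read_genotype_tsv()` round-trip a
#' [geno_matrix()] bit-exactly.
#'
#' @param path file path.
#' @return `read_genotype_tsv()` returns a [geno_matrix()];
#'   `write_genotype_tsv()` returns `path` invisibly.
#' @export
read_genotype_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character(),
    period = readr::col_character(),
    .default = readr::col_integer()
  ))
  meta_cols <- c("sample_id", "population", "period")
  if (!all(meta_cols %in% names(tab))) {
    abort("genotype TSV must have sample_id, population, period columns")
  }
  locus_cols <- setdiff(names(tab), meta_cols)
  if (length(locus_cols) == 0) abort("genotype TSV has no locus columns")
  dos <- as.matrix(tab[locus_cols])
  rownames(dos) <- tab$sample_id
  bad <- !is.na(dos) & !(dos %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("dosage outside {0,1,2,NA} at row %d (%s), locus %s",
                  idx[1], tab$sample_id[idx[1]], locus_cols[idx[2]]))
  }
  geno_matrix(dos, samples = tab[meta_cols])
}

#' @rdname read_genotype_tsv
#' @param g a [geno_matrix()].
#' @export
write_genotype_tsv <- function(g, path) {
  tab <- dplyr::bind_cols(
    g$samples[c("sample_id", "population", "period")],
    tibble::as_tibble(g$dosages)
  )
  readr::write_tsv(tab, path, na = "NA")
  invisible(path)
}

#' Write a genotype matrix in genepop format
#'
#' Two-digit allele coding (`01` reference, `02` alternate, `0000` missing),
#' one `Pop` block per population. For interoperability with classical
#' population-genetics software.
#'
#' @param g a [geno_matrix()].
#' @param path output file path.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "popgenmon export") {
  code <- function(d) {
    dplyr::case_when(is.na(d) ~ "0000", d == 0 ~ "0101",
                     d == 1 ~ "0102", d == 2 ~ "0202")
  }
  lines <- c(title, colnames(g$dosages))
  for (pop in unique(g$samples$population)) {
    lines <- c(lines, "Pop")
    idx <- which(g$samples$population == pop)
    for (i in idx) {
      lines <- c(lines, paste0(
        g$samples$sample_id[i], " ,  ",
        paste(code(g$dosages[i, ]), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a site-metadata table
#'
#' @param path CSV with columns `site`, `region` (northern/southern),
#'   `longitude`, `latitude` (decimal degrees WGS84), `isolated` (logical),
#'   and optionally `na_modal` (modal adult abundance) and `neighbor`.
#' @return validated tibble.
#' @export
read_site_metadata <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols())
  req <- c("site", "region", "longitude", "latitude", "isolated")
  if (!all(req %in% names(tab))) {
    abort(paste("site metadata must contain columns:", paste(req, collapse = ", ")))
  }
  if (!all(tab$region %in% c("northern", "southern"))) {
    abort("region must be 'northern' or 'southern'")
  }
  if (!all(is.finite(tab$longitude)) || !all(is.finite(tab$latitude))) {
    abort("coordinates must be finite")
  }
  tab$isolated <- as.logical(tab$isolated)
  tibble::as_tibble(tab)
}
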