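# build a geno_matrix from a dosage matrix and population labels
make_geno <- function(dosages, populations = "pop1", periods = "all") {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  tab <- tibble::tibble(
    sample_id = paste0("ind", seq_len(n)),
    population = rep_len(populations, n),
    period = rep_len(periods, n)
  )
  geno_matrix(dosages, samples = tab)
}

# two-population fixture from per-population dosage matrices
make_two_pop <- function(d1, d2, names = c("A", "B")) {
  d <- rbind(as.matrix(d1), as.matrix(d2))
  make_geno(d, populations = rep(names, c(nrow(d1), nrow(d2))))
}

# write a small VCF file; gts is a records x samples character matrix of GT
write_tiny_vcf <- function(gts, path = tempfile(fileext = ".vcf"),
                           alt = rep("T", nrow(gts)),
                           samples = paste0("s", seq_len(ncol(gts)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c("chr1", i * 100, paste0("snp", i), "A", alt[i], ".", "PASS",
            ".", "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# independent per-locus transcription of the Weir-Cockerham (1984)
# single-locus component formulas, used as the oracle for the vectorized
# implementation
wc_oracle_locus <- function(dosage_by_pop) {
  n_i <- vapply(dosage_by_pop, function(d) sum(!is.na(d)), numeric(1))
  keep <- n_i > 0
  dosage_by_pop <- dosage_by_pop[keep]
  n_i <- n_i[keep]
  r <- length(n_i)
  p_i <- vapply(dosage_by_pop, function(d) sum(d, na.rm = TRUE), numeric(1)) /
    (2 * n_i)
  h_i <- vapply(dosage_by_pop, function(d) sum(d == 1, na.rm = TRUE),
                numeric(1)) / n_i
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# quick single-site capture dataset from an explicit history matrix
make_captures <- function(histories, sex = NULL, svl = NULL, site = "siteA",
                          temps = NULL) {
  histories <- as.matrix(histories)
  n <- nrow(histories)
  d <- ncol(histories)
  inds <- tibble::tibble(
    id = paste0("i", seq_len(n)), site = site,
    sex = sex %||% rep("U", n),
    svl_mm = svl %||% rep(NA_real_, n))
  occ <- tibble::tibble(site = site, occasion = seq_len(d),
                        air_temp_c = temps %||% rep(15, d))
  capture_dataset(inds, histories, occ)
}

`%||%` <- rlang::`%||%`
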