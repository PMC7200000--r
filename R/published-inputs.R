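#' Published monitoring summaries for the San Francisco gartersnake study
#'
#' Small bundled tables carrying the published per-site summaries that the
#' decision framework consumes: site metadata, diversity statistics,
#' abundance posteriors and effective-size estimates for the seven focal
#' sites. These are inputs for worked examples and for reproducing the
#' derived rescue/ratio tables; the underlying genotypes and capture
#' histories are not public.
#'
#' Site coordinates are *synthetic stand-ins*: the species is endangered
#' and true locations are not published. The bundled coordinates were
#' constructed to preserve the published nearest-neighbour ordering of
#' sites within each regional cluster, which is all the rescue scenarios
#' use; the file is named accordingly.
#'
#' @return tibbles:
#' * `sfgs_sites()`: `site`, `region`, `longitude`, `latitude`, `isolated`,
#'   `na_modal` (modal adult abundance).
#' * `sfgs_diversity(dataset)`: `site`, `year`, `n`, `ar`, `ho`, `he`, `pi`
#'   for the single-period (`"2018"`) or two-period (`"temporal"`) panels.
#' * `sfgs_ne()`: per-site LD and temporal Ne point estimates and 95% CI
#'   bounds (`Inf` encodes an unbounded interval) plus `ne` -- the
#'   preferred point estimate (temporal when available, else LD).
#' @name sfgs_tables
NULL

sfgs_file <- function(name) {
  system.file("extdata", name, package = "popgenmon", mustWork = TRUE)
}

#' @rdname sfgs_tables
#' @export
sfgs_sites <- function() {
  read_site_metadata(sfgs_file("sfgs_sites_synthetic.csv"))
}

#' @rdname sfgs_tables
#' @param dataset which diversity panel to return.
#' @export
sfgs_diversity <- function(dataset = c("2018", "temporal")) {
  dataset <- match.arg(dataset)
  fn <- if (dataset == "2018") "sfgs_diversity_2018.csv" else
    "sfgs_diversity_temporal.csv"
  readr::read_csv(sfgs_file(fn), col_types = readr::cols())
}

#' @rdname sfgs_tables
#' @export
sfgs_ne <- function() {
  tab <- readr::read_csv(sfgs_file("sfgs_ne.csv"), col_types = readr::cols())
  tab$ne <- ifelse(!is.na(tab$temporal_ne), tab$temporal_ne, tab$ld_ne)
  tab
}
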