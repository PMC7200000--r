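#' Mean inbreeding coefficient of a recipient relative to a source
#'
#' Genetic-rescue planning compares the average heterozygosity of a
#' candidate recipient (inbred) population with the expected heterozygosity
#' of a proposed source (outbred): `F = 1 - Ho_recipient / He_source`.
#' Observed heterozygosity is used for the recipient so that both drift and
#' non-random mating contribute.
#'
#' @param ho_recipient mean observed heterozygosity of the recipient.
#' @param he_source mean expected heterozygosity of the source (> 0).
#' @return numeric F (unrounded; tables report it to 2 decimals with ties
#'   away from zero).
#' @export
#' @examples
#' inbreeding_coefficient(0.092, 0.117) # 0.214 -> prints as 0.21
inbreeding_coefficient <- function(ho_recipient, he_source) {
  if (any(he_source <= 0)) abort("`he_source` must be positive")
  1 - ho_recipient / he_source
}

#' Select a source site for a rescue scenario
#'
#' Candidate sources are the sites in the recipient's regional cluster.
#' `"neighbor"` takes the geographically closest other site (great-circle
#' distance); `"max_ne"`, `"max_he"` and `"max_na"` take the argmax of the
#' respective statistic over the cluster *including* the recipient -- when
#' the recipient is itself the argmax the scenario is not applicable and
#' `NA` is returned (the dash convention of rescue tables). He ties are
#' broken by nucleotide diversity, then allelic richness, then site name.
#'
#' @param recipient recipient site name.
#' @param scenario one of `"neighbor"`, `"max_ne"`, `"max_he"`, `"max_na"`.
#' @param sites site-metadata tibble (`site`, `region`, `longitude`,
#'   `latitude`, `isolated`, `na_modal`).
#' @param diversity per-site diversity tibble (`site`, `ho`, `he`, `pi`,
#'   `ar`), e.g. from [diversity_table()].
#' @param ne per-site tibble with a `ne` column (preferred point estimates).
#' @return source site name, or `NA_character_` when the scenario resolves
#'   to the recipient itself.
#' @export
select_source <- function(recipient, scenario, sites, diversity, ne = NULL) {
  scenario <- match.arg(scenario, c("neighbor", "max_ne", "max_he", "max_na"))
  if (!recipient %in% sites$site) abort(sprintf("unknown site '%s'", recipient))
  region <- sites$region[sites$site == recipient]
  cluster <- sites[sites$region == region, ]
  if (nrow(cluster) < 2) abort("recipient's regional cluster has no other site")

  if (scenario == "neighbor") {
    others <- cluster[cluster$site != recipient, ]
    dm <- geo_dist_km(rbind(cluster[cluster$site == recipient, ], others))
    return(others$site[which.min(dm[1, -1])])
  }
  stat <- switch(scenario,
    max_ne = {
      if (is.null(ne)) abort("`ne` table required for scenario max_ne")
      ne$ne[match(cluster$site, ne$site)]
    },
    max_na = cluster$na_modal,
    max_he = NULL)
  if (scenario == "max_he") {
    div <- diversity[match(cluster$site, diversity$site), ]
    ord <- order(-div$he, -div$pi, -div$ar, div$site)
    best <- cluster$site[ord[1]]
  } else {
    if (all(is.na(stat))) abort("no candidate has the required statistic")
    best <- cluster$site[order(-stat, cluster$site)[1]]
  }
  if (identical(best, recipient)) NA_character_ else best
}

#' Genetic-erosion flags for a recipient site
#'
#' A population is flagged `small` when both its modal adult abundance and
#' its effective size are below 100 (small now, and small for multiple
#' generations); `erosion` when the inbreeding coefficient relative to the
#' nearest-neighbour source strictly exceeds `f_threshold` (default 10%);
#' `isolated` is an external input from clustering analyses and is passed
#' through.
#'
#' @param na modal adult abundance.
#' @param ne effective population size point estimate.
#' @param f_neighbor inbreeding coefficient with the nearest-neighbour
#'   source.
#' @param isolated logical, from external clustering.
#' @param f_threshold erosion threshold on F (strict inequality).
#' @return one-row tibble: `isolated`, `small`, `erosion`.
#' @export
erosion_flags <- function(na, ne, f_neighbor, isolated, f_threshold = 0.10) {
  tibble::tibble(
    isolated = isolated,
    small = na < 100 && ne < 100,
    erosion = f_neighbor > f_threshold
  )
}

#' Rescue-scenario assessment table
#'
#' One row per recipient site with the four source scenarios (nearest
#' neighbour, largest Ne, highest He, largest adult abundance), the mean
#' inbreeding coefficient F for each (rounded to 2 decimals, ties away from
#' zero; `NA` where the recipient is its own argmax), and the three erosion
#' flags. Source expected heterozygosity is taken from the
#' nucleotide-diversity column by default (the unbiased expected
#' heterozygosity estimator); set `source_he = "he"` for the plug-in column.
#'
#' @param sites site metadata (`site`, `region`, `longitude`, `latitude`,
#'   `isolated`, `na_modal`).
#' @param diversity per-site diversity (`site`, `ho`, `he`, `pi`, `ar`).
#' @param ne per-site preferred Ne point estimates (`site`, `ne`).
#' @param f_threshold erosion threshold (strict) on F.
#' @param source_he which diversity column stands in for the source's
#'   expected heterozygosity.
#' @return tibble: `recipient`, `region`, then `source_*` / `f_*` column
#'   pairs for the four scenarios and the flags `isolated`, `small`,
#'   `f_exceeds`.
#' @export
rescue_table <- function(sites, diversity, ne, f_threshold = 0.10,
                         source_he = c("pi", "he")) {
  source_he <- match.arg(source_he)
  scen <- c("neighbor", "max_ne", "max_he", "max_na")
  rows <- purrr::map(sites$site, function(rec) {
    ho_rec <- diversity$ho[diversity$site == rec]
    srcs <- purrr::map_chr(scen, function(sc) {
      # a scenario whose statistic is unavailable (e.g. no finite Ne in the
      # cluster) is reported as not applicable rather than failing the table
      tryCatch(select_source(rec, sc, sites, diversity, ne),
               error = function(e) NA_character_)
    })
    f_vals <- purrr::map_dbl(srcs, function(src) {
      if (is.na(src)) return(NA_real_)
      round_half_up(
        inbreeding_coefficient(ho_rec,
                               diversity[[source_he]][diversity$site == src]),
        2)
    })
    flags <- erosion_flags(
      na = sites$na_modal[sites$site == rec],
      ne = ne$ne[ne$site == rec],
      f_neighbor = f_vals[1],
      isolated = sites$isolated[sites$site == rec],
      f_threshold = f_threshold)
    tibble::tibble(
      recipient = rec, region = sites$region[sites$site == rec],
      source_neighbor = srcs[1], f_neighbor = f_vals[1],
      source_max_ne = srcs[2], f_max_ne = f_vals[2],
      source_max_he = srcs[3], f_max_he = f_vals[3],
      source_max_na = srcs[4], f_max_na = f_vals[4],
      isolated = flags$isolated, small = flags$small,
      f_exceeds = flags$erosion)
  })
  dplyr::bind_rows(rows)
}
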