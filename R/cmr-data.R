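#' Capture-history dataset for closed-population abundance estimation
#'
#' Bundles daily binary capture histories with individual covariates (sex,
#' snout-vent length) and per-occasion air temperature, per site. Occasions
#' are calendar days; each observed individual must be captured at least
#' once.
#'
#' @param individuals tibble with one row per observed individual: `id`,
#'   `site`, `sex` (one of `"F"`, `"M"`, `"U"`), `svl_mm` (may be `NA`).
#' @param histories integer 0/1 matrix, individuals x occasions, rows in
#'   the order of `individuals`; columns are the union of occasion indices
#'   (inactive occasions of a site carry 0 and are masked via `occasions`).
#' @param occasions tibble with `site`, `occasion` (1-based index),
#'   `air_temp_c` and optionally `date`.
#' @return an object of class `capture_dataset`.
#' @export
capture_dataset <- function(individuals, histories, occasions) {
  individuals <- tibble::as_tibble(individuals)
  occasions <- tibble::as_tibble(occasions)
  if (!all(c("id", "site", "sex") %in% names(individuals))) {
    abort("individuals needs columns id, site, sex")
  }
  if (!"svl_mm" %in% names(individuals)) individuals$svl_mm <- NA_real_
  if (!all(individuals$sex %in% c("F", "M", "U"))) {
    abort("sex must be one of F, M, U")
  }
  if (any(!is.na(individuals$svl_mm) & individuals$svl_mm <= 0)) {
    abort("svl_mm must be positive where present")
  }
  histories <- as.matrix(histories)
  storage.mode(histories) <- "integer"
  if (nrow(histories) != nrow(individuals)) {
    abort("histories rows must match individuals")
  }
  if (!all(histories %in% 0:1)) abort("histories must be 0/1")
  if (any(rowSums(histories) == 0)) {
    abort("every observed individual must be captured at least once")
  }
  if (!all(c("site", "occasion") %in% names(occasions))) {
    abort("occasions needs columns site, occasion")
  }
  if (!"air_temp_c" %in% names(occasions)) occasions$air_temp_c <- NA_real_
  structure(list(individuals = individuals, histories = histories,
                 occasions = occasions), class = "capture_dataset")
}

#' @export
print.capture_dataset <- function(x, ...) {
  cat(sprintf("<capture_dataset> %d individuals, %d sites, %d occasions\n",
              nrow(x$individuals), length(unique(x$individuals$site)),
              ncol(x$histories)))
  invisible(x)
}

#' Read capture data from CSV files
#'
#' `captures_csv` holds one row per capture event (`individual_id`, `site`,
#' `date` ISO-8601, `sex`, `svl_mm`); `occasions_csv` one row per trapping
#' day (`site`, `date`, `air_temp_c`). Occasion indices are assigned per
#' site in date order.
#'
#' @param captures_csv,occasions_csv file paths.
#' @return a [capture_dataset()].
#' @export
read_captures <- function(captures_csv, occasions_csv) {
  caps <- readr::read_csv(captures_csv, col_types = readr::cols())
  occ <- readr::read_csv(occasions_csv, col_types = readr::cols())
  occ <- occ |>
    dplyr::group_by(.data$site) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::mutate(occasion = dplyr::row_number()) |>
    dplyr::ungroup()
  caps <- dplyr::left_join(
    caps, occ[c("site", "date", "occasion")], by = c("site", "date"))
  if (anyNA(caps$occasion)) abort("capture on a date not listed as an occasion")
  inds <- caps |>
    dplyr::group_by(id = .data$individual_id) |>
    dplyr::summarise(site = dplyr::first(.data$site),
                     sex = dplyr::first(.data$sex),
                     svl_mm = dplyr::first(.data$svl_mm), .groups = "drop")
  d_max <- max(occ$occasion)
  hist <- matrix(0L, nrow(inds), d_max)
  hist[cbind(match(caps$individual_id, inds$id), caps$occasion)] <- 1L
  capture_dataset(inds, hist, occ[c("site", "occasion", "date", "air_temp_c")])
}

#' Augment capture histories with all-zero pseudo-individuals
#'
#' Data augmentation turns abundance estimation into estimation of how many
#' of a fixed pool of `m_total` individuals were real and present: observed
#' histories are padded with all-zero pseudo-histories of unknown sex and
#' size, and (for multi-site pools) latent site membership. Air temperature
#' and SVL covariates are centred and scaled by the observed-data mean and
#' SD. The behavioural covariate is 1 on occasion `d` iff the individual
#' was observed captured on occasion `d - 1` (0 on the first occasion).
#'
#' @param data a [capture_dataset()] (one or several sites).
#' @param m_total total pool size including observed individuals.
#' @return object of class `augmented_data` with the model arrays: `y`
#'   (`m_total` x occasions), `site` (integer, `NA` latent for
#'   pseudo-individuals), `male` (1/0/`NA`), `svl_std`, `behav`, `temp_std`
#'   (site x occasion), `active` (site x occasion 0/1 mask), `n_observed`,
#'   `m_total`, `site_levels`, `standardization`.
#' @export
build_augmented_data <- function(data, m_total) {
  stopifnot(inherits(data, "capture_dataset"))
  n_obs <- nrow(data$individuals)
  m_total <- assert_count(m_total, "m_total")
  if (m_total < n_obs) {
    abort(sprintf("m_total (%d) is smaller than the %d observed individuals",
                  m_total, n_obs))
  }
  site_levels <- sort(unique(data$individuals$site))
  d_max <- ncol(data$histories)

  active <- matrix(0L, length(site_levels), d_max,
                   dimnames = list(site_levels, NULL))
  temp <- matrix(NA_real_, length(site_levels), d_max,
                 dimnames = list(site_levels, NULL))
  for (k in seq_along(site_levels)) {
    occ <- data$occasions[data$occasions$site == site_levels[k], ]
    active[k, occ$occasion] <- 1L
    temp[k, occ$occasion] <- occ$air_temp_c
  }
  t_mean <- mean(temp[active == 1], na.rm = TRUE)
  t_sd <- sd(temp[active == 1], na.rm = TRUE)
  if (!is.finite(t_sd) || t_sd == 0) { t_mean <- 0; t_sd <- 1 }
  temp_std <- (temp - t_mean) / t_sd
  temp_std[is.na(temp_std)] <- 0

  svl <- data$individuals$svl_mm
  s_mean <- mean(svl, na.rm = TRUE)
  s_sd <- sd(svl, na.rm = TRUE)
  if (!is.finite(s_sd) || s_sd == 0) { s_mean <- 0; s_sd <- 1 }

  n_pseudo <- m_total - n_obs
  y <- rbind(data$histories, matrix(0L, n_pseudo, d_max))
  site <- c(match(data$individuals$site, site_levels),
            rep(NA_integer_, n_pseudo))
  male <- c(ifelse(data$individuals$sex == "U", NA_integer_,
                   as.integer(data$individuals$sex == "M")),
            rep(NA_integer_, n_pseudo))
  svl_std <- c((svl - s_mean) / s_sd, rep(NA_real_, n_pseudo))
  behav <- cbind(0L, y[, -d_max, drop = FALSE])

  structure(list(
    y = y, site = site, male = male, svl_std = svl_std, behav = behav,
    temp_std = temp_std, active = active, n_observed = n_obs,
    m_total = m_total, site_levels = site_levels,
    standardization = list(temp = c(mean = t_mean, sd = t_sd),
                           svl = c(mean = s_mean, sd = s_sd))
  ), class = "augmented_data")
}

#' @export
print.augmented_data <- function(x, ...) {
  cat(sprintf("<augmented_data> pool %d = %d observed + %d pseudo; %d site(s), %d occasions\n",
              x$m_total, x$n_observed, x$m_total - x$n_observed,
              length(x$site_levels), ncol(x$y)))
  invisible(x)
}
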