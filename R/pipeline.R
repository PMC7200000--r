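#' Run the full monitoring analysis from a configuration file
#'
#' Configuration-driven orchestration of the analysis chain: presence/MAF
#' filtering, per-site diversity, pairwise theta (+ isolation by distance
#' when coordinates are available), LD and temporal effective size, optional
#' capture-mark-recapture abundance, Ne/Na ratios, and the rescue
#' assessment. Each stage writes a CSV into `output_dir`; a failing stage
#' is isolated (recorded in the manifest with its error) and completed
#' outputs are preserved. A JSON manifest records the configuration hash,
#' seed and stage status, making reruns verifiable.
#'
#' @param config a YAML file path or an equivalent named list with entries:
#'   `genotypes` (TSV path), `sites` (metadata CSV path), optional
#'   `captures`/`occasions` (CSV paths), `filter` (`min_fraction`,
#'   `pcrit`), `ne` (`t`, `pcrit`), `cmr` (`m_total`, `chains`, `n_iter`,
#'   `burnin`, `thin`), `rescue` (`f_threshold`, `source_he`), `seed`.
#' @param output_dir directory for the output CSVs and manifest.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, output_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("config must be a YAML file path or a list")
  if (is.null(cfg$genotypes)) abort("config field `genotypes` is required")
  if (is.null(cfg$sites)) abort("config field `sites` is required")
  seed <- cfg$seed %||% 1
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg)
  header <- sprintf("# config_hash=%s seed=%d", cfg_hash, as.integer(seed))

  status <- list()
  results <- list()
  write_out <- function(tab, name) {
    path <- file.path(output_dir, paste0(name, ".csv"))
    writeLines(header, path)
    suppressWarnings(readr::write_csv(tab, path, append = TRUE,
                                      col_names = TRUE))
    path
  }
  stage <- function(name, expr) {
    res <- tryCatch(list(ok = TRUE, value = expr),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    status[[name]] <<- if (res$ok) "ok" else paste("failed:", res$error)
    if (res$ok) results[[name]] <<- res$value
    res$ok
  }

  stage("input", {
    g <- read_genotype_tsv(cfg$genotypes)
    sites <- read_site_metadata(cfg$sites)
    filt <- cfg$filter %||% list()
    g <- filter_by_presence(g, filt$min_fraction %||% 0.8)
    list(g = g, sites = sites)
  })
  g <- results$input$g
  sites <- results$input$sites

  if (!is.null(g)) {
    stage("diversity", {
      tab <- diversity_table(g)
      write_out(tab, "diversity")
      tab
    })
    stage("theta", {
      set.seed(seed)
      tm <- theta_matrix(g, n_perm = cfg$theta_perm %||% 199, seed = seed)
      out <- tm$pairs
      out$alpha_bonferroni <- tm$alpha_bonferroni
      out$theta_global <- tm$theta_global
      write_out(out, "theta")
      tm
    })
    if (!is.null(results$theta) && nrow(sites) >= 3) {
      stage("ibd", {
        pops <- intersect(rownames(results$theta$matrix), sites$site)
        if (length(pops) < 3) abort("fewer than 3 populations with coordinates")
        geo <- geo_dist_km(sites[match(pops, sites$site), ])
        ibd <- mantel_test(results$theta$matrix[pops, pops], geo,
                           n_perm = cfg$ibd_perm %||% 999, seed = seed)
        write_out(glance(ibd), "ibd")
        ibd
      })
    }
    stage("ne", {
      ne_cfg <- cfg$ne %||% list()
      pcrit <- ne_cfg$pcrit %||% 0.05
      pops <- unique(g$samples$population)
      rows <- purrr::map(pops, function(pop) {
        sub <- gm_subset(g, population = pop)
        periods <- unique(sub$samples$period)
        ld <- tryCatch(
          tidy(ld_ne(gm_subset(sub, period = period_latest(sub)),
                     pcrit = pcrit, ci = "none")),
          error = function(e) NULL)
        tmp <- if (length(periods) == 2 && !is.null(ne_cfg$t)) {
          tryCatch(tidy(ne_temporal(
            gm_subset(sub, period = sort(periods)[1]),
            gm_subset(sub, period = sort(periods)[2]),
            t = ne_cfg$t, pcrit = pcrit)), error = function(e) NULL)
        } else NULL
        out <- dplyr::bind_rows(ld, tmp)
        if (nrow(out) > 0) out$population <- pop
        out
      })
      tab <- dplyr::bind_rows(rows)
      write_out(tab, "ne")
      tab
    })
  }

  if (!is.null(cfg$captures) && !is.null(cfg$occasions)) {
    stage("cmr", {
      cmr_cfg <- cfg$cmr %||% list()
      capt <- read_captures(cfg$captures, cfg$occasions)
      aug <- build_augmented_data(
        capt, cmr_cfg$m_total %||% (nrow(capt$individuals) * 3))
      fit <- fit_cmr(aug, cmr_config(
        chains = cmr_cfg$chains %||% 2,
        n_iter = cmr_cfg$n_iter %||% 2000,
        burnin = cmr_cfg$burnin %||% 500,
        thin = cmr_cfg$thin %||% 1,
        adapt = cmr_cfg$adapt %||% 500,
        seed = seed))
      tab <- tidy(fit)
      write_out(tab, "cmr")
      fit
    })
  } else {
    status$cmr <- "skipped: no capture data configured"
  }

  if (!is.null(results$diversity) && !is.null(results$ne)) {
    stage("rescue", {
      res_cfg <- cfg$rescue %||% list()
      div <- results$diversity
      div$site <- div$population
      ld_tab <- results$ne |>
        dplyr::group_by(site = .data$population) |>
        dplyr::summarise(ne = preferred_ne(.data$method, .data$ne),
                         .groups = "drop")
      sites_use <- sites[sites$site %in% div$site, ]
      tab <- rescue_table(sites_use, div, ld_tab,
                          f_threshold = res_cfg$f_threshold %||% 0.10,
                          source_he = res_cfg$source_he %||% "pi")
      write_out(tab, "rescue")
      tab
    })
  } else {
    status$rescue <- "skipped: needs diversity and ne stages"
  }

  manifest <- list(
    package = "popgenmon",
    version = as.character(utils::packageVersion("popgenmon")),
    config_hash = cfg_hash, seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = status)
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))

  failed <- grepl("^failed", unlist(status))
  if (any(failed)) {
    warn(sprintf("stage(s) failed: %s",
                 paste(names(status)[failed], collapse = ", ")))
  }
  invisible(list(results = results, manifest = manifest))
}

period_latest <- function(g) {
  sort(unique(g$samples$period), decreasing = TRUE)[1]
}

preferred_ne <- function(method, ne) {
  tmp <- ne[method == "temporal" & is.finite(ne)]
  if (length(tmp) > 0) return(tmp[1])
  ld <- ne[method == "LD" & is.finite(ne)]
  if (length(ld) > 0) ld[1] else NA_real_
}
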