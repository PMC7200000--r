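#' Huggins conditional-likelihood abundance estimate
#'
#' Closed-population alternative to data augmentation: the likelihood of
#' each observed capture history is conditioned on being captured at least
#' once (divided by `p*_i = 1 - prod_d (1 - p_{i,d})`), so abundance drops
#' out of the likelihood and is recovered afterwards by Horvitz-Thompson
#' summation `N_hat = sum_i 1 / p*_i`. Capture probability is modelled on
#' the logit scale with a sex effect and occasion (time) fixed effects.
#' Individuals of unknown sex take the midpoint of the sex covariate.
#' Occasions with zero captures cannot support a free occasion effect; that
#' effect is dropped to the shared intercept with a warning.
#'
#' @param data a [capture_dataset()] restricted to one site.
#' @param effects model terms: any of `"sex"`, `"occasion"`.
#' @return list of class `huggins_fit`: `n_hat`, `p_star` (per observed
#'   individual), `coefficients`, `log_lik`, `convergence`.
#' @export
huggins_fit <- function(data, effects = c("sex", "occasion")) {
  stopifnot(inherits(data, "capture_dataset"))
  if (length(unique(data$individuals$site)) != 1) {
    abort("huggins_fit expects a single-site dataset")
  }
  effects <- match.arg(effects, several.ok = TRUE)
  y <- data$histories
  occ_idx <- sort(unique(data$occasions$occasion))
  y <- y[, occ_idx, drop = FALSE]
  n <- nrow(y)
  d <- ncol(y)
  if (d < 2) abort("need at least 2 occasions")
  if (sum(y) <= n) abort("need at least one recapture")

  male <- ifelse(data$individuals$sex == "U", 0.5,
                 as.numeric(data$individuals$sex == "M"))
  occ_free <- rep(TRUE, d)
  if ("occasion" %in% effects) {
    empty <- colSums(y) == 0
    if (any(empty)) {
      warn(sprintf("occasion(s) with zero captures: %s; their occasion effect is dropped",
                   paste(which(empty), collapse = ", ")))
      occ_free[empty] <- FALSE
    }
    occ_free[1] <- FALSE # reference occasion absorbs the intercept
  } else {
    occ_free[] <- FALSE
  }
  n_gamma <- sum(occ_free)
  use_sex <- "sex" %in% effects

  unpack <- function(par) {
    mu <- par[1]
    bsex <- if (use_sex) par[2] else 0
    gamma <- rep(0, d)
    if (n_gamma > 0) gamma[occ_free] <- par[(1 + use_sex) + seq_len(n_gamma)]
    lp <- outer(if (use_sex) mu + bsex * male else rep(mu, n), gamma, `+`)
    plogis(lp)
  }
  negll <- function(par) {
    p <- unpack(par)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    pstar <- 1 - apply(1 - p, 1, prod)
    -(sum(y * log(p) + (1 - y) * log(1 - p)) - sum(log(pstar)))
  }
  init <- rep(0, 1 + use_sex + n_gamma)
  fit <- optim(init, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  p_hat <- unpack(fit$par)
  p_star <- 1 - apply(1 - p_hat, 1, prod)
  coefs <- c(intercept = fit$par[1],
             if (use_sex) c(beta_sex = fit$par[2]),
             if (n_gamma > 0)
               setNames(fit$par[(1 + use_sex) + seq_len(n_gamma)],
                        paste0("occ_", which(occ_free))))
  structure(list(
    n_hat = sum(1 / p_star), p_star = p_star, coefficients = coefs,
    log_lik = -fit$value, convergence = fit$convergence
  ), class = "huggins_fit")
}

#' @export
print.huggins_fit <- function(x, ...) {
  cat(sprintf("Huggins conditional-likelihood estimate: N_hat = %.1f (%d observed)\n",
              x$n_hat, length(x$p_star)))
  invisible(x)
}

#' @rdname huggins_fit
#' @param x a `huggins_fit`.
#' @param ... unused.
#' @export
glance.huggins_fit <- function(x, ...) {
  tibble::tibble(n_hat = x$n_hat, n_observed = length(x$p_star),
                 log_lik = x$log_lik, converged = x$convergence == 0)
}
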