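#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `mass` of the draws:
#' the minimum-width window of `ceiling(mass * n)` consecutive sorted
#' draws.
#'
#' @param draws Numeric vector of posterior draws (>= 50 recommended).
#' @param mass Posterior mass to cover (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  draws <- sort(draws[!is.na(draws)])
  n <- length(draws)
  if (n < 2L) return(c(lower = draws[1], upper = draws[1]))
  k <- ceiling(mass * n)
  k <- min(max(k, 1L), n)
  starts <- seq_len(n - k + 1L)
  widths <- draws[starts + k - 1L] - draws[starts]
  i <- which.min(widths)
  c(lower = draws[i], upper = draws[i + k - 1L])
}

# Per-draw ratio summaries: always ratio-per-draw then summarise, never
# ratio of means.
ratio_summary <- function(num, den, mass = 0.95) {
  ok <- den > 1e-12
  r <- num[ok] / den[ok]
  h <- hpd_interval(r, mass)
  tibble::tibble(estimate = mean(r), conf.low = h[[1]], conf.high = h[[2]],
                 n_excluded = sum(!ok))
}

#' Repeatability of each trait
#'
#' From a model without a separate strain effect: per posterior draw,
#' `Vp[t,t] / (Vp[t,t] + Ve[t])` — how consistent replicate measurements
#' are within a strain relative to across strains. Probit traits are on
#' the latent liability scale (`Ve = 1`).
#'
#' @param fit A `"phylo_mm"` fitted with `strain_effect = FALSE`.
#' @param mass HPD mass (default 0.95).
#' @return Tibble: `trait`, `estimate` (posterior mean), `conf.low`,
#'   `conf.high`, `n_excluded` (draws with numerically zero denominator).
#' @export
repeatability <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "phylo_mm"))
  if (fit$strain_effect)
    stop("repeatability is defined for the model without a strain effect; ",
         "use heritability() for this fit", call. = FALSE)
  purrr::imap_dfr(fit$trait_names, function(tr, t) {
    vp <- pool_Vp(fit, t, t)
    ve <- pool_Ve(fit, t)
    dplyr::bind_cols(tibble::tibble(trait = tr),
                     ratio_summary(vp, vp + ve, mass))
  })
}

#' Phylogenetic heritability of each trait
#'
#' From a model with both phylogenetic and strain effects: per draw,
#' `h2 = Vp/(Vp + Vs)` (proportion of between-strain variance explained
#' by phylogeny) and `h2_total = Vp/(Vp + Vs + Ve)` (proportion of total
#' variance). Probit traits are on the latent liability scale.
#'
#' @param fit A `"phylo_mm"` fitted with `strain_effect = TRUE`.
#' @param mass HPD mass (default 0.95).
#' @return Tibble: `trait`, `statistic` (`"h2"` / `"h2_total"`),
#'   `estimate`, `conf.low`, `conf.high`, `n_excluded`.
#' @export
heritability <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "phylo_mm"))
  if (!fit$strain_effect)
    stop("heritability needs the model with a strain effect; ",
         "use repeatability() for this fit", call. = FALSE)
  purrr::imap_dfr(fit$trait_names, function(tr, t) {
    vp <- pool_Vp(fit, t, t)
    vs <- pool_Vs(fit, t, t)
    ve <- pool_Ve(fit, t)
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(trait = tr, statistic = "h2"),
                       ratio_summary(vp, vp + vs, mass)),
      dplyr::bind_cols(tibble::tibble(trait = tr, statistic = "h2_total"),
                       ratio_summary(vp, vp + vs + ve, mass)))
  })
}

#' Inter-trait phylogenetic correlations and slopes
#'
#' From the phylogenetic covariance matrix, per draw:
#' `r = Vp[x,y] / sqrt(Vp[x,x] * Vp[y,y])` and the regression slope of
#' `y` on `x`, `beta = Vp[x,y] / Vp[x,x]` (asymmetric by definition).
#' Draws with numerically zero variance are excluded and counted.
#'
#' @param fit A `"phylo_mm"` with at least two traits.
#' @param mass HPD mass (default 0.95).
#' @return Tibble: `x`, `y`, `statistic` (`"r"` / `"slope"`),
#'   `estimate`, `conf.low`, `conf.high`, `n_excluded`. Correlations are
#'   reported once per unordered pair; slopes for both orderings.
#' @export
trait_correlations <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "phylo_mm"))
  Tt <- length(fit$trait_names)
  if (Tt < 2) stop("need at least two traits", call. = FALSE)
  out <- list()
  for (i in seq_len(Tt)) for (j in seq_len(Tt)) {
    if (i == j) next
    cov_ij <- pool_Vp(fit, i, j)
    var_i <- pool_Vp(fit, i, i)
    var_j <- pool_Vp(fit, j, j)
    if (i < j)
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(x = fit$trait_names[i], y = fit$trait_names[j],
                       statistic = "r"),
        ratio_summary(cov_ij, sqrt(var_i * var_j), mass))
    # slope of y (= trait j) on x (= trait i)
    out[[length(out) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(x = fit$trait_names[i], y = fit$trait_names[j],
                     statistic = "slope"),
      ratio_summary(cov_ij, var_i, mass))
  }
  dplyr::bind_rows(out)
}

#' Summary of the distance-from-propagation-host effect
#'
#' Posterior mean and HPD interval of the per-trait fixed slope on
#' patristic distance, for fits with a distance covariate.
#'
#' @param fit A `"phylo_mm"` fitted with `distance_from`.
#' @param mass HPD mass (default 0.95).
#' @return Tibble: `trait`, `estimate`, `conf.low`, `conf.high`.
#' @export
distance_effect <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "phylo_mm"))
  if (!fit$has_distance)
    stop("model was fitted without a distance covariate", call. = FALSE)
  Tt <- length(fit$trait_names)
  purrr::imap_dfr(fit$trait_names, function(tr, t) {
    dr <- pool_beta(fit, Tt + t)
    h <- hpd_interval(dr, mass)
    tibble::tibble(trait = tr, estimate = mean(dr),
                   conf.low = h[[1]], conf.high = h[[2]])
  })
}
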