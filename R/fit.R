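#' Fit a multivariate phylogenetic mixed model by MCMC
#'
#' Fits the phylogenetic generalised linear mixed model
#' \deqn{y_{him} = \beta_{1m} (+ \beta_{dm} d_h) + \mu_{p:hm} (+ \mu_{s:hm}) + e_{him}}
#' where the phylogenetic effects have covariance `Vp %x% A` (`A` the
#' relatedness matrix of the tree), the optional strain effects
#' `Vs %x% I`, and residuals are independent with per-trait variances
#' `Ve` (cross-trait residual covariances fixed at 0). Probit traits are
#' handled by latent-liability data augmentation with residual variance
#' fixed at 1. Sampling is by blocked Gibbs with parameter-expanded
#' covariance priors; see [pmm_prior()] and [pmm_chain()].
#'
#' With `strain_effect = TRUE` the model separates phylogenetic from
#' non-phylogenetic between-strain variance ([heritability()] applies);
#' without it the phylogenetic term absorbs all between-strain variance
#' ([repeatability()] applies).
#'
#' @param traits Tidy trait table: columns `strain`, `trait`,
#'   `replicate`, `value`. `NA` values are treated as missing and
#'   predicted by the model (so masking a strain's values yields
#'   out-of-sample predictions).
#' @param tree Rooted `"phylo"` tree with branch lengths whose tips cover
#'   every strain in `traits`.
#' @param trait_types Named vector mapping each trait to `"gaussian"` or
#'   `"probit"`; defaults to the declared traits found in the table,
#'   Gaussian unless the observed values are all 0/1.
#' @param strain_effect Include the non-phylogenetic strain term.
#' @param distance_from Optional: a tip label (e.g. the propagation host)
#'   or a named per-strain numeric vector; adds a per-trait fixed slope
#'   on patristic distance.
#' @param prior A [pmm_prior()].
#' @param chain A [pmm_chain()].
#' @param fix_covariances Optional list with any of `Vp`, `Vs`, `Ve` to
#'   hold fixed instead of sampling (used by the fast leave-one-out mode
#'   and for conditional-prediction checks).
#' @param scale_to_unit_depth Scale `A` to unit maximum depth (default
#'   `FALSE`: unscaled trees, so variance components are per unit branch
#'   length).
#' @param progress Emit a message every 1000 iterations.
#' @return An object of class `"phylo_mm"` with per-chain posterior
#'   draws of fixed effects, covariance matrices, residual variances and
#'   the strain-by-trait linear predictor.
#' @export
fit_phylo_mm <- function(traits, tree, trait_types = NULL,
                         strain_effect = FALSE, distance_from = NULL,
                         prior = pmm_prior(), chain = pmm_chain(),
                         fix_covariances = NULL,
                         scale_to_unit_depth = FALSE, progress = FALSE) {
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("strain", "trait", "value") %in% names(traits)))
  if (is.null(trait_types)) trait_types <- infer_trait_types(traits)
  dat <- pmm_prepare(traits, tree, trait_types, strain_effect,
                     distance_from, scale_to_unit_depth)
  chains <- lapply(seq_len(chain$n_chains), function(cc) {
    pmm_run_chain(dat, prior, chain$n_iter, chain$burn_in, chain$thin,
                  seed = chain_seed(chain$seed, cc),
                  fix = fix_covariances, progress = progress)
  })
  structure(list(
    chains = chains, strains = dat$strains, trait_names = dat$trait_names,
    trait_types = stats::setNames(dat$types, dat$trait_names),
    strain_effect = strain_effect, has_distance = !is.null(dat$d),
    distance = dat$d, tree = tree, A = dat$A, prior = prior,
    chain_settings = chain, n_obs = length(dat$oy)),
    class = "phylo_mm")
}

infer_trait_types <- function(traits) {
  nm <- unique(traits$trait)
  types <- vapply(nm, function(tr) {
    v <- traits$value[traits$trait == tr]
    v <- v[!is.na(v)]
    if (length(v) > 0 && all(v %in% c(0, 1))) "probit" else "gaussian"
  }, character(1))
  stats::setNames(types, nm)
}

#' Number of retained posterior draws (all chains)
#' @param fit A `"phylo_mm"` object.
#' @return Integer draw count.
#' @export
n_draws <- function(fit) {
  sum(vapply(fit$chains, function(ch) nrow(ch$beta), integer(1)))
}

# Pooled draws of one element across chains.
pool_Vp <- function(fit, i, j) {
  unlist(lapply(fit$chains, function(ch) ch$Vp[i, j, ]))
}
pool_Vs <- function(fit, i, j) {
  unlist(lapply(fit$chains, function(ch) ch$Vs[i, j, ]))
}
pool_Ve <- function(fit, t) {
  unlist(lapply(fit$chains, function(ch) ch$Ve[, t]))
}
pool_beta <- function(fit, j) {
  unlist(lapply(fit$chains, function(ch) ch$beta[, j]))
}
# Draws of the linear predictor for strain h, trait t, pooled.
pool_eta <- function(fit, h, t) {
  unlist(lapply(fit$chains, function(ch) ch$eta[h, t, ]))
}

#' Posterior predictions for every strain-by-trait cell
#'
#' Posterior mean of the linear predictor (intercept + phylogenetic and
#' strain effects) per strain and trait; for probit traits also the
#' posterior predictive probability of a positive outcome,
#' `mean(pnorm(eta))` (residual variance 1). For strains whose values
#' were missing or masked these are out-of-sample predictions.
#'
#' @param fit A `"phylo_mm"` object.
#' @return Tibble with columns `strain`, `trait`, `prediction` and
#'   `probability` (NA for Gaussian traits).
#' @export
predicted_values <- function(fit) {
  grid <- expand.grid(h = seq_along(fit$strains),
                      t = seq_along(fit$trait_names))
  purrr::pmap_dfr(grid, function(h, t) {
    eta <- pool_eta(fit, h, t)
    tibble::tibble(
      strain = fit$strains[h], trait = fit$trait_names[t],
      prediction = mean(eta),
      probability = if (fit$trait_types[t] == "probit")
        mean(stats::pnorm(eta)) else NA_real_)
  })
}

#' @export
print.phylo_mm <- function(x, ...) {
  cat("Phylogenetic mixed model (", if (x$strain_effect)
    "phylogenetic + strain effects" else "phylogenetic effects only",
    ")\n", sep = "")
  cat("  traits: ", paste0(x$trait_names, " [", x$trait_types, "]",
                           collapse = ", "), "\n", sep = "")
  cat("  strains:", length(x$strains), "  observations:", x$n_obs, "\n")
  cat("  chains:", length(x$chains), " retained draws:", n_draws(x), "\n")
  invisible(x)
}

#' Tidy posterior summaries of model parameters
#'
#' Broom-style summary: one row per fixed effect, covariance element and
#' residual variance, with posterior mean and 95% HPD interval.
#'
#' @param x A `"phylo_mm"` object.
#' @param conf_level HPD mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @method tidy phylo_mm
#' @export
tidy.phylo_mm <- function(x, conf_level = 0.95, ...) {
  Tt <- length(x$trait_names)
  rows <- list()
  p <- ncol(x$chains[[1]]$beta)
  beta_names <- paste0("intercept_", x$trait_names)
  if (x$has_distance)
    beta_names <- c(beta_names, paste0("distance_", x$trait_names))
  for (j in seq_len(p)) {
    dr <- pool_beta(x, j)
    rows[[length(rows) + 1L]] <- summarise_draws(beta_names[j], dr, conf_level)
  }
  for (i in seq_len(Tt)) for (j in i:Tt) {
    dr <- pool_Vp(x, i, j)
    rows[[length(rows) + 1L]] <- summarise_draws(
      paste0("Vp[", x$trait_names[i], ",", x$trait_names[j], "]"),
      dr, conf_level)
    if (x$strain_effect) {
      dr <- pool_Vs(x, i, j)
      rows[[length(rows) + 1L]] <- summarise_draws(
        paste0("Vs[", x$trait_names[i], ",", x$trait_names[j], "]"),
        dr, conf_level)
    }
  }
  for (t in seq_len(Tt)) {
    dr <- pool_Ve(x, t)
    rows[[length(rows) + 1L]] <- summarise_draws(
      paste0("Ve[", x$trait_names[t], "]"), dr, conf_level)
  }
  dplyr::bind_rows(rows)
}

summarise_draws <- function(term, draws, conf_level = 0.95) {
  h <- hpd_interval(draws, mass = conf_level)
  tibble::tibble(term = term, estimate = mean(draws),
                 conf.low = h[[1]], conf.high = h[[2]])
}

#' One-row model overview
#'
#' @param x A `"phylo_mm"` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of strains, traits, observations,
#'   chains and retained draws, and whether a strain effect was fitted.
#' @method glance phylo_mm
#' @export
glance.phylo_mm <- function(x, ...) {
  tibble::tibble(
    n_strains = length(x$strains), n_traits = length(x$trait_names),
    n_obs = x$n_obs, n_chains = length(x$chains), n_draws = n_draws(x),
    strain_effect = x$strain_effect)
}

#' @export
summary.phylo_mm <- function(object, ...) tidy.phylo_mm(object, ...)

#' Export posterior draws as a tidy table
#'
#' @param fit A `"phylo_mm"` object.
#' @return Tibble with columns `chain`, `iteration`, `parameter`,
#'   `value` covering fixed effects, covariance elements and residual
#'   variances.
#' @export
posterior_draws <- function(fit) {
  Tt <- length(fit$trait_names)
  purrr::imap_dfr(fit$chains, function(ch, cc) {
    nk <- nrow(ch$beta)
    p <- ncol(ch$beta)
    beta_names <- paste0("intercept_", fit$trait_names)
    if (fit$has_distance)
      beta_names <- c(beta_names, paste0("distance_", fit$trait_names))
    pieces <- list()
    for (j in seq_len(p))
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        chain = cc, iteration = seq_len(nk), parameter = beta_names[j],
        value = ch$beta[, j])
    for (i in seq_len(Tt)) for (j in i:Tt) {
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        chain = cc, iteration = seq_len(nk),
        parameter = paste0("Vp[", fit$trait_names[i], ",",
                           fit$trait_names[j], "]"),
        value = ch$Vp[i, j, ])
      if (fit$strain_effect)
        pieces[[length(pieces) + 1L]] <- tibble::tibble(
          chain = cc, iteration = seq_len(nk),
          parameter = paste0("Vs[", fit$trait_names[i], ",",
                             fit$trait_names[j], "]"),
          value = ch$Vs[i, j, ])
    }
    for (t in seq_len(Tt))
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        chain = cc, iteration = seq_len(nk),
        parameter = paste0("Ve[", fit$trait_names[t], "]"),
        value = ch$Ve[, t])
    dplyr::bind_rows(pieces)
  })
}

#' Convergence diagnostics for a fitted model
#'
#' Potential scale reduction factors (PSRF, requires at least two chains)
#' and effective sample sizes per scalar parameter, via
#' [coda::gelman.diag()] and [coda::effectiveSize()]. Parameters with
#' PSRF above 1.1 or ESS below 200 are flagged.
#'
#' @param fit A `"phylo_mm"` object.
#' @param psrf_limit,ess_limit Flagging thresholds.
#' @return Tibble with columns `parameter`, `psrf` (NA with one chain),
#'   `ess`, `flagged`.
#' @export
check_convergence <- function(fit, psrf_limit = 1.1, ess_limit = 200) {
  dr <- posterior_draws(fit)
  params <- unique(dr$parameter)
  mats <- lapply(seq_along(fit$chains), function(cc) {
    m <- sapply(params, function(pp)
      dr$value[dr$chain == cc & dr$parameter == pp])
    coda::mcmc(m)
  })
  ml <- coda::mcmc.list(mats)
  keep <- vapply(params, function(pp) {
    stats::var(unlist(lapply(mats, function(m) as.numeric(m[, pp])))) > 1e-12
  }, logical(1))
  psrf <- rep(NA_real_, length(params))
  if (length(fit$chains) >= 2 && any(keep)) {
    gd <- try(coda::gelman.diag(
      lapply(ml, function(m) m[, params[keep], drop = FALSE]),
      autoburnin = FALSE, multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) psrf[keep] <- gd$psrf[, 1]
  }
  ess <- as.numeric(coda::effectiveSize(ml))
  tibble::tibble(parameter = params, psrf = psrf, ess = ess,
                 flagged = (!is.na(psrf) & psrf > psrf_limit) |
                   ess < ess_limit)
}
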