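#' Priors for the phylogenetic mixed model
#'
#' Covariance matrices of the random terms get parameter-expanded priors:
#' an inverse-Wishart on the working covariance combined with independent
#' normal working scale parameters (mean 0, variance
#' `working_variance`), which induces heavy-tailed scaled-F marginal
#' priors on the variances. Setting `parameter_expansion = FALSE` switches
#' to a plain inverse-Wishart (the robustness-check prior). Residual
#' variances of Gaussian traits get inverse-gamma priors; the residual
#' variance of a probit trait is not identifiable and is fixed at 1, and
#' residual cross-trait covariances are fixed at 0 (each biological
#' replicate measures a single trait).
#'
#' @param working_variance Variance of the normal prior on the working
#'   scale parameters (default 1000).
#' @param nu Inverse-Wishart degrees of freedom; default `T - 1 + 0.002`
#'   where `T` is the number of traits (resolved at fit time).
#' @param V Inverse-Wishart prior covariance; default `diag(T)`. The
#'   scale matrix used is `nu * V`.
#' @param residual_shape,residual_scale Inverse-gamma shape and scale for
#'   Gaussian residual variances (default 0.002, 0.002).
#' @param parameter_expansion Use the parameter-expanded prior (default)
#'   or a plain inverse-Wishart.
#' @return A list of class `"pmm_prior"`.
#' @export
pmm_prior <- function(working_variance = 1000, nu = NULL, V = NULL,
                      residual_shape = 0.002, residual_scale = 0.002,
                      parameter_expansion = TRUE) {
  stopifnot(working_variance > 0, residual_shape > 0, residual_scale > 0)
  structure(list(working_variance = working_variance, nu = nu, V = V,
                 residual_shape = residual_shape,
                 residual_scale = residual_scale,
                 parameter_expansion = parameter_expansion),
            class = "pmm_prior")
}

#' MCMC chain settings
#'
#' Defaults are desk-scale: 40,000 iterations, thinning 20, burn-in
#' 10,000 — the same 4:1 run:burn-in and run:thinning proportions as a
#' full-fidelity run of 13 million generations sampled every 5,000 with 3
#' million burn-in, at a length that fits interactive use. At least 200
#' retained draws per chain are recommended for stable HPD intervals.
#'
#' @param n_iter Total MCMC iterations per chain.
#' @param burn_in Iterations discarded from the start (`< n_iter`).
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param n_chains Number of independent chains (2+ enables PSRF).
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @return A list of class `"pmm_chain"`.
#' @export
pmm_chain <- function(n_iter = 40000, burn_in = 10000, thin = 20,
                      n_chains = 1, seed = 1) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  n_keep <- floor((n_iter - burn_in) / thin)
  if (n_keep < 1) stop("chain settings retain no draws", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), n_keep = as.integer(n_keep)),
            class = "pmm_chain")
}

# Deterministic per-chain seed derived from the master seed, kept < 2^31.
chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 48271 + chain * 16807) %% 2147483647)
}

#' Default trait-type declaration
#'
#' The four-trait panel: binary plaque permissiveness on a probit link and
#' three Gaussian traits (conditional log plaque titre, proportional OD
#' change, log10 fold change in viral load).
#'
#' @return Named character vector mapping trait name to link
#'   (`"probit"` or `"gaussian"`).
#' @export
default_trait_types <- function() {
  c(PA_binary = "probit", PA_cont = "gaussian",
    OD = "gaussian", qPCR = "gaussian")
}
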