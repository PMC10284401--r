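#' Root-mean-squared error
#' @param observed,predicted Equal-length numeric vectors.
#' @return `sqrt(mean((observed - predicted)^2))`.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length", call. = FALSE)
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Wilcoxon rank-sum comparison of two error samples
#'
#' Rank-sum statistic `W` of `x` relative to `y` (midranks for ties) with
#' a two-sided p-value: exact by enumeration when `n1 * n2 <= 400` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity corrections. Computed with [stats::wilcox.test()].
#'
#' @param x,y Numeric vectors (e.g. absolute prediction errors of two
#'   models).
#' @return A list of class `"wilcoxon_rank_sum"`: `W`, `p`, `n1`, `n2`,
#'   `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  structure(list(W = unname(wt$statistic), p = wt$p.value,
                 n1 = length(x), n2 = length(y),
                 exact = use_exact),
            class = "wilcoxon_rank_sum")
}

#' @export
print.wilcoxon_rank_sum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum: W_%d,%d = %g, p = %.4g (%s)\n",
              x$n1, x$n2, x$W, x$p,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

#' Leave-one-out phylogenetic prediction of strain susceptibility
#'
#' For each strain in turn, all of that strain's observations (across all
#' traits simultaneously, so cross-trait correlations cannot leak) are
#' masked and the model predicts them from the phylogeny and the other
#' strains' data. Predictions are posterior means of the held-out
#' strain's linear predictor; probit traits additionally as
#' `P(liability > 0)`. A null (intercept-only, no phylogeny or strain
#' term) prediction is computed from the same training data: the grand
#' mean for Gaussian traits and the observed permissive frequency for
#' probit traits.
#'
#' `mode = "full"` refits the whole model per held-out strain;
#' `mode = "fast"` (default) first fits once on the full data, then holds
#' the covariance matrices at their posterior means and re-runs only the
#' conditional draws of effects and liabilities per strain — an
#' approximation that ignores covariance-parameter uncertainty in the
#' refits.
#'
#' @param traits Tidy trait table (see [fit_phylo_mm()]).
#' @param tree `"phylo"` tree covering all strains.
#' @param trait_types Optional named type vector (see [fit_phylo_mm()]).
#' @param strain_effect Passed to the underlying fits.
#' @param prior,chain Model settings for the full fit; refits reuse them
#'   (fast mode uses `refit_chain`).
#' @param mode `"fast"` or `"full"`.
#' @param refit_chain Chain settings for the per-strain refits in fast
#'   mode (shorter, since covariances are fixed).
#' @param fix_covariances Optional list `Vp`/`Vs`/`Ve` to fix in every
#'   fit (mainly for conditional-prediction checks).
#' @param progress Message per held-out strain.
#' @return An object of class `"phylo_loo"`: tibble with one row per
#'   strain x trait — `strain`, `trait`, `observed` (mean of the held-out
#'   observations; majority permissiveness for probit), `phylo_pred`,
#'   `null_pred` (probability scale for probit traits).
#' @export
loo_predict <- function(traits, tree, trait_types = NULL,
                        strain_effect = FALSE, prior = pmm_prior(),
                        chain = pmm_chain(4000, 1000, 2, seed = 1),
                        mode = c("fast", "full"),
                        refit_chain = pmm_chain(1200, 200, 2,
                                                seed = chain$seed),
                        fix_covariances = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  traits <- tibble::as_tibble(traits)
  if (is.null(trait_types)) trait_types <- infer_trait_types(traits)
  validate_panel(traits, tree)
  strains <- tree$tip.label

  fix <- fix_covariances
  if (mode == "fast" && is.null(fix)) {
    full <- fit_phylo_mm(traits, tree, trait_types,
                         strain_effect = strain_effect,
                         prior = prior, chain = chain)
    Tt <- length(full$trait_names)
    Vp_hat <- matrix(0, Tt, Tt)
    for (i in seq_len(Tt)) for (j in seq_len(Tt))
      Vp_hat[i, j] <- mean(pool_Vp(full, i, j))
    Ve_hat <- vapply(seq_len(Tt), function(t) mean(pool_Ve(full, t)),
                     numeric(1))
    fix <- list(Vp = Vp_hat, Ve = Ve_hat)
    if (strain_effect) {
      Vs_hat <- matrix(0, Tt, Tt)
      for (i in seq_len(Tt)) for (j in seq_len(Tt))
        Vs_hat[i, j] <- mean(pool_Vs(full, i, j))
      fix$Vs <- Vs_hat
    }
  }
  refit_settings <- if (mode == "fast") refit_chain else chain

  rows <- purrr::map_dfr(seq_along(strains), function(si) {
    s <- strains[si]
    if (progress) message("holding out ", s)
    masked <- traits
    masked$value[as.character(masked$strain) == s] <- NA
    fit_s <- fit_phylo_mm(
      masked, tree, trait_types, strain_effect = strain_effect,
      prior = prior,
      chain = pmm_chain(refit_settings$n_iter, refit_settings$burn_in,
                        refit_settings$thin, refit_settings$n_chains,
                        seed = chain_seed(refit_settings$seed, si)),
      fix_covariances = if (mode == "fast") fix else fix_covariances)
    t_idx <- match(names(trait_types), fit_s$trait_names)
    purrr::map_dfr(seq_along(trait_types), function(k) {
      t <- t_idx[k]
      tr <- names(trait_types)[k]
      obs_vals <- traits$value[as.character(traits$strain) == s &
                                 traits$trait == tr]
      obs_vals <- obs_vals[!is.na(obs_vals)]
      train <- traits$value[as.character(traits$strain) != s &
                              traits$trait == tr]
      train <- train[!is.na(train)]
      eta <- pool_eta(fit_s, match(s, fit_s$strains), t)
      if (trait_types[k] == "probit") {
        observed <- if (length(obs_vals) == 0) NA_real_ else
          as.numeric(mean(obs_vals) >= 0.5)   # majority, ties permissive
        phylo_pred <- mean(stats::pnorm(eta))
        null_pred <- if (length(train) == 0) NA_real_ else mean(train)
      } else {
        observed <- if (length(obs_vals) == 0) NA_real_ else mean(obs_vals)
        phylo_pred <- mean(eta)
        null_pred <- if (length(train) == 0) NA_real_ else mean(train)
      }
      tibble::tibble(strain = s, trait = tr, observed = observed,
                     phylo_pred = phylo_pred, null_pred = null_pred)
    })
  })
  structure(rows, class = c("phylo_loo", class(rows)),
            trait_types = trait_types, mode = mode)
}

#' Per-trait error summary of a leave-one-out run
#'
#' RMSE of the phylogenetic and null predictions, binary accuracy for
#' probit traits, and a Wilcoxon rank-sum comparison of the absolute
#' errors of the two models.
#'
#' @param loo A `"phylo_loo"` object.
#' @param threshold Classification threshold for probit traits.
#' @return Tibble: `trait`, `rmse_phylo`, `rmse_null`, `accuracy_phylo`,
#'   `accuracy_null` (NA for Gaussian traits), `wilcoxon_W`,
#'   `wilcoxon_p`.
#' @export
loo_summary <- function(loo, threshold = 0.5) {
  trait_types <- attr(loo, "trait_types")
  purrr::map_dfr(names(trait_types), function(tr) {
    d <- loo[loo$trait == tr & !is.na(loo$observed), ]
    err_p <- abs(d$observed - d$phylo_pred)
    err_n <- abs(d$observed - d$null_pred)
    wt <- wilcoxon_rank_sum(err_p, err_n)
    acc_p <- acc_n <- NA_real_
    if (trait_types[tr] == "probit") {
      acc_p <- mean((d$phylo_pred >= threshold) == (d$observed == 1))
      acc_n <- mean((d$null_pred >= threshold) == (d$observed == 1))
    }
    tibble::tibble(trait = tr,
                   rmse_phylo = rmse(d$observed, d$phylo_pred),
                   rmse_null = rmse(d$observed, d$null_pred),
                   accuracy_phylo = acc_p, accuracy_null = acc_n,
                   wilcoxon_W = wt$W, wilcoxon_p = wt$p)
  })
}

#' Classification accuracy of a binary trait in a leave-one-out run
#'
#' A strain is counted correct when `prediction >= threshold` matches its
#' majority observed permissiveness (ties counted as permissive).
#'
#' @param loo A `"phylo_loo"` object.
#' @param trait Probit trait name (default `"PA_binary"`).
#' @param model `"phylo"` or `"null"`.
#' @param threshold Probability threshold (default 0.5).
#' @return Proportion of strains predicted correctly.
#' @export
binary_accuracy <- function(loo, trait = "PA_binary",
                            model = c("phylo", "null"), threshold = 0.5) {
  model <- match.arg(model)
  d <- loo[loo$trait == trait & !is.na(loo$observed), ]
  if (nrow(d) == 0) stop("no observations for trait ", trait, call. = FALSE)
  pred <- if (model == "phylo") d$phylo_pred else d$null_pred
  mean((pred >= threshold) == (d$observed == 1))
}

#' Observed-versus-predicted panels for a leave-one-out run
#'
#' One panel per trait: held-out observation against phylogenetic
#' prediction, a 1:1 line, dotted RMSE bands around it, and an orange
#' vertical line at the null-model prediction.
#'
#' @param object A `"phylo_loo"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phylo_loo
#' @export
autoplot.phylo_loo <- function(object, ...) {
  d <- object[!is.na(object$observed), ]
  bands <- d |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(rmse = rmse(.data$observed, .data$phylo_pred),
                     null_pred = mean(.data$null_pred), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phylo_pred, y = .data$observed)) +
    ggplot2::geom_vline(data = bands,
                        ggplot2::aes(xintercept = .data$null_pred),
                        colour = "orange", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(data = bands,
                         ggplot2::aes(slope = 1, intercept = .data$rmse),
                         linetype = "dotted") +
    ggplot2::geom_abline(data = bands,
                         ggplot2::aes(slope = 1, intercept = -.data$rmse),
                         linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = "predicted (phylogenetic model)",
                  y = "observed (held-out strain)") +
    ggplot2::theme_bw()
}

#' @export
plot.phylo_loo <- function(x, ...) print(autoplot.phylo_loo(x, ...))
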