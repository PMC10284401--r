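# Synthetic phylogenies and multi-method susceptibility panels with the
# exact covariance structure the mixed model assumes, used as ground
# truth throughout the test suite.

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Unit birth rate, random topology, strictly positive branch lengths;
#' deterministic for a fixed seed. Yule trees produce the clade-structured
#' depth variation typical of a bacterial host panel spanning species and
#' within-species strains.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional seed for reproducibility.
#' @return A `"phylo"` object with tips `s01, s02, ...`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("s%02d", seq_len(n_tips))
  tree
}

#' Simulation configuration for a susceptibility panel
#'
#' Defines the generative model: per-trait intercepts, phylogenetic
#' (`Vp`) and optional strain (`Vs`) covariance matrices, residual
#' variances (`Ve`; fixed at 1 for the probit trait), and the replicate
#' structure. Zero inflation of the continuous plaque trait is generated
#' through the binary liability — a replicate only yields a titre when
#' its liability is positive — so the generator matches the hurdle model
#' the pipeline fits.
#'
#' @param traits Trait names, in order.
#' @param types Per-trait link (`"probit"`/`"gaussian"`).
#' @param intercepts Per-trait intercepts.
#' @param Vp,Vs PSD covariance matrices (Vs may be zero).
#' @param Ve Per-trait residual variances (probit entries forced to 1).
#' @param n_replicates Either a single count or the range `c(4, 6)` from
#'   which per-strain counts are drawn (weighted towards the maximum, as
#'   in panels where most strains reach the full replicate count).
#' @param outlier_rate Proportion of OD replicates replaced by aberrant
#'   low values (simulating anomalous OD readings).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(traits, types, intercepts, Vp, Vs = NULL, Ve,
                       n_replicates = 6, outlier_rate = 0) {
  Tt <- length(traits)
  stopifnot(length(types) == Tt, length(intercepts) == Tt,
            nrow(Vp) == Tt, length(Ve) == Tt)
  if (is.null(Vs)) Vs <- matrix(0, Tt, Tt)
  check_psd(Vp, "Vp"); check_psd(Vs, "Vs")
  if (any(Ve[types == "gaussian"] <= 0))
    stop("Gaussian residual variances must be > 0", call. = FALSE)
  Ve[types == "probit"] <- 1
  if (length(n_replicates) == 1L) n_replicates <- rep(n_replicates, 2L)
  if (min(n_replicates) < 3) stop("n_replicates must be >= 3", call. = FALSE)
  structure(list(traits = traits, types = types, intercepts = intercepts,
                 Vp = Vp, Vs = Vs, Ve = Ve, n_replicates = n_replicates,
                 outlier_rate = outlier_rate),
            class = "sim_config")
}

check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop(name, " is not symmetric", call. = FALSE)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(name, " is not positive semi-definite", call. = FALSE)
  invisible(TRUE)
}

#' Preset simulation configurations
#'
#' `"paper-like"`: the four-trait panel with strong phylogenetic signal —
#' latent-scale binary permissiveness, a weakly heritable conditional
#' titre, OD with repeatability 0.98 and qPCR with 0.99, correlation 0.9
#' among the binary, OD and qPCR phylogenetic effects, and strain
#' variance one ninth of the phylogenetic variance (h2 = 0.9).
#' `"null"`: the same panel with no phylogenetic or strain variance.
#' `"gaussian-pair"`: just the two Gaussian traits (OD, qPCR) with the
#' same variances and their 0.9 correlation — the configuration used for
#' parameter-recovery checks.
#'
#' @param name Preset name.
#' @param strain_variance_ratio `Vs = ratio * Vp` (default 1/9).
#' @return A `"sim_config"`.
#' @export
sim_preset <- function(name = c("paper-like", "null", "gaussian-pair"),
                       strain_variance_ratio = 1 / 9) {
  name <- match.arg(name)
  if (name == "gaussian-pair") {
    sds <- c(OD = sqrt(0.098), qPCR = sqrt(2.0))
    R <- matrix(c(1, 0.9, 0.9, 1), 2)
    Vp <- diag(sds) %*% R %*% diag(sds)
    dimnames(Vp) <- list(names(sds), names(sds))
    return(sim_config(
      traits = c("OD", "qPCR"), types = c("gaussian", "gaussian"),
      intercepts = c(0.5, 2.5), Vp = Vp, Vs = strain_variance_ratio * Vp,
      Ve = c(0.002, 0.0202), n_replicates = 6))
  }
  traits <- c("PA_binary", "PA_cont", "OD", "qPCR")
  types <- c("probit", "gaussian", "gaussian", "gaussian")
  # liability sd ~ 3 gives near-deterministic permissiveness per strain;
  # PA_cont barely heritable (wide CIs), OD/qPCR strongly so.
  sds <- c(PA_binary = 3, PA_cont = 0.22, OD = sqrt(0.098), qPCR = sqrt(2.0))
  R <- diag(4)
  hi <- c(1, 3, 4)                     # binary, OD, qPCR block
  R[hi, hi] <- 0.9; diag(R) <- 1
  Vp <- diag(sds) %*% R %*% diag(sds)
  dimnames(Vp) <- list(traits, traits)
  Ve <- c(1, 1.0, 0.002, 0.0202)
  if (name == "null") {
    Vp[] <- 0
    Vs <- matrix(0, 4, 4)
  } else {
    Vs <- strain_variance_ratio * Vp
  }
  sim_config(traits = traits, types = types,
             intercepts = c(0.5, 4.5, 0.45, 2.5),
             Vp = Vp, Vs = Vs, Ve = Ve,
             n_replicates = c(4, 6), outlier_rate = 0.01)
}

# U (n x Tt) with vec(U) ~ MVN(0, V (x) A): U = L_A Z L_V'.
rmatnorm_kron <- function(V, A) {
  n <- nrow(A); Tt <- nrow(V)
  evA <- eigen(A, symmetric = TRUE)
  LA <- evA$vectors %*% diag(sqrt(pmax(evA$values, 0)), n)
  evV <- eigen(V, symmetric = TRUE)
  LV <- evV$vectors %*% diag(sqrt(pmax(evV$values, 0)), Tt)
  Z <- matrix(stats::rnorm(n * Tt), n, Tt)
  LA %*% Z %*% t(LV)
}

#' Simulate a susceptibility trait table on a phylogeny
#'
#' Draws strain-level phylogenetic effects from `MVN(0, Vp %x% A)` and
#' strain effects from `MVN(0, Vs %x% I)`, then per replicate and trait
#' `y = intercept + u_p + u_s + e`. The probit trait is observed as
#' `1{liability > 0}`; the conditional plaque titre (`PA_cont` when
#' present) is emitted only for permissive replicates. Optional OD
#' outliers are injected as large negative shifts.
#'
#' @param tree `"phylo"` tree.
#' @param config A [sim_config()] / [sim_preset()].
#' @param seed Optional seed.
#' @return A list: `traits` (tidy trait table), `truth` (list with the
#'   drawn `u_p`, `u_s`, liabilities, the config and the tree).
#' @export
simulate_traits <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  A <- relatedness_matrix(tree)
  n <- nrow(A)
  Tt <- length(config$traits)
  Up <- rmatnorm_kron(config$Vp, A)
  Us <- rmatnorm_kron(config$Vs, diag(n))
  dimnames(Up) <- dimnames(Us) <- list(rownames(A), config$traits)

  reps <- if (config$n_replicates[1] == config$n_replicates[2])
    rep(config$n_replicates[1], n)
  else {
    rng <- seq(config$n_replicates[1], config$n_replicates[2])
    # most strains reach the full replicate count
    probs <- c(rep(0.075, length(rng) - 1L), 1 - 0.075 * (length(rng) - 1L))
    sample(rng, n, replace = TRUE, prob = probs)
  }

  bin_t <- which(config$types == "probit")
  has_hurdle <- length(bin_t) == 1L && "PA_cont" %in% config$traits
  cont_t <- if (has_hurdle) which(config$traits == "PA_cont") else integer(0)

  rows <- list()
  liab_rows <- list()
  for (h in seq_len(n)) {
    for (i in seq_len(reps[h])) {
      e <- stats::rnorm(Tt, 0, sqrt(config$Ve))
      y <- config$intercepts + Up[h, ] + Us[h, ] + e
      permissive <- TRUE
      for (t in seq_len(Tt)) {
        val <- y[t]
        if (t %in% bin_t) {
          liab_rows[[length(liab_rows) + 1L]] <- tibble::tibble(
            strain = rownames(A)[h], replicate = i, liability = unname(val))
          permissive <- val > 0
          val <- as.numeric(val > 0)
        }
        if (t %in% cont_t && !permissive) next  # hurdle: no titre
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strain = rownames(A)[h], trait = config$traits[t],
          replicate = i, value = unname(val))
      }
    }
  }
  traits <- dplyr::bind_rows(rows)
  if (config$outlier_rate > 0 && "OD" %in% config$traits) {
    od_i <- which(traits$trait == "OD")
    n_out <- stats::rbinom(1, length(od_i), config$outlier_rate)
    if (n_out > 0) {
      pick <- sample(od_i, n_out)
      traits$value[pick] <- traits$value[pick] - stats::runif(n_out, 2, 4)
    }
  }
  list(traits = traits,
       truth = list(u_p = Up, u_s = Us,
                    liabilities = dplyr::bind_rows(liab_rows),
                    config = config, tree = tree))
}

#' Packaged 8-strain fixture panel
#'
#' A small hand-checked tree and raw assay tables stored with the
#' package (synthetic, constructed for integration tests): 8 strains
#' including one fully resistant clade (`s07`, `s08`), one strain with a
#' major OD outlier (`s03`, replicate 4) and one qPCR record failing the
#' melt filter (`s05`, replicate 1, technical rep 2). Values are frozen
#' in `inst/extdata/`, never regenerated.
#'
#' @return A list: `tree`, `plaque`, `od`, `qpcr` (raw record tables),
#'   `ct_0` (inoculum Ct).
#' @export
fixture_panel <- function() {
  ext <- system.file("extdata", package = "phagephylo")
  list(
    tree = read_tree(file.path(ext, "fixture_tree.nwk")),
    plaque = read_csv_strict(file.path(ext, "fixture_plaque.csv")),
    od = read_csv_strict(file.path(ext, "fixture_od.csv")),
    qpcr = read_csv_strict(file.path(ext, "fixture_qpcr.csv")),
    ct_0 = 20.0)
}

read_csv_strict <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
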