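#' Ancestral state reconstruction under Brownian motion
#'
#' Assigns every internal node the exact conditional expectation of its
#' state under Brownian motion given *all* tip values (global, not local,
#' conditioning): with `C` the tip-tip BM covariance (shared root-to-MRCA
#' path lengths), `c` the node-tip covariances and `mu` the GLS root
#' estimate `1'C^-1 y / 1'C^-1 1`,
#' \deqn{E[node] = mu + c' C^{-1} (y - mu).}
#' The BM rate cancels in the conditional mean; when `sigma2` is supplied
#' (or `"profile"`, the GLS estimate), conditional standard deviations
#' are also returned.
#'
#' @param tree Rooted `"phylo"` tree with branch lengths.
#' @param tip_values Named numeric vector covering every tip.
#' @param sigma2 `NULL` (point estimates only), a BM rate, or
#'   `"profile"`.
#' @return An object of class `"phylo_asr"`: a tibble with columns
#'   `node` (ape node id), `label`, `type` (`"tip"`/`"internal"`),
#'   `value` and optionally `sd`, with the tree attached as an attribute.
#' @export
reconstruct_ancestral <- function(tree, tip_values, sigma2 = NULL) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (is.null(names(tip_values)))
    stop("tip_values must be named by tip label", call. = FALSE)
  missing_tips <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing_tips) > 0)
    stop("missing tip value(s) for: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  y <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(y)) stop("tip_values contain NA", call. = FALSE)

  # Shared-path covariance among all nodes from depths and patristic
  # distances: cov(u, v) = (depth_u + depth_v - dist(u, v)) / 2.
  depth <- ape::node.depth.edgelength(tree)
  D <- ape::dist.nodes(tree)
  S <- (outer(depth, depth, `+`) - D) / 2
  tips <- seq_len(n)
  nodes <- (n + 1L):(n + tree$Nnode)
  C <- S[tips, tips, drop = FALSE]
  cc <- S[nodes, tips, drop = FALSE]
  Ci <- tryCatch(chol2inv(chol(C)),
                 error = function(e) stop(
                   "tip covariance is singular; every tip needs a positive ",
                   "root-to-tip path", call. = FALSE))
  ones <- rep(1, n)
  mu <- sum(Ci %*% y) / sum(Ci)
  anc <- as.numeric(mu + cc %*% Ci %*% (y - mu))

  sd_all <- rep(NA_real_, n + tree$Nnode)
  if (!is.null(sigma2)) {
    if (identical(sigma2, "profile")) {
      r <- y - mu
      sigma2 <- as.numeric(crossprod(r, Ci %*% r)) / (n - 1)
    }
    denom <- sum(Ci)
    cvar <- vapply(seq_along(nodes), function(k) {
      ck <- cc[k, ]
      w <- Ci %*% ck
      # conditional variance + GLS-root uncertainty propagated
      S[nodes[k], nodes[k]] - sum(ck * w) + (1 - sum(w))^2 / denom
    }, numeric(1))
    sd_all[nodes] <- sqrt(pmax(sigma2 * cvar, 0))
    sd_all[tips] <- 0
  }

  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", nodes))
  out <- tibble::tibble(
    node = c(tips, nodes),
    label = labels,
    type = rep(c("tip", "internal"), c(n, tree$Nnode)),
    value = c(y, anc),
    sd = sd_all)
  attr(out, "tree") <- tree
  class(out) <- c("phylo_asr", class(out))
  out
}

#' Ancestral reconstruction of a fitted trait
#'
#' Tip inputs default to each strain's posterior mean linear predictor
#' (intercept plus phylogenetic effect) for the chosen trait, taken from
#' the fitted model; `source = "data"` instead uses raw per-strain means
#' of the observations.
#'
#' @param fit A `"phylo_mm"` object (typically without a strain effect).
#' @param trait Trait name.
#' @param traits Raw trait table, required when `source = "data"`.
#' @param source `"model"` (default) or `"data"`.
#' @param ... Passed to [reconstruct_ancestral()].
#' @return A `"phylo_asr"` object.
#' @export
asr_from_fit <- function(fit, trait, traits = NULL,
                         source = c("model", "data"), ...) {
  source <- match.arg(source)
  t <- match(trait, fit$trait_names)
  if (is.na(t)) stop("unknown trait: ", trait, call. = FALSE)
  if (source == "model") {
    tips <- vapply(seq_along(fit$strains),
                   function(h) mean(pool_eta(fit, h, t)), numeric(1))
    names(tips) <- fit$strains
  } else {
    if (is.null(traits)) stop("source = 'data' needs the trait table",
                              call. = FALSE)
    tv <- traits |>
      dplyr::filter(.data$trait == !!trait, !is.na(.data$value)) |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
    tips <- stats::setNames(tv$value, tv$strain)
  }
  reconstruct_ancestral(fit$tree, tips, ...)
}

#' Export node estimates as CSV
#' @param asr A `"phylo_asr"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asr <- function(asr, path) {
  utils::write.csv(as.data.frame(asr[, c("node", "label", "type", "value")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Annotated Newick with reconstructed node values as labels
#' @param asr A `"phylo_asr"` object.
#' @param path Output path.
#' @param digits Significant digits for node labels.
#' @return `path`, invisibly.
#' @export
write_asr_tree <- function(asr, path, digits = 6) {
  tree <- attr(asr, "tree")
  vals <- asr$value[asr$type == "internal"]
  tree$node.label <- signif(vals, digits)
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Rectangular tree layout: x = depth, y = tip order / mean of children.
tree_layout <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  yy <- numeric(n + tree$Nnode)
  yy[seq_len(n)] <- seq_len(n)
  # postorder so children are set before parents
  po <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(po[, 2], po[, 1])
  for (nm in names(kids)) yy[as.integer(nm)] <- mean(yy[kids[[nm]]])
  list(x = depth, y = yy, edge = tree$edge)
}

#' Plot an ancestral state reconstruction with branch colour gradients
#'
#' Draws the phylogeny with each branch coloured by linear interpolation
#' (in branch-length units) between the parent and child reconstructed
#' values — the smooth fixed-rate transitions expected under Brownian
#' motion. Deterministic for fixed inputs.
#'
#' @param object A `"phylo_asr"` object.
#' @param segments Interpolation segments per branch (default 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phylo_asr
#' @export
autoplot.phylo_asr <- function(object, segments = 12, ...) {
  tree <- attr(object, "tree")
  lay <- tree_layout(tree)
  vals <- object$value[order(object$node)]
  pieces <- purrr::map_dfr(seq_len(nrow(lay$edge)), function(e) {
    par <- lay$edge[e, 1]; chi <- lay$edge[e, 2]
    fr <- seq(0, 1, length.out = segments + 1L)
    x0 <- lay$x[par] + fr * (lay$x[chi] - lay$x[par])
    tibble::tibble(
      x = x0[-length(x0)], xend = x0[-1],
      y = lay$y[chi], yend = lay$y[chi],
      value = vals[par] + (fr[-length(fr)] + fr[-1]) / 2 *
        (vals[chi] - vals[par]))
  })
  verts <- purrr::map_dfr(seq_len(nrow(lay$edge)), function(e) {
    par <- lay$edge[e, 1]; chi <- lay$edge[e, 2]
    tibble::tibble(x = lay$x[par], xend = lay$x[par],
                   y = lay$y[par], yend = lay$y[chi], value = vals[par])
  })
  n <- length(tree$tip.label)
  tips <- tibble::tibble(x = lay$x[seq_len(n)], y = lay$y[seq_len(n)],
                         label = tree$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = verts,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$value),
      linewidth = 0.5) +
    ggplot2::geom_segment(
      data = pieces,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$value),
      linewidth = 0.9) +
    ggplot2::geom_text(
      data = tips,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = -0.1, size = 2.8) +
    ggplot2::scale_colour_viridis_c(option = "inferno", name = "trait value") +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.15))) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
}

#' @export
plot.phylo_asr <- function(x, ...) print(autoplot.phylo_asr(x, ...))
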