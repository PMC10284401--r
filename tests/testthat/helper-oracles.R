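# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route than the package implementation.

# Type-7 quantile by explicit sort-and-interpolate.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Shared root-to-MRCA path length between two nodes, by walking root
# paths on the edge table (independent of ape::vcv / dist.nodes).
oracle_root_path <- function(tree, node) {
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path <- integer(0)
  while (node != root) {
    path <- c(node, path)
    node <- parent[node]
  }
  list(path = c(root, path), parent = parent, elen = elen, root = root)
}

oracle_shared_depth <- function(tree, a, b) {
  pa <- oracle_root_path(tree, a)
  pb <- oracle_root_path(tree, b)
  common <- intersect(pa$path, pb$path)
  sum(pa$elen[setdiff(common, pa$root)])
}

# Tip-tip BM covariance by the oracle route.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  M <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in i:n)
    M[i, j] <- M[j, i] <- oracle_shared_depth(tree, i, j)
  M
}

# BM ancestral states by explicit MVN conditioning with a GLS mean,
# using the oracle covariance construction throughout.
oracle_asr <- function(tree, y) {
  n <- length(tree$tip.label)
  all_nodes <- seq_len(n + tree$Nnode)
  S <- matrix(0, length(all_nodes), length(all_nodes))
  for (i in all_nodes) for (j in all_nodes[all_nodes >= i])
    S[i, j] <- S[j, i] <- oracle_shared_depth(tree, i, j)
  C <- S[seq_len(n), seq_len(n)]
  y <- y[tree$tip.label]
  Ci <- solve(C)
  mu <- sum(Ci %*% y) / sum(Ci)
  internal <- (n + 1):(n + tree$Nnode)
  as.numeric(mu + S[internal, seq_len(n)] %*% Ci %*% (y - mu))
}

# Exact two-sided Wilcoxon rank-sum by full enumeration of group
# assignments (tie-free samples).
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  W_obs <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  vals <- sort(c(x, y))
  idx <- utils::combn(n1 + n2, n1)
  Ws <- apply(idx, 2, function(ii)
    sum(rank(vals)[ii]) - n1 * (n1 + 1) / 2)
  centre <- n1 * n2 / 2
  p <- mean(abs(Ws - centre) >= abs(W_obs - centre) - 1e-9)
  list(W = W_obs, p = p)
}

# One-way ANOVA intraclass correlation (star-tree repeatability oracle).
oracle_icc <- function(values, groups, reps) {
  a <- stats::anova(stats::lm(values ~ factor(groups)))
  msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
  vb <- (msb - msw) / reps
  vb / (vb + msw)
}

# Conditional mean of a held-out strain's trait given the others, from
# the joint Gaussian of strain means with a GLS intercept (flat prior).
oracle_conditional_mean <- function(A, ybar, reps, Vp, Ve, held) {
  obs <- setdiff(seq_len(nrow(A)), held)
  Sig <- Vp * A + diag(Ve / reps, nrow(A))
  S22 <- Sig[obs, obs]
  one <- rep(1, length(obs))
  b <- sum(solve(S22, ybar[obs])) / sum(solve(S22, one))
  as.numeric(b + (Vp * A[held, obs]) %*% solve(S22, ybar[obs] - b))
}

# Small fixtures built in code ----------------------------------------

star_tree <- function(n, depth = 1) {
  tree <- ape::stree(n, "star")
  tree$edge.length <- rep(depth, nrow(tree$edge))
  tree$tip.label <- sprintf("s%02d", seq_len(n))
  tree
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Balanced single-Gaussian-trait panel on an arbitrary tree.
sim_gaussian_panel <- function(tree, Vp = 1, Ve = 1, reps = 6, beta = 0,
                               seed = 1) {
  set.seed(seed)
  A <- relatedness_matrix(tree)
  n <- nrow(A)
  u <- as.vector(t(chol(Vp * A + diag(1e-10, n))) %*% stats::rnorm(n))
  tab <- expand.grid(strain = tree$tip.label, replicate = seq_len(reps),
                     stringsAsFactors = FALSE)
  tab$trait <- "y"
  tab$value <- beta + u[match(tab$strain, tree$tip.label)] +
    stats::rnorm(nrow(tab), 0, sqrt(Ve))
  tibble::as_tibble(tab[, c("strain", "trait", "replicate", "value")])
}

# Minimal phylo_mm-shaped object from hand-set draws, for arithmetic
# checks of the derived statistics.
fake_fit <- function(Vp_draws, Ve_draws, Vs_draws = NULL,
                     trait_names = NULL) {
  Tt <- dim(Vp_draws)[1]
  if (is.null(trait_names)) trait_names <- paste0("t", seq_len(Tt))
  nk <- dim(Vp_draws)[3]
  structure(list(
    chains = list(list(beta = matrix(0, nk, Tt), Vp = Vp_draws,
                       Vs = Vs_draws, Ve = Ve_draws,
                       eta = array(0, c(1, Tt, nk)))),
    strains = "s01", trait_names = trait_names,
    trait_types = stats::setNames(rep("gaussian", Tt), trait_names),
    strain_effect = !is.null(Vs_draws), has_distance = FALSE),
    class = "phylo_mm")
}
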