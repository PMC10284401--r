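# Blocked Gibbs sampler for the multivariate phylogenetic GLMM.
#
# Model, per observation (strain h, trait m, biological replicate i):
#   y_him = beta_1m (+ beta_dm * d_h) + up_hm (+ us_hm) + e_him
# with up ~ N(0, Vp (x) A), us ~ N(0, Vs (x) I), e_him ~ N(0, Ve_m),
# probit traits observed as 1{liability > 0} with Ve fixed at 1.
#
# One iteration:
#   1. joint Gaussian draw of (beta, up, us) from the mixed-model
#      equations given covariances and current liabilities;
#   2. parameter-expanded inverse-Wishart updates of Vp (and Vs):
#      conjugate IW on the working covariance given the effects, then a
#      Gaussian draw of per-trait working scales alpha ~ N(0, wv) from
#      the likelihood, rescaling effects and covariance (Liu-Wu PX);
#   3. conjugate inverse-gamma updates of Gaussian residual variances;
#   4. truncated-normal liability updates for probit observations.
# Missing trait values are excluded from the likelihood; the linear
# predictor over the full strain x trait grid is recorded every retained
# iteration, which is what out-of-sample prediction reads.

# Draw from inverse-Wishart with scale S (of the *inverse*) and df.
riwish <- function(df, S) {
  W <- stats::rWishart(1L, df, chol2inv(chol(S)))[, , 1L]
  chol2inv(chol(W))
}

# Truncated standard-normal draws z > lo (vectorised), via inverse CDF.
rtnorm_lower <- function(lo) {
  p_lo <- stats::pnorm(lo)
  u <- p_lo + stats::runif(length(lo)) * (1 - p_lo)
  stats::qnorm(pmin(pmax(u, 1e-15), 1 - 1e-15))
}
rtnorm_upper <- function(hi) -rtnorm_lower(-hi)

# Assemble data structures shared by every chain.
pmm_prepare <- function(traits, tree, trait_types, strain_effect,
                        distance_from, scale_to_unit_depth) {
  validate_panel(traits, tree)
  trait_names <- names(trait_types)
  bad <- setdiff(unique(traits$trait), trait_names)
  if (length(bad) > 0)
    stop("trait(s) not declared in trait_types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  strains <- tree$tip.label
  n <- length(strains)
  Tt <- length(trait_names)
  A <- relatedness_matrix(tree, scale_to_unit_depth = scale_to_unit_depth)
  cholA <- tryCatch(chol(A), error = function(e)
    stop("relatedness matrix is not positive definite", call. = FALSE))
  Ainv <- chol2inv(cholA)

  obs <- traits[!is.na(traits$value), , drop = FALSE]
  ot <- match(obs$trait, trait_names)
  oh <- match(as.character(obs$strain), strains)
  oy <- as.numeric(obs$value)
  obin <- trait_types[ot] == "probit"
  if (any(obin) && !all(oy[obin] %in% c(0, 1)))
    stop("probit trait values must be coded 0/1", call. = FALSE)
  for (t in seq_len(Tt)) {
    v <- oy[ot == t & !obin]
    if (length(v) > 1 && stats::var(v) < 1e-12)
      warning("trait '", trait_names[t], "' has (near) zero variance",
              call. = FALSE)
  }
  counts <- matrix(0, n, Tt)
  tab <- table(factor(oh, levels = seq_len(n)), factor(ot, levels = seq_len(Tt)))
  counts[] <- as.numeric(tab)

  d <- NULL
  if (!is.null(distance_from)) {
    if (length(distance_from) == 1L && is.character(distance_from)) {
      d <- patristic_distances_from(tree, distance_from)[strains]
    } else {
      if (is.null(names(distance_from)) ||
          !all(strains %in% names(distance_from)))
        stop("distance_from must be a tip label or a named vector covering ",
             "all strains", call. = FALSE)
      d <- distance_from[strains]
    }
  }
  list(n = n, Tt = Tt, strains = strains, trait_names = trait_names,
       types = unname(trait_types), A = A, Ainv = Ainv,
       ot = ot, oh = oh, oy = oy, obin = obin, ok = (ot - 1L) * n + oh,
       counts = counts, d = d, strain_effect = strain_effect)
}

# Run one chain; returns a list of draw arrays.
pmm_run_chain <- function(dat, prior, n_iter, burn_in, thin, seed,
                          fix = NULL, progress = FALSE) {
  set.seed(seed)
  n <- dat$n; Tt <- dat$Tt
  gaussian_t <- dat$types == "gaussian"
  ot <- dat$ot; oh <- dat$oh; oy <- dat$oy; obin <- dat$obin; ok <- dat$ok
  has_dist <- !is.null(dat$d)
  use_s <- dat$strain_effect
  p <- if (has_dist) 2L * Tt else Tt
  nT <- n * Tt
  q <- p + nT + if (use_s) nT else 0L
  ip <- p + seq_len(nT)                      # indices of up in theta
  is_ <- if (use_s) p + nT + seq_len(nT) else integer(0)

  nu0 <- if (is.null(prior$nu)) Tt - 1 + 0.002 else prior$nu
  V0 <- if (is.null(prior$V)) diag(Tt) else prior$V
  S0 <- nu0 * V0
  wv <- prior$working_variance
  px <- prior$parameter_expansion
  fix_Vp <- !is.null(fix$Vp); fix_Vs <- !is.null(fix$Vs)
  fix_Ve <- !is.null(fix$Ve)

  # fixed-effect design summaries per trait
  cs <- colSums(dat$counts)                      # obs per trait
  if (has_dist) {
    csd <- colSums(dat$counts * dat$d)
    csd2 <- colSums(dat$counts * dat$d^2)
  }

  # initial state
  Ve <- vapply(seq_len(Tt), function(t) {
    v <- oy[ot == t & !obin]
    if (length(v) > 1 && stats::var(v) > 1e-8) stats::var(v) else 1
  }, numeric(1))
  Ve[!gaussian_t] <- 1
  if (fix_Ve) { Ve <- fix$Ve; Ve[!gaussian_t] <- 1 }
  Vp <- if (fix_Vp) fix$Vp else diag(Ve, Tt)
  Vs <- if (use_s) { if (fix_Vs) fix$Vs else diag(Ve, Tt) } else NULL
  Up <- matrix(0, n, Tt)
  Us <- matrix(0, n, Tt)
  alpha_p <- rep(1, Tt)
  alpha_s <- rep(1, Tt)
  beta <- numeric(p)
  liab <- ifelse(oy[obin] > 0, 0.5, -0.5)
  eta_grid <- matrix(0, n, Tt)

  n_keep <- floor((n_iter - burn_in) / thin)
  draw_beta <- matrix(NA_real_, n_keep, p)
  draw_Vp <- array(NA_real_, c(Tt, Tt, n_keep))
  draw_Vs <- if (use_s) array(NA_real_, c(Tt, Tt, n_keep)) else NULL
  draw_Ve <- matrix(NA_real_, n_keep, Tt)
  draw_eta <- array(NA_real_, c(n, Tt, n_keep))
  kept <- 0L

  obs_by_t <- lapply(seq_len(Tt), function(t) which(ot == t))
  w_obs_t <- ot                                  # trait index per obs

  for (iter in seq_len(n_iter)) {
    ystar <- oy
    if (any(obin)) ystar[obin] <- liab
    w <- 1 / Ve

    ## -- 1. joint (beta, up, us) draw via mixed-model equations --------
    Dw <- as.vector(sweep(dat$counts, 2, w, `*`))  # trait-major vec (h fastest)
    svec <- numeric(nT)
    agg <- rowsum(ystar, ok)
    svec[as.integer(rownames(agg))] <- agg

    C <- matrix(0, q, q)
    # fixed-effects block
    for (t in seq_len(Tt)) {
      C[t, t] <- w[t] * cs[t] + 1e-8
      if (has_dist) {
        C[t, Tt + t] <- C[Tt + t, t] <- w[t] * csd[t]
        C[Tt + t, Tt + t] <- w[t] * csd2[t] + 1e-8
      }
    }
    # beta x up / beta x us couplings
    for (t in seq_len(Tt)) {
      kk <- (t - 1L) * n + seq_len(n)
      row_i <- w[t] * dat$counts[, t]
      C[t, p + kk] <- row_i
      if (use_s) C[t, p + nT + kk] <- row_i
      if (has_dist) {
        row_d <- row_i * dat$d
        C[Tt + t, p + kk] <- row_d
        if (use_s) C[Tt + t, p + nT + kk] <- row_d
      }
    }
    C[ip, seq_len(p)] <- t(C[seq_len(p), ip])
    if (use_s) C[is_, seq_len(p)] <- t(C[seq_len(p), is_])
    # random-effect blocks
    Cpp <- kronecker(chol2inv(chol(Vp)), dat$Ainv)
    diag(Cpp) <- diag(Cpp) + Dw
    C[ip, ip] <- Cpp
    if (use_s) {
      Css <- kronecker(chol2inv(chol(Vs)), diag(n))
      diag(Css) <- diag(Css) + Dw
      C[is_, is_] <- Css
      C[cbind(ip, is_)] <- C[cbind(ip, is_)] + Dw
      C[cbind(is_, ip)] <- C[cbind(is_, ip)] + Dw
    }
    rhs <- numeric(q)
    for (t in seq_len(Tt)) {
      kk <- (t - 1L) * n + seq_len(n)
      rhs[t] <- w[t] * sum(svec[kk])
      if (has_dist) rhs[Tt + t] <- w[t] * sum(dat$d * svec[kk])
    }
    rhs[ip] <- rhs[ip] + rep(w, each = n) * svec
    if (use_s) rhs[is_] <- rhs[is_] + rep(w, each = n) * svec

    R <- chol(C)
    mn <- backsolve(R, forwardsolve(t(R), rhs))
    theta <- mn + backsolve(R, stats::rnorm(q))
    beta <- theta[seq_len(p)]
    Up[] <- theta[ip]
    if (use_s) Us[] <- theta[is_]

    eta_grid[] <- rep(beta[seq_len(Tt)], each = n) + Up
    if (use_s) eta_grid <- eta_grid + Us
    if (has_dist)
      eta_grid <- eta_grid + outer(dat$d, beta[Tt + seq_len(Tt)])
    resid <- ystar - eta_grid[cbind(oh, ot)]

    ## -- 2. covariance updates (PX inverse-Wishart) --------------------
    # Liu-Wu parameter expansion with persistent working scales: the
    # data-scale effects are u = alpha * u_tilde, the IW prior sits on
    # the working covariance of u_tilde, and alpha ~ N(0, wv) absorbs
    # the overall scale, giving scaled-F marginal priors on V.
    if (!fix_Vp) {
      if (px) {
        Ut <- sweep(Up, 2, alpha_p, `/`)
        Vt <- riwish(nu0 + n, S0 + crossprod(Ut, dat$Ainv %*% Ut))
        for (t in seq_len(Tt)) {
          j <- obs_by_t[[t]]
          u_j <- Ut[oh[j], t]
          rho <- resid[j] + Up[oh[j], t]
          prec <- w[t] * sum(u_j^2) + 1 / wv
          mu_a <- w[t] * sum(u_j * rho) / prec
          a <- stats::rnorm(1, mu_a, sqrt(1 / prec))
          alpha_p[t] <- if (abs(a) < 1e-8) sign(a + 1e-12) * 1e-8 else a
        }
        Up_new <- sweep(Ut, 2, alpha_p, `*`)
        Vp <- diag(alpha_p, Tt) %*% Vt %*% diag(alpha_p, Tt)
        eta_grid <- eta_grid - Up + Up_new
        Up <- Up_new
        resid <- ystar - eta_grid[cbind(oh, ot)]
      } else {
        Vp <- riwish(nu0 + n, S0 + crossprod(Up, dat$Ainv %*% Up))
      }
      Vp <- (Vp + t(Vp)) / 2
    }
    if (use_s && !fix_Vs) {
      if (px) {
        Ut <- sweep(Us, 2, alpha_s, `/`)
        Vt <- riwish(nu0 + n, S0 + crossprod(Ut))
        for (t in seq_len(Tt)) {
          j <- obs_by_t[[t]]
          u_j <- Ut[oh[j], t]
          rho <- resid[j] + Us[oh[j], t]
          prec <- w[t] * sum(u_j^2) + 1 / wv
          mu_a <- w[t] * sum(u_j * rho) / prec
          a <- stats::rnorm(1, mu_a, sqrt(1 / prec))
          alpha_s[t] <- if (abs(a) < 1e-8) sign(a + 1e-12) * 1e-8 else a
        }
        Us_new <- sweep(Ut, 2, alpha_s, `*`)
        Vs <- diag(alpha_s, Tt) %*% Vt %*% diag(alpha_s, Tt)
        eta_grid <- eta_grid - Us + Us_new
        Us <- Us_new
        resid <- ystar - eta_grid[cbind(oh, ot)]
      } else {
        Vs <- riwish(nu0 + n, S0 + crossprod(Us))
      }
      Vs <- (Vs + t(Vs)) / 2
    }

    ## -- 3. Gaussian residual variances --------------------------------
    if (!fix_Ve) {
      for (t in which(gaussian_t)) {
        j <- obs_by_t[[t]]
        shape <- prior$residual_shape + length(j) / 2
        rate <- prior$residual_scale + sum(resid[j]^2) / 2
        Ve[t] <- 1 / stats::rgamma(1, shape, rate)
      }
    }

    ## -- 4. probit liabilities ------------------------------------------
    if (any(obin)) {
      m_bin <- eta_grid[cbind(oh, ot)][obin]
      y_bin <- oy[obin]
      z <- numeric(length(m_bin))
      up_i <- y_bin > 0
      if (any(up_i)) z[up_i] <- rtnorm_lower(-m_bin[up_i])
      if (any(!up_i)) z[!up_i] <- rtnorm_upper(-m_bin[!up_i])
      liab <- m_bin + z
    }

    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draw_beta[kept, ] <- beta
      draw_Vp[, , kept] <- Vp
      if (use_s) draw_Vs[, , kept] <- Vs
      draw_Ve[kept, ] <- Ve
      draw_eta[, , kept] <- eta_grid
    }
    if (progress && iter %% 1000L == 0L)
      message("iteration ", iter, "/", n_iter)
  }
  list(beta = draw_beta, Vp = draw_Vp, Vs = draw_Vs, Ve = draw_Ve,
       eta = draw_eta, seed = seed)
}
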