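test_that("rmse follows its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1:10, 1:10 + 2), 2)
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("Wilcoxon rank-sum matches hand-derived small cases", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$W, 0)
  expect_equal(w$p, 1 / 3, tolerance = 1e-10)
  expect_true(w$exact)
  w2 <- wilcoxon_rank_sum(c(1, 4), c(2, 3))
  expect_equal(w2$W, 2)   # = n1 n2 / 2, perfectly interleaved
  expect_equal(w2$p, 1)
  # identical samples: midranks give the central statistic
  w3 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w3$W, 4.5)  # n1 n2 / 2
  expect_false(w3$exact)   # ties force the approximation
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("exact p-values match enumeration for all tie-free n1, n2 <= 5", {
  set.seed(61)
  for (n1 in 1:5) for (n2 in 1:5) {
    vals <- sample(seq_len(40), n1 + n2)   # distinct -> tie-free
    x <- vals[seq_len(n1)]
    y <- vals[n1 + seq_len(n2)]
    got <- wilcoxon_rank_sum(x, y)
    want <- oracle_wilcoxon(x, y)
    expect_equal(got$W, want$W, info = sprintf("n1=%d n2=%d", n1, n2))
    expect_equal(got$p, want$p, tolerance = 1e-10,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("held-out predictions match the closed-form conditional mean", {
  t3 <- toy_tree()
  A <- relatedness_matrix(t3)
  Vp <- 1; Ve <- 0.25; reps <- 4
  traits <- sim_gaussian_panel(t3, Vp = Vp, Ve = Ve, reps = reps, beta = 1,
                               seed = 62)
  ybar <- tapply(traits$value, traits$strain, mean)[t3$tip.label]
  loo <- loo_predict(traits, t3,
                     fix_covariances = list(Vp = matrix(Vp, 1, 1), Ve = Ve),
                     refit_chain = pmm_chain(5000, 1000, 2, seed = 18),
                     mode = "fast")
  for (h in 1:3) {
    oracle <- oracle_conditional_mean(A, ybar, reps, Vp, Ve, held = h)
    got <- loo$phylo_pred[loo$strain == t3$tip.label[h]]
    expect_equal(got, oracle, tolerance = 0.05)
  }
})

test_that("null predictions equal the training grand mean", {
  tree <- simulate_tree(10, seed = 63)
  traits <- sim_gaussian_panel(tree, Vp = 0.5, Ve = 0.5, reps = 4, seed = 64)
  loo <- loo_predict(traits, tree, chain = pmm_chain(1200, 300, 3, seed = 19),
                     refit_chain = pmm_chain(600, 150, 3, seed = 19))
  for (s in tree$tip.label) {
    train_mean <- mean(traits$value[traits$strain != s])
    expect_equal(loo$null_pred[loo$strain == s], train_mean,
                 tolerance = 1e-10)
  }
})

test_that("star-tree phylo and null predictions coincide", {
  tree <- star_tree(10)
  traits <- sim_gaussian_panel(tree, Vp = 1, Ve = 0.5, reps = 4, seed = 65)
  loo <- loo_predict(traits, tree, chain = pmm_chain(2000, 500, 3, seed = 20),
                     refit_chain = pmm_chain(1500, 300, 3, seed = 20))
  expect_equal(loo$phylo_pred, loo$null_pred, tolerance = 0.2)
})

test_that("binary accuracy counts majority-matched strains", {
  d <- tibble::tibble(
    strain = letters[1:4], trait = "PA_binary",
    observed = c(1, 1, 0, 0),
    phylo_pred = c(0.9, 0.9, 0.9, 0.9),
    null_pred = c(0.6, 0.6, 0.6, 0.6))
  loo <- structure(d, class = c("phylo_loo", class(d)),
                   trait_types = c(PA_binary = "probit"))
  expect_equal(binary_accuracy(loo), 0.5)  # constant prediction, half right
  d2 <- d; d2$observed <- 1
  loo2 <- structure(d2, class = c("phylo_loo", class(d2)),
                    trait_types = c(PA_binary = "probit"))
  expect_equal(binary_accuracy(loo2), 1)
  expect_equal(binary_accuracy(loo2, model = "null"), 1)
})

test_that("clade-structured resistance is predicted better with phylogeny", {
  # one resistant clade in a 16-strain panel, strong liability signal;
  # the null model predicts the permissive majority for everyone
  wins <- 0L
  for (run in 1:6) {
    tree <- simulate_tree(16, seed = 100 + run)
    # smallest clade with >= 4 tips becomes the resistant clade
    clade <- NULL
    for (node in 17:31) {
      tips <- ape::extract.clade(tree, node)$tip.label
      if (length(tips) >= 4 && length(tips) <= 6) { clade <- tips; break }
    }
    skip_if(is.null(clade), "no suitably sized clade in this tree")
    u <- ifelse(tree$tip.label %in% clade, -3, 3)
    set.seed(200 + run)
    traits <- tidyr::expand_grid(strain = tree$tip.label, replicate = 1:4) |>
      dplyr::mutate(trait = "PA_binary",
                    value = as.numeric(
                      u[match(strain, tree$tip.label)] + rnorm(dplyr::n()) > 0))
    loo <- loo_predict(traits, tree,
                       trait_types = c(PA_binary = "probit"),
                       chain = pmm_chain(1500, 400, 3, seed = 300 + run),
                       refit_chain = pmm_chain(800, 200, 3, seed = 300 + run))
    acc_p <- binary_accuracy(loo)
    acc_n <- binary_accuracy(loo, model = "null")
    if (acc_p > acc_n) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})

test_that("loo summary and plot cover every trait", {
  tree <- simulate_tree(8, seed = 66)
  cfg <- sim_preset("gaussian-pair")
  sim <- simulate_traits(tree, cfg, seed = 67)
  loo <- loo_predict(sim$traits, tree,
                     chain = pmm_chain(1000, 300, 3, seed = 21),
                     refit_chain = pmm_chain(600, 150, 3, seed = 21))
  summ <- loo_summary(loo)
  expect_setequal(summ$trait, c("OD", "qPCR"))
  expect_true(all(is.finite(summ$rmse_phylo)))
  expect_true(all(is.finite(summ$wilcoxon_p)))
  expect_s3_class(autoplot(loo), "ggplot")
})
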