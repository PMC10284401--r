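test_that("od_change formula, scale invariance and error handling", {
  expect_equal(od_change(1.0, 0.1), 0.9)
  expect_equal(od_change(0.5, 0.5), 0.0)
  expect_equal(od_change(0.4, 0.6), -0.5)
  # scale invariance
  set.seed(1)
  u <- runif(20, 0.2, 2); i <- runif(20, 0, 2); cc <- runif(20, 0.1, 5)
  expect_equal(od_change(cc * u, cc * i), od_change(u, i))
  expect_error(od_change(0, 0.1), "> 0")
})

test_that("MOI arithmetic from final concentrations", {
  expect_equal(moi(2.5e3, 5e4), 0.05)
  expect_error(moi(1, 0), "> 0")
})

test_that("IQR outlier flags agree with the quantile oracle", {
  v <- c(1, 2, 3, 4, 100)
  q1 <- oracle_quantile7(v, 0.25); q3 <- oracle_quantile7(v, 0.75)
  iqr <- q3 - q1
  expect_equal(iqr_outlier_flags(v, "minor"),
               v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr)
  expect_equal(which(iqr_outlier_flags(v, "minor")), 5L)
  expect_equal(sum(iqr_outlier_flags(rep(5, 5), "minor")), 0L)
  # [1..5] at major: fence exceeds the extremes under type 7
  expect_equal(sum(iqr_outlier_flags(1:5, "major")), 0L)
  expect_error(iqr_outlier_flags(1:3), "at least 4")
  # idempotence on well-spread data with gross outliers: re-flagging the
  # retained set flags nothing new
  set.seed(2)
  for (rep in 1:10) {
    x <- c(runif(12), runif(2, 8, 15))
    for (sev in c("minor", "major")) {
      kept <- x[!iqr_outlier_flags(x, sev)]
      if (length(kept) >= 4)
        expect_equal(sum(iqr_outlier_flags(kept, sev)), 0L)
    }
  }
})

test_that("plaque titres pick the most-diluted countable spot", {
  expect_equal(pfu_per_ul(50, -6, 5), 1e7)
  expect_equal(pfu_per_ul(10, 0, 5), 2)
  rec <- tibble::tibble(
    strain = "s", replicate = 1,
    dilution_exponent = c(0, -2, -4, -6),
    plaque_count = c(NA, 300, 50, 0),   # confluent, too many, countable, none
    spotted_volume = 5)
  expect_equal(plaque_titres(rec)$titre, 50 / (5 * 1e-4))
  rec0 <- rec; rec0$plaque_count <- c(0, 0, 0, 0)
  expect_true(is.na(plaque_titres(rec0)$titre))
})

test_that("hurdle decomposition partitions replicates", {
  titres <- tibble::tibble(strain = "s", replicate = 1:2,
                           titre = c(NA, 5000))
  out <- hurdle_decompose(titres)
  expect_equal(out$value[out$trait == "PA_binary"], c(0, 1))
  expect_equal(out$value[out$trait == "PA_cont"], log10(5000))
  # partition counts conserve replicates
  set.seed(3)
  tt <- tibble::tibble(strain = rep(letters[1:6], each = 5),
                       replicate = rep(1:5, 6),
                       titre = ifelse(runif(30) < 0.4, NA, 10^runif(30, 2, 6)))
  dec <- hurdle_decompose(tt)
  expect_equal(sum(dec$trait == "PA_binary"), nrow(tt))
  expect_equal(sum(dec$trait == "PA_cont"),
               sum(dec$value[dec$trait == "PA_binary"]))
  # all-absent and all-present extremes
  expect_equal(sum(hurdle_decompose(
    tibble::tibble(strain = "s", replicate = 1:3, titre = NA_real_))$value), 0)
  allp <- hurdle_decompose(
    tibble::tibble(strain = "s", replicate = 1:3, titre = 100))
  expect_equal(allp$value[allp$trait == "PA_binary"], rep(1, 3))
})

test_that("melt filter drops failed and off-peak records", {
  rec <- tibble::tibble(
    ct = c(15, 16, 15.5, NA, 17),
    melt_peak = c(78, 78.2, 77.9, 78, 80))
  kept <- melt_filter(rec, tolerance = 1.5)
  expect_equal(nrow(kept), 3L)            # NA ct and the 80C peak dropped
  expect_equal(attr(kept, "n_dropped"), 2L)
  kept2 <- melt_filter(rec, tolerance = 1.5, reference = 78)
  expect_false(any(abs(kept2$melt_peak - 78) > 1.5))
  expect_error(melt_filter(tibble::tibble(ct = NA_real_, melt_peak = 78)),
               "no positive samples")
})

test_that("plate correction removes a balanced plate offset exactly", {
  base <- tibble::tibble(strain = rep(letters[1:4], each = 2),
                         replicate = 1, ct = rep(c(15, 18, 20, 23), each = 2))
  rec <- base
  rec$plate <- rep(c("P1", "P2"), 4)
  rec$ct <- rec$ct + ifelse(rec$plate == "P2", 0.8, 0)
  out <- plate_correct(rec)
  # corrected values identical across plates per sample
  sp <- split(out$ct_corrected, out$strain)
  for (v in sp) expect_equal(v[1], v[2], tolerance = 1e-10)
  # each sample's cross-plate mean preserved
  for (s in letters[1:4])
    expect_equal(mean(out$ct_corrected[out$strain == s]),
                 mean(rec$ct[rec$strain == s]), tolerance = 1e-10)
  # single plate: no-op
  one <- base; one$plate <- "P1"
  expect_equal(plate_correct(one)$ct_corrected, one$ct)
  # no offset: correction is numerically zero
  flat <- base; flat$plate <- rep(c("P1", "P2"), 4)
  expect_equal(plate_correct(flat)$ct_corrected, flat$ct, tolerance = 1e-10)
  # confounded plates: warn and skip
  conf <- base; conf$plate <- rep(c("P1", "P1", "P2", "P2"), 2)[1:8]
  conf$plate <- c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P2")
  expect_warning(plate_correct(conf), "confounded")
})

test_that("qPCR fold change follows the 2^-dCt conversion", {
  expect_equal(qpcr_fold_change(20, 20), 0)
  expect_equal(qpcr_fold_change(20, 30), 10 * log10(2), tolerance = 1e-6)
  expect_equal(qpcr_fold_change(20, 30), 3.0103, tolerance = 1e-4)
  expect_equal(qpcr_fold_change(31, 30), -0.3010, tolerance = 1e-4)
  # antisymmetry
  set.seed(4)
  a <- runif(20, 10, 35); b <- runif(20, 10, 35)
  expect_equal(qpcr_fold_change(a, b), -qpcr_fold_change(b, a))
})

test_that("prepare_traits reproduces the frozen fixture table", {
  fx <- fixture_panel()
  prep <- prepare_traits(fx$plaque, fx$od, fx$qpcr, ct_0 = fx$ct_0)
  golden <- read.csv(system.file("extdata", "fixture_traits.csv",
                                 package = "phagephylo"))
  expect_equal(as.data.frame(prep$traits), golden, tolerance = 1e-12)
  # resistant clade is all non-permissive
  pa <- prep$traits[prep$traits$trait == "PA_binary", ]
  expect_true(all(pa$value[pa$strain %in% c("s07", "s08")] == 0))
  expect_true(all(pa$value[pa$strain == "s01"] == 1))
  # the major OD outlier was removed
  od3 <- prep$traits[prep$traits$trait == "OD" & prep$traits$strain == "s03", ]
  expect_false(4 %in% od3$replicate)
  # severity toggle changes only the OD drop count
  prep_major <- prepare_traits(fx$plaque, fx$od, fx$qpcr, ct_0 = fx$ct_0,
                               od_outliers = "major")
  expect_equal(prep$report$n_dropped[c(1, 3)],
               prep_major$report$n_dropped[c(1, 3)])
  expect_gt(prep$report$n_dropped[2], prep_major$report$n_dropped[2])
})
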