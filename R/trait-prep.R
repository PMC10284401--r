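#' Proportional change in optical density due to infection
#'
#' Susceptibility on the OD scale, standardised for differences in growth
#' rate between strains: `(OD_uninfected - OD_infected) / OD_uninfected`.
#' Can be negative when the infected culture grew more than the control.
#'
#' @param od_uninfected,od_infected OD600 readings of the paired uninfected
#'   and infected cultures. Vectorised.
#' @return Numeric vector of proportional OD changes.
#' @export
od_change <- function(od_uninfected, od_infected) {
  if (any(od_uninfected <= 0, na.rm = TRUE))
    stop("od_uninfected must be > 0", call. = FALSE)
  (od_uninfected - od_infected) / od_uninfected
}

#' Multiplicity of infection at inoculation
#'
#' Ratio of infectious phage particles to bacterial cells, from the final
#' in-well concentrations.
#'
#' @param pfu_per_ml Phage concentration (PFU/mL).
#' @param cfu_per_ml Bacterial concentration (CFU/mL).
#' @return The MOI (dimensionless).
#' @export
moi <- function(pfu_per_ml, cfu_per_ml) {
  if (any(cfu_per_ml <= 0)) stop("cfu_per_ml must be > 0", call. = FALSE)
  pfu_per_ml / cfu_per_ml
}

#' Tukey-fence outlier flags
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` with `k = 1.5` for
#' `severity = "minor"` and `k = 3` for `"major"`. Quartiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7);
#' flags near the fence depend on this convention, so it is fixed here.
#'
#' @param values Numeric vector (at least 4 values; quartiles are unstable
#'   below that).
#' @param severity `"minor"` (k = 1.5) or `"major"` (k = 3).
#' @return Logical vector, `TRUE` where the value lies outside the fences.
#' @export
iqr_outlier_flags <- function(values, severity = c("minor", "major")) {
  severity <- match.arg(severity)
  vals <- values[!is.na(values)]
  if (length(vals) < 4L)
    stop("need at least 4 non-missing values to place quartile fences; got ",
         length(vals), call. = FALSE)
  k <- if (severity == "minor") 1.5 else 3
  q <- stats::quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  out <- values < q[1] - k * iqr | values > q[2] + k * iqr
  out & !is.na(values)
}

#' Plaque titre from a spot count
#'
#' Converts a plaque count at a known dilution and spotted volume to
#' PFU/uL: `count / (volume * 10^dilution_exponent)`.
#'
#' @param plaque_count Non-negative plaque count. Vectorised.
#' @param dilution_exponent Base-10 dilution exponent (0 for undiluted,
#'   -6 for a 10^-6 dilution).
#' @param spotted_volume Spotted volume in uL (> 0).
#' @return Titre in PFU/uL.
#' @export
pfu_per_ul <- function(plaque_count, dilution_exponent, spotted_volume) {
  if (any(spotted_volume <= 0)) stop("spotted_volume must be > 0", call. = FALSE)
  if (any(plaque_count < 0, na.rm = TRUE))
    stop("plaque_count must be >= 0", call. = FALSE)
  plaque_count / (spotted_volume * 10^dilution_exponent)
}

#' Per-replicate plaque titres from a spotting series
#'
#' For each (strain, replicate), picks the most-diluted spot whose count
#' lies inside the countable window and converts it to PFU/uL — the
#' "dilution with the highest number of discernible plaques" read in
#' reverse: past that dilution counts fall to zero, before it spots are
#' confluent. Replicates with no countable non-zero spot get `NA` titre
#' (non-permissive, or unreadable).
#'
#' @param records Data frame with columns `strain`, `replicate`,
#'   `dilution_exponent`, `plaque_count` (`NA` for uncountable/confluent
#'   spots), `spotted_volume`.
#' @param countable Length-2 numeric: the countable window of plaques per
#'   spot (default 1 to 200).
#' @return A tibble with one row per (strain, replicate) and a `titre`
#'   column (PFU/uL, `NA` when no spot was countable).
#' @export
plaque_titres <- function(records, countable = c(1, 200)) {
  stopifnot(all(c("strain", "replicate", "dilution_exponent",
                  "plaque_count", "spotted_volume") %in% names(records)))
  records |>
    dplyr::group_by(.data$strain, .data$replicate) |>
    dplyr::summarise(titre = {
      ok <- !is.na(.data$plaque_count) &
        .data$plaque_count >= countable[1] & .data$plaque_count <= countable[2]
      if (!any(ok)) NA_real_ else {
        i <- which(ok)[which.min(.data$dilution_exponent[ok])]
        pfu_per_ul(.data$plaque_count[i], .data$dilution_exponent[i],
                   .data$spotted_volume[i])
      }
    }, .groups = "drop")
}

#' Hurdle decomposition of zero-inflated plaque titres
#'
#' Splits per-replicate titres into a binary permissiveness trait
#' (`PA_binary`, 1 if any plaques formed) and, only for permissive
#' replicates, a continuous titre trait (`PA_cont`) — the two-part hurdle
#' representation used by the mixed model. `PA_cont` is log10(PFU/uL) by
#' default because raw titres span orders of magnitude and the model
#' treats the trait as Gaussian; `log10 = FALSE` keeps the raw scale.
#'
#' @param titres Data frame with columns `strain`, `replicate`, `titre`
#'   (`NA` = no plaques / non-permissive), e.g. from [plaque_titres()].
#' @param log10 Emit `PA_cont` as log10 titre (default) or raw.
#' @return A tidy tibble with columns `strain`, `trait` (`"PA_binary"` /
#'   `"PA_cont"`), `replicate`, `value`. Binary rows cover every input
#'   replicate; continuous rows only the permissive ones.
#' @export
hurdle_decompose <- function(titres, log10 = TRUE) {
  stopifnot(all(c("strain", "replicate", "titre") %in% names(titres)))
  bin <- titres |>
    dplyr::transmute(.data$strain, trait = "PA_binary", .data$replicate,
                     value = as.numeric(!is.na(.data$titre) & .data$titre > 0))
  cont <- titres |>
    dplyr::filter(!is.na(.data$titre), .data$titre > 0) |>
    dplyr::transmute(.data$strain, trait = "PA_cont", .data$replicate,
                     value = if (log10) log10(.data$titre) else .data$titre)
  dplyr::bind_rows(bin, cont)
}

#' Reference melt-curve peak of positive samples
#'
#' The modal peak temperature among samples that amplified, computed as
#' the centre of the most populated 0.5 degree window (ties resolved by
#' the median of the tied centres).
#'
#' @param peaks Numeric vector of melt peaks (degrees C) from positive
#'   samples.
#' @return A single reference temperature.
#' @export
melt_reference <- function(peaks) {
  peaks <- peaks[!is.na(peaks)]
  if (length(peaks) == 0L)
    stop("no positive samples: melt reference peak is undefined",
         call. = FALSE)
  counts <- vapply(peaks, function(p) sum(abs(peaks - p) <= 0.25), integer(1))
  stats::median(peaks[counts == max(counts)])
}

#' Melt-curve exclusion filter for qPCR records
#'
#' Drops records that failed to amplify (missing Ct), lack a melt peak, or
#' whose peak departs from the reference peak of positive samples by more
#' than `tolerance` (default 1.5 degrees C) — evidence of off-target
#' amplification or contamination.
#'
#' @param records Data frame with columns `ct` (`NA` = failed) and
#'   `melt_peak` (`NA` = absent).
#' @param tolerance Maximum allowed departure from the reference peak.
#' @param reference Optional reference peak; computed by
#'   [melt_reference()] from the records' positive samples when `NULL`.
#' @return The retained rows as a tibble, with attribute `"n_dropped"`.
#' @export
melt_filter <- function(records, tolerance = 1.5, reference = NULL) {
  stopifnot(all(c("ct", "melt_peak") %in% names(records)))
  positive <- !is.na(records$ct)
  if (is.null(reference)) reference <- melt_reference(records$melt_peak[positive])
  keep <- positive & !is.na(records$melt_peak) &
    abs(records$melt_peak - reference) <= tolerance
  out <- tibble::as_tibble(records[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Correct qPCR Ct values for plate effects
#'
#' Fits the additive two-factor model `ct ~ sample + plate` by least
#' squares and subtracts the estimated plate deviations, centred to mean
#' zero across plates so corrected values stay on the original Ct scale
#' and each sample's cross-plate mean is preserved. A no-op with a single
#' plate; skipped with a warning when plates are fully confounded with
#' samples (no shared samples to identify the contrast).
#'
#' @param records Data frame with columns `strain`, `replicate`, `ct`,
#'   `plate`.
#' @return The input as a tibble with an added `ct_corrected` column.
#' @export
plate_correct <- function(records) {
  stopifnot(all(c("strain", "replicate", "ct", "plate") %in% names(records)))
  out <- tibble::as_tibble(records)
  out$ct_corrected <- out$ct
  plates <- unique(out$plate[!is.na(out$ct)])
  if (length(plates) < 2L) return(out)
  dat <- out[!is.na(out$ct), ]
  dat$sample_id <- interaction(dat$strain, dat$replicate, drop = TRUE)
  dat$plate_f <- factor(dat$plate)
  fit <- stats::lm(ct ~ sample_id + plate_f, data = dat)
  cf <- stats::coef(fit)
  plate_cf <- cf[grep("^plate_f", names(cf))]
  if (anyNA(plate_cf)) {
    warning("plates fully confounded with samples; plate correction skipped",
            call. = FALSE)
    return(out)
  }
  eff <- c(0, plate_cf)                       # first plate level is baseline
  names(eff) <- levels(dat$plate_f)
  eff <- eff - mean(eff)                      # centred plate deviations
  idx <- !is.na(out$ct)
  out$ct_corrected[idx] <- out$ct[idx] - eff[as.character(out$plate[idx])]
  out
}

#' log10 fold change in viral load from paired Ct values
#'
#' The 2^-dCt conversion with `dCt = ct_24 - ct_0`, reported on the log10
#' scale: `log10(2^-(ct_24 - ct_0)) = -(ct_24 - ct_0) * log10(2)`.
#'
#' @param ct_24 Endpoint Ct (mean of the technical-replicate pair).
#' @param ct_0 Ct of the inoculum at time zero.
#' @return log10 fold change in viral load. Vectorised.
#' @export
qpcr_fold_change <- function(ct_24, ct_0) {
  -(ct_24 - ct_0) * log10(2)
}

#' OD trait values with optional outlier removal
#'
#' Computes [od_change()] per record and, per strain across biological
#' replicates, drops Tukey-fence outliers at the requested severity
#' (anomalous OD readings typically show up as values far below zero).
#'
#' @param records Data frame with columns `strain`, `replicate`,
#'   `od_infected`, `od_uninfected`.
#' @param outliers `"none"`, `"minor"` (1.5 IQR) or `"major"` (3 IQR).
#' @return Tidy tibble `strain`, `trait = "OD"`, `replicate`, `value`,
#'   with attribute `"n_dropped"`.
#' @export
od_traits <- function(records, outliers = c("minor", "major", "none")) {
  outliers <- match.arg(outliers)
  out <- records |>
    dplyr::transmute(.data$strain, trait = "OD", .data$replicate,
                     value = od_change(.data$od_uninfected, .data$od_infected))
  if (outliers == "none") {
    attr(out, "n_dropped") <- 0L
    return(tibble::as_tibble(out))
  }
  out <- out |>
    dplyr::group_by(.data$strain) |>
    dplyr::mutate(.flag = if (dplyr::n() >= 4L)
      iqr_outlier_flags(.data$value, severity = outliers)
      else rep(FALSE, dplyr::n())) |>
    dplyr::ungroup()
  n_drop <- sum(out$.flag)
  out <- out |> dplyr::filter(!.data$.flag) |> dplyr::select(-".flag")
  attr(out, "n_dropped") <- n_drop
  out
}

#' qPCR trait values from raw plate records
#'
#' Full qPCR preprocessing: melt-curve exclusion, plate-effect correction,
#' averaging of technical-replicate pairs, and conversion to log10 fold
#' change in viral load against the time-zero inoculum Ct.
#'
#' @param records Data frame with columns `strain`, `replicate`,
#'   `technical_rep`, `ct`, `melt_peak`, `plate`.
#' @param ct_0 Inoculum Ct at time zero (a single value, e.g. the mean of
#'   the time-zero extraction replicates).
#' @param tolerance Melt-peak tolerance passed to [melt_filter()].
#' @return Tidy tibble `strain`, `trait = "qPCR"`, `replicate`, `value`,
#'   with attribute `"n_dropped"` (records removed by the melt filter).
#' @export
qpcr_traits <- function(records, ct_0, tolerance = 1.5) {
  kept <- melt_filter(records, tolerance = tolerance)
  n_drop <- attr(kept, "n_dropped")
  corrected <- plate_correct(kept)
  out <- corrected |>
    dplyr::group_by(.data$strain, .data$replicate) |>
    dplyr::summarise(ct_24 = mean(.data$ct_corrected), .groups = "drop") |>
    dplyr::transmute(.data$strain, trait = "qPCR", .data$replicate,
                     value = qpcr_fold_change(.data$ct_24, ct_0))
  attr(out, "n_dropped") <- n_drop
  out
}

#' Build the analysis trait table from raw assay records
#'
#' Combines the plaque hurdle traits, OD changes and qPCR fold changes
#' into one tidy trait table (columns `strain`, `trait`, `replicate`,
#' `value`) ready for [fit_phylo_mm()], together with a report of how many
#' records each filter removed.
#'
#' @param plaque Plaque spot records (see [plaque_titres()]).
#' @param od OD records (see [od_traits()]).
#' @param qpcr qPCR records (see [qpcr_traits()]).
#' @param ct_0 Time-zero inoculum Ct for the qPCR conversion.
#' @param od_outliers Outlier severity for the OD trait.
#' @param countable Countable plaque window for [plaque_titres()].
#' @param melt_tolerance Melt-peak tolerance (degrees C).
#' @param log10_titre Log-transform the continuous plaque trait.
#' @return A list of class `"trait_prep"`: `$traits` (the tidy trait
#'   table) and `$report` (a tibble of per-filter drop counts).
#' @export
prepare_traits <- function(plaque, od, qpcr, ct_0,
                           od_outliers = "minor", countable = c(1, 200),
                           melt_tolerance = 1.5, log10_titre = TRUE) {
  titres <- plaque_titres(plaque, countable = countable)
  pa <- hurdle_decompose(titres, log10 = log10_titre)
  odt <- od_traits(od, outliers = od_outliers)
  qt <- qpcr_traits(qpcr, ct_0 = ct_0, tolerance = melt_tolerance)
  traits <- dplyr::bind_rows(pa, odt, qt) |>
    dplyr::arrange(.data$strain, .data$trait, .data$replicate)
  report <- tibble::tibble(
    rule = c("plaque: no countable spot", "OD: outliers removed",
             "qPCR: melt filter"),
    n_dropped = c(sum(is.na(titres$titre)), attr(odt, "n_dropped"),
                  attr(qt, "n_dropped")))
  structure(list(traits = traits, report = report), class = "trait_prep")
}

#' @export
print.trait_prep <- function(x, ...) {
  cat("Trait table:", nrow(x$traits), "observations,",
      length(unique(x$traits$strain)), "strains,",
      length(unique(x$traits$trait)), "traits\n")
  cat("Filter report:\n")
  print(x$report)
  invisible(x)
}
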