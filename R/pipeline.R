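# File-based pipeline orchestration. Each stage reads and writes plain
# files (Newick, tidy CSV, JSON) and appends a manifest entry recording
# the command, inputs, seed and outputs, so any run can be reproduced
# from its manifest alone.

write_manifest <- function(outdir, command, seed, inputs, outputs,
                           settings = list()) {
  man_path <- file.path(outdir, "manifest.json")
  entry <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("phagephylo")),
    seed = seed,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = outputs,
    settings = settings)
  existing <- if (file.exists(man_path))
    jsonlite::read_json(man_path) else list()
  jsonlite::write_json(c(existing, list(entry)), man_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man_path)
}

#' Simulate a panel to files
#'
#' Writes a Yule tree (Newick), a simulated trait table (CSV) and the
#' ground-truth record (JSON) to `outdir`, plus a manifest entry.
#'
#' @param outdir Output directory (created if needed).
#' @param n_strains Number of strains (>= 2).
#' @param preset Preset name for [sim_preset()].
#' @param seed Master seed.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(outdir, n_strains = 64, preset = "paper-like",
                         seed = 1) {
  if (n_strains < 2) stop("n_strains must be >= 2", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- sim_preset(preset)
  tree <- simulate_tree(n_strains, seed = seed)
  sim <- simulate_traits(tree, config, seed = seed + 1)
  tree_path <- file.path(outdir, "tree.nwk")
  traits_path <- file.path(outdir, "traits.csv")
  truth_path <- file.path(outdir, "truth.json")
  write_tree(tree, tree_path)
  utils::write.csv(sim$traits, traits_path, row.names = FALSE)
  jsonlite::write_json(
    list(Vp = sim$truth$config$Vp, Vs = sim$truth$config$Vs,
         Ve = sim$truth$config$Ve, intercepts = sim$truth$config$intercepts,
         u_p = sim$truth$u_p, u_s = sim$truth$u_s),
    truth_path, digits = NA, pretty = TRUE)
  write_manifest(outdir, "simulate", seed, character(0),
                 c(tree_path, traits_path, truth_path),
                 list(n_strains = n_strains, preset = preset))
  invisible(list(tree = tree_path, traits = traits_path, truth = truth_path))
}

#' Prepare the trait table from raw assay CSVs
#'
#' Reads plaque, OD and qPCR record CSVs, applies the filters and
#' conversions of [prepare_traits()], writes the tidy trait table and a
#' filter report.
#'
#' @param outdir Output directory.
#' @param plaque_csv,od_csv,qpcr_csv Paths to the raw record CSVs.
#' @param ct_0 Time-zero inoculum Ct.
#' @param ... Passed to [prepare_traits()].
#' @return Invisibly, the written paths.
#' @export
run_prepare <- function(outdir, plaque_csv, od_csv, qpcr_csv, ct_0, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in c(plaque_csv, od_csv, qpcr_csv))
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  qpcr <- read_csv_strict(qpcr_csv)
  if (nrow(qpcr) == 0) stop("empty qPCR file: ", qpcr_csv, call. = FALSE)
  prep <- prepare_traits(read_csv_strict(plaque_csv),
                         read_csv_strict(od_csv), qpcr, ct_0 = ct_0, ...)
  traits_path <- file.path(outdir, "traits.csv")
  report_path <- file.path(outdir, "filter_report.csv")
  utils::write.csv(prep$traits, traits_path, row.names = FALSE)
  utils::write.csv(prep$report, report_path, row.names = FALSE)
  write_manifest(outdir, "prepare", NA,
                 c(plaque_csv, od_csv, qpcr_csv),
                 c(traits_path, report_path), list(ct_0 = ct_0))
  invisible(list(traits = traits_path, report = report_path))
}

#' Fit the phylogenetic mixed model from files
#'
#' @param outdir Output directory.
#' @param traits_csv Tidy trait table CSV (from [run_prepare()] or
#'   [run_simulate()]).
#' @param tree_file Newick tree.
#' @param strain_effect Fit the model with the strain term.
#' @param seed Master seed.
#' @param ... Passed to [fit_phylo_mm()].
#' @return Invisibly, the fitted `"phylo_mm"` object; posterior draws
#'   and parameter summaries are written as CSV.
#' @export
run_fit <- function(outdir, traits_csv, tree_file, strain_effect = FALSE,
                    seed = 1, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(traits_csv))
    stop("missing trait table '", traits_csv,
         "'; produce it with run_prepare() or run_simulate()", call. = FALSE)
  traits <- read_csv_strict(traits_csv)
  tree <- read_tree(tree_file)
  dots <- list(...)
  if (is.null(dots$chain)) dots$chain <- pmm_chain(seed = seed)
  fit <- do.call(fit_phylo_mm,
                 c(list(traits = traits, tree = tree,
                        strain_effect = strain_effect), dots))
  draws_path <- file.path(outdir, "posterior_draws.csv")
  summary_path <- file.path(outdir, "parameter_summary.csv")
  utils::write.csv(posterior_draws(fit), draws_path, row.names = FALSE)
  utils::write.csv(tidy(fit), summary_path, row.names = FALSE)
  write_manifest(outdir, "fit", seed, c(traits_csv, tree_file),
                 c(draws_path, summary_path),
                 list(strain_effect = strain_effect))
  invisible(fit)
}

#' Derived statistics from a fitted model
#'
#' Writes repeatability (model without strain effect) or heritability
#' (model with strain effect) plus inter-trait correlations and slopes.
#'
#' @param outdir Output directory.
#' @param fit A `"phylo_mm"` object (from [run_fit()]).
#' @return Invisibly, the written paths.
#' @export
run_stats <- function(outdir, fit) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (fit$strain_effect) {
    tab <- heritability(fit)
    path1 <- file.path(outdir, "heritability.csv")
  } else {
    tab <- repeatability(fit)
    path1 <- file.path(outdir, "repeatability.csv")
  }
  utils::write.csv(tab, path1, row.names = FALSE)
  path2 <- file.path(outdir, "correlations.csv")
  utils::write.csv(trait_correlations(fit), path2, row.names = FALSE)
  write_manifest(outdir, "stats", NA, character(0), c(path1, path2))
  invisible(list(stats = path1, correlations = path2))
}

#' Ancestral state reconstruction from a fitted model
#'
#' @param outdir Output directory.
#' @param fit A `"phylo_mm"` object.
#' @param trait Trait to reconstruct.
#' @return Invisibly, the written paths (node CSV, annotated Newick,
#'   PDF figure).
#' @export
run_asr <- function(outdir, fit, trait = "OD") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  asr <- asr_from_fit(fit, trait)
  csv_path <- file.path(outdir, paste0("asr_", trait, ".csv"))
  nwk_path <- file.path(outdir, paste0("asr_", trait, ".nwk"))
  fig_path <- file.path(outdir, paste0("asr_", trait, ".pdf"))
  write_asr(asr, csv_path)
  write_asr_tree(asr, nwk_path)
  grDevices::pdf(fig_path, width = 7, height = 9)
  print(autoplot(asr))
  grDevices::dev.off()
  write_manifest(outdir, "asr", NA, character(0),
                 c(csv_path, nwk_path, fig_path), list(trait = trait))
  invisible(list(csv = csv_path, newick = nwk_path, figure = fig_path))
}

#' Leave-one-out prediction from files
#'
#' @param outdir Output directory.
#' @param traits_csv Tidy trait table CSV.
#' @param tree_file Newick tree.
#' @param seed Master seed.
#' @param ... Passed to [loo_predict()].
#' @return Invisibly, the `"phylo_loo"` object; per-strain predictions,
#'   the error summary and the observed-vs-predicted figure are written.
#' @export
run_loo <- function(outdir, traits_csv, tree_file, seed = 1, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(traits_csv))
    stop("missing trait table '", traits_csv,
         "'; produce it with run_prepare() or run_simulate()", call. = FALSE)
  traits <- read_csv_strict(traits_csv)
  tree <- read_tree(tree_file)
  dots <- list(...)
  if (is.null(dots$chain)) dots$chain <- pmm_chain(4000, 1000, 2, seed = seed)
  loo <- do.call(loo_predict, c(list(traits = traits, tree = tree), dots))
  pred_path <- file.path(outdir, "loo_predictions.csv")
  summ_path <- file.path(outdir, "loo_summary.csv")
  fig_path <- file.path(outdir, "loo_observed_vs_predicted.pdf")
  utils::write.csv(as.data.frame(loo), pred_path, row.names = FALSE)
  utils::write.csv(loo_summary(loo), summ_path, row.names = FALSE)
  grDevices::pdf(fig_path, width = 8, height = 6)
  print(autoplot(loo))
  grDevices::dev.off()
  write_manifest(outdir, "loo", seed, c(traits_csv, tree_file),
                 c(pred_path, summ_path, fig_path))
  invisible(loo)
}
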