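#' Run the full detection + saliency-overlap experiment
#'
#' Orchestrates, per AI system: detection evaluation (rank AUC with a
#' stratified percentile bootstrap CI and the CI-excludes-0.5 significance
#' rule) over all scored images, and the saliency-overlap analysis
#' (optimal-threshold DSC, median/IQR) over the case-side lesion-bearing
#' images only — controls contribute to detection, not to overlap.
#' Exclusions (images without a usable lesion mask) are counted. All
#' randomized stages sub-seed deterministically from the single master
#' seed, so one seed reproduces the whole run, and identical configs
#' produce byte-identical report files.
#'
#' @param config Either a named list or the path to a key-value config
#'   file (see [read_run_config()]). Recognized keys: `manifest`,
#'   `systems` (character vector), `saliency_dir`, `scores_dir`,
#'   `out_dir`, `seed`, `n_boot` (default 2000), `level` (default 0.95),
#'   `per_woman` (default `FALSE`), `cluster_boot` (default `FALSE`),
#'   `logfile`.
#' @return Invisibly, an object of class `salovlap_report`: the per-system
#'   rows data frame, with the output directory as attribute.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- cfg$logfile
  if (!is.null(logfile)) {
    salovlap_log(sprintf("run started: seed=%d n_boot=%d level=%g",
                         cfg$seed, cfg$n_boot, cfg$level), logfile)
  }

  manifest <- read_manifest(cfg$manifest)
  seeds <- derive_seeds(cfg$seed, length(cfg$systems))
  rows <- list()
  for (s in seq_along(cfg$systems)) {
    sysname <- cfg$systems[s]
    scores_path <- file.path(cfg$scores_dir, paste0(sysname, ".csv"))
    if (!file.exists(scores_path)) {
      stop("missing scores CSV for system ", sysname, ": ", scores_path)
    }
    eval_res <- evaluate_scores(
      scores_path, n_boot = cfg$n_boot, level = cfg$level, seed = seeds[s],
      per_woman = cfg$per_woman, cluster_boot = cfg$cluster_boot
    )
    ovl <- saliency_overlap(manifest, file.path(cfg$saliency_dir, sysname),
                            logfile = logfile)
    utils::write.csv(
      ovl$per_image,
      file.path(cfg$out_dir, paste0("overlap_", sysname, ".csv")),
      row.names = FALSE
    )
    if (!is.null(logfile)) {
      salovlap_log(sprintf(
        "%s: AUC %.3f [%.3f, %.3f] boot seed %d; overlap n=%d excluded=%d",
        sysname, eval_res$auc, eval_res$ci_low, eval_res$ci_high, seeds[s],
        ovl$n_images, ovl$n_excluded), logfile)
    }
    rows[[s]] <- data.frame(
      system = sysname,
      auc = eval_res$auc, ci_low = eval_res$ci_low,
      ci_high = eval_res$ci_high, significant = eval_res$significant,
      median_dsc = ovl$median_dsc, iqr_dsc = ovl$iqr_dsc,
      n_overlap_images = ovl$n_images, n_excluded_images = ovl$n_excluded,
      n_images = eval_res$n_cases + eval_res$n_controls,
      stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, rows)
  write_report(rows,
               csv_path = file.path(cfg$out_dir, "report.csv"),
               json_path = file.path(cfg$out_dir, "report.json"))
  jsonlite::write_json(
    list(
      seed = cfg$seed, n_boot = cfg$n_boot, level = cfg$level,
      per_woman = cfg$per_woman, cluster_boot = cfg$cluster_boot,
      system_seeds = as.list(stats::setNames(seeds, cfg$systems)),
      decisions = list(
        threshold_rule = "pixels with saliency >= tau; exact search over all distinct values",
        tie_break = "largest DSC-maximizing threshold (smallest area of interest)",
        quantile_rule = "linear interpolation between order statistics (type 7)",
        bootstrap = "stratified percentile, classes resampled separately",
        significance = "95% CI strictly excludes 0.5"
      )
    ),
    file.path(cfg$out_dir, "run_metadata.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  structure(rows, class = c("salovlap_report", "data.frame"),
            out_dir = cfg$out_dir)
}

validate_config <- function(config) {
  for (key in c("manifest", "systems", "saliency_dir", "scores_dir",
                "out_dir", "seed")) {
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  }
  list(
    manifest = config$manifest,
    systems = as.character(config$systems),
    saliency_dir = config$saliency_dir,
    scores_dir = config$scores_dir,
    out_dir = config$out_dir,
    seed = as.integer(config$seed),
    n_boot = as.integer(config$n_boot %||% 2000),
    level = as.numeric(config$level %||% 0.95),
    per_woman = isTRUE(config$per_woman),
    cluster_boot = isTRUE(config$cluster_boot),
    logfile = config$logfile
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate detection scores for one system
#'
#' Reads a scores CSV and runs the bootstrap AUC analysis; optionally
#' aggregates to one score per woman first, or clusters the bootstrap by
#' woman.
#'
#' @param scores_path Path to the scores CSV.
#' @param n_boot,level,seed Passed to [auc_boot()].
#' @param per_woman Aggregate to per-woman max scores before analysis.
#' @param cluster_boot Resample whole women rather than images.
#' @return An `auc_boot` object.
#' @export
evaluate_scores <- function(scores_path, n_boot = 2000, level = 0.95,
                            seed, per_woman = FALSE, cluster_boot = FALSE) {
  scores <- read_scores(scores_path)
  if (per_woman) scores <- aggregate_by_woman(scores)
  cluster <- if (cluster_boot && !per_woman) scores$woman_id else NULL
  auc_boot(scores$score, scores$label, n_boot = n_boot, level = level,
           seed = seed, cluster = cluster)
}

#' Match a cohort file and write the pairs
#'
#' Stage wrapper: reads a cohort CSV, performs exact-key 1:1 matching of
#' cases to control candidates, and writes `pairs.csv` plus
#' `unmatched.csv` under `out_dir`.
#'
#' @param cohort_path Cohort CSV path.
#' @param out_dir Output directory.
#' @param seed Integer seed for candidate selection.
#' @return The [match_cases()] result, invisibly.
#' @export
stage_match <- function(cohort_path, out_dir, seed) {
  cohort <- read_cohort(cohort_path)
  res <- match_cases(cohort[cohort$status == "case", , drop = FALSE],
                     cohort[cohort$status == "control", , drop = FALSE],
                     seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$pairs, file.path(out_dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(case_id = res$unmatched),
                   file.path(out_dir, "unmatched.csv"), row.names = FALSE)
  invisible(res)
}

#' @export
print.salovlap_report <- function(x, ...) {
  cat("Detection performance and saliency-lesion overlap\n")
  fmt <- data.frame(
    System = x$system,
    AUC = sprintf("%.3f", x$auc),
    `95% CI` = sprintf("%.3f–%.3f", x$ci_low, x$ci_high),
    Significant = ifelse(x$significant, "yes", "no"),
    `DSC (IQR)` = sprintf("%.3f (%.3f)", x$median_dsc, x$iqr_dsc),
    `DSC %` = sprintf("%.1f%% (%.1f%%)",
                      100 * x$median_dsc, 100 * x$iqr_dsc),
    n = x$n_images,
    check.names = FALSE
  )
  print(fmt, row.names = FALSE)
  n_exc <- sum(x$n_excluded_images)
  if (n_exc > 0) {
    cat(sprintf("(%d lesion image(s) excluded from overlap: no usable mask)\n",
                n_exc))
  }
  invisible(x)
}
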