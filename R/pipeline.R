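# End-to-end study orchestration: simulate (or load) -> extract -> filter ->
# analyze -> report. All randomness flows from config$seed; report files are
# written deterministically so identical seeds give byte-identical bundles.

#' Study run configuration
#'
#' Defaults reproduce the reference analysis settings: 128 gray-level bins,
#' 5x5x5 sub-volumes, strict-interior eligibility, 11-fold stratified
#' cross-validation, inclusion filters at 64 voxels and SUVmax 2.5, and the
#' default synthetic cohort of 35 benign / 81 malignant lesions.
#'
#' @param mode `"synthetic"` (generate the cohort) or `"files"` (read a
#'   cohort written by [write_cohort()] from `input_dir`).
#' @param out_dir directory for the report bundle (created if needed).
#' @param input_dir cohort directory for `"files"` mode.
#' @param n_benign,n_malignant synthetic cohort composition.
#' @param seed master seed; owns every random draw of the run.
#' @param n_bins,subvolume,distance,policy,epsilon,planes texture settings,
#'   see [texture_config()].
#' @param n_folds cross-validation folds (default 11).
#' @param stratified stratify folds by class.
#' @param min_voxels,min_suvmax inclusion filters.
#' @param reader_noise_with,reader_noise_without latent noise SDs for the
#'   simulated reader scores with / without texture reference.
#' @param reader_signal feature driving the simulated reader scores.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       out_dir = tempfile("petngtdm_run_"),
                       input_dir = NULL,
                       n_benign = 35L, n_malignant = 81L,
                       seed = 7L,
                       n_bins = 128L, subvolume = 5L, distance = 1L,
                       policy = "strict-interior", epsilon = 1e-8,
                       planes = "central",
                       n_folds = 11L, stratified = TRUE,
                       min_voxels = 64, min_suvmax = 2.5,
                       reader_noise_with = 0.8,
                       reader_noise_without = 1.3,
                       reader_signal = "delayed_busyness") {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(input_dir))
    stop("`input_dir` is required in files mode", call. = FALSE)
  cfg <- list(mode = mode, out_dir = out_dir, input_dir = input_dir,
              n_benign = as.integer(n_benign),
              n_malignant = as.integer(n_malignant),
              seed = as.integer(seed),
              n_bins = as.integer(n_bins), subvolume = as.integer(subvolume),
              distance = as.integer(distance), policy = policy,
              epsilon = epsilon, planes = planes,
              n_folds = as.integer(n_folds), stratified = stratified,
              min_voxels = min_voxels, min_suvmax = min_suvmax,
              reader_noise_with = reader_noise_with,
              reader_noise_without = reader_noise_without,
              reader_signal = reader_signal)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a cohort directory
#'
#' On-disk layout: `cohort.csv` (`id,label`) plus, per lesion,
#' `<id>_early.nii.gz`, `<id>_delayed.nii.gz` and `<id>_mask.nii.gz` on the
#' same grid. [read_cohort()] errors naming the lesion if any of the three
#' files of a pair is missing.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param dir target directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   cohort list (`lesions`, `truth`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (les in cohort$lesions) {
    write_pet_volume(les$early, file.path(dir, paste0(les$id, "_early.nii.gz")))
    write_pet_volume(les$delayed, file.path(dir, paste0(les$id, "_delayed.nii.gz")))
    write_lesion_mask(les$mask, file.path(dir, paste0(les$id, "_mask.nii.gz")),
                      spacing = les$early$spacing)
  }
  tab <- data.frame(id = vapply(cohort$lesions, `[[`, "", "id"),
                    label = vapply(cohort$lesions, `[[`, "", "label"),
                    stringsAsFactors = FALSE)
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tab_path <- file.path(dir, "cohort.csv")
  if (!file.exists(tab_path)) stop("no cohort.csv in ", dir, call. = FALSE)
  tab <- read.csv(tab_path, stringsAsFactors = FALSE)
  lesions <- lapply(seq_len(nrow(tab)), function(k) {
    id <- tab$id[k]
    paths <- file.path(dir, paste0(id, c("_early.nii.gz", "_delayed.nii.gz",
                                         "_mask.nii.gz")))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop(sprintf("lesion %s: missing file(s) %s", id,
                   paste(basename(missing), collapse = ", ")), call. = FALSE)
    list(id = id, label = tab$label[k],
         early = read_pet_volume(paths[1], "early"),
         delayed = read_pet_volume(paths[2], "delayed"),
         mask = read_lesion_mask(paths[3]))
  })
  list(lesions = lesions, truth = tab)
}

study_features <- c("early_busyness", "early_coarseness", "early_contrast",
                    "delayed_busyness", "delayed_coarseness", "delayed_contrast",
                    "early_suvmax", "delayed_suvmax")

#' Group-comparison table (mean +/- SD per class, Wilcoxon z and p)
#'
#' @param records included feature records.
#' @param features feature columns to compare.
#' @return Data frame, one row per feature.
#' @export
group_comparison_table <- function(records, features = study_features) {
  rows <- lapply(features, function(f) {
    m <- records[[f]][records$label == "malignant"]
    b <- records[[f]][records$label == "benign"]
    w <- wilcoxon_rank_sum(b, m)
    data.frame(feature = f,
               malignant_mean = mean(m), malignant_sd = sd(m),
               benign_mean = mean(b), benign_sd = sd(b),
               z = w$z, p = w$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-feature ROC table (AUC, threshold, sensitivity, specificity, accuracy)
#'
#' @inheritParams group_comparison_table
#' @return List: `table` (data frame, one row per feature) and `curves`
#'   (stacked ROC curve points).
#' @export
roc_table <- function(records, features = study_features) {
  rows <- list()
  curves <- list()
  for (f in features) {
    r <- roc_analysis(records[[f]], records$label)
    rows[[f]] <- data.frame(feature = f, auc = r$auc, threshold = r$threshold,
                            sensitivity = r$sensitivity,
                            specificity = r$specificity,
                            accuracy = r$accuracy,
                            orientation = r$orientation,
                            stringsAsFactors = FALSE)
    cv <- r$curve
    cv$feature <- f
    curves[[f]] <- cv[, c("feature", "threshold", "fpr", "tpr")]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, curves = do.call(rbind, curves))
}

#' Run the full dual-time-point texture study
#'
#' Orchestrates the pipeline end to end: obtain the cohort (synthetic or
#' from disk), extract dual-time-point NGTDM features, apply the inclusion
#' filters, and emit the report bundle: per-lesion feature tables (wide and
#' long), the benign/malignant group-comparison table, the per-feature ROC
#' table with curve points, stratified cross-validated summaries, simulated
#' reader scores with their feature correlations, the exclusion log, and a
#' run manifest (config + seed + package version). Reruns with the same
#' config are byte-identical.
#'
#' @param config a [run_config()].
#' @return The report bundle as a list, invisibly; all tables are also
#'   written under `config$out_dir`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- switch(config$mode,
    synthetic = generate_cohort(config$n_benign, config$n_malignant,
                                seed = config$seed),
    files = read_cohort(config$input_dir))

  tcfg <- texture_config(n_bins = config$n_bins, subvolume = config$subvolume,
                         distance = config$distance, policy = config$policy,
                         epsilon = config$epsilon, planes = config$planes)
  records <- extract_cohort_features(cohort$lesions, tcfg)

  filt <- apply_inclusion_filters(records, config$min_voxels, config$min_suvmax)
  included <- filt$included
  if (nrow(included) == 0L)
    stop("no lesion passes the inclusion filters", call. = FALSE)
  if (length(unique(included$label)) < 2L)
    stop("post-filter cohort contains a single class", call. = FALSE)

  comparison <- group_comparison_table(included)
  rocs <- roc_table(included)

  plan <- make_cv_plan(included$id, included$label,
                       n_folds = config$n_folds,
                       seed = derive_seed(config$seed, 1777L),
                       stratified = config$stratified)
  cv_rows <- list()
  cv_folds <- list()
  for (f in study_features) {
    cv <- cross_validated_auc(included, f, plan)
    cv_rows[[f]] <- data.frame(feature = f, t(cv$average),
                               n_folds_used = nrow(cv$folds),
                               stringsAsFactors = FALSE)
    fl <- cv$folds
    fl$feature <- f
    cv_folds[[f]] <- fl[, c("feature", setdiff(names(cv$folds), "feature"))]
  }
  cv_summary <- do.call(rbind, cv_rows)
  rownames(cv_summary) <- NULL

  scored <- included
  scored$score_with_texture <- simulate_reader_scores(
    included, config$reader_signal, config$reader_noise_with,
    seed = derive_seed(config$seed, 1888L))
  scored$score_without_texture <- simulate_reader_scores(
    included, config$reader_signal, config$reader_noise_without,
    seed = derive_seed(config$seed, 1889L))
  corr_rows <- lapply(study_features, function(f) {
    cw <- pearson_correlation(scored[[f]], scored$score_with_texture)
    co <- pearson_correlation(scored[[f]], scored$score_without_texture)
    data.frame(feature = f, r_with_texture = cw$r, p_with_texture = cw$p,
               r_without_texture = co$r, p_without_texture = co$p,
               stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, corr_rows)
  rownames(correlations) <- NULL

  bundle <- list(
    config = config,
    truth = cohort$truth,
    features = records,
    included = scored,
    excluded = filt$excluded,
    group_comparison = comparison,
    roc = rocs$table,
    roc_curves = rocs$curves,
    cv_plan = plan,
    cv_summary = cv_summary,
    cv_folds = do.call(rbind, cv_folds),
    reader_correlations = correlations
  )
  write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    rownames(df) <- NULL
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(bundle$features, "features_wide.csv")
  wcsv(feature_table_long(bundle$features), "features_long.csv")
  wcsv(bundle$included, "included_records.csv")
  wcsv(bundle$group_comparison, "group_comparison.csv")
  wcsv(bundle$roc, "roc_table.csv")
  wcsv(bundle$roc_curves, "roc_curves.csv")
  wcsv(bundle$cv_plan, "cv_plan.csv")
  wcsv(bundle$cv_summary, "cv_summary.csv")
  wcsv(bundle$cv_folds, "cv_folds.csv")
  wcsv(bundle$reader_correlations, "reader_correlations.csv")
  jsonlite::write_json(
    list(n_input = nrow(bundle$features),
         n_included = nrow(bundle$included),
         n_excluded = nrow(bundle$excluded),
         exclusions = bundle$excluded[, intersect(c("id", "reason"),
                                                  names(bundle$excluded))]),
    file.path(out_dir, "exclusions.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cfg <- bundle$config
  class(cfg) <- NULL
  cfg$out_dir <- NULL  # keep the manifest location-independent
  jsonlite::write_json(
    list(package = "petngtdm",
         version = as.character(utils::packageVersion("petngtdm")),
         config = cfg),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
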