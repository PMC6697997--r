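#' Retention index
#'
#' Percent change of SUV from the early to the delayed acquisition,
#' `100 * (SUV_delayed - SUV_early) / SUV_early`. Malignant lesions tend to
#' retain FDG (positive index); benign/inflammatory lesions tend to wash
#' out or stay stable.
#'
#' @param suv_early early-scan SUV (g/ml), must be positive.
#' @param suv_delayed delayed-scan SUV (g/ml).
#' @return Percent change (vectorized).
#' @examples
#' retention_index(10, 11)  # +10
#' retention_index(5, 4)    # -20
#' @export
retention_index <- function(suv_early, suv_delayed) {
  if (any(!is.finite(suv_early)) || any(suv_early <= 0))
    stop("`suv_early` must be positive", call. = FALSE)
  100 * (suv_delayed - suv_early) / suv_early
}

#' Apply cohort inclusion filters
#'
#' Small lesions and faint lesions make texture unreliable: a record
#' survives iff its metabolic volume is at least `min_voxels` voxels AND its
#' early-scan SUVmax is at least `min_suvmax`. Exclusions carry
#' machine-readable reasons (`"small-volume"`, `"low-uptake"`, or both,
#' comma-separated). The split is a partition: `included` and `excluded`
#' together restore the input, and filtering is idempotent.
#'
#' @param records data frame with columns `n_voxels` and `early_suvmax`.
#' @param min_voxels minimum metabolic volume in voxels (default 64).
#' @param min_suvmax minimum early SUVmax in g/ml (default 2.5).
#' @return List with `included` (data frame) and `excluded` (data frame with
#'   an extra `reason` column).
#' @export
apply_inclusion_filters <- function(records, min_voxels = 64, min_suvmax = 2.5) {
  stopifnot(is.data.frame(records),
            all(c("n_voxels", "early_suvmax") %in% names(records)))
  small <- records$n_voxels < min_voxels
  faint <- records$early_suvmax < min_suvmax
  out <- small | faint
  reason <- character(nrow(records))
  reason[small] <- "small-volume"
  reason[faint] <- ifelse(small[faint], "small-volume,low-uptake", "low-uptake")
  excluded <- records[out, , drop = FALSE]
  excluded$reason <- reason[out]
  list(included = records[!out, , drop = FALSE], excluded = excluded)
}

#' Extract the dual-time-point feature table for a cohort
#'
#' Runs [lesion_features()] on the early and delayed volume of every lesion
#' and assembles one wide record per lesion: both time points' coarseness,
#' contrast, busyness and SUVmax, the metabolic volume, the retention index,
#' and the ground-truth label.
#'
#' @param cohort list of lesion samples; each element is a list with `id`,
#'   `label` (`"benign"`/`"malignant"`), `early` and `delayed`
#'   ([pet_volume()]s) and `mask` (logical array).
#' @param config a [texture_config()].
#' @return Data frame with one row per lesion.
#' @export
extract_cohort_features <- function(cohort, config = texture_config()) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  rows <- lapply(cohort, function(les) {
    fe <- lesion_features(les$early, les$mask, config)
    fd <- lesion_features(les$delayed, les$mask, config)
    data.frame(
      id = les$id,
      label = les$label,
      early_coarseness = fe$coarseness,
      early_contrast = fe$contrast,
      early_busyness = fe$busyness,
      early_suvmax = fe$suvmax,
      delayed_coarseness = fd$coarseness,
      delayed_contrast = fd$contrast,
      delayed_busyness = fd$busyness,
      delayed_suvmax = fd$suvmax,
      n_voxels = fe$n_voxels,
      n_undefined_early = fe$n_undefined,
      n_undefined_delayed = fd$n_undefined,
      retention_index = retention_index(fe$suvmax, fd$suvmax),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format per-lesion, per-time-point feature table
#'
#' Reshapes the wide feature table to one row per lesion x time point with
#' columns `id, timepoint, coarseness, contrast, busyness, suvmax, n_voxels,
#' n_undefined` - the on-disk exchange format.
#'
#' @param records wide data frame from [extract_cohort_features()].
#' @return Long data frame.
#' @export
feature_table_long <- function(records) {
  mk <- function(tp) {
    data.frame(
      id = records$id,
      timepoint = tp,
      coarseness = records[[paste0(tp, "_coarseness")]],
      contrast = records[[paste0(tp, "_contrast")]],
      busyness = records[[paste0(tp, "_busyness")]],
      suvmax = records[[paste0(tp, "_suvmax")]],
      n_voxels = records$n_voxels,
      n_undefined = records[[paste0("n_undefined_", tp)]],
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(mk("early"), mk("delayed"))
  out[order(out$id, out$timepoint), , drop = FALSE]
}
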