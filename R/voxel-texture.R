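#' Texture-extraction configuration
#'
#' Bundles the knobs of the voxel-wise NGTDM scheme. Defaults reproduce the
#' reference settings: 128 gray-level bins, 5x5x5 sub-volumes, neighborhood
#' distance 1, strict-interior pixel eligibility, coarseness regularizer
#' 1e-8, and features computed on the single central plane of each of the
#' three orientations.
#'
#' @param n_bins number of equal-width gray-level bins (>= 2).
#' @param subvolume odd edge length of the cube extracted around each lesion
#'   voxel.
#' @param distance NGTDM neighborhood radius in pixels.
#' @param policy pixel-eligibility policy, see [build_ngtdm()].
#' @param epsilon coarseness regularizer, see [ngtdm_coarseness()].
#' @param planes `"central"` computes each feature on the central plane of
#'   each orientation (3 planes per voxel, then averaged); `"all"` averages
#'   over every slice of the cube within each orientation first.
#' @return A list of class `"texture_config"`.
#' @export
texture_config <- function(n_bins = 128L, subvolume = 5L, distance = 1L,
                           policy = c("strict-interior", "all-valid"),
                           epsilon = 1e-8,
                           planes = c("central", "all")) {
  policy <- match.arg(policy)
  planes <- match.arg(planes)
  n_bins <- as.integer(n_bins)
  subvolume <- as.integer(subvolume)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  if (subvolume < 3L || subvolume %% 2L == 0L)
    stop("`subvolume` must be an odd integer >= 3", call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  structure(list(n_bins = n_bins, subvolume = subvolume,
                 distance = as.integer(distance), policy = policy,
                 epsilon = epsilon, planes = planes),
            class = "texture_config")
}

#' Quantize a lesion volume to gray-level bins
#'
#' Equal-width binning of SUV values into `n_bins` bins whose edges span the
#' intensity range *inside the lesion mask*; the lesion maximum maps to bin
#' `n_bins`. Voxels outside the mask (which may fall inside extracted
#' sub-volumes) are binned with the same lesion-derived edges and clamped to
#' `[1, n_bins]`. Because the edges are min-max within the lesion, the
#' binning - and hence every downstream texture feature - is invariant to
#' global affine rescaling `a*SUV + b` (a > 0) of the volume.
#'
#' @param volume a [pet_volume()] or 3-D numeric array.
#' @param mask logical 3-D array of the same shape; must contain at least
#'   one `TRUE` voxel.
#' @param n_bins number of bins (default 128).
#' @return Integer 3-D array of bin indices in `1..n_bins`.
#' @export
quantize_lesion <- function(volume, mask, n_bins = 128L) {
  v <- as_suv_array(volume)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  if (!is.logical(mask) || !identical(dim(mask), dim(v)))
    stop("`mask` must be a logical array matching the volume", call. = FALSE)
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  rng <- range(v[mask])
  if (rng[2] <= rng[1]) {
    warning("constant lesion intensities: all voxels map to bin 1")
    return(array(1L, dim(v)))
  }
  w <- (rng[2] - rng[1]) / n_bins
  b <- floor((v - rng[1]) / w) + 1
  b[b < 1] <- 1
  b[b > n_bins] <- n_bins
  array(as.integer(b), dim(v))
}

#' Extract the sub-volume around a lesion voxel
#'
#' Returns the `size^3` cube of bin indices centered on `center`. Cells
#' falling outside the image carry `valid = FALSE`; no padding values are
#' invented.
#'
#' @param binned integer 3-D array of bin indices (from [quantize_lesion()]).
#' @param center integer length-3 voxel coordinate (1-based).
#' @param size odd cube edge length (default 5).
#' @return List with `values` (integer `size^3` array, `NA` outside the
#'   image) and `valid` (logical array of the same shape).
#' @export
extract_subvolume <- function(binned, center, size = 5L) {
  stopifnot(is.array(binned), length(dim(binned)) == 3L)
  size <- as.integer(size)
  if (size < 3L || size %% 2L == 0L)
    stop("`size` must be an odd integer >= 3", call. = FALSE)
  center <- as.integer(center)
  dm <- dim(binned)
  if (length(center) != 3L || any(center < 1L) || any(center > dm))
    stop("`center` must be a voxel coordinate inside the image", call. = FALSE)
  h <- size %/% 2L
  vals <- array(NA_integer_, c(size, size, size))
  ok <- array(FALSE, c(size, size, size))
  lo <- pmax(center - h, 1L)
  hi <- pmin(center + h, dm)
  src <- lapply(1:3, function(a) lo[a]:hi[a])
  dst <- lapply(1:3, function(a) (lo[a] - center[a] + h + 1L):(hi[a] - center[a] + h + 1L))
  vals[dst[[1]], dst[[2]], dst[[3]]] <- binned[src[[1]], src[[2]], src[[3]]]
  ok[dst[[1]], dst[[2]], dst[[3]]] <- TRUE
  list(values = vals, valid = ok, center = h + 1L)
}

#' Per-voxel NGTDM features from a sub-volume
#'
#' For each of the three orientations (axial = fixed first index, coronal =
#' fixed second, sagittal = fixed third) the features are computed on 2-D
#' planes of the cube and averaged within the orientation, then averaged
#' over the orientations that produced a defined value. With
#' `planes = "central"` only the plane through the center voxel is used per
#' orientation. A voxel whose every plane has no eligible pixel is
#' undefined and returns an all-`NA` triplet.
#'
#' @param subvolume list from [extract_subvolume()].
#' @param config a [texture_config()].
#' @return Named numeric triplet (coarseness, contrast, busyness), all `NA`
#'   when undefined.
#' @export
voxel_features <- function(subvolume, config = texture_config()) {
  stopifnot(is.list(subvolume), !is.null(subvolume$values))
  size <- dim(subvolume$values)[1]
  ctr <- subvolume$center
  strict <- config$policy == "strict-interior"
  slices <- if (config$planes == "central") ctr else seq_len(size)
  out <- c(coarseness = NA_real_, contrast = NA_real_, busyness = NA_real_)
  acc <- c(0, 0, 0)
  n_orient <- 0L
  for (ax in 1:3) {
    oacc <- c(0, 0, 0)
    n_def <- 0L
    for (sl in slices) {
      vals <- slice_matrix(subvolume$values, ax, sl)
      ok <- slice_matrix(subvolume$valid, ax, sl)
      if (!any(ok)) next
      vals[!ok] <- 1L  # never read: masked by validity
      f <- cpp_patch_features(vals, ok, config$distance, strict, config$epsilon)
      if (anyNA(f)) next
      oacc <- oacc + f
      n_def <- n_def + 1L
    }
    if (n_def > 0L) {
      acc <- acc + oacc / n_def
      n_orient <- n_orient + 1L
    }
  }
  if (n_orient == 0L) return(out)
  out[] <- acc / n_orient
  out
}

slice_matrix <- function(arr, axis, index) {
  m <- switch(axis,
              arr[index, , , drop = TRUE],
              arr[, index, , drop = TRUE],
              arr[, , index, drop = TRUE])
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  m
}

#' Lesion-level NGTDM features
#'
#' Runs the full voxel-wise scheme over a lesion: quantizes the volume over
#' the lesion's intensity range, visits every mask voxel, computes the
#' plane-averaged NGTDM triplet per voxel, and averages over the voxels with
#' defined features. Also reports SUVmax within the mask, the metabolic
#' volume (mask voxel count) and the number of undefined voxels (clipped
#' neighborhoods under the strict-interior policy, excluded from the mean
#' rather than imputed).
#'
#' @param volume a [pet_volume()] or 3-D numeric array of SUV values.
#' @param mask logical 3-D array, same shape, at least one `TRUE` voxel.
#' @param config a [texture_config()].
#' @return List: `coarseness`, `contrast`, `busyness`, `suvmax`, `n_voxels`,
#'   `n_undefined`, plus `voxel_features` (matrix of per-voxel triplets, one
#'   row per mask voxel in `which(mask)` order).
#' @export
lesion_features <- function(volume, mask, config = texture_config()) {
  v <- as_suv_array(volume)
  if (!is.logical(mask) || !identical(dim(mask), dim(v)))
    stop("`mask` must be a logical array matching the volume", call. = FALSE)
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  binned <- quantize_lesion(v, mask, config$n_bins)
  centers <- which(mask, arr.ind = TRUE)
  storage.mode(centers) <- "integer"
  feats <- cpp_lesion_features(
    as.integer(binned), dim(binned), centers,
    config$subvolume, config$distance,
    config$policy == "strict-interior", config$epsilon,
    config$planes == "central")
  defined <- !is.na(feats[, 1])
  if (!any(defined))
    stop("all lesion voxels have undefined texture (no eligible pixels)",
         call. = FALSE)
  means <- colMeans(feats[defined, , drop = FALSE])
  list(coarseness = means[["coarseness"]],
       contrast = means[["contrast"]],
       busyness = means[["busyness"]],
       suvmax = max(v[mask]),
       n_voxels = nrow(centers),
       n_undefined = sum(!defined),
       voxel_features = feats)
}
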