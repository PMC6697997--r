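#' PET volume container
#'
#' A light container for a 3-D PET image in SUV units (g/ml), carrying the
#' voxel spacing in mm and a time-point tag distinguishing the early
#' (~60 min post-injection) from the delayed (~180 min) acquisition.
#'
#' @param data 3-D numeric array of SUV values; all values must be finite.
#' @param spacing numeric length-3 voxel dimensions in mm, strictly positive.
#' @param timepoint `"early"` or `"delayed"`.
#' @return Object of class `"pet_volume"`.
#' @export
pet_volume <- function(data, spacing = c(4.25, 4.25, 4.25),
                       timepoint = c("early", "delayed")) {
  timepoint <- match.arg(timepoint)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(data))) stop("intensities must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, timepoint = timepoint),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("PET volume (%s): %s voxels, %.2f x %.2f x %.2f mm, SUV range [%.2f, %.2f]\n",
              x$timepoint, paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

as_suv_array <- function(volume) {
  if (inherits(volume, "pet_volume")) return(volume$data)
  if (is.array(volume) && length(dim(volume)) == 3L) return(volume)
  stop("expected a `pet_volume` or a 3-D array", call. = FALSE)
}

#' Read / write PET volumes and lesion masks as NIfTI
#'
#' Volumes are stored as float64 NIfTI so that features recomputed after a
#' disk round trip match the in-memory values to numerical precision. Masks
#' are written as 0/1 volumes on the same grid and read back as logical
#' arrays.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param timepoint time-point tag to attach on read.
#' @return `read_pet_volume()` a [pet_volume()]; `read_lesion_mask()` a
#'   logical 3-D array.
#' @name pet_io
NULL

#' @rdname pet_io
#' @param volume a [pet_volume()] to write.
#' @export
write_pet_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname pet_io
#' @export
read_pet_volume <- function(path, timepoint = c("early", "delayed")) {
  timepoint <- match.arg(timepoint)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  pet_volume(arr, spacing = spacing, timepoint = timepoint)
}

#' @rdname pet_io
#' @param mask logical 3-D array to write.
#' @export
write_lesion_mask <- function(mask, path, spacing = c(4.25, 4.25, 4.25)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname pet_io
#' @export
read_lesion_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img)[1:3])
}

#' Label connected components of a 3-D mask
#'
#' Flood-fill labeling under 6-connectivity (face neighbors). Used to verify
#' the focal structure of phantoms, e.g. counting distinct high-uptake
#' regions above an SUV isocontour.
#'
#' @param mask logical 3-D array.
#' @return Integer array of the same shape: 0 outside the mask, component
#'   ids 1..k inside.
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  coords <- arrayInd(idx, dm)
  inside <- array(FALSE, dm)
  inside[idx] <- TRUE
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comp <- 0L
  for (k in seq_along(idx)) {
    if (lab[idx[k]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(coords[k, ], nrow = 1)
    lab[idx[k]] <- comp
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (j in seq_len(6)) {
        p <- cur + nb[j, ]
        if (any(p < 1L) || any(p > dm)) next
        if (!inside[p[1], p[2], p[3]] || lab[p[1], p[2], p[3]] != 0L) next
        lab[p[1], p[2], p[3]] <- comp
        queue <- rbind(queue, p)
      }
    }
  }
  lab
}
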