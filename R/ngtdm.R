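#' Build a neighborhood gray-tone difference matrix (NGTDM)
#'
#' Constructs, for a 2-D patch of integer bin indices, the accumulated
#' absolute difference `s(i)` between each eligible pixel of bin `i` and the
#' mean bin value `A` of its neighbors (center excluded), together with the
#' occurrence probabilities `p(i)` over the pixels that entered the matrix.
#'
#' Two pixel-eligibility policies are supported. Under `"strict-interior"`
#' (the classical definition) a pixel enters the matrix only if its full
#' `(2d+1)^2` neighborhood lies inside the valid region of the patch. Under
#' `"all-valid"` any pixel with at least one valid neighbor is eligible and
#' `A` averages over the valid neighbors that exist; this keeps all 25 pixels
#' of a 5x5 patch in play instead of the central 9.
#'
#' @param patch integer matrix of bin indices (>= 1). Values at invalid
#'   cells are ignored.
#' @param valid logical matrix of the same shape marking cells that carry
#'   data (`FALSE` for padding outside the image). Defaults to all `TRUE`.
#' @param distance neighborhood radius `d` in pixels (default 1,
#'   8-connected).
#' @param policy pixel-eligibility policy, `"strict-interior"` or
#'   `"all-valid"`.
#' @return An object of class `"ngtdm"`: a list with `s` (named numeric,
#'   one entry per bin up to the largest present), `p` (probabilities summing
#'   to 1), `n_considered`, `levels_present` and `n_gray_levels`.
#'   If no pixel is eligible an error of class `"petngtdm_empty_ngtdm"` is
#'   signalled; callers treat the corresponding voxel as feature-undefined.
#' @examples
#' patch <- matrix(c(1, 1, 1, 1, 2, 1, 1, 1, 1), 3, 3)
#' tab <- build_ngtdm(patch)
#' tab$s[2]            # |2 - 1| = 1
#' ngtdm_coarseness(tab)
#' @export
build_ngtdm <- function(patch, valid = NULL,
                        distance = 1L,
                        policy = c("strict-interior", "all-valid")) {
  policy <- match.arg(policy)
  if (!is.matrix(patch)) stop("`patch` must be a matrix", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(patch), ncol(patch))
  if (!is.logical(valid) || !identical(dim(valid), dim(patch)))
    stop("`valid` must be a logical matrix matching `patch`", call. = FALSE)
  if (!any(valid)) stop_empty_ngtdm()
  storage.mode(patch) <- "integer"
  vv <- patch[valid]
  if (anyNA(vv) || any(vv < 1L))
    stop("valid cells must hold bin indices >= 1", call. = FALSE)
  distance <- as.integer(distance)
  if (distance < 1L) stop("`distance` must be a positive integer", call. = FALSE)

  raw <- cpp_ngtdm(patch, valid, distance, policy == "strict-interior")
  if (raw$n_considered == 0L) stop_empty_ngtdm()
  s <- raw$s
  cnt <- raw$counts
  names(s) <- seq_along(s)
  p <- cnt / raw$n_considered
  names(p) <- seq_along(p)
  levels_present <- which(cnt > 0L)
  structure(
    list(
      s = s,
      p = p,
      n_considered = raw$n_considered,
      levels_present = levels_present,
      n_gray_levels = length(levels_present),
      distance = distance,
      policy = policy
    ),
    class = "ngtdm"
  )
}

stop_empty_ngtdm <- function() {
  stop(structure(
    class = c("petngtdm_empty_ngtdm", "error", "condition"),
    list(message = "no pixel is eligible under the neighborhood policy",
         call = sys.call(-1))
  ))
}

check_ngtdm <- function(t) {
  if (!inherits(t, "ngtdm")) stop("expected an `ngtdm` object", call. = FALSE)
  t
}

#' NGTDM coarseness
#'
#' `1 / (epsilon + sum_i p(i) s(i))`. High coarseness corresponds to large
#' uniform texture granules; for a constant patch the sum vanishes and the
#' value caps at `1 / epsilon`.
#'
#' @param t an `ngtdm` object from [build_ngtdm()].
#' @param epsilon small positive regularizer keeping the value finite
#'   (default `1e-8`; must be much smaller than one bin-difference unit).
#' @return Nonnegative scalar.
#' @export
ngtdm_coarseness <- function(t, epsilon = 1e-8) {
  check_ngtdm(t)
  stopifnot_scalar_number(epsilon, "epsilon")
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  1 / (epsilon + sum(t$p * t$s))
}

#' NGTDM contrast
#'
#' Product of the gray-level dispersion term
#' `1/(Ng (Ng - 1)) * sum_ij p(i) p(j) (i - j)^2` and the mean neighborhood
#' difference `1/n * sum_i s(i)`, where `Ng` counts gray levels present among
#' the considered pixels and `n` is the number of considered pixels.
#' Returns 0 by convention when a single gray level is present.
#'
#' @inheritParams ngtdm_coarseness
#' @return Nonnegative scalar.
#' @export
ngtdm_contrast <- function(t) {
  check_ngtdm(t)
  ng <- t$n_gray_levels
  if (ng <= 1L) return(0)
  i <- as.numeric(t$levels_present)
  p <- t$p[t$levels_present]
  m1 <- sum(p * i)
  m2 <- sum(p * i^2)
  disp <- 2 * (m2 - m1^2) / (ng * (ng - 1))
  disp * sum(t$s) / t$n_considered
}

#' NGTDM busyness
#'
#' `sum_i p(i) s(i) / sum_ij |i p(i) - j p(j)|`, both sums over gray levels
#' with nonzero probability (the denominator over ordered pairs). High
#' busyness indicates rapid local intensity alternation. Returns 0 by
#' convention when the denominator vanishes (e.g. a constant patch), so the
#' textureless limit never produces NaN in lesion averages.
#'
#' @inheritParams ngtdm_coarseness
#' @return Nonnegative scalar.
#' @export
ngtdm_busyness <- function(t) {
  check_ngtdm(t)
  ip <- as.numeric(t$levels_present) * t$p[t$levels_present]
  den <- sum(abs(outer(ip, ip, "-")))
  if (den == 0) return(0)
  sum(t$p * t$s) / den
}

#' All three NGTDM features of a patch
#'
#' Convenience wrapper: builds the NGTDM and returns the named triplet
#' (coarseness, contrast, busyness). Computed in compiled code; agrees with
#' [ngtdm_coarseness()], [ngtdm_contrast()] and [ngtdm_busyness()] applied to
#' [build_ngtdm()].
#'
#' @inheritParams build_ngtdm
#' @param epsilon coarseness regularizer, see [ngtdm_coarseness()].
#' @return Named numeric vector of length 3, or all-`NA` if no pixel is
#'   eligible.
#' @export
ngtdm_features <- function(patch, valid = NULL, distance = 1L,
                           policy = c("strict-interior", "all-valid"),
                           epsilon = 1e-8) {
  policy <- match.arg(policy)
  if (!is.matrix(patch)) stop("`patch` must be a matrix", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(patch), ncol(patch))
  storage.mode(patch) <- "integer"
  cpp_patch_features(patch, valid, as.integer(distance),
                     policy == "strict-interior", epsilon)
}

#' @export
print.ngtdm <- function(x, ...) {
  cat(sprintf(
    "NGTDM: %d pixel(s) considered, %d gray level(s) present (d = %d, %s)\n",
    x$n_considered, x$n_gray_levels, x$distance, x$policy))
  invisible(x)
}
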