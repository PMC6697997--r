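# Synthetic dual-time-point PET lesion phantoms.
#
# The generator encodes the two contrasting uptake architectures the
# analysis is designed to separate: malignant nodules as a single compact
# blob whose uptake rises from the early to the delayed scan, and benign
# (inflammatory) nodules as several spatially separated small foci whose
# uptake stays flat or washes out and whose focal pattern sharpens on the
# delayed image. Gray-level texture features are invariant to global uptake
# scaling, so the benign/malignant delayed-image gap is carried by this
# structural change, not by the SUV multiplier.

#' Phantom generator configuration
#'
#' Defaults emulate FDG-avid solitary pulmonary nodules on a 4.25-mm
#' isotropic grid reconstructed with an 8-mm FWHM Gaussian filter. Peak
#' early SUV draws follow truncated normals with the means and SDs reported
#' for malignant (11.22 +/- 6.24 g/ml) and benign (6.94 +/- 3.58 g/ml)
#' cohorts, truncated at 3 g/ml so every lesion is FDG-avid. Malignant
#' lesions are a single compact Gaussian blob retaining uptake on the
#' delayed scan (multiplier 1.10-1.40); benign lesions are 3-6 disjoint
#' foci (pairwise separation at least `separation_factor` times the larger
#' post-filter sigma, which puts the inter-focus dip below the 50%-of-max
#' isocontour) with stable-to-washout uptake (0.85-1.05), sharpened focal
#' radii (x0.8) and per-focus amplitude jitter on the delayed image.
#' Delayed-image noise is 1.3x the early noise, reflecting tracer decay.
#'
#' @param kind `"malignant"` or `"benign"`.
#' @param grid_dim image extents in voxels.
#' @param spacing voxel size in mm (default 4.25 isotropic).
#' @param background_suv background activity (g/ml).
#' @param psf_fwhm_mm reconstruction Gaussian filter FWHM in mm.
#' @param noise_sd_early additive Gaussian noise SD on the early image
#'   (SUV units).
#' @param delayed_noise_mult delayed-to-early noise ratio (>= 1).
#' @param mask_threshold lesion mask = envelope activity above this
#'   fraction of its maximum.
#' @param envelope_sigma extra smoothing (voxels) applied when deriving the
#'   mask envelope, so multi-focal lesions get one connected mask.
#' @param n_foci_range,focus_sigma_range,focus_amp_range,peak_suv_mean,peak_suv_sd,peak_suv_min,delayed_mult_range,delayed_sharpen,delayed_amp_jitter,separation_factor,spread_radius
#'   kind-specific structural parameters; see Details above. Override only
#'   to study departures from the default conditions.
#' @param min_voxels minimum metabolic volume guaranteed by construction.
#' @param max_retries focus-radius enlargements attempted before giving up
#'   on a sub-`min_voxels` mask.
#' @return List of class `"phantom_config"`.
#' @export
phantom_config <- function(kind = c("malignant", "benign"),
                           grid_dim = c(32L, 32L, 32L),
                           spacing = c(4.25, 4.25, 4.25),
                           background_suv = 0.5,
                           psf_fwhm_mm = 8,
                           noise_sd_early = 0.2,
                           delayed_noise_mult = 1.3,
                           mask_threshold = 0.25,
                           envelope_sigma = 1.5,
                           n_foci_range = NULL,
                           focus_sigma_range = NULL,
                           focus_amp_range = NULL,
                           peak_suv_mean = NULL,
                           peak_suv_sd = NULL,
                           peak_suv_min = 3,
                           delayed_mult_range = NULL,
                           delayed_sharpen = NULL,
                           delayed_amp_jitter = NULL,
                           separation_factor = 4.8,
                           spread_radius = 6.5,
                           min_voxels = 64L,
                           max_retries = 5L) {
  kind <- match.arg(kind)
  def <- if (kind == "malignant") {
    list(n_foci_range = c(1L, 1L), focus_sigma_range = c(2.2, 3.6),
         focus_amp_range = c(1, 1), peak_suv_mean = 11.22, peak_suv_sd = 6.24,
         delayed_mult_range = c(1.10, 1.40), delayed_sharpen = 1,
         delayed_amp_jitter = 0)
  } else {
    list(n_foci_range = c(3L, 6L), focus_sigma_range = c(0.7, 1.1),
         focus_amp_range = c(0.7, 1), peak_suv_mean = 6.94, peak_suv_sd = 3.58,
         delayed_mult_range = c(0.85, 1.05), delayed_sharpen = 0.8,
         delayed_amp_jitter = 0.15)
  }
  pick <- function(x, d) if (is.null(x)) d else x
  cfg <- list(
    kind = kind,
    grid_dim = as.integer(grid_dim),
    spacing = spacing,
    background_suv = background_suv,
    psf_fwhm_mm = psf_fwhm_mm,
    psf_sigma_vox = (psf_fwhm_mm / (2 * sqrt(2 * log(2)))) / mean(spacing),
    noise_sd_early = noise_sd_early,
    delayed_noise_mult = delayed_noise_mult,
    mask_threshold = mask_threshold,
    envelope_sigma = envelope_sigma,
    n_foci_range = as.integer(pick(n_foci_range, def$n_foci_range)),
    focus_sigma_range = pick(focus_sigma_range, def$focus_sigma_range),
    focus_amp_range = pick(focus_amp_range, def$focus_amp_range),
    peak_suv_mean = pick(peak_suv_mean, def$peak_suv_mean),
    peak_suv_sd = pick(peak_suv_sd, def$peak_suv_sd),
    peak_suv_min = peak_suv_min,
    delayed_mult_range = pick(delayed_mult_range, def$delayed_mult_range),
    delayed_sharpen = pick(delayed_sharpen, def$delayed_sharpen),
    delayed_amp_jitter = pick(delayed_amp_jitter, def$delayed_amp_jitter),
    separation_factor = separation_factor,
    spread_radius = spread_radius,
    min_voxels = as.integer(min_voxels),
    max_retries = as.integer(max_retries)
  )
  if (kind == "benign" && cfg$n_foci_range[1] < 2L)
    stop("benign phantoms need at least 2 foci (spatial separation is the mechanism)",
         call. = FALSE)
  if (any(cfg$focus_sigma_range <= 0) || cfg$noise_sd_early < 0 ||
      cfg$delayed_noise_mult < 1)
    stop("invalid phantom configuration", call. = FALSE)
  class(cfg) <- "phantom_config"
  cfg
}

# Sum of separable isotropic Gaussians on the voxel grid.
render_foci <- function(grid_dim, centers, sigmas, amps) {
  field <- array(0, grid_dim)
  ax <- lapply(grid_dim, seq_len)
  for (k in seq_along(sigmas)) {
    s2 <- 2 * sigmas[k]^2
    e1 <- exp(-(ax[[1]] - centers[k, 1])^2 / s2)
    e2 <- exp(-(ax[[2]] - centers[k, 2])^2 / s2)
    e3 <- exp(-(ax[[3]] - centers[k, 3])^2 / s2)
    field <- field + amps[k] * (e1 %o% e2 %o% e3)
  }
  field
}

rtruncnorm1 <- function(mean, sd, lower) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
  lower
}

# Place n focus centers inside a ball of radius R around `origin`, pairwise
# separated by sep_factor * max(sigma_eff of the pair). The spread radius
# grows 15% per failed round so placement always terminates.
place_foci <- function(n, origin, R, sigma_eff, sep_factor) {
  for (round in 1:8) {
    pts <- matrix(origin + runif(3, -0.5, 0.5), nrow = 1)
    tries <- 0L
    while (nrow(pts) < n && tries < 400L) {
      tries <- tries + 1L
      repeat {
        u <- runif(3, -1, 1)
        if (sum(u^2) <= 1) break
      }
      cand <- origin + u * R
      j <- nrow(pts) + 1L
      need <- sep_factor * pmax(sigma_eff[j], sigma_eff[seq_len(nrow(pts))])
      d <- sqrt(rowSums((pts - matrix(cand, nrow(pts), 3, byrow = TRUE))^2))
      if (all(d >= need)) pts <- rbind(pts, cand)
    }
    if (nrow(pts) == n) return(pts)
    R <- R * 1.15
  }
  stop("could not place separated foci; spread radius too small", call. = FALSE)
}

#' Generate one dual-time-point lesion phantom
#'
#' Draws the lesion's structural parameters under `seed`, renders noise-free
#' early and delayed activity patterns (focus Gaussians composed analytically
#' with the reconstruction point-spread function), derives the lesion mask
#' from a smoothed envelope above a fixed activity fraction (guaranteed at
#' least `min_voxels` voxels, enlarging focal radii and retrying a bounded
#' number of times if needed), rescales to the drawn peak SUV, and adds
#' independent Gaussian noise per time point. Identical seeds give
#' bit-identical volumes.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for this lesion's draws.
#' @param id lesion identifier stored in the sample.
#' @return Lesion sample: list with `id`, `label`, `early`, `delayed`
#'   ([pet_volume()]s), `mask` (logical array) and `params` (ground-truth
#'   generator draws).
#' @export
generate_lesion <- function(config, seed, id = "lesion") {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    nf <- if (config$n_foci_range[1] == config$n_foci_range[2])
      config$n_foci_range[1]
    else sample(config$n_foci_range[1]:config$n_foci_range[2], 1)
    sigmas <- runif(nf, config$focus_sigma_range[1], config$focus_sigma_range[2])
    amps <- runif(nf, config$focus_amp_range[1], config$focus_amp_range[2])
    peak <- rtruncnorm1(config$peak_suv_mean, config$peak_suv_sd,
                        config$peak_suv_min)
    dmult <- runif(1, config$delayed_mult_range[1], config$delayed_mult_range[2])
    amp_jit <- exp(rnorm(nf, 0, config$delayed_amp_jitter))
    origin <- (config$grid_dim + 1) / 2
    sig_eff <- sqrt(sigmas^2 + config$psf_sigma_vox^2)
    centers <- if (nf == 1L) {
      matrix(origin + runif(3, -1, 1), nrow = 1)
    } else {
      place_foci(nf, origin, config$spread_radius, sig_eff,
                 config$separation_factor)
    }

    scale_try <- 1
    mask <- NULL
    for (r in 0:config$max_retries) {
      se <- sqrt((sigmas * scale_try)^2 + config$psf_sigma_vox^2)
      env_sigma <- sqrt(se^2 + config$envelope_sigma^2)
      env <- render_foci(config$grid_dim, centers, env_sigma, amps)
      mask <- env >= config$mask_threshold * max(env)
      if (sum(mask) >= config$min_voxels) break
      if (r == config$max_retries)
        stop(sprintf("lesion %s: mask below %d voxels after %d retries",
                     id, config$min_voxels, config$max_retries), call. = FALSE)
      scale_try <- scale_try * 1.2
    }
    sigmas <- sigmas * scale_try
    sig_eff <- sqrt(sigmas^2 + config$psf_sigma_vox^2)

    field_e <- render_foci(config$grid_dim, centers, sig_eff, amps)
    field_e <- field_e * (peak / max(field_e))
    early <- field_e + config$background_suv +
      array(rnorm(prod(config$grid_dim), 0, config$noise_sd_early),
            config$grid_dim)

    sig_d <- sqrt((sigmas * config$delayed_sharpen)^2 + config$psf_sigma_vox^2)
    field_d <- render_foci(config$grid_dim, centers, sig_d, amps * amp_jit)
    field_d <- field_d * (peak * dmult / max(field_d))
    delayed <- field_d + config$background_suv +
      array(rnorm(prod(config$grid_dim), 0,
                  config$noise_sd_early * config$delayed_noise_mult),
            config$grid_dim)

    list(
      id = id,
      label = config$kind,
      early = pet_volume(early, config$spacing, "early"),
      delayed = pet_volume(delayed, config$spacing, "delayed"),
      mask = mask,
      params = list(seed = seed, n_foci = nf, sigmas = sigmas, amps = amps,
                    peak_suv_early = peak, delayed_mult = dmult,
                    centers = centers, n_voxels = sum(mask))
    )
  })
}

#' Generate a synthetic dual-time-point cohort
#'
#' Default composition mirrors the reference cohort: 35 benign and 81
#' malignant lesions, every one FDG-avid and at least 64 voxels by
#' construction. Each lesion draws from its own seed derived from `seed`
#' and its index, so cohorts are reproducible lesion by lesion and two
#' different seeds give different truth tables with the same composition.
#'
#' @param n_benign,n_malignant class counts (each >= 1).
#' @param seed base seed.
#' @param benign_config,malignant_config [phantom_config()]s.
#' @return List: `lesions` (list of lesion samples), `truth` (data frame of
#'   ground-truth generator draws), `seed`.
#' @export
generate_cohort <- function(n_benign = 35L, n_malignant = 81L, seed = 7L,
                            benign_config = phantom_config("benign"),
                            malignant_config = phantom_config("malignant")) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L)
  n <- n_benign + n_malignant
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  ids <- sprintf("lesion_%03d", seq_len(n))
  lesions <- vector("list", n)
  for (k in seq_len(n)) {
    cfg <- if (labels[k] == "benign") benign_config else malignant_config
    lesions[[k]] <- generate_lesion(cfg, derive_seed(seed, k), id = ids[k])
  }
  truth <- do.call(rbind, lapply(lesions, function(l) {
    data.frame(id = l$id, label = l$label, seed = l$params$seed,
               n_foci = l$params$n_foci,
               peak_suv_early = l$params$peak_suv_early,
               delayed_mult = l$params$delayed_mult,
               n_voxels = l$params$n_voxels,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(lesions = lesions, truth = truth, seed = seed)
}

#' Simulate ordinal 5-point reader scores
#'
#' Latent score = standardized feature + Gaussian noise, discretized into
#' scores 1..5 by the fixed 20/40/60/80% quantile cuts of the latent
#' distribution `N(0, 1 + noise_sd^2)`. Lower `noise_sd` models readers
#' whose judgment tracks the feature more closely (higher correlation).
#'
#' @param records data frame carrying the feature column.
#' @param signal_feature feature column driving the latent score.
#' @param noise_sd reader-noise standard deviation (latent units).
#' @param seed RNG seed.
#' @return Integer vector of scores in 1..5, one per record.
#' @export
simulate_reader_scores <- function(records, signal_feature = "delayed_busyness",
                                   noise_sd = 1, seed = 1L) {
  stopifnot(is.data.frame(records), signal_feature %in% names(records))
  x <- records[[signal_feature]]
  if (sd(x) == 0) stop("feature has zero variance", call. = FALSE)
  z <- (x - mean(x)) / sd(x)
  with_seed(seed, {
    latent <- z + rnorm(length(z), 0, noise_sd)
    cuts <- qnorm(c(0.2, 0.4, 0.6, 0.8), 0, sqrt(1 + noise_sd^2))
    findInterval(latent, cuts) + 1L
  })
}

#' Blob-fragmentation phantom sweep
#'
#' Splits one blob's activity into `n_foci` in {1, 2, 4, 8} equal-activity
#' foci of fixed individual size on symmetric layouts of growing spatial
#' frequency, at fixed total volume: the lesion mask is always the
#' `mask_voxels` highest-activity voxels of the noise-free pattern.
#' Measurement noise at the generator's level is added under `seed`, so
#' repeated calls with different seeds are independent replicates; the
#' expected (replicate-averaged) lesion busyness is non-decreasing and
#' coarseness non-increasing in `n_foci` as the uptake fragments.
#'
#' @param n_foci 1, 2, 4 or 8.
#' @param sigma individual focus sigma in voxels (fixed across the sweep).
#' @param peak_suv noise-free activity maximum (SUV).
#' @param mask_voxels metabolic volume of the phantom, identical for all
#'   `n_foci`.
#' @param noise_sd additive Gaussian noise SD (SUV).
#' @param grid_dim image extents.
#' @param jitter uniform positional jitter (voxels) applied under `seed` to
#'   avoid grid-aligned symmetry artifacts.
#' @param seed RNG seed for jitter and noise.
#' @param config a [phantom_config()] supplying PSF, spacing and background.
#' @return List with `volume` ([pet_volume()]), `mask`, `n_foci`.
#' @export
fragmentation_phantom <- function(n_foci, sigma = 1.6, peak_suv = 8,
                                  mask_voxels = 400L, noise_sd = 0.2,
                                  grid_dim = c(32L, 32L, 32L),
                                  jitter = 0.3, seed = 1L,
                                  config = phantom_config("malignant")) {
  layouts <- list(
    `1` = matrix(0, 1, 3),
    `2` = rbind(c(2.6, 0, 0), c(-2.6, 0, 0)),
    `4` = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3) * 3.0,
    `8` = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3) * 3.4
  )
  key <- as.character(n_foci)
  if (!key %in% names(layouts))
    stop("`n_foci` must be one of 1, 2, 4, 8", call. = FALSE)
  origin <- (grid_dim + 1) / 2
  sig_eff <- sqrt(sigma^2 + config$psf_sigma_vox^2)
  out <- with_seed(seed, {
    pos <- layouts[[key]] + matrix(runif(3 * n_foci, -jitter, jitter), n_foci, 3)
    centers <- sweep(pos, 2, origin, "+")
    field <- render_foci(grid_dim, centers, rep(sig_eff, n_foci),
                         rep(1 / n_foci, n_foci))
    field <- field * (peak_suv / max(field))
    mask <- array(FALSE, grid_dim)
    mask[order(field, decreasing = TRUE)[seq_len(mask_voxels)]] <- TRUE
    vol <- field + config$background_suv +
      array(rnorm(prod(grid_dim), 0, noise_sd), grid_dim)
    list(vol = vol, mask = mask)
  })
  list(volume = pet_volume(out$vol, config$spacing, "early"),
       mask = out$mask, n_foci = n_foci)
}
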