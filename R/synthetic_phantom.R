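#' Specification of a synthetic whole-body phantom
#'
#' The phantom emulates a whole-body PSMA-PET SUV volume: a uniform soft
#' tissue background, physiological hot organs (bladder, kidneys,
#' salivary glands, liver, ...) as uniform ellipsoids with matching
#' masks, ellipsoidal tumour lesions of known analytic volume and
#' uptake, optional isotropic Gaussian smoothing emulating partial
#' volume, and additive Gaussian noise clipped at zero. Structures are
#' painted by overwriting (organs first, lesions last), so a lesion's
#' nominal uptake is its voxel value.
#'
#' @param shape integer length-3 grid shape.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param background_suv background SUV level.
#' @param organs list of organ specs: `list(name=, center_mm=,
#'   radii_mm=, suv=)`.
#' @param lesions list of lesion specs: `list(center_mm=, radii_mm=,
#'   suv=, compartment=)` (compartment defaults to "unspecified").
#' @param noise_sd SD of additive Gaussian noise in SUV units.
#' @param psf_sigma_mm isotropic Gaussian smoothing sigma applied before
#'   noise (0 = off).
#' @param seed integer; fixes the generated volume bit-for-bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, background_suv = 1.0,
                         organs = list(), lesions = list(),
                         noise_sd = 0, psf_sigma_mm = 0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            background_suv >= 0, noise_sd >= 0, psf_sigma_mm >= 0)
  for (o in c(organs, lesions)) {
    if (any(o$radii_mm <= 0)) stop("structure radii must be positive")
    if (!is.null(o$suv) && o$suv < 0) stop("uptake must be non-negative")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 background_suv = background_suv, organs = organs,
                 lesions = lesions, noise_sd = noise_sd,
                 psf_sigma_mm = psf_sigma_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Logical ellipsoid mask by voxel-centre inclusion.
ellipsoid_mask <- function(shape, spacing, origin, center_mm, radii_mm) {
  cx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  ex <- ((cx - center_mm[1]) / radii_mm[1])^2
  ey <- ((cy - center_mm[2]) / radii_mm[2])^2
  ez <- ((cz - center_mm[3]) / radii_mm[3])^2
  outer(outer(ex, ey, "+"), ez, "+") <= 1
}

# Separable Gaussian smoothing along each axis (reflective edges).
gaussian_smooth3d <- function(arr, sigma_mm, spacing) {
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    if (sig_vox <= 0) next
    half <- max(1L, ceiling(3 * sig_vox))
    k <- stats::dnorm(seq(-half, half), sd = sig_vox)
    k <- k / sum(k)
    arr <- apply(arr, setdiff(1:3, ax), function(v) {
      n <- length(v)
      vp <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1L]))
      stats::filter(vp, k, sides = 2)[(half + 1L):(half + n)]
    })
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

#' Generate a synthetic phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @param frame_id frame label for the generated grid.
#' @return List with `image` (an [suv_image()]), `masks` (an
#'   [organ_mask_set()] with one mask per organ), and `truth` (data
#'   frame with one row per lesion: analytic mL volume
#'   `volume_analytic_ml`, voxelised volume `volume_voxel_ml`, nominal
#'   `suv`, centre, compartment).
#' @export
generate_phantom <- function(spec, frame_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; spacing <- spec$spacing
  origin <- c(0, 0, 0)
  extent_lo <- origin - spacing / 2
  extent_hi <- origin + (shape - 0.5) * spacing
  vals <- array(spec$background_suv, dim = shape)
  masks <- list()
  for (o in spec$organs) {
    m <- ellipsoid_mask(shape, spacing, origin, o$center_mm, o$radii_mm)
    vals[m] <- o$suv
    masks[[o$name]] <- m
  }
  vox_ml <- prod(spacing) / 1000
  truth <- list()
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    if (any(l$center_mm < extent_lo) || any(l$center_mm > extent_hi))
      stop("lesion ", i, " lies outside the grid")
    m <- ellipsoid_mask(shape, spacing, origin, l$center_mm, l$radii_mm)
    if (!any(m)) stop("lesion ", i, " covers no voxel centre")
    vals[m] <- l$suv
    truth[[i]] <- data.frame(
      lesion = i,
      volume_analytic_ml = 4 / 3 * pi * prod(l$radii_mm) / 1000,
      volume_voxel_ml = sum(m) * vox_ml,
      suv = l$suv,
      center_x_mm = l$center_mm[1], center_y_mm = l$center_mm[2],
      center_z_mm = l$center_mm[3],
      compartment = if (is.null(l$compartment)) "unspecified"
                    else l$compartment)
  }
  if (spec$psf_sigma_mm > 0)
    vals <- gaussian_smooth3d(vals, spec$psf_sigma_mm, spacing)
  if (spec$noise_sd > 0) {
    vals <- with_seed(spec$seed,
      vals + array(stats::rnorm(prod(shape), sd = spec$noise_sd),
                   dim = shape))
  }
  vals <- pmax(vals, 0)
  dim(vals) <- shape
  list(
    image = suv_image(vals, spacing = spacing, origin = origin,
                      frame_id = frame_id),
    masks = organ_mask_set(masks, frame_id = frame_id),
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(lesion = integer(), volume_analytic_ml = numeric(),
                 volume_voxel_ml = numeric(), suv = numeric(),
                 center_x_mm = numeric(), center_y_mm = numeric(),
                 center_z_mm = numeric(), compartment = character())
  )
}

#' Generate a paired pre/post phantom study
#'
#' The post-therapy phantom rescales each baseline lesion's volume and
#' uptake (ellipsoid radii scale with the cube root of the volume
#' multiplier, preserving the centroid) and may add new lesions. The
#' returned ground truth carries the analytic whole-body delta-TLP and
#' delta-MTV implied by the multipliers, for end-to-end recovery tests.
#'
#' @param spec_pre baseline [phantom_spec()].
#' @param volume_mult,uptake_mult per-lesion multipliers (> 0),
#'   recycled over the baseline lesions.
#' @param new_lesions list of lesion specs added to the post phantom.
#' @return List with `pre`, `post` (each as from [generate_phantom()])
#'   and `truth` (`delta_tlp_pct`, `delta_mtv_pct`, analytic totals).
#' @export
generate_paired_study <- function(spec_pre, volume_mult = 1,
                                  uptake_mult = 1, new_lesions = list()) {
  stopifnot(inherits(spec_pre, "phantom_spec"))
  nl <- length(spec_pre$lesions)
  if (nl == 0L) stop("baseline spec has no lesions")
  if (any(volume_mult <= 0) || any(uptake_mult <= 0))
    stop("multipliers must be positive")
  vm <- rep_len(volume_mult, nl)
  um <- rep_len(uptake_mult, nl)
  post_lesions <- lapply(seq_len(nl), function(i) {
    l <- spec_pre$lesions[[i]]
    l$radii_mm <- l$radii_mm * vm[i]^(1 / 3)
    l$suv <- l$suv * um[i]
    l
  })
  post_lesions <- c(post_lesions, new_lesions)
  spec_post <- phantom_spec(
    shape = spec_pre$shape, spacing = spec_pre$spacing,
    background_suv = spec_pre$background_suv, organs = spec_pre$organs,
    lesions = post_lesions, noise_sd = spec_pre$noise_sd,
    psf_sigma_mm = spec_pre$psf_sigma_mm, seed = spec_pre$seed + 1L)

  vol_pre <- vapply(spec_pre$lesions,
                    function(l) 4 / 3 * pi * prod(l$radii_mm) / 1000, 1)
  suv_pre <- vapply(spec_pre$lesions, `[[`, 1, "suv")
  vol_post <- vol_pre * vm
  suv_post <- suv_pre * um
  vol_new <- vapply(new_lesions,
                    function(l) 4 / 3 * pi * prod(l$radii_mm) / 1000,
                    numeric(1))
  suv_new <- vapply(new_lesions, `[[`, numeric(1), "suv")
  mtv_pre <- sum(vol_pre); mtv_post <- sum(vol_post) + sum(vol_new)
  tlp_pre <- sum(vol_pre * suv_pre)
  tlp_post <- sum(vol_post * suv_post) + sum(vol_new * suv_new)
  list(
    pre = generate_phantom(spec_pre, frame_id = "pre"),
    post = generate_phantom(spec_post, frame_id = "post"),
    truth = list(
      mtv_pre_ml = mtv_pre, mtv_post_ml = mtv_post,
      tlp_pre = tlp_pre, tlp_post = tlp_post,
      delta_mtv_pct = 100 * (mtv_post - mtv_pre) / mtv_pre,
      delta_tlp_pct = 100 * (tlp_post - tlp_pre) / tlp_pre,
      n_new_lesions = length(new_lesions))
  )
}
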