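#' SUV image container
#'
#' A 3-D scalar grid of standardized uptake values (SUV, dimensionless)
#' together with its voxel geometry. Voxel indices are 1-based in R; the
#' physical centre of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing` (voxel-centre convention).
#'
#' @param values 3-D numeric array of SUV values; finite and >= 0.
#' @param spacing numeric length-3, voxel edge lengths in mm; all > 0.
#' @param origin numeric length-3, physical offset of the first voxel
#'   centre in mm.
#' @param frame_id character label tying masks to this grid.
#'
#' @return An object of class `suv_image` with elements `values`,
#'   `spacing`, `origin`, `frame_id`.
#' @export
suv_image <- function(values, spacing, origin = c(0, 0, 0),
                      frame_id = "frame") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(dim(values) < 1L))
    stop("grid must have at least one voxel per axis")
  if (!all(is.finite(values)))
    stop("SUV values must all be finite")
  if (any(values < 0))
    stop("SUV values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite physical offsets (mm)")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         frame_id = as.character(frame_id)[1L]),
    class = "suv_image"
  )
}

#' @export
print.suv_image <- function(x, ...) {
  cat("<suv_image> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, frame '", x$frame_id, "'\n", sep = "")
  cat("  SUV range: ", signif(min(x$values), 4), " - ",
      signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Named set of binary organ / exclusion masks
#'
#' Masks mark physiological uptake regions to exclude from tumour
#' segmentation, plus the special regions `liver` (segmented with the
#' relative liver threshold) and `healthy_liver` (the reference region
#' defining that threshold). Every mask must share the exact grid of the
#' image it applies to; no resampling is performed.
#'
#' @param masks named list of logical (or strictly 0/1) 3-D arrays.
#' @param frame_id character label of the grid the masks live on.
#' @return An object of class `organ_mask_set`.
#' @export
organ_mask_set <- function(masks, frame_id = "frame") {
  if (length(masks) == 0L) {
    masks <- list()
  } else {
    if (is.null(names(masks)) || any(!nzchar(names(masks))))
      stop("every mask must be named")
    if (anyDuplicated(names(masks)))
      stop("mask names must be unique")
    masks <- lapply(masks, function(m) {
      if (!is.array(m) || length(dim(m)) != 3L)
        stop("each mask must be a 3-D array")
      if (is.logical(m)) return(m)
      if (!all(m %in% c(0, 1)))
        stop("masks must be strictly binary")
      array(m == 1, dim = dim(m))
    })
    d <- dim(masks[[1L]])
    for (m in masks)
      if (!identical(dim(m), d)) stop("all masks must share one grid shape")
  }
  structure(list(masks = masks, frame_id = as.character(frame_id)[1L]),
            class = "organ_mask_set")
}

# Stops unless every mask shares the image grid (shape and frame label).
check_masks_aligned <- function(image, mask_set) {
  if (is.null(mask_set) || length(mask_set$masks) == 0L) return(invisible())
  if (!identical(mask_set$frame_id, image$frame_id))
    stop("mask frame '", mask_set$frame_id, "' does not match image frame '",
         image$frame_id, "'; masks must share the exact grid (no resampling)")
  for (nm in names(mask_set$masks))
    if (!identical(dim(mask_set$masks[[nm]]), dim(image$values)))
      stop("mask '", nm, "' shape differs from the image grid; ",
           "masks must share the exact grid (no resampling)")
  invisible()
}

#' Acquisition metadata for SUV conversion
#'
#' @param injected_activity_mbq injected activity in MBq (> 0).
#' @param injection_time,scan_time timestamps, either `POSIXct`/parseable
#'   date-time strings or plain numbers interpreted as minutes.
#' @param half_life_min isotope half-life in minutes; the default is the
#'   68Ga half-life (67.71 min).
#' @param body_weight_kg patient body weight in kg (> 0).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_activity_mbq, injection_time,
                             scan_time, half_life_min = 67.71,
                             body_weight_kg) {
  if (!is.numeric(injected_activity_mbq) || injected_activity_mbq <= 0)
    stop("injected activity must be a positive number of MBq")
  if (!is.numeric(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be a positive number of kg")
  if (!is.numeric(half_life_min) || half_life_min <= 0)
    stop("half-life must be positive minutes")
  dt <- elapsed_minutes(injection_time, scan_time)
  if (dt < 0) stop("scan_time must not precede injection_time")
  structure(
    list(injected_activity_mbq = as.numeric(injected_activity_mbq),
         injection_time = injection_time, scan_time = scan_time,
         half_life_min = as.numeric(half_life_min),
         body_weight_kg = as.numeric(body_weight_kg)),
    class = "acquisition_meta"
  )
}

elapsed_minutes <- function(from, to) {
  if (is.numeric(from) && is.numeric(to)) return(as.numeric(to - from))
  from <- as.POSIXct(from, tz = "UTC")
  to <- as.POSIXct(to, tz = "UTC")
  as.numeric(difftime(to, from, units = "mins"))
}

#' Convert an activity-concentration map to body-weight SUV
#'
#' Body-weight SUV: tissue activity concentration (Bq/mL) divided by
#' decay-corrected injected activity (Bq) per gram of body weight. The
#' injected activity is decay-corrected from injection time to scan start
#' using the isotope half-life, so with zero elapsed time
#' `SUV = conc * body_weight_g / injected_Bq` exactly.
#'
#' @param activity_bqml 3-D array of activity concentration in Bq/mL.
#' @param meta an [acquisition_meta()] object.
#' @param spacing,origin,frame_id grid geometry forwarded to
#'   [suv_image()].
#' @return An [suv_image()].
#' @export
to_suv <- function(activity_bqml, meta, spacing, origin = c(0, 0, 0),
                   frame_id = "frame") {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (any(activity_bqml < 0, na.rm = TRUE))
    stop("activity map must be non-negative")
  dt_min <- elapsed_minutes(meta$injection_time, meta$scan_time)
  decayed_bq <- meta$injected_activity_mbq * 1e6 *
    2^(-dt_min / meta$half_life_min)
  suv <- activity_bqml * (meta$body_weight_kg * 1000) / decayed_bq
  suv_image(suv, spacing = spacing, origin = origin, frame_id = frame_id)
}

#' Volume of a single voxel in mL
#'
#' @param image an [suv_image()].
#' @return Voxel volume in mL (product of the mm spacings / 1000).
#' @export
voxel_volume_ml <- function(image) {
  stopifnot(inherits(image, "suv_image"))
  prod(image$spacing) / 1000
}

# Physical centre coordinates (mm) of voxels given as an n x 3 index
# matrix (1-based indices).
voxel_centers_mm <- function(image, ind) {
  sweep(sweep(ind - 1, 2L, image$spacing, "*"), 2L, image$origin, "+")
}
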