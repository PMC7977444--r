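#' Per-lesion volume and uptake statistics
#'
#' MTV is voxel count times voxel volume; SUV_mean and SUV_max are taken
#' over the lesion voxels; SUV_peak is the mean SUV in a 1 mL sphere
#' centred at the lesion's hottest voxel (sphere voxelised by
#' centre-inclusion, clipped to the grid). All arithmetic is in double
#' precision; rounding happens only at the reporting layer.
#'
#' @param voxel_indices linear (1-based) indices of the lesion voxels.
#' @param image the [suv_image()] the indices refer to.
#' @return List with `voxel_indices`, `n_voxels`, `mtv_ml`, `suv_mean`,
#'   `suv_max`, `suv_peak`, `centroid_mm`.
#' @export
lesion_stats <- function(voxel_indices, image) {
  stopifnot(inherits(image, "suv_image"))
  voxel_indices <- as.integer(voxel_indices)
  if (length(voxel_indices) == 0L)
    stop("lesion voxel set must be non-empty")
  nvox <- prod(dim(image$values))
  if (any(voxel_indices < 1L | voxel_indices > nvox))
    stop("voxel indices outside the grid")
  vals <- image$values[voxel_indices]
  ind <- arrayInd(voxel_indices, dim(image$values))
  centers <- voxel_centers_mm(image, ind)
  hottest <- voxel_indices[which.max(vals)]
  list(
    voxel_indices = voxel_indices,
    n_voxels = length(voxel_indices),
    mtv_ml = length(voxel_indices) * voxel_volume_ml(image),
    suv_mean = mean(vals),
    suv_max = max(vals),
    suv_peak = suv_peak(image, hottest),
    centroid_mm = colMeans(centers)
  )
}

#' SUV_peak at a voxel
#'
#' Mean SUV over all grid voxels whose centres lie within a 1 mL sphere
#' (radius 6.2035 mm) centred on the centre of `center_voxel`; the sphere
#' is clipped at the grid boundary.
#'
#' @param image an [suv_image()].
#' @param center_voxel linear (1-based) index of the sphere centre voxel.
#' @param sphere_volume_ml sphere volume (default 1 mL).
#' @return Mean SUV in the sphere.
#' @export
suv_peak <- function(image, center_voxel, sphere_volume_ml = 1) {
  stopifnot(inherits(image, "suv_image"), length(center_voxel) == 1L)
  d <- dim(image$values)
  r_mm <- (3 * 1000 * sphere_volume_ml / (4 * pi))^(1 / 3)
  c_ind <- arrayInd(as.integer(center_voxel), d)[1L, ]
  # bounding box of candidate voxels, clipped to the grid
  half <- ceiling(r_mm / image$spacing)
  lo <- pmax(c_ind - half, 1L)
  hi <- pmin(c_ind + half, d)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  dx2 <- ((gx - c_ind[1]) * image$spacing[1])^2
  dy2 <- ((gy - c_ind[2]) * image$spacing[2])^2
  dz2 <- ((gz - c_ind[3]) * image$spacing[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r_mm^2
  block <- image$values[gx, gy, gz, drop = FALSE]
  mean(block[inside])
}

#' Whole-body tumour burden
#'
#' Totals over a segmented [segment_lesions()] result: molecular tumour
#' volume `mtv` (mL, the sum of lesion volumes) and total lesion PSMA
#' `tlp` (mL x SUV, the sum over lesions of volume times SUV_mean —
#' algebraically the voxelwise sum of SUV times voxel volume over all
#' lesion voxels).
#'
#' @param lesions a `lesion_set`.
#' @return List of class `burden_summary`: `tlp`, `mtv`, `n_lesions`,
#'   `suv_max_global`, `suv_peak_global`. An empty lesion set gives an
#'   all-zero summary.
#' @export
total_burden <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  ls <- lesions$lesions
  if (length(ls) == 0L) {
    return(structure(list(tlp = 0, mtv = 0, n_lesions = 0L,
                          suv_max_global = 0, suv_peak_global = 0),
                     class = "burden_summary"))
  }
  mtv_i <- vapply(ls, `[[`, numeric(1), "mtv_ml")
  mean_i <- vapply(ls, `[[`, numeric(1), "suv_mean")
  structure(list(
    tlp = sum(mtv_i * mean_i),
    mtv = sum(mtv_i),
    n_lesions = length(ls),
    suv_max_global = max(vapply(ls, `[[`, numeric(1), "suv_max")),
    suv_peak_global = max(vapply(ls, `[[`, numeric(1), "suv_peak"))
  ), class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat("<burden_summary> TLP ", signif(x$tlp, 6), " mL x SUV | MTV ",
      signif(x$mtv, 5), " mL | ", x$n_lesions, " lesion(s) | SUVmax ",
      signif(x$suv_max_global, 4), "\n", sep = "")
  invisible(x)
}

#' Burden summary as a one-row data frame
#'
#' The machine-readable twin of a per-timepoint imaging row
#' (patient_id, timepoint, tlp, mtv, n_lesions, suv_max, suv_peak).
#'
#' @param x a `burden_summary`.
#' @param patient_id,timepoint identifiers for the row.
#' @return A one-row data frame.
#' @export
burden_row <- function(x, patient_id = NA_character_,
                       timepoint = NA_character_) {
  stopifnot(inherits(x, "burden_summary"))
  data.frame(patient_id = patient_id, timepoint = timepoint,
             tlp = x$tlp, mtv = x$mtv, n_lesions = x$n_lesions,
             suv_max = x$suv_max_global, suv_peak = x$suv_peak_global)
}
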