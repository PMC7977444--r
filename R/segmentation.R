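#' Tumour segmentation configuration
#'
#' Defaults reproduce the whole-body PSMA-PET workflow: a fixed SUV 3.0
#' inclusion threshold everywhere except the liver, where lesions are
#' segmented at `liver_factor` times the mean SUV of a healthy-liver
#' reference region; 26-neighbourhood component labelling; no minimum
#' lesion size; 15 mm centroid radius for longitudinal lesion matching.
#'
#' @param global_threshold SUV inclusion threshold (voxels with
#'   SUV >= threshold are lesion candidates).
#' @param liver_factor multiplier on healthy-liver mean SUV for the
#'   liver-compartment threshold.
#' @param connectivity component-labelling neighbourhood (6, 18 or 26).
#' @param min_voxels smallest component (in voxels) kept as a lesion.
#' @param matching_radius_mm centroid distance within which a pre and a
#'   post lesion are considered the same lesion.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(global_threshold = 3.0, liver_factor = 1.5,
                                connectivity = 26, min_voxels = 1L,
                                matching_radius_mm = 15) {
  if (global_threshold <= 0) stop("global_threshold must be > 0")
  if (liver_factor <= 0) stop("liver_factor must be > 0")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  if (matching_radius_mm <= 0) stop("matching_radius_mm must be > 0")
  structure(
    list(global_threshold = global_threshold, liver_factor = liver_factor,
         connectivity = connectivity, min_voxels = as.integer(min_voxels),
         matching_radius_mm = matching_radius_mm),
    class = "segmentation_config"
  )
}

#' Liver-compartment SUV threshold
#'
#' The relative threshold for liver metastases: `factor` times the mean
#' SUV over the healthy-liver reference mask.
#'
#' @param image an [suv_image()].
#' @param healthy_liver logical 3-D mask of lesion-free liver tissue.
#' @param factor multiplier (default 1.5).
#' @return A single SUV value.
#' @export
liver_threshold <- function(image, healthy_liver, factor = 1.5) {
  stopifnot(inherits(image, "suv_image"))
  if (!identical(dim(healthy_liver), dim(image$values)))
    stop("healthy_liver mask shape differs from the image grid")
  n <- sum(healthy_liver)
  if (n == 0L)
    stop("healthy_liver mask is empty: the relative liver threshold is undefined")
  factor * sum(image$values[healthy_liver]) / n
}

#' Segment tumour lesions by SUV thresholding
#'
#' Voxels with SUV at or above the global threshold, outside all
#' exclusion masks and outside the liver, are labelled into connected
#' components; each component of at least `min_voxels` voxels becomes a
#' lesion. If a `liver` mask is present, liver voxels are thresholded
#' separately at `liver_factor * mean SUV(healthy_liver)` and the
#' resulting components are appended as liver-compartment lesions (a
#' `healthy_liver` mask is then required). Every mask other than `liver`
#' and `healthy_liver` is treated as a physiological-uptake exclusion.
#'
#' @param image an [suv_image()].
#' @param exclusions an [organ_mask_set()] or `NULL`.
#' @param config a [segmentation_config()].
#' @return An object of class `lesion_set`: list with `lesions` (each a
#'   list with `label`, `voxel_indices` (linear, 1-based), `n_voxels`,
#'   `mtv_ml`, `suv_mean`, `suv_max`, `suv_peak`, `centroid_mm`,
#'   `compartment`), `frame_id`, and `config_used`.
#' @export
segment_lesions <- function(image, exclusions = NULL,
                            config = segmentation_config()) {
  stopifnot(inherits(image, "suv_image"),
            inherits(config, "segmentation_config"))
  check_masks_aligned(image, exclusions)
  masks <- if (is.null(exclusions)) list() else exclusions$masks
  liver <- masks[["liver"]]
  healthy_liver <- masks[["healthy_liver"]]
  excl_names <- setdiff(names(masks), c("liver", "healthy_liver"))

  body <- image$values >= config$global_threshold
  for (nm in excl_names) body <- body & !masks[[nm]]
  if (!is.null(liver)) body <- body & !liver
  if (!is.null(healthy_liver)) body <- body & !healthy_liver

  lesions <- components_to_lesions(image, body, config, "unspecified")

  if (!is.null(liver)) {
    if (is.null(healthy_liver))
      stop("a liver mask was supplied without a healthy_liver mask: ",
           "the relative liver threshold is undefined")
    thr <- liver_threshold(image, healthy_liver, config$liver_factor)
    liver_fg <- liver & (image$values >= thr)
    liver_lesions <- components_to_lesions(image, liver_fg, config, "liver")
    off <- length(lesions)
    for (i in seq_along(liver_lesions))
      liver_lesions[[i]]$label <- off + i
    lesions <- c(lesions, liver_lesions)
  }

  structure(list(lesions = lesions, frame_id = image$frame_id,
                 config_used = config),
            class = "lesion_set")
}

components_to_lesions <- function(image, fg, config, compartment) {
  lab <- label_components(fg, config$connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  out <- vector("list", k)
  kept <- 0L
  for (i in seq_len(k)) {
    vox <- which(lab == i)
    if (length(vox) < config$min_voxels) next
    kept <- kept + 1L
    st <- lesion_stats(vox, image)
    out[[kept]] <- c(list(label = kept), st,
                     list(compartment = compartment))
  }
  out[seq_len(kept)]
}

#' @export
print.lesion_set <- function(x, ...) {
  b <- total_burden(x)
  cat("<lesion_set> ", length(x$lesions), " lesion(s) on frame '",
      x$frame_id, "'\n", sep = "")
  cat("  MTV ", signif(b$mtv, 5), " mL, TLP ", signif(b$tlp, 6),
      " mL x SUV\n", sep = "")
  invisible(x)
}

#' Per-lesion summary table
#'
#' @param x a `lesion_set`.
#' @param patient_id,timepoint identifiers copied into every row.
#' @return A data frame with one row per lesion (the per-lesion CSV
#'   contract: label, compartment, mtv_ml, suv_mean, suv_max, suv_peak,
#'   centroid coordinates).
#' @export
lesion_table <- function(x, patient_id = NA_character_,
                         timepoint = NA_character_) {
  stopifnot(inherits(x, "lesion_set"))
  if (length(x$lesions) == 0L) {
    return(data.frame(patient_id = character(), timepoint = character(),
                      label = integer(), compartment = character(),
                      mtv_ml = numeric(), suv_mean = numeric(),
                      suv_max = numeric(), suv_peak = numeric(),
                      centroid_x_mm = numeric(), centroid_y_mm = numeric(),
                      centroid_z_mm = numeric()))
  }
  do.call(rbind, lapply(x$lesions, function(l) data.frame(
    patient_id = patient_id, timepoint = timepoint, label = l$label,
    compartment = l$compartment, mtv_ml = l$mtv_ml, suv_mean = l$suv_mean,
    suv_max = l$suv_max, suv_peak = l$suv_peak,
    centroid_x_mm = l$centroid_mm[1], centroid_y_mm = l$centroid_mm[2],
    centroid_z_mm = l$centroid_mm[3])))
}

#' Match lesions between co-registered timepoints
#'
#' Greedy nearest-centroid pairing: the globally closest (pre, post)
#' centroid pair within `matching_radius_mm` is matched first, both are
#' removed, and the step repeats. Post-therapy lesions left unmatched are
#' candidate new metastases. This is an automatic surrogate for
#' reader-based new-lesion adjudication; a manual per-patient
#' new-metastasis flag always takes precedence in response
#' classification.
#'
#' @param pre,post `lesion_set`s in the same physical frame.
#' @param config a [segmentation_config()] (uses `matching_radius_mm`).
#' @return List with `pairs` (data frame: pre_label, post_label,
#'   distance_mm) and `new_candidates` (integer post labels).
#' @export
match_lesions <- function(pre, post, config = segmentation_config()) {
  stopifnot(inherits(pre, "lesion_set"), inherits(post, "lesion_set"))
  np <- length(pre$lesions); nq <- length(post$lesions)
  pairs <- data.frame(pre_label = integer(), post_label = integer(),
                      distance_mm = numeric())
  if (np == 0L || nq == 0L) {
    return(list(pairs = pairs,
                new_candidates = vapply(post$lesions, `[[`, 1L, "label")))
  }
  cp <- t(vapply(pre$lesions, `[[`, numeric(3), "centroid_mm"))
  cq <- t(vapply(post$lesions, `[[`, numeric(3), "centroid_mm"))
  d <- sqrt(pmax(outer(rowSums(cp^2), rep(1, nq)) +
                 outer(rep(1, np), rowSums(cq^2)) - 2 * cp %*% t(cq), 0))
  used_p <- rep(FALSE, np); used_q <- rep(FALSE, nq)
  repeat {
    d_open <- d
    d_open[used_p, ] <- Inf
    d_open[, used_q] <- Inf
    m <- which.min(d_open)
    if (!length(m) || d_open[m] > config$matching_radius_mm) break
    i <- (m - 1L) %% np + 1L
    j <- (m - 1L) %/% np + 1L
    pairs <- rbind(pairs, data.frame(
      pre_label = pre$lesions[[i]]$label,
      post_label = post$lesions[[j]]$label,
      distance_mm = d[i, j]))
    used_p[i] <- TRUE; used_q[j] <- TRUE
    if (all(used_p) || all(used_q)) break
  }
  new_candidates <- vapply(post$lesions[!used_q], `[[`, 1L, "label")
  list(pairs = pairs, new_candidates = new_candidates)
}
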