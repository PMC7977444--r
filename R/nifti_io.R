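#' Read and write SUV images and masks as NIfTI-1
#'
#' Voxel spacing is taken from the NIfTI `pixdim` header and the physical
#' origin from the xform translation column. Values are stored as-is
#' (SUV for images, 0/1 for masks, integer labels for label maps).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param frame_id frame label to attach on read.
#' @return `read_suv_image()` returns an [suv_image()];
#'   `write_suv_image()` returns `path` invisibly.
#' @export
read_suv_image <- function(path, frame_id = basename(path)) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  orig <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  suv_image(vals, spacing = sp, origin = as.numeric(orig),
            frame_id = frame_id)
}

#' @param image an [suv_image()] (for `write_suv_image`).
#' @rdname read_suv_image
#' @export
write_suv_image <- function(image, path) {
  stopifnot(inherits(image, "suv_image"))
  img <- RNifti::asNifti(image$values)
  img <- RNifti::`pixdim<-`(img, image$spacing)
  m <- diag(c(image$spacing, 1))
  m[1:3, 4] <- image$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read acquisition metadata from a JSON sidecar
#'
#' Expected keys: `injected_activity_mbq`, `injection_time`, `scan_time`,
#' `half_life_min` (optional, defaults to the 68Ga half-life) and
#' `body_weight_kg`.
#'
#' @param path path to the JSON file.
#' @return An [acquisition_meta()].
#' @export
read_acquisition_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("injected_activity_mbq", "injection_time", "scan_time",
            "body_weight_kg")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("sidecar is missing keys: ", paste(missing, collapse = ", "))
  acquisition_meta(
    injected_activity_mbq = x$injected_activity_mbq,
    injection_time = x$injection_time,
    scan_time = x$scan_time,
    half_life_min = if (is.null(x$half_life_min)) 67.71 else x$half_life_min,
    body_weight_kg = x$body_weight_kg
  )
}
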