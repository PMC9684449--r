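## Volume and montage serialization: NIfTI export of label grids and fields,
## JSON round-trip of montage definitions.

#' Export a phantom label grid as NIfTI
#'
#' Voxel labels 0-5 with the phantom's RAS geometry.
#'
#' @param phantom A `head_phantom`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_phantom_nifti <- function(phantom, path) {
  img <- RNifti::asNifti(phantom$label)
  h <- phantom$voxel_size_mm
  RNifti::pixdim(img) <- c(h, h, h)
  xf <- diag(c(h, h, h, 1))
  xf[1:3, 4] <- phantom$origin_mm + h / 2
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a phantom label grid from NIfTI
#'
#' Returns the voxel data and geometry; round-trips the label grid written by
#' [write_phantom_nifti()] exactly.
#'
#' @param path NIfTI file path.
#' @return List with `label`, `voxel_size_mm`, `origin_mm`.
#' @export
read_phantom_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  list(label = array(as.integer(img), dim(img)),
       voxel_size_mm = unname(xf[1, 1]),
       origin_mm = unname(xf[1:3, 4] - xf[1, 1] / 2))
}

#' Export a field solution as NIfTI
#'
#' Writes the E-field magnitude (V/m) and optionally the three vector
#' components as a 4-volume series.
#'
#' @param sol A `field_solution`.
#' @param path Output `.nii` path.
#' @param vectors Include the vector components.
#' @return `path`, invisibly.
#' @export
write_field_nifti <- function(sol, path, vectors = TRUE) {
  ph <- sol$phantom
  arrs <- if (vectors) {
    c(list(sol$e_mag), sol$e_vec)
  } else list(sol$e_mag)
  dat <- array(NA_real_, c(dim(sol$e_mag), length(arrs)))
  for (i in seq_along(arrs)) dat[, , , i] <- arrs[[i]]
  img <- RNifti::asNifti(dat)
  h <- ph$voxel_size_mm
  RNifti::pixdim(img) <- c(h, h, h, 1)
  xf <- diag(c(h, h, h, 1))
  xf[1:3, 4] <- ph$origin_mm + h / 2
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a montage definition to JSON
#'
#' Serializes name, per-electrode center/shape/polarity and total current;
#' [read_montage_json()] reconstructs the montage exactly.
#'
#' @param m A `montage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage_json <- function(m, path) {
  obj <- list(
    name = m$name,
    total_current_mA = m$total_current_mA,
    round_tag = m$round_tag,
    electrodes = lapply(m$electrodes, function(e) {
      list(center = e$center, shape = e$shape, polarity = e$polarity,
           e1 = e$e1, e2 = e$e2, label = e$label)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a montage definition from JSON
#'
#' @param path JSON path written by [write_montage_json()].
#' @param phantom The `head_phantom` the montage applies to.
#' @return A `montage`.
#' @export
read_montage_json <- function(path, phantom) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  els <- lapply(obj$electrodes, function(e) {
    shape <- e$shape
    el <- make_pad(unlist(e$center),
                   if (shape$type == "rect") pad_shape("rect", shape$width_cm, shape$height_cm)
                   else pad_shape("disc", diameter_cm = shape$diameter_cm),
                   e$polarity, phantom, label = e$label)
    el$e1 <- unlist(e$e1); el$e2 <- unlist(e$e2)
    el
  })
  montage(obj$name, els, phantom, obj$total_current_mA,
          if (is.null(obj$round_tag)) NA_character_ else obj$round_tag)
}
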