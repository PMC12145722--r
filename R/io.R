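# NIfTI, CSV and JSON serialisation.
#
# Volumes are written as .nii.gz with spacing and origin in the header
# (RAS-style affine built from the LR/AP/SI axis convention).
# Displacement fields are 4D NIfTI volumes with the three mm components
# on the fourth dimension; the pull-back convention is recorded in the
# header description.

.niftiFrom <- function(data, grid, description = "") {
  img <- RNifti::asNifti(data)
  attr(img, "pixdim") <- grid@spacing
  img <- RNifti::asNifti(img)
  aff <- diag(c(grid@spacing, 1))
  aff[1:3, 4] <- grid@origin
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write a volume as NIfTI
#'
#' @param x a [ScalarImage-class], [DoseGrid-class], [LabelMap-class]
#'   mask (pass `maskName`) or [DisplacementField-class]
#' @param path output path (`.nii` / `.nii.gz`)
#' @param maskName for a LabelMap, which mask to write (as 0/1)
#' @return the path, invisibly
#' @export
writeVolume <- function(x, path, maskName = NULL) {
  if (is(x, "LabelMap")) {
    stopifnot(!is.null(maskName))
    data <- mask(x, maskName) * 1L
  } else if (is(x, "DisplacementField")) {
    data <- x@data
  } else data <- x@data
  img <- .niftiFrom(data, grid(x),
                    if (is(x, "DisplacementField"))
                      "displacement mm, pull-back (fixed -> moving)" else "")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file
#' @param what one of `"image"`, `"dose"`, `"field"`, `"mask"`
#' @return the corresponding subfracdose object
#' @export
readVolume <- function(path, what = c("image", "dose", "field", "mask")) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  sp <- RNifti::niftiHeader(img)$pixdim[2:4]
  xf <- RNifti::xform(img)
  orig <- xf[1:3, 4]
  data <- array(as.numeric(img), dim = dim(img))
  g <- voxelGrid(dim(img)[1:3], spacing = sp, origin = orig)
  switch(what,
    image = scalarImage(g, data),
    dose = doseGrid(g, data),
    field = displacementField(g, data),
    mask = data > 0.5)
}

#' Write shift records as CSV
#'
#' Columns: patient, fraction, interval, dx_lr, dy_ap, dz_si (mm),
#' magnitude, source.
#' @param records a [shiftRecords()] table
#' @param path output CSV path
#' @export
writeShiftRecords <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Read shift records from CSV
#' @param path CSV path written by [writeShiftRecords()]
#' @return a [shiftRecords()] table
#' @export
readShiftRecords <- function(path) {
  shiftRecords(utils::read.csv(path, stringsAsFactors = FALSE))
}

# protocol trace -> one readable text block per patient
.formatProtocolTrace <- function(patientId, state) {
  c(sprintf("patient %s: %s", patientId,
            if (state$switched)
              sprintf("switched to large margins at fraction %d",
                      state$switchFraction)
            else "completed with tight margins"),
    paste0("  ", state$log))
}
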