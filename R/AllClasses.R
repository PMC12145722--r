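#' VoxelGrid: geometry shared by all volumes of a session
#'
#' A regular 3D voxel grid with a fixed axis convention: the first array
#' dimension runs left-right (LR, positive towards the patient's left),
#' the second anterior-posterior (AP, positive posterior), the third
#' superior-inferior (SI, positive superior). Voxel indices are 0-based in
#' world-coordinate arithmetic: world mm = origin + index0 * spacing.
#'
#' @slot shape integer(3), voxels per axis (each >= 8)
#' @slot spacing numeric(3), mm per voxel along (LR, AP, SI)
#' @slot origin numeric(3), world mm of the first voxel centre
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  prototype(shape = c(16L, 16L, 16L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("VoxelGrid", function(object) {
  msgs <- character(0)
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msgs <- c(msgs, "shape must have length 3 with at least 8 voxels per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be 3 finite values (mm)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape integer(3) voxels per axis (LR, AP, SI)
#' @param spacing numeric(3) or scalar, mm per voxel
#' @param origin numeric(3), world mm of the first voxel centre
#' @return A [VoxelGrid-class] object.
#' @examples
#' voxelGrid(c(32, 32, 32), spacing = 2.5)
#' @export
voxelGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VoxelGrid", shape = as.integer(rep_len(shape, 3)),
      spacing = as.numeric(rep_len(spacing, 3)),
      origin = as.numeric(rep_len(origin, 3)))
}

# shared validity helper: volume data conforms to its grid
.checkVolumeData <- function(grid, data, what = "data") {
  msgs <- character(0)
  if (!identical(dim(data), as.integer(grid@shape)))
    msgs <- c(msgs, sprintf("%s dimensions do not match grid shape", what))
  if (any(!is.finite(data)))
    msgs <- c(msgs, sprintf("%s contains non-finite values", what))
  msgs
}

#' ScalarImage: a 3D intensity volume on a VoxelGrid
#'
#' @slot grid the [VoxelGrid-class]
#' @slot data numeric 3D array of intensities (arbitrary units, finite)
#' @export
setClass("ScalarImage", representation(grid = "VoxelGrid", data = "array"))

setValidity("ScalarImage", function(object) {
  msgs <- .checkVolumeData(object@grid, object@data, "intensity")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ScalarImage-class
#' @param grid a [VoxelGrid-class]
#' @param data numeric 3D array matching `grid`
#' @export
scalarImage <- function(grid, data) new("ScalarImage", grid = grid, data = data)

#' LabelMap: binary organ masks on a shared VoxelGrid
#'
#' Holds the segmentation of one anatomy instance: `gtv`, `prostate`,
#' `ctv`, `bladder` and `rectum` masks (logical arrays), plus any derived
#' masks (`ptv`, `ring`). Invariants: GTV is contained in the CTV and the
#' CTV never intersects bladder or rectum.
#'
#' @slot grid the [VoxelGrid-class]
#' @slot masks named list of logical 3D arrays
#' @export
setClass("LabelMap", representation(grid = "VoxelGrid", masks = "list"))

setValidity("LabelMap", function(object) {
  msgs <- character(0)
  sh <- as.integer(object@grid@shape)
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), sh))
      msgs <- c(msgs, sprintf("mask '%s' must be a logical array on the grid", nm))
  }
  m <- object@masks
  if (all(c("gtv", "ctv") %in% names(m)) && any(m$gtv & !m$ctv))
    msgs <- c(msgs, "GTV must be contained in the CTV")
  if (all(c("ctv", "bladder") %in% names(m)) && any(m$ctv & m$bladder))
    msgs <- c(msgs, "CTV must not intersect the bladder")
  if (all(c("ctv", "rectum") %in% names(m)) && any(m$ctv & m$rectum))
    msgs <- c(msgs, "CTV must not intersect the rectum")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LabelMap-class
#' @param grid a [VoxelGrid-class]
#' @param masks named list of logical arrays
#' @export
labelMap <- function(grid, masks) new("LabelMap", grid = grid, masks = masks)

#' DoseGrid: absorbed dose (Gy) on a VoxelGrid
#'
#' @slot grid the [VoxelGrid-class]
#' @slot data numeric 3D array of dose in Gy (non-negative, finite)
#' @export
setClass("DoseGrid", representation(grid = "VoxelGrid", data = "array"))

setValidity("DoseGrid", function(object) {
  msgs <- .checkVolumeData(object@grid, object@data, "dose")
  if (length(msgs) == 0 && any(object@data < 0))
    msgs <- c(msgs, "dose must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DoseGrid-class
#' @param grid a [VoxelGrid-class]
#' @param data numeric 3D array of dose in Gy
#' @export
doseGrid <- function(grid, data) new("DoseGrid", grid = grid, data = data)

#' DisplacementField: per-voxel 3-vector displacement in mm
#'
#' Pull-back convention: the field maps fixed-image coordinates x to
#' moving-image coordinates x + u(x); warping samples the moving volume at
#' x + u(x). Stored as a 4D array with the displacement component (LR,
#' AP, SI) on the fourth dimension.
#'
#' @slot grid the [VoxelGrid-class]
#' @slot data numeric 4D array `[nx, ny, nz, 3]` of displacements (mm)
#' @slot log list, registration diagnostics (per-level residuals,
#'   convergence flag, warning flag)
#' @export
setClass("DisplacementField",
  representation(grid = "VoxelGrid", data = "array", log = "list"),
  prototype(log = list())
)

setValidity("DisplacementField", function(object) {
  msgs <- character(0)
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 3L ||
      !identical(d[1:3], as.integer(object@grid@shape)))
    msgs <- c(msgs, "field must be [nx, ny, nz, 3] on the grid")
  if (any(!is.finite(object@data)))
    msgs <- c(msgs, "field contains non-finite values")
  if (length(msgs)) msgs else TRUE
})

#' @rdname DisplacementField-class
#' @param grid a [VoxelGrid-class]
#' @param data 4D array `[nx, ny, nz, 3]` of displacements in mm
#' @param log list of registration diagnostics
#' @export
displacementField <- function(grid, data, log = list())
  new("DisplacementField", grid = grid, data = data, log = log)

# zero field on a grid
.zeroField <- function(grid)
  displacementField(grid, array(0, dim = c(grid@shape, 3L)))

#' FractionSession: one treatment session with its image sequence
#'
#' Holds the four per-session MR volumes (MR1 acquired for plan
#' adaptation, MR2 during the adapt-to-shape procedure, MR3 during the
#' first sub-fraction delivery, MR4 during the second), the segmentation
#' on MR1, ground-truth propagated segmentations on MR2-MR4, and the
#' generating motion samples so that every downstream estimate has an
#' oracle.
#'
#' @slot patient character, patient identifier
#' @slot fraction integer, fraction index (1-5)
#' @slot images named list of [ScalarImage-class] (MR1..MR4)
#' @slot labels [LabelMap-class] on MR1
#' @slot labelsAt named list of [LabelMap-class] for MR2..MR4 (ground truth)
#' @slot motions named list of motion samples (see [sampleMotion()]) for
#'   intervals `MR1_MR2`, `MR2_MR3`, `MR3_MR4`
#' @export
setClass("FractionSession",
  representation(patient = "character", fraction = "integer",
                 images = "list", labels = "LabelMap",
                 labelsAt = "list", motions = "list")
)

setValidity("FractionSession", function(object) {
  msgs <- character(0)
  if (!all(c("MR1", "MR2", "MR3", "MR4") %in% names(object@images)))
    msgs <- c(msgs, "images must contain MR1..MR4")
  if (!(object@fraction >= 1L))
    msgs <- c(msgs, "fraction index must be >= 1")
  if (length(msgs)) msgs else TRUE
})
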