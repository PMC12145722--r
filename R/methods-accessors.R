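.AXES <- c("LR", "AP", "SI")

.hasGridSlot <- function(x) is(x, "ScalarImage") || is(x, "LabelMap") ||
  is(x, "DoseGrid") || is(x, "DisplacementField")

#' @rdname accessors
setMethod("grid", "VoxelGrid", function(x) x)
#' @rdname accessors
setMethod("grid", "ScalarImage", function(x) x@grid)
#' @rdname accessors
setMethod("grid", "LabelMap", function(x) x@grid)
#' @rdname accessors
setMethod("grid", "DoseGrid", function(x) x@grid)
#' @rdname accessors
setMethod("grid", "DisplacementField", function(x) x@grid)

#' @rdname accessors
setMethod("spacing", "VoxelGrid", function(x) setNames(x@spacing, .AXES))
#' @rdname accessors
setMethod("spacing", "ANY", function(x) spacing(grid(x)))

#' @rdname accessors
setMethod("origin", "VoxelGrid", function(x) setNames(x@origin, .AXES))
#' @rdname accessors
setMethod("origin", "ANY", function(x) origin(grid(x)))

#' @rdname accessors
setMethod("gridShape", "VoxelGrid", function(x) setNames(x@shape, .AXES))
#' @rdname accessors
setMethod("gridShape", "ANY", function(x) gridShape(grid(x)))

#' @rdname accessors
setMethod("voxels", "ScalarImage", function(x) x@data)
#' @rdname accessors
setMethod("voxels", "DoseGrid", function(x) x@data)
#' @rdname accessors
setMethod("voxels", "DisplacementField", function(x) x@data)

#' @rdname accessors
setMethod("masks", "LabelMap", function(x) x@masks)
#' @rdname accessors
setMethod("mask", "LabelMap", function(x, name) {
  if (!name %in% names(x@masks))
    stop("no mask named '", name, "' in this LabelMap")
  x@masks[[name]]
})

#' @rdname accessors
setMethod("voxelVolumeCc", "VoxelGrid", function(x) prod(x@spacing) / 1000)
#' @rdname accessors
setMethod("voxelVolumeCc", "ANY", function(x) voxelVolumeCc(grid(x)))

# world mm <-> fractional 1-based voxel index conversions
.worldToVox <- function(grid, xyz) {
  sweep(sweep(xyz, 2, grid@origin, "-"), 2, grid@spacing, "/") + 1
}
.voxToWorld <- function(grid, ijk) {
  sweep(sweep(ijk - 1, 2, grid@spacing, "*"), 2, grid@origin, "+")
}

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@shape, collapse = " x "), "voxels, spacing",
      paste(format(object@spacing, digits = 3), collapse = "/"),
      "mm (LR/AP/SI)\n")
})

setMethod("show", "ScalarImage", function(object) {
  cat("ScalarImage on ")
  show(object@grid)
  cat("  intensity range:",
      paste(format(range(object@data), digits = 4), collapse = " .. "), "\n")
})

setMethod("show", "LabelMap", function(object) {
  cat("LabelMap on ")
  show(object@grid)
  vv <- voxelVolumeCc(object@grid)
  for (nm in names(object@masks))
    cat(sprintf("  %-8s %6d voxels (%.1f cm3)\n", nm,
                sum(object@masks[[nm]]), sum(object@masks[[nm]]) * vv))
})

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid on ")
  show(object@grid)
  cat(sprintf("  dose range: %.3f .. %.3f Gy\n",
              min(object@data), max(object@data)))
})

setMethod("show", "DisplacementField", function(object) {
  cat("DisplacementField on ")
  show(object@grid)
  mag <- sqrt(object@data[, , , 1]^2 + object@data[, , , 2]^2 +
                object@data[, , , 3]^2)
  cat(sprintf("  |u|: mean %.3f mm, max %.3f mm%s\n", mean(mag), max(mag),
              if (isTRUE(object@log$warning)) "  [non-converged]" else ""))
})

setMethod("show", "FractionSession", function(object) {
  cat(sprintf("FractionSession: patient %s, fraction %d, images %s\n",
              object@patient, object@fraction,
              paste(names(object@images), collapse = ", ")))
})
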