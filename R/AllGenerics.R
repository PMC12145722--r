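#' @name accessors
#' @title Accessors for subfracdose volume classes
#' @description `grid()`, `spacing()`, `origin()`, `gridShape()` return the
#'   geometry of a volume; `voxels()` returns the underlying array;
#'   `masks()` returns the named mask list of a [LabelMap-class];
#'   `voxelVolumeCc()` the volume of one voxel in cm3.
#' @param x a volume object
#' @param name mask name (for `mask()`)
NULL

#' @rdname accessors
#' @export
setGeneric("grid", function(x) standardGeneric("grid"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname accessors
#' @export
setGeneric("mask", function(x, name) standardGeneric("mask"))

#' @rdname accessors
#' @export
setGeneric("voxelVolumeCc", function(x) standardGeneric("voxelVolumeCc"))
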