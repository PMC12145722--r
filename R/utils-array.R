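# Vectorised 3D array primitives shared by the phantom, registration,
# planning and accumulation code. All operate on plain numeric/logical
# arrays; geometry (spacing, origin) is handled by the callers.

#' @importFrom stats dnorm rnorm runif sd median quantile setNames
NULL

# Clamp numeric vector into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Sample a 3D array at fractional 1-based voxel coordinates by trilinear
# interpolation. Coordinates outside the grid take nearest-edge values.
# xi, yi, zi: numeric vectors of equal length. Compiled kernel; the R
# reference implementation (.interpTrilinearR) defines the semantics.
.interpTrilinear <- function(arr, xi, yi, zi) {
  .cppInterp3(arr, dim(arr), as.numeric(xi), as.numeric(yi), as.numeric(zi),
              nearest = FALSE)
}

.interpTrilinearR <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  xi <- .clamp(xi, 1, d[1]); yi <- .clamp(yi, 1, d[2]); zi <- .clamp(zi, 1, d[3])
  x0 <- .clamp(floor(xi), 1, d[1] - 1L)
  y0 <- .clamp(floor(yi), 1, d[2] - 1L)
  z0 <- .clamp(floor(zi), 1, d[3] - 1L)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- (x0) + (y0 - 1) * nx + (z0 - 1) * nxy   # linear index of (x0,y0,z0)
  v000 <- arr[base];            v100 <- arr[base + 1]
  v010 <- arr[base + nx];       v110 <- arr[base + nx + 1]
  v001 <- arr[base + nxy];      v101 <- arr[base + nxy + 1]
  v011 <- arr[base + nx + nxy]; v111 <- arr[base + nx + nxy + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Nearest-neighbour sampling at fractional 1-based voxel coordinates.
.interpNearest <- function(arr, xi, yi, zi) {
  .cppInterp3(arr, dim(arr), as.numeric(xi), as.numeric(yi), as.numeric(zi),
              nearest = TRUE)
}

.interpNearestR <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  x0 <- .clamp(round(xi), 1, d[1])
  y0 <- .clamp(round(yi), 1, d[2])
  z0 <- .clamp(round(zi), 1, d[3])
  arr[x0 + (y0 - 1) * d[1] + (z0 - 1) * d[1] * d[2]]
}

# Shift an array by an integer voxel offset along one axis, replicating
# (pad = "edge") or filling (pad = value) at the boundary.
.shiftAxis <- function(arr, offset, axis, pad = "edge") {
  d <- dim(arr)
  n <- d[axis]
  idx <- seq_len(n) + offset
  if (identical(pad, "edge")) {
    idx <- .clamp(idx, 1, n)
    sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    sel[[axis]] <- idx
    return(arr[sel[[1]], sel[[2]], sel[[3]], drop = FALSE])
  }
  out <- array(pad, dim = d)
  keep <- idx >= 1 & idx <= n
  if (!any(keep)) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  src[[axis]] <- idx[keep]
  dst[[axis]] <- seq_len(n)[keep]
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

# Separable Gaussian smoothing with per-axis sigma in voxel units.
# Kernel truncated at 3 sigma; edges handled by replication. Compiled
# kernel; .smoothGaussianR is the R reference implementation.
.smoothGaussian <- function(arr, sigmaVox) {
  .cppSmooth3(arr, dim(arr), as.numeric(rep_len(sigmaVox, 3)))
}

.smoothGaussianR <- function(arr, sigmaVox) {
  sigmaVox <- rep_len(sigmaVox, 3)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    acc <- array(0, dim = dim(arr))
    for (k in seq(-r, r)) {
      acc <- acc + w[k + r + 1] * .shiftAxis(arr, k, axis, pad = "edge")
    }
    arr <- acc
  }
  arr
}

# Truncated separable squared Euclidean distance transform.
# Returns per-voxel squared distance (in the units implied by `spacing`)
# to the nearest TRUE voxel of `mask`, exact up to `dmax`; larger
# distances are capped at dmax^2 * 1.01. Anisotropic metrics are obtained
# by passing scaled spacings (e.g. spacing / margin for margin-normalised
# distance).
.edtSquared <- function(mask, spacing, dmax) {
  stopifnot(length(dim(mask)) == 3, all(spacing > 0), dmax > 0)
  cap <- dmax^2 * 1.01
  D <- array(ifelse(mask, 0, cap), dim = dim(mask))
  for (axis in 1:3) {
    sp <- spacing[axis]
    r <- min(dim(mask)[axis] - 1L, ceiling(dmax / sp))
    if (r < 1) next
    acc <- D
    for (o in seq(-r, r)) {
      if (o == 0) next
      acc <- pmin(acc, .shiftAxis(D, o, axis, pad = cap) + (o * sp)^2)
    }
    D <- pmin(acc, cap)
  }
  D
}

# Signed Euclidean distance (mm): negative inside the mask.
.signedDistance <- function(mask, spacing, dmax = 30) {
  dOut <- sqrt(.edtSquared(mask, spacing, dmax))
  dIn <- sqrt(.edtSquared(!mask, spacing, dmax))
  dOut - dIn
}

# Central-difference gradient of a 3D array, per-axis spacing in mm.
# Returns a list of three arrays (d/dLR, d/dAP, d/dSI).
.gradient3 <- function(arr, spacing) {
  lapply(1:3, function(axis) {
    (.shiftAxis(arr, 1L, axis, pad = "edge") -
       .shiftAxis(arr, -1L, axis, pad = "edge")) / (2 * spacing[axis])
  })
}

# Voxel-coordinate (1-based, fractional) centroid of a logical mask.
.maskCentroidVox <- function(mask) {
  idx <- which(mask)
  stopifnot(length(idx) > 0)
  d <- dim(mask)
  i <- ((idx - 1L) %% d[1]) + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  c(mean(i), mean(j), mean(k))
}

# Block-average downsampling by an integer factor per axis (for image
# pyramids). Trailing voxels that do not fill a block are averaged into
# the last block.
.downsample <- function(arr, factor) {
  if (factor == 1L) return(arr)
  d <- dim(arr)
  nd <- pmax(2L, ceiling(d / factor))
  out <- array(0, dim = nd)
  cnt <- array(0, dim = nd)
  # accumulate by index mapping (vectorised over the full array)
  i <- pmin(((seq_len(d[1]) - 1L) %/% factor) + 1L, nd[1])
  j <- pmin(((seq_len(d[2]) - 1L) %/% factor) + 1L, nd[2])
  k <- pmin(((seq_len(d[3]) - 1L) %/% factor) + 1L, nd[3])
  lin <- outer(outer(i, (j - 1L) * nd[1], "+"), (k - 1L) * nd[1] * nd[2], "+")
  sums <- rowsum(as.vector(arr), group = as.vector(lin))
  ns <- rowsum(rep(1, length(arr)), group = as.vector(lin))
  out[as.integer(rownames(sums))] <- sums / ns
  out
}

# Trilinear upsampling of a 3D array to target dims, aligning grid
# extents (used for displacement-field pyramids; values unchanged in mm).
.upsampleTo <- function(arr, targetDim) {
  d <- dim(arr)
  g <- expand.grid(
    x = seq(1, d[1], length.out = targetDim[1]),
    y = seq(1, d[2], length.out = targetDim[2]),
    z = seq(1, d[3], length.out = targetDim[3])
  )
  array(.interpTrilinear(arr, g$x, g$y, g$z), dim = targetDim)
}
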