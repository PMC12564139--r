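#' Access the voxel array of a volume or mask
#' @param x a [CTVolume-class] or [CTMask-class].
#' @return The 3D voxel array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Access the voxel spacing (mm per axis)
#' @param x a [CTVolume-class] or [CTMask-class].
#' @return numeric(3) spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Access the world-space origin (mm)
#' @param x a [CTVolume-class] or [CTMask-class].
#' @return numeric(3) origin in mm.
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname voxels
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname voxelOrigin
#' @export
setMethod("voxelOrigin", "CTVolume", function(x) x@origin)

#' @describeIn CTVolume-class grid dimensions.
#' @param x a `CTVolume`.
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("%s %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "CTMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTMask %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@voxels),
              100 * mean(object@voxels)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d^3 grid @ (%.2f, %.2f, %.2f) mm, seed %d\n",
              object@gridSize, object@voxelSpacing[1], object@voxelSpacing[2],
              object@voxelSpacing[3], object@seed))
  cat(sprintf("  dens r=%.1f mm h=%.1f mm shell=%.1f mm; HU bg/trab/cort = %g/%g/%g\n",
              object@densRadius, object@densHeight, object@shellThickness,
              object@backgroundHu, object@trabecularHu, object@corticalHu))
  if (object@fracturePresent)
    cat(sprintf("  fracture: width %.2f mm, displacement %.2f mm, angle %.1f deg\n",
                object@fractureWidth, object@fractureDisplacement, object@fractureAngle))
  else cat("  no fracture\n")
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase (%s): ", if (object@label) "fracture" else "no fracture"))
  show(object@volume)
})
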