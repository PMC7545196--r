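# Accessor generics and methods; slots are never touched directly by users.

#' @rdname Contour
#' @param object,x an object of the documented class.
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))
#' @rdname Contour
#' @export
setMethod("contourPoints", "Contour", function(object) object@points)

#' @rdname Contour
#' @export
setGeneric("slicePosition", function(object) standardGeneric("slicePosition"))
#' @rdname Contour
#' @export
setMethod("slicePosition", "Contour", function(object) object@slicePosition)

#' @rdname Centerline
#' @param object an object of the documented class.
#' @export
setGeneric("centerlinePoints",
           function(object) standardGeneric("centerlinePoints"))
#' @rdname Centerline
#' @export
setMethod("centerlinePoints", "Centerline", function(object) object@points)

#' @rdname Centerline
#' @export
setGeneric("onHead", function(object) standardGeneric("onHead"))
#' @rdname Centerline
#' @export
setMethod("onHead", "Centerline", function(object) object@onHead)

#' @rdname Centerline
#' @export
setGeneric("lensCenter", function(object) standardGeneric("lensCenter"))
#' @rdname Centerline
#' @export
setMethod("lensCenter", "Centerline", function(object)
  if (length(object@lensCenter)) object@lensCenter else NULL)

#' @rdname ImageVolume
#' @param object an object of the documented class.
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname ImageVolume
#' @export
setMethod("volumeData", "ImageVolume", function(object) object@data)

#' @rdname ImageVolume
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname ImageVolume
#' @export
setMethod("voxelSpacing", "ImageVolume", function(object) object@spacing)

#' @rdname ImageVolume
#' @export
setGeneric("intensityMax", function(object) standardGeneric("intensityMax"))
#' @rdname ImageVolume
#' @export
setMethod("intensityMax", "ImageVolume", function(object) object@intensityMax)

#' Axial position (mm) of each slice in a volume
#'
#' Voxel-center convention: slice k (1-based) sits at (k - 1) * slice
#' spacing.
#' @param object an [ImageVolume-class].
#' @return numeric vector of slice positions in mm.
#' @export
setGeneric("slicePositions", function(object)
  standardGeneric("slicePositions"))
#' @rdname slicePositions
#' @export
setMethod("slicePositions", "ImageVolume", function(object)
  (seq_len(dim(object@data)[3L]) - 1L) * object@spacing[3L])

#' @rdname SliceMeasurement-class
#' @param object an object of the documented class.
#' @export
setGeneric("onContour", function(object) standardGeneric("onContour"))
#' @rdname SliceMeasurement-class
#' @export
setMethod("onContour", "SliceMeasurement", function(object) object@onContour)
#' @rdname SliceMeasurement-class
#' @export
setGeneric("onsContour", function(object) standardGeneric("onsContour"))
#' @rdname SliceMeasurement-class
#' @export
setMethod("onsContour", "SliceMeasurement", function(object)
  object@onsContour)

#' Areas and equivalent diameters of a slice measurement
#'
#' @param object a [SliceMeasurement-class].
#' @return named numeric vector with entries \code{on_area_mm2},
#'   \code{ons_area_mm2}, \code{on_diameter_mm}, \code{ons_diameter_mm},
#'   \code{offset_mm}.
#' @export
setGeneric("measurementValues", function(object)
  standardGeneric("measurementValues"))
#' @rdname measurementValues
#' @export
setMethod("measurementValues", "SliceMeasurement", function(object)
  c(on_area_mm2 = object@onAreaMm2, ons_area_mm2 = object@onsAreaMm2,
    on_diameter_mm = object@onDiameterMm,
    ons_diameter_mm = object@onsDiameterMm, offset_mm = object@offsetMm))

#' @rdname RatingsTable
#' @param object an object of the documented class.
#' @export
setGeneric("ratings", function(object) standardGeneric("ratings"))
#' @rdname RatingsTable
#' @export
setMethod("ratings", "RatingsTable", function(object) object@values)

#' Reliability report values as a named vector
#'
#' @param object a [ReliabilityReport-class].
#' @return named numeric vector (icc, cv, mean_abs_diff, sd_abs_diff,
#'   percent_diff, percent_sd).
#' @export
setGeneric("reportValues", function(object) standardGeneric("reportValues"))
#' @rdname reportValues
#' @export
setMethod("reportValues", "ReliabilityReport", function(object)
  c(icc = object@icc, cv = object@cv, mean_abs_diff = object@meanAbsDiff,
    sd_abs_diff = object@sdAbsDiff, percent_diff = object@percentDiff,
    percent_sd = object@percentSd))

setMethod("show", "Contour", function(object) {
  cat(sprintf(
    "Contour: %d vertices, slice z = %.3f mm, area %.4f mm^2, Q = %.3f\n",
    nrow(object@points), object@slicePosition, polygonArea(object),
    isoperimetricQuotient(object)))
})

setMethod("show", "Centerline", function(object) {
  al <- arcLength(object@points)
  cat(sprintf(
    "Centerline: %d points, path length %.2f mm, ON head (%.2f, %.2f, %.2f)\n",
    nrow(object@points), al[length(al)], object@onHead[1L],
    object@onHead[2L], object@onHead[3L]))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ImageVolume: %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm, range [%g, %g]\n",
    d[1L], d[2L], d[3L], object@spacing[1L], object@spacing[2L],
    object@spacing[3L], min(object@data), max(object@data)))
})

setMethod("show", "DeviationResult", function(object) {
  cat(sprintf(
    "ON deviation: %.4f mm at %.2f mm along a %.2f mm trajectory\n",
    object@deviationMm, object@argPositionMm, object@truncatedLengthMm))
})

setMethod("show", "SliceMeasurement", function(object) {
  cat(sprintf("Slice measurement %g mm posterior to the ON head:\n",
              object@offsetMm))
  cat(sprintf("  ON : area %7.3f mm^2, equivalent diameter %5.3f mm\n",
              object@onAreaMm2, object@onDiameterMm))
  cat(sprintf("  ONS: area %7.3f mm^2, equivalent diameter %5.3f mm\n",
              object@onsAreaMm2, object@onsDiameterMm))
})

setMethod("show", "RatingsTable", function(object) {
  cat(sprintf("RatingsTable '%s'%s: %d cases x %d repeats\n",
              object@parameter,
              if (nzchar(object@units)) paste0(" (", object@units, ")")
              else "",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "ReliabilityReport", function(object) {
  cat(sprintf("Reliability of '%s'%s\n", object@parameter,
              if (nzchar(object@units)) paste0(" (", object@units, ")")
              else ""))
  cat(sprintf("  mean +/- SD diff : %.3f +/- %.3f (%.1f%% +/- %.1f%%)\n",
              object@meanAbsDiff, object@sdAbsDiff, object@percentDiff,
              object@percentSd))
  cat(sprintf("  ICC [%s]  : %.3f\n", object@iccForm, object@icc))
  cat(sprintf("  CV (fraction)    : %.3f\n", object@cv))
})
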