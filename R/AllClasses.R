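#' @import methods
NULL

#' Closed planar contour in physical coordinates
#'
#' A \code{Contour} is a closed, simple (non-self-intersecting), ordered
#' polyline in millimetre coordinates, attached to an axial slice position.
#' The first and last vertices are treated as joined; the stored vertex list
#' does not repeat the first vertex. Construction normalizes orientation to
#' counter-clockwise so the shoelace area is positive.
#'
#' @slot points numeric matrix, n x 2, vertex (x, y) coordinates in mm.
#' @slot slicePosition numeric(1), axial position of the slice in mm.
#'
#' @seealso [Contour()] for the validating constructor, [polygonArea()],
#'   [polygonPerimeter()], [isoperimetricQuotient()].
#' @exportClass Contour
setClass("Contour",
  representation(points = "matrix", slicePosition = "numeric"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 2L)
      return("points must be a numeric n x 2 matrix")
    if (anyNA(p) || any(!is.finite(p)))
      return("contour vertices must be finite")
    if (nrow(unique(p)) < 3L)
      return("a contour needs at least 3 distinct vertices")
    if (length(object@slicePosition) != 1L || !is.finite(object@slicePosition))
      return("slicePosition must be a single finite number")
    a <- .shoelace(p)
    if (abs(a) < .Machine$double.eps * 100 * max(1, max(abs(p))))
      return("degenerate contour: zero enclosed area (collinear vertices?)")
    TRUE
  })

#' Optic nerve centerline in 3D
#'
#' Ordered 3D points (mm) tracing the optic nerve path from the ON head
#' posteriorly, as exported from multiplanar-reconstruction point picking.
#' The ON head is a distinguished point; it must coincide with, or lie
#' within a snap tolerance of, the first path point. An optional lens
#' center may be carried for provenance.
#'
#' @slot points numeric matrix, n x 3, path points (x, y, z) in mm,
#'   anterior to posterior.
#' @slot onHead numeric(3), ON head location in mm.
#' @slot lensCenter numeric, either length 0 (absent) or length 3 (mm).
#'
#' @seealso [Centerline()], [readCenterline()], [computeDeviation()].
#' @exportClass Centerline
setClass("Centerline",
  representation(points = "matrix", onHead = "numeric",
                 lensCenter = "numeric"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L)
      return("points must be a numeric n x 3 matrix")
    if (nrow(p) < 3L)
      return("a centerline needs at least 3 points")
    if (anyNA(p) || any(!is.finite(p)))
      return("centerline points must be finite")
    d <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                       p[-nrow(p), , drop = FALSE])^2))
    if (any(d == 0))
      return("consecutive centerline points must be distinct")
    if (length(object@onHead) != 3L || any(!is.finite(object@onHead)))
      return("onHead must be a finite length-3 point")
    if (!(length(object@lensCenter) %in% c(0L, 3L)))
      return("lensCenter must be absent or a length-3 point")
    TRUE
  })

#' 3D image volume with voxel spacing
#'
#' A scalar intensity grid with per-axis voxel spacing in mm and an
#' intensity encoding ceiling (12-bit convention, 0-4095, by default).
#' Axis convention: dimensions 1 and 2 are in-plane (x, y), dimension 3 is
#' the slice (axial) axis; voxel centers sit at 0-based index times spacing.
#'
#' @slot data numeric 3D array of intensities in \code{[0, intensityMax]}.
#' @slot spacing numeric(3), voxel spacing (x, y, slice) in mm.
#' @slot intensityMax numeric(1), encoding ceiling (default 4095).
#'
#' @seealso [ImageVolume()], [readImageVolume()], [measureVolume()].
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric",
                 intensityMax = "numeric"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three strictly positive values (mm)")
    if (length(object@intensityMax) != 1L || object@intensityMax <= 0)
      return("intensityMax must be a single positive number")
    rng <- range(object@data, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > object@intensityMax)
      return(sprintf("intensities outside [0, %g]", object@intensityMax))
    TRUE
  })

#' Per-scan adaptive threshold context
#'
#' Holds the per-scan mean background intensities, their cohort mean, and
#' the common threshold value C used by the adaptive rule
#' T = C + (cohort mean - scan background) (literal convention) or
#' T = C + (scan background - cohort mean) (brightness-tracking convention).
#'
#' @slot backgrounds named numeric, mean background intensity per scan.
#' @slot cohortMean numeric(1), mean of \code{backgrounds}.
#' @slot commonValue numeric(1), common value C (> 0).
#' @slot signConvention character(1), "literal" or "brightness_tracking".
#'
#' @seealso [ThresholdContext()], [computeThreshold()].
#' @exportClass ThresholdContext
setClass("ThresholdContext",
  representation(backgrounds = "numeric", cohortMean = "numeric",
                 commonValue = "numeric", signConvention = "character"),
  validity = function(object) {
    if (is.null(names(object@backgrounds)) ||
        any(!nzchar(names(object@backgrounds))))
      return("backgrounds must be a named vector (one entry per scan)")
    if (any(object@backgrounds < 0))
      return("backgrounds must be non-negative")
    if (length(object@commonValue) != 1L || object@commonValue <= 0)
      return("commonValue C must be a single positive number")
    if (!object@signConvention %in% c("literal", "brightness_tracking"))
      return("signConvention must be 'literal' or 'brightness_tracking'")
    TRUE
  })

#' Result of an ON deviation computation
#'
#' @slot deviationMm numeric(1), maximum orthogonal distance (mm) of the
#'   fitted centerline from the chord.
#' @slot argPositionMm numeric(1), arc length (mm) from the ON head at
#'   which the maximum occurs.
#' @slot chordEndpoints numeric matrix 2 x 3, the chord endpoints (ON head
#'   and the 20 mm point) in mm.
#' @slot truncatedLengthMm numeric(1), trajectory length actually used.
#' @slot parameters list, resolved parameters for provenance.
#'
#' @seealso [computeDeviation()].
#' @exportClass DeviationResult
setClass("DeviationResult",
  representation(deviationMm = "numeric", argPositionMm = "numeric",
                 chordEndpoints = "matrix", truncatedLengthMm = "numeric",
                 parameters = "list"),
  validity = function(object) {
    if (object@deviationMm < 0) return("deviationMm must be >= 0")
    if (!all(dim(object@chordEndpoints) == c(2L, 3L)))
      return("chordEndpoints must be a 2 x 3 matrix")
    TRUE
  })

#' Paired ON/ONS cross-section measurement at a posterior offset
#'
#' Holds the optic nerve and sheath contours at a given posterior distance
#' from the ON head, with their cross-sectional areas (mm^2) and circular
#' equivalent diameters (mm). The ON contour lies strictly inside the ONS
#' contour and has the smaller area.
#'
#' @slot onContour,onsContour [Contour-class] objects.
#' @slot onAreaMm2,onsAreaMm2 numeric(1), areas in mm^2.
#' @slot onDiameterMm,onsDiameterMm numeric(1), equivalent diameters
#'   2*sqrt(A/pi) in mm.
#' @slot offsetMm numeric(1), posterior distance from the ON head in mm.
#'
#' @seealso [measureVolume()], [interpolateContourAtOffset()].
#' @exportClass SliceMeasurement
setClass("SliceMeasurement",
  representation(onContour = "Contour", onsContour = "Contour",
                 onAreaMm2 = "numeric", onsAreaMm2 = "numeric",
                 onDiameterMm = "numeric", onsDiameterMm = "numeric",
                 offsetMm = "numeric"),
  validity = function(object) {
    if (object@onAreaMm2 <= 0 || object@onsAreaMm2 <= 0)
      return("areas must be positive")
    if (object@onAreaMm2 >= object@onsAreaMm2)
      return("ON area must be smaller than ONS area")
    TRUE
  })

#' Digital phantom specification
#'
#' Geometry, voxel grid, tissue intensities and noise model for the
#' synthetic optic-sheath phantom: a pair of concentric tubes whose outer
#' (sheath) diameter tapers linearly from \code{onsWideMm} to
#' \code{onsNarrowMm} over \code{axialLengthMm}, with a concentric nerve of
#' diameter \code{onDiameterMm}. Defaults reproduce the reference phantom
#' geometry (7 to 5 mm taper, 3.35 mm nerve, 20 mm length) at coronal
#' T2 acquisition resolution (253 um in-plane, 600 um slice spacing).
#'
#' @slot onsWideMm,onsNarrowMm,onDiameterMm numeric(1), diameters in mm.
#' @slot axialLengthMm numeric(1), tube length in mm.
#' @slot spacing numeric(3), voxel spacing (x, y, slice) in mm.
#' @slot intensities named numeric(3): background (orbital fat), on
#'   (nerve), csf (subarachnoid fluid) region means.
#' @slot snr numeric(1), CSF mean over Rician noise sigma; \code{Inf}
#'   disables noise.
#' @slot seed integer(1), RNG seed for the noise draw.
#' @slot marginMm numeric(1), in-plane margin around the widest tube.
#'
#' @seealso [PhantomSpec()], [idealizedPhantom()], [subjectLikePhantom()].
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(onsWideMm = "numeric", onsNarrowMm = "numeric",
                 onDiameterMm = "numeric", axialLengthMm = "numeric",
                 spacing = "numeric", intensities = "numeric",
                 snr = "numeric", seed = "integer", marginMm = "numeric"),
  prototype(onsWideMm = 7, onsNarrowMm = 5, onDiameterMm = 3.35,
            axialLengthMm = 20, spacing = c(0.253, 0.253, 0.600),
            intensities = c(background = 700, on = 500, csf = 3000),
            snr = Inf, seed = 1L, marginMm = 2.5),
  validity = function(object) {
    if (!(object@onDiameterMm < object@onsNarrowMm &&
          object@onsNarrowMm <= object@onsWideMm))
      return("need onDiameterMm < onsNarrowMm <= onsWideMm")
    if (object@axialLengthMm <= 0) return("axialLengthMm must be positive")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be three positive values (mm)")
    need <- c("background", "on", "csf")
    if (!all(need %in% names(object@intensities)))
      return("intensities needs named entries background, on, csf")
    if (any(object@intensities < 0))
      return("intensities must be non-negative")
    if (object@snr <= 0) return("snr must be positive")
    if (object@marginMm <= 0) return("marginMm must be positive")
    TRUE
  })

#' Repeated-measures ratings table
#'
#' Complete matrix of measurements, rows = cases (e.g. MRI data sets or
#' phantom geometries), columns = repeats / raters / scans. Missing cells
#' are disallowed: the reliability design is complete.
#'
#' @slot values numeric matrix, cases x repeats, no NA.
#' @slot parameter character(1), label of the measured parameter.
#' @slot units character(1), measurement units.
#'
#' @seealso [RatingsTable()], [icc()], [cvRepeats()],
#'   [consensusDifferences()].
#' @exportClass RatingsTable
setClass("RatingsTable",
  representation(values = "matrix", parameter = "character",
                 units = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (nrow(v) < 2L || ncol(v) < 2L)
      return("need at least 2 cases and 2 repeats")
    if (anyNA(v)) return("missing cells are not allowed (complete design)")
    TRUE
  })

#' Reliability report for a ratings table
#'
#' @slot icc numeric(1), intraclass correlation coefficient.
#' @slot iccForm character(1), estimator form label.
#' @slot cv numeric(1), coefficient of variation (fraction, not percent).
#' @slot meanAbsDiff,sdAbsDiff numeric(1), mean and SD of case-wise
#'   absolute differences from the consensus value, in parameter units.
#' @slot percentDiff,percentSd numeric(1), the same as percentages of the
#'   consensus.
#' @slot parameter,units character(1), labels carried from the table.
#'
#' @seealso [reliabilityReport()].
#' @exportClass ReliabilityReport
setClass("ReliabilityReport",
  representation(icc = "numeric", iccForm = "character", cv = "numeric",
                 meanAbsDiff = "numeric", sdAbsDiff = "numeric",
                 percentDiff = "numeric", percentSd = "numeric",
                 parameter = "character", units = "character"),
  validity = function(object) {
    if (object@cv < 0) return("cv must be >= 0")
    TRUE
  })
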