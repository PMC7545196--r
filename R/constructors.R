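#' Construct a Contour
#'
#' Validates and normalizes a closed planar contour. Vertices are given in
#' order; the closing edge back to the first vertex is implicit (a repeated
#' final vertex is dropped). Orientation is normalized to counter-clockwise.
#' By default the polygon is checked for self-intersection with an O(n^2)
#' segment-pair test; internal callers that construct contours guaranteed
#' simple (e.g. marching-squares output) may pass \code{check = FALSE}.
#'
#' @param points numeric n x 2 matrix (or coercible) of (x, y) vertices, mm.
#' @param slicePosition axial slice position in mm (default 0).
#' @param check logical; run the self-intersection test (default TRUE).
#' @return A [Contour-class] object with counter-clockwise orientation.
#' @examples
#' sq <- Contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' polygonArea(sq)
#' @export
Contour <- function(points, slicePosition = 0, check = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("contour points must have two columns (x, y)")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  n <- nrow(points)
  if (n >= 2L && all(points[1L, ] == points[n, ]))
    points <- points[-n, , drop = FALSE]
  if (nrow(unique(points)) < 3L)
    stop("degenerate contour: fewer than 3 distinct vertices")
  a <- .shoelace(points)
  if (abs(a) < .Machine$double.eps * 100 * max(1, max(abs(points))))
    stop("degenerate contour: zero enclosed area (collinear vertices?)")
  if (a < 0)  # normalize to counter-clockwise
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (check && .selfIntersects(points))
    stop("contour is self-intersecting")
  new("Contour", points = points, slicePosition = as.numeric(slicePosition))
}

#' Construct a Centerline
#'
#' @param points n x 3 matrix of path points in mm, anterior to posterior.
#' @param onHead ON head location (mm); defaults to the first path point.
#'   Must lie within \code{snapTolMm} of the first path point.
#' @param lensCenter optional lens center (mm), provenance only.
#' @param snapTolMm tolerance (mm) for the ON head / first-point agreement.
#' @return A [Centerline-class] object.
#' @examples
#' cl <- Centerline(cbind(x = 0:5, y = 0, z = 0))
#' onHead(cl)
#' @export
Centerline <- function(points, onHead = NULL, lensCenter = NULL,
                       snapTolMm = 1) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (is.null(onHead)) onHead <- points[1L, ]
  onHead <- as.numeric(onHead)
  if (length(onHead) == 3L && nrow(points) >= 1L) {
    d <- sqrt(sum((onHead - points[1L, ])^2))
    if (is.finite(d) && d > snapTolMm)
      stop(sprintf(
        "ON head is %.3f mm from the first path point (snap tolerance %g mm)",
        d, snapTolMm))
  }
  new("Centerline", points = points, onHead = onHead,
      lensCenter = if (is.null(lensCenter)) numeric(0)
                   else as.numeric(lensCenter))
}

#' Construct an ImageVolume
#'
#' @param data numeric 3D array of intensities.
#' @param spacing voxel spacing (x, y, slice) in mm; coronal T2 defaults
#'   \code{c(0.253, 0.253, 0.600)}.
#' @param intensityMax encoding ceiling (default 4095, 12-bit).
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(data, spacing = c(0.253, 0.253, 0.600),
                        intensityMax = 4095) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      intensityMax = as.numeric(intensityMax))
}

#' Construct a ThresholdContext
#'
#' @param backgrounds named numeric vector of per-scan mean background
#'   intensities (names are scan ids).
#' @param commonValue the common value C added to the cohort offset; the
#'   default 1850 is the midpoint of the phantom background (700) and CSF
#'   (3000) intensities. For real data supply a cohort-appropriate C.
#' @param signConvention "literal" (T = C + cohortMean - scanBackground) or
#'   "brightness_tracking" (T = C + scanBackground - cohortMean).
#' @return A [ThresholdContext-class] object.
#' @examples
#' ctx <- ThresholdContext(c(scanA = 650, scanB = 750), commonValue = 1000)
#' computeThreshold(ctx, "scanA")
#' @export
ThresholdContext <- function(backgrounds, commonValue = 1850,
                             signConvention = c("literal",
                                                "brightness_tracking")) {
  signConvention <- match.arg(signConvention)
  backgrounds <- unlist(backgrounds)
  new("ThresholdContext", backgrounds = backgrounds,
      cohortMean = mean(backgrounds), commonValue = as.numeric(commonValue),
      signConvention = signConvention)
}

#' Construct a PhantomSpec
#'
#' All arguments default to the reference phantom: sheath diameter 7 mm
#' tapering to 5 mm over a 20 mm axial length, concentric nerve of 3.35 mm
#' diameter, voxels 0.253 x 0.253 x 0.600 mm.
#'
#' @param onsWideMm,onsNarrowMm sheath outer diameter at the wide (ON head)
#'   and narrow ends, mm.
#' @param onDiameterMm nerve diameter, mm.
#' @param axialLengthMm tube length, mm.
#' @param spacing voxel spacing (x, y, slice), mm.
#' @param intensities named region means: background (orbital fat), on
#'   (nerve), csf (fluid); defaults mimic T2 contrast (CSF >> fat > nerve).
#' @param snr CSF mean / Rician noise sigma; \code{Inf} for noise-free.
#' @param seed RNG seed used for the noise draw.
#' @param marginMm in-plane background margin around the widest tube, mm.
#' @return A [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(onsWideMm = 7, onsNarrowMm = 5, onDiameterMm = 3.35,
                        axialLengthMm = 20,
                        spacing = c(0.253, 0.253, 0.600),
                        intensities = c(background = 700, on = 500,
                                        csf = 3000),
                        snr = Inf, seed = 1L, marginMm = 2.5) {
  new("PhantomSpec", onsWideMm = onsWideMm, onsNarrowMm = onsNarrowMm,
      onDiameterMm = onDiameterMm, axialLengthMm = axialLengthMm,
      spacing = as.numeric(spacing), intensities = intensities,
      snr = snr, seed = as.integer(seed), marginMm = marginMm)
}

#' Construct a RatingsTable
#'
#' @param values numeric matrix, rows = cases, columns = repeats/raters;
#'   complete (no NA), at least 2 x 2.
#' @param parameter label of the measured parameter.
#' @param units measurement units.
#' @return A [RatingsTable-class] object.
#' @export
RatingsTable <- function(values, parameter = "parameter", units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RatingsTable", values = values, parameter = parameter, units = units)
}
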