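# Semi-automated ON/ONS cross-section extraction from coronal T2-like
# volumes: histogram-mode background estimation, cohort-normalized
# adaptive threshold, cubic in-plane upsampling, iso-contouring, roundness
# filtering, inter-slice interpolation at a posterior offset, and
# area/equivalent-diameter computation.

#' Estimate background intensity of a slice
#'
#' Histograms the slice at unit intensity bin width, locates the peak of
#' the (smoothed) histogram -- the mode of the orbital-fat background --
#' and returns the mean intensity over pixels within \code{modeWindow} of
#' that mode. The mask excludes bright CSF and dark nerve tissue so the
#' estimate tracks the fatty background only. The unit-bin counts are
#' smoothed with a moving average of width \code{smoothBins} before
#' peak-picking, since the raw per-bin counts of a noisy slice are too
#' sparse to define a stable peak.
#'
#' @param slice 2D numeric matrix of intensities.
#' @param modeWindow half-width of the intensity window around the modal
#'   bin; default 10\% of \code{intensityMax}.
#' @param intensityMax encoding ceiling (default 4095).
#' @param smoothBins moving-average width (intensity units) for the
#'   histogram peak search; default 1\% of \code{intensityMax}.
#' @return mean background intensity (scalar).
#' @export
estimateBackground <- function(slice, modeWindow = 0.1 * intensityMax,
                               intensityMax = 4095,
                               smoothBins = round(0.01 * intensityMax)) {
  v <- as.numeric(slice)
  v <- v[is.finite(v)]
  if (!length(v)) stop("cannot estimate background of an empty slice")
  bins <- floor(v)  # unit-width histogram bins
  counts <- tabulate(bins - min(bins) + 1L,
                     nbins = max(bins) - min(bins) + 1L)
  w <- max(1L, as.integer(smoothBins))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && length(counts) > w) {
    sm <- stats::filter(counts, rep(1 / w, w), sides = 2L)
    sm[is.na(sm)] <- 0
    counts <- as.numeric(sm)
  }
  mode <- min(bins) + which.max(counts) - 1L
  sel <- abs(v - mode) <= modeWindow
  mean(v[sel])
}

#' Adaptive threshold for one scan
#'
#' T = C + (cohort mean background - scan background) under the literal
#' convention, or T = C + (scan background - cohort mean) under the
#' brightness-tracking convention (which moves the threshold up for
#' brighter scans). The convention in force is recorded in the returned
#' value's \code{"convention"} attribute for provenance.
#'
#' @param ctx a [ThresholdContext-class].
#' @param scanId name of the scan within \code{ctx}.
#' @return threshold intensity (scalar with a \code{convention} attribute).
#' @export
computeThreshold <- function(ctx, scanId) {
  stopifnot(is(ctx, "ThresholdContext"))
  if (!scanId %in% names(ctx@backgrounds))
    stop("unknown scan id: ", scanId)
  bs <- ctx@backgrounds[[scanId]]
  off <- switch(ctx@signConvention,
                literal = ctx@cohortMean - bs,
                brightness_tracking = bs - ctx@cohortMean)
  structure(ctx@commonValue + off, convention = ctx@signConvention)
}

# Catmull-Rom (Keys a = -0.5) interpolation weight matrix mapping n input
# samples to (n-1)*factor + 1 output samples. Boundary taps use linearly
# extrapolated virtual samples (v0 = 2 v1 - v2 and mirrored at the right
# edge) so linear intensity ramps are reproduced exactly up to the border.
.cubicWeights <- function(n, factor) {
  nOut <- (n - 1L) * factor + 1L
  u <- (seq_len(nOut) - 1L) / factor        # output position, 0-based
  i0 <- pmin(floor(u), n - 2L)              # left base index
  f <- u - i0
  # Catmull-Rom basis on taps (i0-1, i0, i0+1, i0+2)
  w <- cbind(0.5 * (-f + 2 * f^2 - f^3),
             0.5 * (2 - 5 * f^2 + 3 * f^3),
             0.5 * (f + 4 * f^2 - 3 * f^3),
             0.5 * (-f^2 + f^3))
  Wp <- matrix(0, nrow = nOut, ncol = n + 2L)  # columns = virtual -1 .. n
  rows <- seq_len(nOut)
  for (t in 0:3) {
    col <- i0 + t + 1L  # 0-based tap i0 + t - 1 shifted into 1 .. n + 2
    Wp[cbind(rows, col)] <- Wp[cbind(rows, col)] + w[, t + 1L]
  }
  W <- Wp[, 2:(n + 1L), drop = FALSE]
  W[, 1L] <- W[, 1L] + 2 * Wp[, 1L]            # v_-1 = 2 v_0 - v_1
  W[, 2L] <- W[, 2L] - Wp[, 1L]
  W[, n] <- W[, n] + 2 * Wp[, n + 2L]          # v_n = 2 v_{n-1} - v_{n-2}
  W[, n - 1L] <- W[, n - 1L] - Wp[, n + 2L]
  W
}

#' Cubically upsample a slice in-plane
#'
#' Separable Catmull-Rom cubic convolution onto a grid \code{factor} times
#' denser in each in-plane axis. The mm coordinates of the original pixel
#' centers are preserved: output sample j (0-based) sits at j / factor
#' original pixel units, so original pixel values are reproduced exactly,
#' and linear intensity ramps are reproduced exactly everywhere.
#'
#' @param slice 2D numeric matrix.
#' @param factor integer upsampling factor >= 1; 1 is the identity.
#' @return upsampled matrix of size \code{(nrow-1)*factor+1} by
#'   \code{(ncol-1)*factor+1}.
#' @export
upsampleSlice <- function(slice, factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a single integer >= 1")
  factor <- as.integer(factor)
  m <- as.matrix(slice)
  if (factor == 1L) return(m)
  Wr <- .cubicWeights(nrow(m), factor)
  Wc <- .cubicWeights(ncol(m), factor)
  Wr %*% m %*% t(Wc)
}

#' Extract closed iso-contours from a slice
#'
#' Marching-squares style iso-contouring (via \code{grDevices::contourLines},
#' linear interpolation along pixel edges) at threshold level \code{level}.
#' Coordinates are physical mm under the voxel-center convention: pixel
#' (i, j) (0-based) sits at (i * dx, j * dy). Open contours that terminate
#' on the image border are discarded.
#'
#' @param slice 2D numeric matrix (rows = x, columns = y).
#' @param level iso-level (threshold intensity).
#' @param pixelSizeMm in-plane pixel size (x, y) of \emph{this} grid in mm
#'   (after any upsampling), scalar or length-2.
#' @param slicePosition axial position attached to the contours, mm.
#' @return list of [Contour-class] objects (possibly empty).
#' @export
extractContours <- function(slice, level, pixelSizeMm = c(0.253, 0.253),
                            slicePosition = 0) {
  m <- as.matrix(slice)
  if (length(pixelSizeMm) == 1L) pixelSizeMm <- rep(pixelSizeMm, 2L)
  xs <- (seq_len(nrow(m)) - 1L) * pixelSizeMm[1L]
  ys <- (seq_len(ncol(m)) - 1L) * pixelSizeMm[2L]
  # a featureless slice legitimately yields no contours; silence the
  # "all z values are equal" warning
  cl <- suppressWarnings(
    grDevices::contourLines(x = xs, y = ys, z = m, levels = level))
  segs <- lapply(cl, function(cc) cbind(cc$x, cc$y))
  out <- list()
  for (pts in .stitchContourSegments(segs)) {
    pts <- pts[-nrow(pts), , drop = FALSE]  # drop repeated closing vertex
    if (nrow(pts) < 3L || nrow(unique(pts)) < 3L) next
    # marching-squares loops are simple by construction
    out[[length(out) + 1L]] <-
      Contour(pts, slicePosition = slicePosition, check = FALSE)
  }
  out
}

# contourLines splits a closed iso-curve into open pieces wherever the
# level passes exactly through a grid node; chain segments whose endpoints
# coincide back into loops. Chains that never close (they terminate on the
# image border) are dropped.
.stitchContourSegments <- function(segs) {
  loops <- list()
  used <- rep(FALSE, length(segs))
  key <- function(p) paste(format(p[1L], digits = 15L),
                           format(p[2L], digits = 15L))
  for (i in seq_along(segs)) {
    if (used[i]) next
    used[i] <- TRUE
    chain <- segs[[i]]
    repeat {
      n <- nrow(chain)
      if (all(chain[1L, ] == chain[n, ])) {  # closed
        loops[[length(loops) + 1L]] <- chain
        break
      }
      endK <- key(chain[n, ])
      nxt <- 0L
      flip <- FALSE
      for (j in seq_along(segs)) {
        if (used[j]) next
        if (key(segs[[j]][1L, ]) == endK) { nxt <- j; flip <- FALSE; break }
        if (key(segs[[j]][nrow(segs[[j]]), ]) == endK) {
          nxt <- j; flip <- TRUE; break
        }
      }
      if (nxt == 0L) break  # open chain: terminates on the border
      used[nxt] <- TRUE
      add <- segs[[nxt]]
      if (flip) add <- add[rev(seq_len(nrow(add))), , drop = FALSE]
      chain <- rbind(chain, add[-1L, , drop = FALSE])
    }
  }
  loops
}

#' Select the ON/ONS contour pair
#'
#' Applies the point-count filter (vertex count >= \code{minPoints} at the
#' contouring resolution) and the roundness filter (isoperimetric quotient
#' >= \code{qMin}), then searches the survivors for a nested pair: an
#' outer contour containing the inner one, with centroids closer than half
#' the inner equivalent radius. Among candidate pairs the one with the
#' roundest inner member wins. In T2 contrast the CSF between nerve and
#' sheath is bright, so the inner contour is the ON boundary and the outer
#' the ONS boundary.
#'
#' @param contours list of [Contour-class] candidates for one slice.
#' @param minPoints minimum vertex count (default 20).
#' @param qMin minimum isoperimetric quotient (default 0.6).
#' @return list with elements \code{on} and \code{ons} ([Contour-class]).
#' @export
selectOnOnsContours <- function(contours, minPoints = 20, qMin = 0.6) {
  keep <- Filter(function(cc)
    nrow(contourPoints(cc)) >= minPoints &&
      isoperimetricQuotient(cc) >= qMin, contours)
  k <- length(keep)
  if (k >= 2L) {
    areas <- vapply(keep, polygonArea, numeric(1))
    cents <- t(vapply(keep, function(cc) .centroid(contourPoints(cc)),
                      numeric(2)))
    qs <- vapply(keep, isoperimetricQuotient, numeric(1))
    best <- NULL
    bestQ <- -Inf
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j || areas[i] >= areas[j]) next  # i inner, j outer
      rin <- sqrt(areas[i] / pi)
      if (sqrt(sum((cents[i, ] - cents[j, ])^2)) > rin / 2) next
      if (!.pointInPolygon(cents[i, ], contourPoints(keep[[j]]))) next
      if (qs[i] > bestQ) {
        bestQ <- qs[i]
        best <- list(on = keep[[i]], ons = keep[[j]])
      }
    }
    if (!is.null(best)) return(best)
  }
  stop(sprintf("ON/ONS not found: no nested contour pair among %d filter survivor(s)",
               k))
}

# resample a star-shaped contour to radii at nAngles uniform angles about
# its centroid; returns list(center, radii, angles)
.radialResample <- function(contour, nAngles = 128L) {
  p <- contourPoints(contour)
  ctr <- .centroid(p)
  th <- atan2(p[, 2L] - ctr[2L], p[, 1L] - ctr[1L])
  r <- sqrt((p[, 1L] - ctr[1L])^2 + (p[, 2L] - ctr[2L])^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # wrap for periodic interpolation
  th2 <- c(th[length(th)] - 2 * pi, th, th[1L] + 2 * pi)
  r2 <- c(r[length(r)], r, r[1L])
  ang <- seq(-pi, pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
  ri <- stats::approx(th2, r2, xout = ang, ties = "ordered")$y
  list(center = ctr, radii = ri, angles = ang)
}

.contourFromRadial <- function(center, radii, angles, slicePosition) {
  Contour(cbind(center[1L] + radii * cos(angles),
                center[2L] + radii * sin(angles)),
          slicePosition = slicePosition, check = FALSE)
}

.makeMeasurement <- function(on, ons, offsetMm) {
  onA <- polygonArea(on); onsA <- polygonArea(ons)
  new("SliceMeasurement", onContour = on, onsContour = ons,
      onAreaMm2 = onA, onsAreaMm2 = onsA,
      onDiameterMm = equivalentDiameter(onA),
      onsDiameterMm = equivalentDiameter(onsA),
      offsetMm = offsetMm)
}

#' Interpolate ON/ONS contours at a posterior offset
#'
#' Computes the measurement plane at \code{offsetMm} posterior to the ON
#' head along the slice axis. If the target falls on a measured slice that
#' slice's contours are returned unchanged; otherwise the two bracketing
#' slices' contours are each resampled to \code{nAngles} radii about their
#' centroids and centroid plus per-angle radii are blended linearly by
#' axial weight (\code{mode = "shape"}). \code{mode = "area"} blends the
#' scalar areas only (cross-check mode); the reported contour is then the
#' shape-blend but areas come from the linear area blend.
#'
#' @param perSlice list of per-slice records, each a list with elements
#'   \code{slicePosition} (mm), \code{on} and \code{ons} ([Contour-class]).
#' @param onHead length-3 ON head location, mm.
#' @param offsetMm posterior offset from the ON head, mm (default 3).
#' @param nAngles angular resampling resolution (default 128).
#' @param mode "shape" (default) or "area".
#' @return A [SliceMeasurement-class].
#' @export
interpolateContourAtOffset <- function(perSlice, onHead, offsetMm = 3,
                                       nAngles = 128L,
                                       mode = c("shape", "area")) {
  mode <- match.arg(mode)
  if (!length(perSlice)) stop("no measured slices supplied")
  z <- vapply(perSlice, function(s) s$slicePosition, numeric(1))
  o <- order(z)
  z <- z[o]; perSlice <- perSlice[o]
  target <- onHead[3L] + offsetMm
  tol <- 1e-9 * max(1, abs(target))
  hit <- which(abs(z - target) <= tol)
  if (length(hit)) {
    s <- perSlice[[hit[1L]]]
    return(.makeMeasurement(s$on, s$ons, offsetMm))
  }
  if (target < z[1L] || target > z[length(z)])
    stop(sprintf(
      "target position %.3f mm is outside the measured range [%.3f, %.3f] mm",
      target, z[1L], z[length(z)]))
  kU <- which(z > target)[1L]
  kL <- kU - 1L
  w <- (target - z[kL]) / (z[kU] - z[kL])
  lo <- perSlice[[kL]]; up <- perSlice[[kU]]
  blend <- function(cLo, cUp) {
    rl <- .radialResample(cLo, nAngles)
    ru <- .radialResample(cUp, nAngles)
    .contourFromRadial((1 - w) * rl$center + w * ru$center,
                       (1 - w) * rl$radii + w * ru$radii,
                       rl$angles, target)
  }
  on <- blend(lo$on, up$on)
  ons <- blend(lo$ons, up$ons)
  m <- .makeMeasurement(on, ons, offsetMm)
  if (mode == "area") {
    onA <- (1 - w) * polygonArea(lo$on) + w * polygonArea(up$on)
    onsA <- (1 - w) * polygonArea(lo$ons) + w * polygonArea(up$ons)
    m@onAreaMm2 <- onA; m@onsAreaMm2 <- onsA
    m@onDiameterMm <- equivalentDiameter(onA)
    m@onsDiameterMm <- equivalentDiameter(onsA)
  }
  m
}

#' Measure ON/ONS geometry in a volume
#'
#' End-to-end semi-automated pipeline: per-slice background estimation,
#' adaptive threshold for the scan, cubic in-plane upsampling,
#' iso-contouring, ON/ONS pair selection, and inter-slice interpolation at
#' \code{offsetMm} posterior to the user-supplied ON head. Slices where
#' selection fails are dropped with a message; the remaining slices must
#' still bracket the target plane. Deterministic given inputs and
#' parameters.
#'
#' @param volume an [ImageVolume-class].
#' @param onHead ON head location (x, y, z) in mm; must lie inside the
#'   volume.
#' @param ctx optional [ThresholdContext-class] shared across a cohort of
#'   scans; if NULL a single-scan context is built from this volume (so
#'   T = \code{commonValue}).
#' @param scanId scan name within \code{ctx} (default "scan").
#' @param commonValue common threshold value C used when \code{ctx} is
#'   NULL.
#' @param upsampleFactor in-plane cubic upsampling factor (default 4,
#'   about 63 um effective pixel at the T2 default spacing).
#' @param minPoints,qMin contour selection filters, see
#'   [selectOnOnsContours()]; \code{minPoints} applies at the upsampled
#'   resolution.
#' @param offsetMm posterior measurement offset, mm (default 3).
#' @param nAngles angular resampling resolution for interpolation.
#' @param interpMode "shape" or "area", see [interpolateContourAtOffset()].
#' @param zRangeMm optional length-2 axial window (mm) restricting which
#'   slices are processed; default the whole volume.
#' @param verbose emit per-slice selection failures as messages.
#' @return list with elements \code{measurement}
#'   ([SliceMeasurement-class]), \code{sliceTable} (data.frame with
#'   slice_position_mm, on_area_mm2, ons_area_mm2, on_q, ons_q),
#'   \code{contours} (per-slice contour list for 3D rendering),
#'   \code{threshold}, \code{background}, and \code{parameters}.
#' @export
measureVolume <- function(volume, onHead, ctx = NULL, scanId = "scan",
                          commonValue = 1850, upsampleFactor = 4L,
                          minPoints = 20, qMin = 0.6, offsetMm = 3,
                          nAngles = 128L,
                          interpMode = c("shape", "area"),
                          zRangeMm = NULL, verbose = FALSE) {
  stopifnot(is(volume, "ImageVolume"))
  interpMode <- match.arg(interpMode)
  onHead <- as.numeric(onHead)
  dims <- dim(volumeData(volume))
  sp <- voxelSpacing(volume)
  extent <- (dims - 1L) * sp
  if (length(onHead) != 3L || any(onHead < 0) || any(onHead > extent))
    stop(sprintf(
      "ON head (%.2f, %.2f, %.2f) mm lies outside the volume extent (%.2f, %.2f, %.2f) mm",
      onHead[1L], onHead[2L], onHead[3L], extent[1L], extent[2L],
      extent[3L]))
  dat <- volumeData(volume)
  zAll <- slicePositions(volume)
  sel <- seq_along(zAll)
  if (!is.null(zRangeMm))
    sel <- sel[zAll >= zRangeMm[1L] & zAll <= zRangeMm[2L]]
  if (length(sel) < 2L) stop("fewer than 2 slices selected for processing")

  # per-scan background: mean of slice-by-slice histogram-mode estimates
  bgs <- vapply(sel, function(k)
    estimateBackground(dat[, , k], intensityMax = intensityMax(volume)),
    numeric(1))
  bg <- mean(bgs)
  if (is.null(ctx)) {
    ctx <- ThresholdContext(stats::setNames(bg, scanId),
                            commonValue = commonValue)
  } else if (!scanId %in% names(ctx@backgrounds)) {
    stop("scanId '", scanId, "' not present in the threshold context")
  }
  thr <- computeThreshold(ctx, scanId)
  pxUp <- sp[1:2] / upsampleFactor

  perSlice <- list()
  tab <- data.frame(slice_position_mm = numeric(0), on_area_mm2 = numeric(0),
                    ons_area_mm2 = numeric(0), on_q = numeric(0),
                    ons_q = numeric(0))
  for (k in sel) {
    up <- upsampleSlice(dat[, , k], upsampleFactor)
    cts <- extractContours(up, as.numeric(thr), pixelSizeMm = pxUp,
                           slicePosition = zAll[k])
    pair <- tryCatch(selectOnOnsContours(cts, minPoints = minPoints,
                                         qMin = qMin),
                     error = function(e) {
                       if (verbose)
                         message(sprintf("slice z = %.2f mm skipped: %s",
                                         zAll[k], conditionMessage(e)))
                       NULL
                     })
    if (is.null(pair)) next
    perSlice[[length(perSlice) + 1L]] <-
      list(slicePosition = zAll[k], on = pair$on, ons = pair$ons)
    tab <- rbind(tab, data.frame(
      slice_position_mm = zAll[k],
      on_area_mm2 = polygonArea(pair$on),
      ons_area_mm2 = polygonArea(pair$ons),
      on_q = isoperimetricQuotient(pair$on),
      ons_q = isoperimetricQuotient(pair$ons)))
  }
  if (!length(perSlice))
    stop("no slice passed ON/ONS contour selection")
  meas <- interpolateContourAtOffset(perSlice, onHead, offsetMm = offsetMm,
                                     nAngles = nAngles, mode = interpMode)
  list(measurement = meas, sliceTable = tab, contours = perSlice,
       threshold = as.numeric(thr), background = bg,
       parameters = list(scan_id = scanId,
                         common_value = ctx@commonValue,
                         sign_convention = ctx@signConvention,
                         upsample_factor = upsampleFactor,
                         min_points = minPoints, q_min = qMin,
                         offset_mm = offsetMm, n_angles = nAngles,
                         interp_mode = interpMode))
}

#' Serialize a volume measurement to a JSON record
#'
#' @param result the list returned by [measureVolume()].
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
measurementToJSON <- function(result, path = NULL) {
  v <- measurementValues(result$measurement)
  rec <- list(measurement = as.list(v),
              threshold = result$threshold,
              background = result$background,
              parameters = result$parameters,
              n_slices_accepted = nrow(result$sliceTable),
              package_version =
                as.character(utils::packageVersion("onsmorph")))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
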