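# Optic nerve deviation: spline fit to operator-picked centerline points,
# truncation at 20 mm trajectory length, maximum orthogonal distance from
# the chord joining the ON head to the 20 mm point.

#' Read a centerline from a CSV of (X, Y, Z) coordinates
#'
#' Parses the comma-separated point lists exported by multiplanar
#' reconstruction tools: one row per picked point, columns X, Y, Z in mm,
#' optional header. By convention the first row is the ON head unless
#' \code{onHead} is supplied.
#'
#' @param path path to the CSV file.
#' @param onHead optional explicit ON head (length-3, mm); defaults to the
#'   first point.
#' @param lensCenter optional lens center (length-3, mm).
#' @param snapTolMm ON head snap tolerance passed to [Centerline()].
#' @return A [Centerline-class].
#' @export
readCenterline <- function(path, onHead = NULL, lensCenter = NULL,
                           snapTolMm = 1) {
  if (!file.exists(path)) stop("centerline file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty centerline file: ", path)
  start <- 1L
  first <- strsplit(lines[1L], ",")[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) start <- 2L  # header
  rows <- lines[seq.int(start, length(lines))]
  if (length(rows) < 3L)
    stop("centerline file has fewer than 3 coordinate rows: ", path)
  pts <- matrix(NA_real_, nrow = length(rows), ncol = 3L)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(strsplit(rows[i], ",")[[1L]]))
    if (length(v) != 3L || anyNA(v))
      stop(sprintf("malformed coordinate row at line %d of %s: '%s'",
                   i + start - 1L, path, rows[i]))
    pts[i, ] <- v
  }
  dup <- which(rowSums(abs(pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])) == 0)
  if (length(dup))
    stop(sprintf("duplicate consecutive point at line %d of %s",
                 dup[1L] + start, path))
  Centerline(pts, onHead = onHead, lensCenter = lensCenter,
             snapTolMm = snapTolMm)
}

#' Write a centerline to CSV
#'
#' @param centerline a [Centerline-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCenterline <- function(centerline, path) {
  p <- centerlinePoints(centerline)
  utils::write.csv(data.frame(X = p[, 1L], Y = p[, 2L], Z = p[, 3L]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit an upsampled interpolating spline to centerline points
#'
#' Interpolating cubic spline through the picked points, parameterized by
#' cumulative chord length and sampled at uniform parameter steps of at
#' most \code{sampleStepMm}, so the returned polyline passes through every
#' input point. With fewer than 4 points a piecewise-linear fallback is
#' used with a warning.
#'
#' @param centerline a [Centerline-class] or an n x 3 point matrix.
#' @param sampleStepMm sampling step along the curve parameter, mm
#'   (default 0.1, well below the in-plane acquisition resolution).
#' @return matrix of sampled 3D points (mm) along the fitted curve.
#' @export
fitSpline <- function(centerline, sampleStepMm = 0.1) {
  if (!is.numeric(sampleStepMm) || length(sampleStepMm) != 1L ||
      sampleStepMm <= 0)
    stop("sampleStepMm must be a single positive length")
  p <- if (is(centerline, "Centerline")) centerlinePoints(centerline)
       else as.matrix(centerline)
  if (nrow(p) < 2L) stop("need at least 2 points to fit a curve")
  if (nrow(p) < 4L) {
    warning("fewer than 4 points: falling back to piecewise-linear path")
    return(resamplePath(p, sampleStepMm))
  }
  t0 <- arcLength(p)
  total <- t0[length(t0)]
  tNew <- seq(0, total, length.out = max(2L, ceiling(total / sampleStepMm))
              + 1L)
  out <- vapply(1:3, function(k) {
    f <- stats::splinefun(t0, p[, k], method = "fmm")
    f(tNew)
  }, numeric(length(tNew)))
  matrix(out, ncol = 3L)
}

#' Truncate a path at a given arc length
#'
#' Returns the prefix of the path whose total chordal arc length equals
#' \code{lengthMm}; the final point is linearly interpolated within the
#' last segment.
#'
#' @param path n x 3 matrix of ordered points, mm.
#' @param lengthMm target trajectory length, mm (default 20).
#' @return truncated point matrix.
#' @export
truncateAtArcLength <- function(path, lengthMm = 20) {
  p <- as.matrix(path)
  s <- arcLength(p)
  total <- s[length(s)]
  if (total < lengthMm)
    stop(sprintf(
      "path is only %.3f mm long; cannot truncate at %.3f mm",
      total, lengthMm))
  if (total == lengthMm) return(p)
  k <- which(s >= lengthMm)[1L]  # first point at or past the target
  if (s[k] == lengthMm) return(p[seq_len(k), , drop = FALSE])
  f <- (lengthMm - s[k - 1L]) / (s[k] - s[k - 1L])
  endPoint <- p[k - 1L, ] + f * (p[k, ] - p[k - 1L, ])
  out <- rbind(p[seq_len(k - 1L), , drop = FALSE], endPoint)
  dimnames(out) <- NULL
  out
}

#' Compute optic nerve deviation
#'
#' Fits an interpolating spline to the centerline points, truncates it at
#' \code{lengthMm} (default 20 mm) of trajectory arc length measured from
#' the ON head, and reports the maximum orthogonal distance of the sampled
#' curve from the straight line connecting the ON head to the truncation
#' point. If the ON head is not the first path point it is prepended
#' before fitting. The result is invariant under rigid motion of the
#' input.
#'
#' @param centerline a [Centerline-class] reaching at least \code{lengthMm}
#'   of arc length from the ON head.
#' @param lengthMm trajectory length defining the chord, mm (default 20).
#' @param sampleStepMm spline sampling step, mm (default 0.1).
#' @return A [DeviationResult-class].
#' @examples
#' # gentle circular arc of radius 50 mm: deviation is the sagitta
#' s <- seq(0, 24, by = 1.5)
#' arc <- cbind(50 * sin(s / 50), 50 * (1 - cos(s / 50)), 0)
#' computeDeviation(Centerline(arc))  # ~ 50 * (1 - cos(10 / 50))
#' @export
computeDeviation <- function(centerline, lengthMm = 20, sampleStepMm = 0.1) {
  stopifnot(is(centerline, "Centerline"))
  p <- centerlinePoints(centerline)
  head3 <- onHead(centerline)
  if (sqrt(sum((head3 - p[1L, ])^2)) > 1e-12) {
    p <- rbind(head3, p)
    dimnames(p) <- NULL
  }
  curve <- fitSpline(p, sampleStepMm = sampleStepMm)
  curve <- truncateAtArcLength(curve, lengthMm)
  a <- curve[1L, ]
  b <- curve[nrow(curve), ]
  d <- .pointsToLineDistance(curve, a, b)
  i <- which.max(d)
  s <- arcLength(curve)
  chord <- rbind(a, b)
  dimnames(chord) <- NULL
  new("DeviationResult",
      deviationMm = unname(d[i]), argPositionMm = unname(s[i]),
      chordEndpoints = chord,
      truncatedLengthMm = s[length(s)],
      parameters = list(length_mm = lengthMm,
                        sample_step_mm = sampleStepMm))
}

#' Serialize a DeviationResult to a JSON record
#'
#' @param result a [DeviationResult-class].
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
deviationToJSON <- function(result, path = NULL) {
  rec <- list(
    deviation_mm = result@deviationMm,
    arg_position_mm = result@argPositionMm,
    chord_endpoints = list(head = as.numeric(result@chordEndpoints[1L, ]),
                           distal = as.numeric(result@chordEndpoints[2L, ])),
    truncated_length_mm = result@truncatedLengthMm,
    parameters = result@parameters,
    package_version = as.character(utils::packageVersion("onsmorph")))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
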