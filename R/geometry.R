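# Planar/spatial geometry primitives shared by the deviation and
# segmentation pipelines. All coordinates are physical millimetres.

# signed shoelace area; positive for counter-clockwise vertex order
.shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  0.5 * sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L])
}

# O(n^2) proper-intersection test between non-adjacent edges of a closed
# polygon; contours are small so quadratic cost is acceptable
.selfIntersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  j <- c(2:n, 1L)
  ax <- p[, 1L]; ay <- p[, 2L]
  bx <- p[j, 1L]; by <- p[j, 2L]
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    # skip edges adjacent to i (share a vertex)
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]
    if (!length(ks)) next
    d1 <- cross(ax[i], ay[i], bx[i], by[i], ax[ks], ay[ks])
    d2 <- cross(ax[i], ay[i], bx[i], by[i], bx[ks], by[ks])
    d3 <- cross(ax[ks], ay[ks], bx[ks], by[ks], ax[i], ay[i])
    d4 <- cross(ax[ks], ay[ks], bx[ks], by[ks], bx[i], by[i])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

.asContourMatrix <- function(contour) {
  if (is(contour, "Contour")) contourPoints(contour)
  else {
    p <- as.matrix(contour)
    if (ncol(p) != 2L) stop("expected an n x 2 coordinate matrix")
    p
  }
}

#' Polygon area (shoelace formula)
#'
#' Enclosed area of a closed contour in mm^2. Contours are normalized to
#' counter-clockwise orientation at construction, so the shoelace sum is
#' positive; the absolute value is returned for raw matrices.
#'
#' @param contour a [Contour-class] or an n x 2 vertex matrix (closing edge
#'   implicit).
#' @return area in mm^2, strictly positive.
#' @examples
#' polygonArea(Contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))  # 1
#' @export
polygonArea <- function(contour) {
  p <- .asContourMatrix(contour)
  if (nrow(unique(p)) < 3L)
    stop("degenerate contour: fewer than 3 distinct vertices")
  a <- abs(.shoelace(p))
  if (a < .Machine$double.eps * 100 * max(1, max(abs(p))))
    stop("degenerate contour: zero enclosed area")
  a
}

#' Polygon perimeter
#'
#' Sum of edge lengths of a closed contour, including the closing edge.
#'
#' @inheritParams polygonArea
#' @return perimeter in mm.
#' @export
polygonPerimeter <- function(contour) {
  p <- .asContourMatrix(contour)
  if (nrow(unique(p)) < 3L)
    stop("degenerate contour: fewer than 3 distinct vertices")
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(sqrt((p[j, 1L] - p[, 1L])^2 + (p[j, 2L] - p[, 2L])^2))
}

#' Isoperimetric quotient (roundness)
#'
#' Q = 4 * pi * A / P^2 for a closed contour of area A and perimeter P.
#' Q = 1 for a circle and decreases for elongated or irregular shapes;
#' used to reject vessel-like candidates during ON/ONS contour selection.
#'
#' @inheritParams polygonArea
#' @return dimensionless roundness in (0, 1] (fine polygonal circles
#'   approach 1 from below).
#' @examples
#' isoperimetricQuotient(Contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
#' # pi / 4
#' @export
isoperimetricQuotient <- function(contour) {
  4 * pi * polygonArea(contour) / polygonPerimeter(contour)^2
}

#' Cumulative arc length of a 3D path
#'
#' Chordal cumulative lengths along an ordered point sequence; first entry
#' 0, monotone non-decreasing.
#'
#' @param path n x 3 (or n x 2) numeric matrix of ordered points, mm.
#' @return numeric vector of length n of cumulative lengths, mm.
#' @examples
#' arcLength(rbind(c(0, 0, 0), c(3, 4, 0)))  # 0 5
#' @export
arcLength <- function(path) {
  p <- as.matrix(path)
  if (nrow(p) < 2L) stop("a path needs at least 2 points")
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                     p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Perpendicular distance from a point to a line
#'
#' Distance from \code{p} to the infinite line through \code{a} and
#' \code{b} in 3D; invariant under rigid motion.
#'
#' @param p,a,b numeric length-3 points (mm); \code{a != b}.
#' @return distance in mm.
#' @export
pointToLineDistance <- function(p, a, b) {
  p <- as.numeric(p); a <- as.numeric(a); b <- as.numeric(b)
  u <- b - a
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("line is undefined: a and b coincide")
  w <- p - a
  # |w x u| / |u|
  cr <- c(w[2L] * u[3L] - w[3L] * u[2L],
          w[3L] * u[1L] - w[1L] * u[3L],
          w[1L] * u[2L] - w[2L] * u[1L])
  sqrt(sum(cr^2)) / nu
}

# vectorized variant: rows of P against line (a, b)
.pointsToLineDistance <- function(P, a, b) {
  u <- b - a
  nu <- sqrt(sum(u^2))
  W <- sweep(P, 2L, a)
  cr1 <- W[, 2L] * u[3L] - W[, 3L] * u[2L]
  cr2 <- W[, 3L] * u[1L] - W[, 1L] * u[3L]
  cr3 <- W[, 1L] * u[2L] - W[, 2L] * u[1L]
  sqrt(cr1^2 + cr2^2 + cr3^2) / nu
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Places points along the piecewise-linear path at equal arc-length steps
#' no larger than \code{stepMm}; both endpoints are preserved.
#'
#' @param path n x 3 (or n x 2) matrix of ordered points, mm.
#' @param stepMm positive target spacing, mm.
#' @return matrix of resampled points (same column count as input).
#' @export
resamplePath <- function(path, stepMm) {
  if (!is.numeric(stepMm) || length(stepMm) != 1L || stepMm <= 0)
    stop("stepMm must be a single positive length")
  p <- as.matrix(path)
  s <- arcLength(p)
  total <- s[length(s)]
  nSeg <- max(1L, ceiling(total / stepMm))
  sNew <- seq(0, total, length.out = nSeg + 1L)
  out <- vapply(seq_len(ncol(p)),
                function(k) stats::approx(s, p[, k], xout = sNew,
                                          ties = "ordered")$y,
                numeric(length(sNew)))
  matrix(out, ncol = ncol(p))
}

#' Circular equivalent diameter of an area
#'
#' Diameter of the circle with the same area: d = 2 * sqrt(A / pi).
#' This is the convention used to report ON/ONS diameters from measured
#' cross-sectional areas under a circular cross-section assumption.
#'
#' @param areaMm2 positive area(s) in mm^2 (vectorized).
#' @return diameter(s) in mm.
#' @examples
#' equivalentDiameter(pi)    # 2
#' equivalentDiameter(9.98)  # 3.56 at 2 d.p.
#' @export
equivalentDiameter <- function(areaMm2) {
  if (any(!is.finite(areaMm2)) || any(areaMm2 <= 0))
    stop("area must be positive and finite")
  2 * sqrt(areaMm2 / pi)
}

# even-odd point-in-polygon; pt length-2, poly n x 2 (closing edge implicit)
.pointInPolygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  x <- poly[, 1L]; y <- poly[, 2L]
  xj <- x[j]; yj <- y[j]
  crosses <- ((y > pt[2L]) != (yj > pt[2L]))
  if (!any(crosses)) return(FALSE)
  xin <- x[crosses] + (pt[2L] - y[crosses]) / (yj[crosses] - y[crosses]) *
    (xj[crosses] - x[crosses])
  sum(xin > pt[1L]) %% 2L == 1L
}

.centroid <- function(p) colMeans(p)
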