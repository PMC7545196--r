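# Digital imaging phantom: concentric-tube volumes of known ON/ONS
# geometry with partial-volume rendering and Rician noise, plus centerline
# fixtures of known deviation. Provides analytic ground truth so the
# deviation and segmentation pipelines are testable without restricted
# clinical data.

# run expr with a locally seeded RNG, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# magnitude-MRI (Rician) noise: |signal + n1 + i n2|, n1, n2 ~ N(0, sigma)
.ricianNoise <- function(x, sigma) {
  n <- length(x)
  sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# 3x3 in-plane block mean of a supersampled matrix
.blockMean3 <- function(m) {
  nr <- nrow(m) / 3L
  nc <- ncol(m) / 3L
  # average rows in triplets, then columns
  r <- (m[seq(1L, nrow(m), 3L), ] + m[seq(2L, nrow(m), 3L), ] +
        m[seq(3L, nrow(m), 3L), ]) / 3
  (r[, seq(1L, ncol(m), 3L)] + r[, seq(2L, ncol(m), 3L)] +
     r[, seq(3L, ncol(m), 3L)]) / 3
}

# shared renderer: radiusFun(zMm) -> list(onR, onsRadiiFun(theta))
.renderPhantom <- function(spec, onsRadiusAt) {
  sp <- spec@spacing
  fov <- spec@onsWideMm + 2 * spec@marginMm
  n <- ceiling(fov / sp[1L]) + 1L       # in-plane grid (square)
  nz <- floor(spec@axialLengthMm / sp[3L]) + 1L
  ctr <- (n - 1L) / 2 * sp[1L]          # tube axis at the grid center
  if (spec@onsWideMm / 2 + ctr > (n - 1L) * sp[1L] ||
      spec@onsWideMm / 2 > ctr)
    stop("phantom geometry exceeds the voxel grid")
  # 3x supersampled in-plane coordinates (voxel-center convention)
  sub <- as.vector(outer((seq_len(n) - 1L) * sp[1L],
                         c(-1, 0, 1) / 3 * sp[1L], `+`))
  sub <- sort(sub)
  dx <- outer(sub - ctr, rep(1, length(sub)))
  dy <- t(dx)
  r2 <- dx^2 + dy^2
  theta <- atan2(dy, dx)
  rOn <- spec@onDiameterMm / 2
  ints <- spec@intensities
  vol <- array(0, dim = c(n, n, nz))
  zOff <- c(-1, 0, 1) / 3 * sp[3L]
  for (k in seq_len(nz)) {
    z <- (k - 1L) * sp[3L]
    acc <- matrix(0, nrow(r2), ncol(r2))
    for (dz in zOff) {
      zs <- min(max(z + dz, 0), spec@axialLengthMm)
      rOns <- onsRadiusAt(zs, theta)
      img <- matrix(ints[["background"]], nrow(r2), ncol(r2))
      img[r2 <= rOns^2] <- ints[["csf"]]
      img[r2 <= rOn^2] <- ints[["on"]]
      acc <- acc + img
    }
    vol[, , k] <- .blockMean3(acc / 3)
  }
  if (is.finite(spec@snr)) {
    sigma <- ints[["csf"]] / spec@snr
    vol <- .withSeed(spec@seed, array(.ricianNoise(vol, sigma), dim(vol)))
    vol[vol > 4095] <- 4095
  }
  list(volume = ImageVolume(vol, spacing = sp),
       center = c(ctr, ctr), nz = nz)
}

.phantomTruth <- function(spec, center, nz, onsAreaFun) {
  z <- (seq_len(nz) - 1L) * spec@spacing[3L]
  onsR <- (spec@onsWideMm -
           (spec@onsWideMm - spec@onsNarrowMm) * z / spec@axialLengthMm) / 2
  onArea <- pi * (spec@onDiameterMm / 2)^2
  list(slice_position_mm = z,
       ons_radius_mm = onsR,
       on_area_mm2 = rep(onArea, nz),
       ons_area_mm2 = onsAreaFun(onsR),
       on_head_mm = c(center, 0),
       spec = list(ons_wide_mm = spec@onsWideMm,
                   ons_narrow_mm = spec@onsNarrowMm,
                   on_diameter_mm = spec@onDiameterMm,
                   axial_length_mm = spec@axialLengthMm,
                   spacing_mm = spec@spacing,
                   intensities = as.list(spec@intensities),
                   snr = spec@snr, seed = spec@seed))
}

#' Generate the idealized concentric-tube phantom
#'
#' Renders a volume containing one idealized optic-subarachnoid-space
#' geometry: a sheath tube whose outer diameter tapers linearly from
#' \code{onsWideMm} (at the ON-head end, z = 0) to \code{onsNarrowMm}
#' over the axial length, with a concentric nerve of constant diameter.
#' Voxel intensities are partial-volume means (3x supersampling per axis)
#' of the region intensities; finite \code{snr} adds seeded Rician noise
#' with sigma = CSF mean / snr. Ground truth areas are analytic.
#'
#' @param spec a [PhantomSpec-class] (defaults reproduce the reference
#'   geometry: 7 to 5 mm taper, 3.35 mm nerve, 20 mm length).
#' @return list with elements \code{volume} ([ImageVolume-class]),
#'   \code{truth} (list of per-slice analytic areas, the ON head location,
#'   and a spec echo).
#' @examples
#' ph <- idealizedPhantom(PhantomSpec(spacing = c(0.5, 0.5, 2)))
#' ph$truth$on_area_mm2[1]  # pi * (3.35 / 2)^2
#' @export
idealizedPhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  taper <- function(z)
    (spec@onsWideMm - (spec@onsWideMm - spec@onsNarrowMm) *
       z / spec@axialLengthMm) / 2
  r <- .renderPhantom(spec, function(zs, theta) taper(zs))
  truth <- .phantomTruth(spec, r$center, r$nz, function(onsR) pi * onsR^2)
  list(volume = r$volume, truth = truth)
}

#' Generate a subject-like irregular phantom
#'
#' Like [idealizedPhantom()] but the sheath cross-section is perturbed by
#' a low-order Fourier series in polar angle, r(theta, z) = R(z) +
#' sum_k a_k cos(k theta + phi_k) for harmonics k = 2, 3, 4, emulating the
#' irregular subject-specific geometries used for reliability testing.
#' Relative harmonic amplitudes and phases are drawn from the seeded RNG
#' and scaled so the amplitudes sum to \code{irregularity}. Ground-truth
#' sheath areas follow the closed form pi R^2 + (pi / 2) sum a_k^2.
#'
#' @param spec a [PhantomSpec-class].
#' @param irregularity total perturbation amplitude in mm (>= 0);
#'   0 reproduces the idealized phantom exactly. Rejected if the perturbed
#'   sheath could touch the nerve
#'   (irregularity >= narrow sheath radius - nerve radius).
#' @param geometrySeed seed for the harmonic amplitude/phase draw; defaults
#'   to the seed in `spec`. Keeping it fixed while varying that seed
#'   re-scans the same geometry with fresh noise.
#' @return As [idealizedPhantom()]; the truth list gains
#'   \code{fourier = list(k, amplitude, phase)}.
#' @export
subjectLikePhantom <- function(spec = PhantomSpec(), irregularity = 0.3,
                               geometrySeed = spec@seed) {
  stopifnot(is(spec, "PhantomSpec"))
  if (irregularity < 0) stop("irregularity must be >= 0")
  maxAmp <- spec@onsNarrowMm / 2 - spec@onDiameterMm / 2
  if (irregularity >= maxAmp)
    stop(sprintf(
      "irregularity %.3f mm would let the sheath touch the nerve (limit %.3f mm)",
      irregularity, maxAmp))
  ks <- 2:4
  if (irregularity == 0) {
    amp <- rep(0, length(ks)); ph <- rep(0, length(ks))
  } else {
    coef <- .withSeed(as.integer(geometrySeed) + 1000L, list(
      rel = stats::runif(length(ks), 0.2, 1),
      phase = stats::runif(length(ks), 0, 2 * pi)))
    amp <- coef$rel / sum(coef$rel) * irregularity
    ph <- coef$phase
  }
  taper <- function(z)
    (spec@onsWideMm - (spec@onsWideMm - spec@onsNarrowMm) *
       z / spec@axialLengthMm) / 2
  r <- .renderPhantom(spec, function(zs, theta) {
    R <- taper(zs)
    pert <- 0
    for (i in seq_along(ks))
      pert <- pert + amp[i] * cos(ks[i] * theta + ph[i])
    R + pert
  })
  truth <- .phantomTruth(spec, r$center, r$nz,
                         function(onsR) pi * onsR^2 + pi / 2 * sum(amp^2))
  truth$fourier <- list(k = ks, amplitude = amp, phase = ph)
  list(volume = r$volume, truth = truth)
}

#' Generate a centerline fixture of known deviation
#'
#' Emulates operator point picking along the nerve: points at roughly
#' 1-2 mm spacing on a planar circular arc of radius \code{bendRadiusMm}
#' (or a straight line when the radius is infinite), with optional seeded
#' isotropic Gaussian jitter. For the 20 mm trajectory the true deviation
#' is the sagitta R (1 - cos(10 / R)); 0 for the straight line.
#'
#' @param bendRadiusMm arc radius in mm, >= 10.05 so a 20 mm arc spans at
#'   most a half circle; \code{Inf} for a straight path.
#' @param nPoints number of picked points (>= 4); default places points at
#'   1.5 mm spacing along \code{totalLengthMm}.
#' @param jitterMm SD of isotropic Gaussian jitter applied to every
#'   coordinate (default 0).
#' @param seed RNG seed for the jitter draw.
#' @param totalLengthMm total picked path length, mm (default 24, so the
#'   20 mm trajectory is well covered).
#' @return list with elements \code{centerline} ([Centerline-class]) and
#'   \code{trueDeviationMm}.
#' @examples
#' fx <- deviationFixture(bendRadiusMm = 50)
#' fx$trueDeviationMm  # 50 * (1 - cos(0.2))
#' @export
deviationFixture <- function(bendRadiusMm = Inf, nPoints = NULL,
                             jitterMm = 0, seed = 1L, totalLengthMm = 24) {
  if (is.finite(bendRadiusMm) && bendRadiusMm < 10.05)
    stop("bendRadiusMm must be >= 10.05 mm (20 mm arc within a half circle)")
  if (totalLengthMm < 20) stop("totalLengthMm must be at least 20 mm")
  if (is.null(nPoints)) nPoints <- ceiling(totalLengthMm / 1.5) + 1L
  if (nPoints < 4L) stop("need at least 4 picked points")
  s <- seq(0, totalLengthMm, length.out = nPoints)
  pts <- if (is.finite(bendRadiusMm)) {
    R <- bendRadiusMm
    cbind(R * sin(s / R), R * (1 - cos(s / R)), 0)
  } else {
    cbind(s, 0, 0)
  }
  if (jitterMm > 0)
    pts <- pts + .withSeed(seed,
      matrix(stats::rnorm(length(pts), 0, jitterMm), ncol = 3L))
  trueDev <- if (is.finite(bendRadiusMm))
    bendRadiusMm * (1 - cos(10 / bendRadiusMm)) else 0
  list(centerline = Centerline(pts, snapTolMm = Inf),
       trueDeviationMm = trueDev)
}
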