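# Reliability statistics for repeated measurements: consensus differences,
# intraclass correlation (ANOVA variance-components estimators), and
# coefficient of variation.

#' Read a ratings table from CSV
#'
#' Rows are cases, columns are repeats/raters; a header row is expected.
#'
#' @param path CSV file path.
#' @param parameter,units labels stored in the table.
#' @return A [RatingsTable-class].
#' @export
readRatingsCSV <- function(path, parameter = "parameter", units = "") {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, header = TRUE)
  RatingsTable(as.matrix(df), parameter = parameter, units = units)
}

.ratingsMatrix <- function(table) {
  if (is(table, "RatingsTable")) ratings(table)
  else {
    m <- as.matrix(table)
    if (nrow(m) < 2L || ncol(m) < 2L || anyNA(m))
      stop("need a complete matrix with >= 2 cases and >= 2 repeats")
    m
  }
}

#' Case-wise differences from the consensus value
#'
#' For each case the consensus is the mean over repeats (there is no gold
#' standard, so the mean of all reliability measurements is taken as the
#' true value). Differences are the absolute deviations of each
#' measurement from its case consensus; their mean and SD are reported in
#' parameter units and as percentages of the case consensus.
#'
#' @param table a [RatingsTable-class] or a cases x repeats matrix.
#' @param sdType "sample" (n - 1, default) or "population" (n) SD.
#' @return named list: \code{mean_abs_diff}, \code{sd_abs_diff},
#'   \code{percent_diff}, \code{percent_sd}.
#' @examples
#' consensusDifferences(rbind(c(1, 2, 3), c(2, 2, 2)))
#' @export
consensusDifferences <- function(table, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  m <- .ratingsMatrix(table)
  if (ncol(m) < 2L) stop("need at least 2 repeats")
  consensus <- rowMeans(m)
  diffs <- abs(m - consensus)
  pct <- 100 * diffs / consensus
  sdf <- function(x) {
    s <- stats::sd(x)  # sample (n - 1)
    if (sdType == "population") s * sqrt((length(x) - 1) / length(x)) else s
  }
  list(mean_abs_diff = mean(diffs), sd_abs_diff = sdf(as.numeric(diffs)),
       percent_diff = mean(pct), percent_sd = sdf(as.numeric(pct)))
}

#' Intraclass correlation coefficient
#'
#' ANOVA variance-components estimators on a complete cases x repeats
#' table. The default form is ICC(2,1), two-way random effects, absolute
#' agreement, single measurement:
#' \deqn{(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with n cases, k repeats, row (case) mean square MS_R, column
#' (rater/repeat) mean square MS_C and residual MS_E. The one-way form
#' ICC(1,1) pools column effects into the residual. The estimator can be
#' slightly negative; a table with zero total variance is defined to have
#' ICC 1 (with a message).
#'
#' @param table a [RatingsTable-class] or a cases x repeats matrix.
#' @param form "two-way-absolute-single" (default) or "one-way".
#' @return ICC value (scalar, <= 1).
#' @examples
#' icc(rbind(c(1, 1.1), c(2, 2.1), c(3, 2.9)))
#' @export
icc <- function(table, form = c("two-way-absolute-single", "one-way")) {
  form <- match.arg(form)
  m <- .ratingsMatrix(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) {
    message("zero total variance: ICC defined as 1")
    return(1)
  }
  ssr <- k * sum((rowMeans(m) - grand)^2)
  msr <- ssr / (n - 1)
  if (form == "one-way") {
    msw <- (sst - ssr) / (n * (k - 1))
    return((msr - msw) / (msr + (k - 1) * msw))
  }
  ssc <- n * sum((colMeans(m) - grand)^2)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Coefficient of variation of repeated measurements
#'
#' Per-case SD over repeats divided by the per-case mean, averaged over
#' cases; reported as a dimensionless fraction (not percent). Sample
#' (n - 1) SD is used.
#'
#' @param table a [RatingsTable-class] or a cases x repeats matrix.
#' @return CV as a fraction.
#' @examples
#' cvRepeats(rbind(c(9, 10, 11), c(18, 20, 22)))
#' @export
cvRepeats <- function(table) {
  m <- .ratingsMatrix(table)
  means <- rowMeans(m)
  if (any(means == 0)) stop("per-case mean of zero: CV undefined")
  mean(apply(m, 1L, stats::sd) / means)
}

#' Full reliability report for a ratings table
#'
#' Combines [consensusDifferences()], [icc()] and [cvRepeats()] into one
#' record mirroring a standard reliability table row
#' (mean +/- SD difference, percent, ICC, CV).
#'
#' @param table a [RatingsTable-class] or a cases x repeats matrix.
#' @param iccForm ICC estimator form, see [icc()].
#' @param sdType SD convention for the consensus differences.
#' @return A [ReliabilityReport-class].
#' @export
reliabilityReport <- function(table,
                              iccForm = c("two-way-absolute-single",
                                          "one-way"),
                              sdType = c("sample", "population")) {
  iccForm <- match.arg(iccForm)
  cd <- consensusDifferences(table, sdType = match.arg(sdType))
  par <- if (is(table, "RatingsTable")) table@parameter else "parameter"
  un <- if (is(table, "RatingsTable")) table@units else ""
  new("ReliabilityReport",
      icc = icc(table, form = iccForm), iccForm = iccForm,
      cv = cvRepeats(table),
      meanAbsDiff = cd$mean_abs_diff, sdAbsDiff = cd$sd_abs_diff,
      percentDiff = cd$percent_diff, percentSd = cd$percent_sd,
      parameter = par, units = un)
}

#' Serialize a ReliabilityReport to JSON
#'
#' @param report a [ReliabilityReport-class].
#' @param path optional output path; if NULL the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
reliabilityToJSON <- function(report, path = NULL) {
  rec <- c(list(parameter = report@parameter, units = report@units,
                icc_form = report@iccForm),
           as.list(reportValues(report)),
           list(package_version =
                  as.character(utils::packageVersion("onsmorph"))))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Two-scan phantom reliability study
#'
#' Digital analog of scanning a physical phantom twice: renders a panel of
#' synthetic sheath geometries (idealized tubes of varying wide-end
#' diameter plus subject-like irregular tubes), simulates two
#' independently seeded noisy scans of each, processes both scans with the
#' identical segmentation pipeline, and assembles the ONS and ON areas at
#' the posterior measurement plane into ratings tables (cases =
#' geometries, repeats = scans) with their reliability reports.
#'
#' @param seed base RNG seed; scan noise seeds are derived from it.
#' @param snr scan SNR (CSF mean / Rician sigma), default 20.
#' @param wideDiametersMm wide-end sheath diameters of the idealized
#'   geometries, mm.
#' @param irregularities perturbation amplitudes of the subject-like
#'   geometries, mm.
#' @param spacing voxel spacing of the rendered scans, mm.
#' @param zRangeMm axial window processed around the 3 mm measurement
#'   plane (default c(1.2, 4.8): the bracketing slices plus margin).
#' @param ... further arguments passed to [measureVolume()].
#' @return list with \code{onsTable}, \code{onTable}
#'   ([RatingsTable-class]), \code{onsReport}, \code{onReport}
#'   ([ReliabilityReport-class]), and \code{scanDiffSdOns} (SD of the
#'   between-scan ONS area differences, mm^2).
#' @export
phantomReliabilityStudy <- function(seed = 1L, snr = 20,
                                    wideDiametersMm = c(6.5, 7, 7.5),
                                    irregularities = c(0.2, 0.3, 0.4),
                                    spacing = c(0.253, 0.253, 0.600),
                                    zRangeMm = c(1.2, 4.8), ...) {
  seed <- as.integer(seed)
  cases <- c(lapply(wideDiametersMm, function(d)
               list(kind = "idealized", wide = d, irr = NA)),
             lapply(seq_along(irregularities), function(i)
               list(kind = "subject", wide = 7,
                    irr = irregularities[i], geomSeed = seed + 100L + i)))
  nC <- length(cases)
  ons <- matrix(NA_real_, nC, 2L,
                dimnames = list(NULL, c("scan1", "scan2")))
  on <- ons
  for (ci in seq_len(nC)) {
    cs <- cases[[ci]]
    for (sc in 1:2) {
      scanSeed <- seed + 10L * ci + sc
      spec <- PhantomSpec(onsWideMm = cs$wide, snr = snr, seed = scanSeed,
                          spacing = spacing)
      ph <- if (cs$kind == "idealized") idealizedPhantom(spec)
            else subjectLikePhantom(spec, irregularity = cs$irr,
                                    geometrySeed = cs$geomSeed)
      res <- measureVolume(ph$volume, ph$truth$on_head_mm,
                           zRangeMm = zRangeMm, ...)
      v <- measurementValues(res$measurement)
      ons[ci, sc] <- v[["ons_area_mm2"]]
      on[ci, sc] <- v[["on_area_mm2"]]
    }
  }
  onsTab <- RatingsTable(ons, parameter = "ONS cross-sectional area",
                         units = "mm^2")
  onTab <- RatingsTable(on, parameter = "ON cross-sectional area",
                        units = "mm^2")
  list(onsTable = onsTab, onTable = onTab,
       onsReport = reliabilityReport(onsTab),
       onReport = reliabilityReport(onTab),
       scanDiffSdOns = stats::sd(ons[, 1L] - ons[, 2L]))
}
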