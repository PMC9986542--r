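# Spectral metrics: band integration, optical redox ratio, R_flavin, and
# group-average spectra.

#' Fluorescence spectrum container
#'
#' @param wavelengths Strictly increasing grid in nm within `[430, 740]`,
#'   at least two samples.
#' @param intensities Non-negative intensities (arbitrary fluorescence
#'   units), same length as `wavelengths`.
#' @return Object of class `fl_spectrum` with fields `wavelengths` and
#'   `intensities`.
#' @export
fl_spectrum <- function(wavelengths, intensities) {
  check_grid(wavelengths)
  stopifnot(length(intensities) == length(wavelengths))
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (any(intensities < -1e-12)) stop("intensities must be non-negative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = pmax(as.numeric(intensities), 0)),
            class = "fl_spectrum")
}

#' @export
print.fl_spectrum <- function(x, ...) {
  cat(sprintf("<fl_spectrum: %d samples, %.0f-%.0f nm, peak %.4g at %.0f nm>\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              max(x$intensities), x$wavelengths[which.max(x$intensities)]))
  invisible(x)
}

#' Spectral band and peak definitions
#'
#' The NAD(P)H integration band spans 430-475 nm and the FAD band
#' 520-600 nm; peak reads for the protein-bound FMN to FAD ratio are taken
#' at 495 nm and 530 nm as the mean intensity within `peak_window` nm of
#' the peak center (`peak_window = 0` reads the nearest grid sample).
#'
#' @param nadh_band,fad_band Numeric length-2 vectors, nm.
#' @param peak_fmn,peak_fad Peak centers in nm.
#' @param peak_window Half-width of the peak averaging window in nm (>= 0).
#' @return List of class `band_definition`.
#' @export
band_definition <- function(nadh_band = c(430, 475), fad_band = c(520, 600),
                            peak_fmn = 495, peak_fad = 530, peak_window = 2) {
  stopifnot(length(nadh_band) == 2, length(fad_band) == 2,
            nadh_band[1] < nadh_band[2], fad_band[1] < fad_band[2],
            peak_window >= 0)
  structure(list(nadh_band = nadh_band, fad_band = fad_band,
                 peak_fmn = peak_fmn, peak_fad = peak_fad,
                 peak_window = peak_window),
            class = "band_definition")
}

#' Trapezoidal band integral of a spectrum
#'
#' Integrates the spectrum over the closed band with the trapezoid rule;
#' band endpoints that fall between grid samples are included via linear
#' interpolation.
#'
#' @param spectrum A [fl_spectrum()].
#' @param band Numeric length-2 vector `(lo, hi)` in nm; must lie within
#'   the spectral coverage.
#' @return The band integral (intensity x nm).
#' @export
band_integrate <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "fl_spectrum"), length(band) == 2, band[1] < band[2])
  wl <- spectrum$wavelengths
  if (band[1] < wl[1] - 1e-9 || band[2] > wl[length(wl)] + 1e-9) {
    stop(sprintf("band [%g, %g] nm outside spectral coverage [%g, %g] nm",
                 band[1], band[2], wl[1], wl[length(wl)]))
  }
  inside <- wl > band[1] & wl < band[2]
  x <- c(band[1], wl[inside], band[2])
  y <- c(stats::approx(wl, spectrum$intensities, xout = band[1])$y,
         spectrum$intensities[inside],
         stats::approx(wl, spectrum$intensities, xout = band[2])$y)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Mean intensity in a window around a peak
#'
#' @param spectrum A [fl_spectrum()].
#' @param center Peak center in nm.
#' @param window Half-width in nm; `0` returns the nearest grid sample.
#' @return Mean intensity within the window.
#' @export
peak_intensity <- function(spectrum, center, window = 2) {
  wl <- spectrum$wavelengths
  if (window <= 0) {
    return(spectrum$intensities[which.min(abs(wl - center))])
  }
  sel <- abs(wl - center) <= window + 1e-9
  if (!any(sel)) {
    return(spectrum$intensities[which.min(abs(wl - center))])
  }
  mean(spectrum$intensities[sel])
}

#' Optical redox ratio
#'
#' `RR = FAD / (NAD(P)H + FAD)`, where the NAD(P)H and FAD fluorescence are
#' the band integrals over 430-475 nm and 520-600 nm respectively. The
#' ratio lies in `[0, 1]` and is invariant to a global intensity scale.
#'
#' @param spectrum A [fl_spectrum()].
#' @param bands A [band_definition()].
#' @return The redox ratio.
#' @export
redox_ratio <- function(spectrum, bands = band_definition()) {
  nadh <- band_integrate(spectrum, bands$nadh_band)
  fad <- band_integrate(spectrum, bands$fad_band)
  if (nadh + fad <= 0) stop("redox ratio undefined: both band integrals are zero")
  fad / (nadh + fad)
}

#' Protein-bound FMN to FAD peak ratio
#'
#' `R_flavin = I495 / I530`, the ratio of (window-averaged) intensities at
#' the protein-bound FMN main emission peak (495 nm) and the FAD peak /
#' FMN side peak (530 nm).
#'
#' @inheritParams redox_ratio
#' @return The peak ratio (> 0 whenever defined).
#' @export
r_flavin <- function(spectrum, bands = band_definition()) {
  i495 <- peak_intensity(spectrum, bands$peak_fmn, bands$peak_window)
  i530 <- peak_intensity(spectrum, bands$peak_fad, bands$peak_window)
  if (i530 <= 0) stop("R_flavin undefined: intensity at 530 nm is zero")
  i495 / i530
}

#' Group-average spectra normalized to the global maximum
#'
#' Point-wise mean spectrum per group, with every group divided by the
#' single maximum across all group means ("relative spectral intensity";
#' the brightest group attains 1.0 at its peak). All spectra must share
#' one wavelength grid.
#'
#' @param spectra List of [fl_spectrum()] objects.
#' @param groups Vector of group labels, one per spectrum; every group must
#'   be non-empty.
#' @return Named list of normalized `fl_spectrum` objects, one per group,
#'   with the global maximum stored in attribute `"global_max"`.
#' @export
average_group_spectra <- function(spectra, groups) {
  stopifnot(length(spectra) == length(groups), length(spectra) > 0)
  wl <- spectra[[1]]$wavelengths
  for (s in spectra) {
    if (length(s$wavelengths) != length(wl) || any(abs(s$wavelengths - wl) > 1e-9)) {
      stop("all spectra must share a common wavelength grid")
    }
  }
  groups <- as.character(groups)
  means <- lapply(split(seq_along(spectra), groups), function(idx) {
    rowMeans(vapply(spectra[idx], function(s) s$intensities, numeric(length(wl))))
  })
  global_max <- max(vapply(means, max, numeric(1)))
  if (global_max <= 0) stop("all group-average spectra are zero")
  out <- lapply(means, function(m) fl_spectrum(wl, m / global_max))
  attr(out, "global_max") <- global_max
  out
}

#' Read / write a two-column spectrum TSV
#'
#' Tab-separated file with header `wavelength_nm<TAB>intensity`, one file
#' per region of interest.
#'
#' @param spectrum A [fl_spectrum()].
#' @param path File path.
#' @return `write_spectrum_tsv` returns `path` invisibly;
#'   `read_spectrum_tsv` returns a [fl_spectrum()].
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  df <- data.frame(wavelength_nm = spectrum$wavelengths,
                   intensity = spectrum$intensities)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("wavelength_nm", "intensity") %in% names(df))) {
    stop("spectrum TSV must have columns wavelength_nm and intensity")
  }
  fl_spectrum(df$wavelength_nm, df$intensity)
}
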