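# Frequency-domain lifetime estimation (phasor forward model, phase and
# modulation lifetimes) and FLIM image / ROI handling for the 500-580 nm
# flavin band.

#' Phasor forward response of an exponential-decay mixture
#'
#' For lifetime components `tau_i` with non-negative intensity weights
#' `w_i`, the demodulated response at modulation frequency `f_mod` is the
#' weight-normalized phasor sum
#' `g = sum w_i / (1 + (w tau_i)^2)`, `s = sum w_i w tau_i / (1 + (w tau_i)^2)`
#' with `w = 2 pi f_mod`, giving `phase = atan2(s, g)` and modulation depth
#' `m = sqrt(g^2 + s^2)`.
#'
#' @param tau_ns Lifetime components in ns.
#' @param weights Intensity weights (>= 0, positive sum), same length.
#' @param f_mod Modulation frequency in Hz (default 10 MHz).
#' @return Object of class `modulated_response` with fields `phase`
#'   (radians), `modulation_depth` and `f_mod`.
#' @export
forward_response <- function(tau_ns, weights, f_mod = 1e7) {
  stopifnot(length(tau_ns) == length(weights), length(tau_ns) >= 1,
            all(is.finite(tau_ns)), all(tau_ns >= 0),
            all(is.finite(weights)))
  if (any(weights < 0)) stop("weights must be non-negative")
  tot <- sum(weights)
  if (tot <= 0) stop("at least one component must carry positive weight")
  w <- weights / tot
  omega <- 2 * pi * f_mod
  ot <- omega * tau_ns * 1e-9
  g <- sum(w / (1 + ot^2))
  s <- sum(w * ot / (1 + ot^2))
  structure(list(phase = atan2(s, g), modulation_depth = sqrt(g^2 + s^2),
                 f_mod = f_mod),
            class = "modulated_response")
}

#' Phase lifetime
#'
#' `tau_phi = tan(phase) / (2 pi f_mod)`, the lifetime a mono-exponential
#' decay with the same phase shift would have. This is the reported flavin
#' lifetime throughout the pipeline.
#'
#' @param response A [forward_response()] object.
#' @return Lifetime in ns.
#' @export
phase_lifetime <- function(response) {
  stopifnot(inherits(response, "modulated_response"))
  if (response$phase < 0 || response$phase >= pi / 2) {
    stop("phase must lie in [0, pi/2) for a physical decay")
  }
  tan(response$phase) / (2 * pi * response$f_mod) * 1e9
}

#' Modulation lifetime
#'
#' `tau_m = sqrt(1 / m^2 - 1) / (2 pi f_mod)`. Equals the phase lifetime
#' only for mono-exponential decays, otherwise `tau_m >= tau_phi`; the
#' difference is a diagnostic for lifetime heterogeneity.
#'
#' @param response A [forward_response()] object.
#' @return Lifetime in ns.
#' @export
modulation_lifetime <- function(response) {
  stopifnot(inherits(response, "modulated_response"))
  m <- response$modulation_depth
  if (!is.finite(m) || m <= 0 || m > 1 + 1e-12) {
    stop("modulation depth must lie in (0, 1]")
  }
  m <- min(m, 1)
  sqrt(1 / m^2 - 1) / (2 * pi * response$f_mod) * 1e9
}

#' Apparent flavin lifetime of a fluorophore mixture
#'
#' Band-limited FD-FLIM lifetime of the flavin species: each flavin
#' component contributes its lifetime components weighted by its
#' band-integrated emission (abundance x quantum yield x shape mass inside
#' the detection band) times the component's intensity fraction, and the
#' weighted phasor sum is converted to a phase lifetime at `f_mod`.
#'
#' @param abundances Named non-negative vector of fluorophore abundances.
#' @param components Fluorophore library.
#' @param band Detection band in nm (default the 500-580 nm flavin band).
#' @param f_mod Modulation frequency in Hz.
#' @return Phase lifetime in ns.
#' @export
flavin_lifetime_of_state <- function(abundances,
                                     components = fluorophore_library(),
                                     band = c(500, 580), f_mod = 1e7) {
  stopifnot(length(band) == 2, band[1] < band[2])
  grid <- seq(band[1], band[2], by = 0.5)
  taus <- numeric(0)
  weights <- numeric(0)
  for (nm in names(abundances)) {
    cc <- components[[nm]]
    if (is.null(cc) || !isTRUE(cc$is_flavin)) next
    shape <- component_shape(cc, grid)
    mass <- sum(diff(grid) * (utils::head(shape, -1) + utils::tail(shape, -1)) / 2)
    emission <- abundances[[nm]] * cc$quantum_yield_rel * mass
    taus <- c(taus, cc$lifetime_components$tau_ns)
    weights <- c(weights, emission * cc$lifetime_components$fraction)
  }
  if (length(weights) == 0 || sum(weights) <= 0) {
    stop("no flavin component with positive band-weighted intensity")
  }
  phase_lifetime(forward_response(taus, weights, f_mod = f_mod))
}

#' FLIM image container
#'
#' Co-registered per-pixel flavin lifetime (ns) and demodulated intensity
#' (mV_RMS) maps with physical pixel size; `fov_mm = pixel_size_mm * n`.
#'
#' @param lifetime_map,intensity_map Numeric matrices of equal shape;
#'   lifetimes must be positive.
#' @param fov_mm Field of view (square) in mm.
#' @return Object of class `flim_image`.
#' @export
flim_image <- function(lifetime_map, intensity_map, fov_mm = 6.5) {
  stopifnot(is.matrix(lifetime_map), is.matrix(intensity_map),
            all(dim(lifetime_map) == dim(intensity_map)),
            all(is.finite(lifetime_map)), all(lifetime_map > 0),
            all(is.finite(intensity_map)), all(intensity_map >= 0),
            nrow(lifetime_map) == ncol(lifetime_map))
  structure(list(lifetime_map = lifetime_map, intensity_map = intensity_map,
                 fov_mm = fov_mm,
                 pixel_size_mm = fov_mm / nrow(lifetime_map)),
            class = "flim_image")
}

#' Square region of interest
#'
#' Coordinates in mm with the origin at the image top-left corner, x
#' rightward (columns) and y downward (rows).
#'
#' @param center_x_mm,center_y_mm ROI center.
#' @param side_mm Side length (default 0.6 mm).
#' @return Object of class `flim_roi`.
#' @export
flim_roi <- function(center_x_mm, center_y_mm, side_mm = 0.6) {
  stopifnot(side_mm > 0)
  structure(list(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
                 side_mm = side_mm),
            class = "flim_roi")
}

roi_pixel_mask <- function(image, roi) {
  n <- nrow(image$lifetime_map)
  px <- image$pixel_size_mm
  x0 <- roi$center_x_mm - roi$side_mm / 2
  x1 <- roi$center_x_mm + roi$side_mm / 2
  y0 <- roi$center_y_mm - roi$side_mm / 2
  y1 <- roi$center_y_mm + roi$side_mm / 2
  if (x0 < -1e-9 || y0 < -1e-9 || x1 > image$fov_mm + 1e-9 ||
      y1 > image$fov_mm + 1e-9) {
    stop("ROI extends outside the field of view")
  }
  centers <- (seq_len(n) - 0.5) * px
  # pixel centers inside the square, half-open on the max edges
  col_in <- centers >= x0 & centers < x1
  row_in <- centers >= y0 & centers < y1
  outer(row_in, col_in, `&`)
}

#' Intensity-weighted mean lifetime over an ROI
#'
#' @param image A [flim_image()].
#' @param roi A [flim_roi()]; must lie fully inside the field of view.
#' @return Weighted mean lifetime in ns.
#' @export
roi_mean_lifetime <- function(image, roi) {
  stopifnot(inherits(image, "flim_image"), inherits(roi, "flim_roi"))
  mask <- roi_pixel_mask(image, roi)
  if (!any(mask)) stop("ROI covers no pixel centers")
  w <- image$intensity_map[mask]
  if (sum(w) <= 0) stop("zero total intensity inside the ROI")
  sum(image$lifetime_map[mask] * w) / sum(w)
}

#' Simulate one FLIM image for a cohort sample
#'
#' Background pixels are drawn around the sample's lifetime with Gaussian
#' pixel noise; an optional circular hotspot (as seen for focal lesions)
#' carries an elevated lifetime. The paired intensity map is drawn
#' log-normally around `intensity_mv` (mV_RMS).
#'
#' @param tau_ns Sample (background) lifetime in ns.
#' @param fov_mm Field of view in mm (square, default 6.5).
#' @param n_pixels Pixels per side (>= 4).
#' @param hotspot Optional list with `fraction` (area fraction in `[0, 1)`),
#'   `tau_ns` (hotspot lifetime) and optionally `center_mm` (length-2).
#' @param pixel_sd_ns SD of the per-pixel lifetime noise.
#' @param intensity_mv Mean demodulated intensity in mV_RMS.
#' @return A [flim_image()].
#' @export
generate_flim_image <- function(tau_ns, fov_mm = 6.5, n_pixels = 64,
                                hotspot = NULL, pixel_sd_ns = 0.05,
                                intensity_mv = 100) {
  stopifnot(n_pixels >= 4, tau_ns > 0)
  lifetime <- matrix(stats::rnorm(n_pixels^2, tau_ns, pixel_sd_ns),
                     n_pixels, n_pixels)
  intensity <- matrix(stats::rlnorm(n_pixels^2, log(intensity_mv), 0.2),
                      n_pixels, n_pixels)
  if (!is.null(hotspot)) {
    frac <- hotspot$fraction %||% 0.02
    if (frac < 0 || frac >= 1) stop("hotspot fraction must lie in [0, 1)")
    radius <- sqrt(frac / pi) * fov_mm
    if (2 * radius > fov_mm) stop("hotspot larger than the field of view")
    center <- hotspot$center_mm %||% c(fov_mm / 2, fov_mm / 2)
    px <- fov_mm / n_pixels
    centers <- (seq_len(n_pixels) - 0.5) * px
    dist2 <- outer((centers - center[2])^2, (centers - center[1])^2, `+`)
    mask <- dist2 <= radius^2
    lifetime[mask] <- stats::rnorm(sum(mask), hotspot$tau_ns, pixel_sd_ns)
  }
  lifetime[lifetime <= 0.01] <- 0.01
  flim_image(lifetime, intensity, fov_mm = fov_mm)
}

# Fixed storage scales for the 2-page 32-bit float TIFF: page values are
# stored divided by these so they fall inside the writer's [0, 1] contract.
FLIM_TIFF_LIFETIME_SCALE_NS <- 25
FLIM_TIFF_INTENSITY_SCALE_MV <- 1000

#' Read / write a FLIM image as a 2-page 32-bit float TIFF
#'
#' Page 1 holds the lifetime map (ns), page 2 the demodulated intensity
#' (mV_RMS). Values are stored divided by fixed scales (25 ns, 1000 mV_RMS)
#' so they fit the float writer's `[0, 1]` storage contract; the reader
#' restores physical units.
#'
#' @param image A [flim_image()].
#' @param path File path.
#' @param fov_mm Field of view assumed when reading.
#' @return `write_flim_tiff` returns `path` invisibly; `read_flim_tiff`
#'   returns a [flim_image()].
#' @export
write_flim_tiff <- function(image, path) {
  stopifnot(inherits(image, "flim_image"))
  pages <- list(image$lifetime_map / FLIM_TIFF_LIFETIME_SCALE_NS,
                image$intensity_map / FLIM_TIFF_INTENSITY_SCALE_MV)
  if (any(vapply(pages, max, numeric(1)) > 1)) {
    stop("values exceed the fixed TIFF storage scales")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read / write an ROI list as YAML
#'
#' Each entry carries `center_x_mm`, `center_y_mm` and `side_mm`.
#'
#' @param rois List of [flim_roi()] objects.
#' @param path File path.
#' @return `write_roi_yaml` returns `path` invisibly; `read_roi_yaml`
#'   returns a list of [flim_roi()] objects.
#' @export
write_roi_yaml <- function(rois, path) {
  yaml::write_yaml(list(rois = lapply(rois, unclass)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_roi_yaml
#' @export
read_roi_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  lapply(obj$rois, function(r) {
    flim_roi(r$center_x_mm, r$center_y_mm, r$side_mm %||% 0.6)
  })
}

#' @rdname write_flim_tiff
#' @export
read_flim_tiff <- function(path, fov_mm = 6.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2) stop("FLIM TIFF must have exactly 2 pages")
  flim_image(pages[[1]] * FLIM_TIFF_LIFETIME_SCALE_NS,
             pages[[2]] * FLIM_TIFF_INTENSITY_SCALE_MV,
             fov_mm = fov_mm)
}
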