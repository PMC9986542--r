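# Photophysical forward model: endogenous fluorophore library, Gaussian
# emission shapes, and the latent glycolytic-index -> abundance map.

#' Construct a fluorophore component
#'
#' An emission model for one endogenous fluorophore species: a sum of
#' Gaussian sub-peaks, a relative quantum yield, and a set of exponential
#' lifetime components with intensity fractions.
#'
#' @param name One of `"NADH_free"`, `"NADH_bound"`, `"FMN_bound"`, `"FAD"`.
#' @param subpeaks `data.frame` with columns `center` (nm), `fwhm` (nm, > 0)
#'   and `rel_amplitude` (unitless, the main peak should be 1).
#' @param quantum_yield_rel Relative quantum yield (> 0); only ratios between
#'   species matter.
#' @param lifetime_components `data.frame` with columns `tau_ns` (> 0) and
#'   `fraction` (intensity fraction, must sum to 1).
#' @param is_flavin Logical; flavin species contribute to the 500-580 nm
#'   lifetime band.
#' @return An object of class `fluorophore_component`.
#' @export
fluorophore_component <- function(name, subpeaks, quantum_yield_rel,
                                  lifetime_components, is_flavin = FALSE) {
  stopifnot(
    name %in% c("NADH_free", "NADH_bound", "FMN_bound", "FAD"),
    is.data.frame(subpeaks),
    all(c("center", "fwhm", "rel_amplitude") %in% names(subpeaks)),
    all(subpeaks$fwhm > 0), all(subpeaks$rel_amplitude > 0),
    is.data.frame(lifetime_components),
    all(c("tau_ns", "fraction") %in% names(lifetime_components)),
    all(lifetime_components$tau_ns > 0)
  )
  stop_if_not_scalar_number(quantum_yield_rel, "quantum_yield_rel")
  if (quantum_yield_rel <= 0) stop("quantum_yield_rel must be > 0")
  if (abs(sum(lifetime_components$fraction) - 1) > 1e-8) {
    stop("lifetime component fractions must sum to 1")
  }
  structure(
    list(name = name, subpeaks = subpeaks,
         quantum_yield_rel = quantum_yield_rel,
         lifetime_components = lifetime_components,
         is_flavin = isTRUE(is_flavin)),
    class = "fluorophore_component"
  )
}

#' Default endogenous fluorophore library
#'
#' Emission peaks follow the fluorophore assignments used throughout the
#' analysis: free NAD(P)H at 462 nm, protein-bound FMN with its main peak at
#' 495 nm and a side peak near 530 nm, and FAD at 530 nm. Protein-bound FMN
#' carries a tenfold higher quantum yield than FAD and a single long
#' lifetime component of 4.7 ns; FAD combines a dominant short component of
#' 0.3 ns (protein-bound, OXPHOS regime) with a 2.5 ns free-FAD component.
#'
#' Shape widths (FWHM 60 nm for NAD(P)H, 40 nm for the FMN main peak, 45 nm
#' for FAD, 60 nm for the broad FMN side peak at relative amplitude 0.55)
#' and the FAD short-component fraction are configuration parameters, since
#' only the peak positions, the quantum-yield ratio and the lifetime
#' components are physically anchored.
#'
#' @param fwhm_nadh,fwhm_fmn,fwhm_fmn_side,fwhm_fad Peak widths in nm.
#' @param fmn_side_amplitude Relative amplitude of the FMN 530 nm side peak.
#' @param fad_short_fraction Intensity fraction of the 0.3 ns FAD component.
#' @return Named list of [fluorophore_component()] objects.
#' @export
fluorophore_library <- function(fwhm_nadh = 60, fwhm_fmn = 40,
                                fwhm_fmn_side = 60, fwhm_fad = 45,
                                fmn_side_amplitude = 0.55,
                                fad_short_fraction = 0.8) {
  lib <- list(
    NADH_free = fluorophore_component(
      "NADH_free",
      data.frame(center = 462, fwhm = fwhm_nadh, rel_amplitude = 1),
      quantum_yield_rel = 1,
      lifetime_components = data.frame(tau_ns = 0.4, fraction = 1)
    ),
    NADH_bound = fluorophore_component(
      "NADH_bound",
      data.frame(center = 445, fwhm = fwhm_nadh, rel_amplitude = 1),
      quantum_yield_rel = 1,
      lifetime_components = data.frame(tau_ns = 2.4, fraction = 1)
    ),
    FMN_bound = fluorophore_component(
      "FMN_bound",
      data.frame(center = c(495, 530), fwhm = c(fwhm_fmn, fwhm_fmn_side),
                 rel_amplitude = c(1, fmn_side_amplitude)),
      quantum_yield_rel = 10,
      lifetime_components = data.frame(tau_ns = 4.7, fraction = 1),
      is_flavin = TRUE
    ),
    FAD = fluorophore_component(
      "FAD",
      data.frame(center = 530, fwhm = fwhm_fad, rel_amplitude = 1),
      quantum_yield_rel = 1,
      lifetime_components = data.frame(
        tau_ns = c(0.3, 2.5),
        fraction = c(fad_short_fraction, 1 - fad_short_fraction)
      ),
      is_flavin = TRUE
    )
  )
  validate_fluorophore_library(lib)
  lib
}

validate_fluorophore_library <- function(components) {
  stopifnot(is.list(components), length(components) > 0)
  nm <- vapply(components, function(cc) cc$name, character(1))
  if (all(c("FMN_bound", "FAD") %in% nm)) {
    ratio <- components[[which(nm == "FMN_bound")]]$quantum_yield_rel /
      components[[which(nm == "FAD")]]$quantum_yield_rel
    if (abs(ratio - 10) > 1e-8) {
      stop("FMN_bound quantum yield must be 10 times the FAD quantum yield")
    }
  }
  invisible(components)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Unit-amplitude emission shape of one component on a wavelength grid
# (excludes the quantum yield).
component_shape <- function(component, wavelengths) {
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(component$subpeaks))) {
    p <- component$subpeaks[i, ]
    s <- fwhm_to_sigma(p$fwhm)
    out <- out + p$rel_amplitude * exp(-(wavelengths - p$center)^2 / (2 * s^2))
  }
  out
}

#' Default spectrometer wavelength grid
#'
#' @param by Grid spacing in nm.
#' @return Numeric vector covering 430-740 nm.
#' @export
wavelength_grid <- function(by = 1) seq(430, 740, by = by)

#' Forward emission spectrum of a fluorophore mixture
#'
#' Evaluates `sum_f abundance_f * quantum_yield_f * shape_f(lambda)` on the
#' wavelength grid. Abundances are concentration-equivalents in arbitrary
#' units; the resulting intensities are arbitrary fluorescence units.
#'
#' @param components Fluorophore library (named list, see
#'   [fluorophore_library()]).
#' @param abundances Named non-negative numeric vector; names must be a
#'   subset of the library names. Must not be empty.
#' @param wavelengths Strictly increasing grid in nm within `[430, 740]`.
#' @return A `fl_spectrum` object (see [fl_spectrum()]).
#' @export
emission_spectrum <- function(components, abundances,
                              wavelengths = wavelength_grid()) {
  if (length(abundances) == 0) stop("abundance map must not be empty")
  if (is.null(names(abundances)) || any(!nzchar(names(abundances)))) {
    stop("abundances must be a named vector")
  }
  if (any(!is.finite(abundances)) || any(abundances < 0)) {
    stop("abundances must be finite and non-negative")
  }
  unknown <- setdiff(names(abundances), names(components))
  if (length(unknown)) {
    stop("unknown fluorophore(s): ", paste(unknown, collapse = ", "))
  }
  check_grid(wavelengths)
  intensity <- numeric(length(wavelengths))
  for (nm in names(abundances)) {
    cc <- components[[nm]]
    intensity <- intensity +
      abundances[[nm]] * cc$quantum_yield_rel * component_shape(cc, wavelengths)
  }
  fl_spectrum(wavelengths, intensity)
}

check_grid <- function(wavelengths) {
  stopifnot(is.numeric(wavelengths), length(wavelengths) >= 2)
  if (any(diff(wavelengths) <= 0)) stop("wavelength grid must be strictly increasing")
  if (min(wavelengths) < 430 - 1e-9 || max(wavelengths) > 740 + 1e-9) {
    stop("wavelength grid must lie within [430, 740] nm")
  }
  invisible(wavelengths)
}

#' Latent glycolytic index to fluorophore composition
#'
#' Affine interpolation between two boundary compositions: an
#' OXPHOS-dominated state at `g = 0` (FAD-rich) and a glycolytic state at
#' `g = 1` (rich in free NAD(P)H and protein-bound FMN). Along this path the
#' free NAD(P)H and FMN abundances are non-decreasing and the FAD abundance
#' is non-increasing, with floors at zero. The default endpoints are the
#' calibrated central compositions of the control and meningioma groups
#' (normalized to unit total), the two extremes of the cohort in redox space.
#'
#' @param g Glycolytic index in `[0, 1]` (vectorized).
#' @param endpoints List with named numeric vectors `g0` and `g1` (same
#'   names) giving the boundary abundances.
#' @return Matrix with one row per `g` value, one column per fluorophore.
#' @export
abundance_map <- function(g, endpoints = default_abundance_endpoints()) {
  if (any(!is.finite(g)) || any(g < 0) || any(g > 1)) {
    stop("glycolytic index g must lie in [0, 1]")
  }
  stopifnot(identical(names(endpoints$g0), names(endpoints$g1)))
  a0 <- endpoints$g0
  a1 <- endpoints$g1
  out <- outer(1 - g, a0) + outer(g, a1)
  out[out < 0] <- 0
  colnames(out) <- names(a0)
  rownames(out) <- NULL
  out
}

#' Default abundance-path endpoints
#'
#' Unit-total compositions for the `g = 0` (control-like, FAD-rich) and
#' `g = 1` (meningioma-like, NAD(P)H/FMN-rich) ends of the metabolic path,
#' as obtained from the anchor calibration of the default presets.
#'
#' @return List with elements `g0` and `g1`.
#' @export
default_abundance_endpoints <- function() {
  ep <- .redoxflim_cache$abundance_endpoints
  if (!is.null(ep)) return(ep)
  presets <- default_presets()
  attr(presets, "abundance_endpoints")
}

.redoxflim_cache <- new.env(parent = emptyenv())
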