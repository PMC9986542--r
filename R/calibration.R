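# Calibration of the synthetic-cohort generator: per-group quartile targets
# for the three metrics, average-spectrum peak anchors, and the latent
# coupling that sets the pooled R_flavin-vs-RR correlation.

#' Cohort quartile targets for the three metrics
#'
#' Per-group (CTL, LGG, HGG, MNG, MET) 0.25/0.5/0.75 quantile targets for
#' the optical redox ratio, the protein-bound FMN to FAD ratio and the
#' flavin fluorescence lifetime (ns), i.e. the descriptive statistics the
#' generator is calibrated to reproduce.
#'
#' @return `data.frame` with columns `group`, `metric`, `q25`, `q50`, `q75`.
#' @export
table2_targets <- function() {
  tab <- rbind(
    data.frame(metric = "redox_ratio",
               group = GROUP_LEVELS,
               q25 = c(0.82, 0.69, 0.73, 0.61, 0.76),
               q50 = c(0.83, 0.71, 0.76, 0.67, 0.80),
               q75 = c(0.84, 0.73, 0.79, 0.72, 0.83)),
    data.frame(metric = "r_flavin",
               group = GROUP_LEVELS,
               q25 = c(0.85, 1.17, 0.98, 1.16, 0.85),
               q50 = c(0.86, 1.22, 1.06, 1.29, 0.94),
               q75 = c(0.97, 1.31, 1.16, 1.53, 1.08)),
    data.frame(metric = "tau_ns",
               group = GROUP_LEVELS,
               q25 = c(1.34, 2.31, 2.07, 3.44, 2.09),
               q50 = c(1.43, 2.71, 2.31, 4.06, 2.41),
               q75 = c(1.69, 2.97, 2.60, 4.72, 2.78))
  )
  tab[, c("group", "metric", "q25", "q50", "q75")]
}

#' Average-spectrum peak anchors
#'
#' Relative spectral intensities of the group-average spectra at the free
#' NAD(P)H (462 nm), protein-bound FMN (495 nm) and FAD / FMN side (530 nm)
#' peaks, normalized to the global maximum across groups.
#'
#' @return Numeric matrix, groups x peaks (`"462"`, `"495"`, `"530"`).
#' @export
spectral_anchors <- function() {
  m <- rbind(
    CTL = c(0.15, 0.28, 0.30),
    LGG = c(0.29, 0.47, 0.38),
    HGG = c(0.27, 0.44, 0.40),
    MNG = c(0.69, 1.00, 0.72),
    MET = c(0.18, 0.33, 0.34)
  )
  colnames(m) <- c("462", "495", "530")
  m
}

#' Pooled correlation target between R_flavin and the redox ratio
#' @return A single number.
#' @export
pooled_correlation_target <- function() -0.87

# Window-averaged unit-amplitude response of each active species at the
# anchor wavelengths: the calibration design matrix.
anchor_design_matrix <- function(components, bands,
                                 wavelengths = wavelength_grid()) {
  species <- c("NADH_free", "FMN_bound", "FAD")
  peaks <- c(462, bands$peak_fmn, bands$peak_fad)
  M <- sapply(species, function(nm) {
    sp <- fl_spectrum(wavelengths, component_shape(components[[nm]], wavelengths))
    vapply(peaks, function(p) peak_intensity(sp, p, bands$peak_window), numeric(1))
  })
  rownames(M) <- as.character(peaks)
  M
}

#' Calibrate group presets to cohort targets
#'
#' Three calibration stages:
#' \enumerate{
#'   \item Metric marginals: a quantile-anchored two-piece normal per
#'     group x metric, matching the `(q25, median, q75)` targets exactly.
#'   \item Spectral composition: per group, the amplitudes of free NAD(P)H,
#'     protein-bound FMN and FAD are solved from the linear system that
#'     makes the noiseless group spectrum meet the 462/495/530 nm anchors
#'     (window-averaged, common arbitrary units across groups).
#'   \item Latent coupling: the loading of the shared glycolytic factor in
#'     the Gaussian copula is tuned by a one-dimensional search (common
#'     random numbers, oversized draw) so the pooled Pearson correlation of
#'     R_flavin vs RR at the design group sizes matches the target.
#' }
#'
#' @param targets Quartile targets as from [table2_targets()].
#' @param anchors Peak anchors as from [spectral_anchors()].
#' @param pooled_r Pooled correlation target.
#' @param components Fluorophore library.
#' @param bands A [band_definition()].
#' @param f_mod Modulation frequency in Hz used for forward lifetimes.
#' @param seed Seed for the coupling search draws.
#' @param coupling_tol Maximal acceptable `|achieved - target|` for the
#'   pooled correlation at the oversized calibration draw.
#' @return Object of class `cohort_presets`: one preset per group plus
#'   attributes `coupling`, `components`, `bands`, `f_mod`,
#'   `abundance_endpoints` and a calibration `report` (anchor residuals,
#'   central metrics, achieved pooled correlation).
#' @export
calibrate_presets <- function(targets = table2_targets(),
                              anchors = spectral_anchors(),
                              pooled_r = pooled_correlation_target(),
                              components = fluorophore_library(),
                              bands = band_definition(),
                              f_mod = 1e7,
                              seed = 20230220L,
                              coupling_tol = 0.03) {
  groups <- GROUP_LEVELS
  if (!all(groups %in% rownames(anchors))) stop("anchors must cover all five groups")
  miss <- setdiff(as.vector(outer(groups, METRIC_NAMES, paste)),
                  paste(targets$group, targets$metric))
  if (length(miss)) stop("incomplete quartile targets: ", paste(miss, collapse = "; "))

  ## stage 1: metric marginals
  marginals <- lapply(groups, function(gr) {
    out <- lapply(METRIC_NAMES, function(me) {
      row <- targets[targets$group == gr & targets$metric == me, ]
      fit_two_piece(row$q25, row$q50, row$q75)
    })
    names(out) <- METRIC_NAMES
    out
  })
  names(marginals) <- groups

  ## stage 2: spectral composition from anchors (linear solve per group)
  M <- anchor_design_matrix(components, bands)
  amplitudes <- t(apply(anchors[groups, , drop = FALSE], 1,
                        function(a) solve(M, a)))
  colnames(amplitudes) <- colnames(M)
  if (any(amplitudes < 0)) {
    bad <- groups[apply(amplitudes < 0, 1, any)]
    stop("anchor calibration infeasible (negative amplitude) for: ",
         paste(bad, collapse = ", "))
  }
  qy <- vapply(colnames(amplitudes),
               function(nm) components[[nm]]$quantum_yield_rel, numeric(1))
  abundances <- sweep(amplitudes, 2, qy, `/`)
  central_abundances <- lapply(groups, function(gr) {
    ab <- c(abundances[gr, ], NADH_bound = 0)
    ab[names(components)]
  })
  names(central_abundances) <- groups

  # metabolic path endpoints: control-like (g = 0) to meningioma-like
  # (g = 1) compositions, scaled to unit total emission amplitude
  amp_tot <- rowSums(amplitudes)
  endpoints <- list(
    g0 = central_abundances$CTL / amp_tot["CTL"],
    g1 = central_abundances$MNG / amp_tot["MNG"],
    brightness = c(g0 = unname(amp_tot["CTL"]), g1 = unname(amp_tot["MNG"]))
  )

  # central forward metrics per group, and group positions on the g path
  central <- do.call(rbind, lapply(groups, function(gr) {
    sp <- emission_spectrum(components, central_abundances[[gr]])
    data.frame(group = gr,
               redox_ratio = redox_ratio(sp, bands),
               r_flavin = r_flavin(sp, bands),
               tau_ns = flavin_lifetime_of_state(central_abundances[[gr]],
                                                 components, f_mod = f_mod))
  }))
  rr_of_g <- function(g) {
    ab <- abundance_map(g, endpoints)[1, ]
    redox_ratio(emission_spectrum(components, ab), bands)
  }
  rr_range <- c(rr_of_g(0), rr_of_g(1))
  g_center <- vapply(seq_along(groups), function(i) {
    target_rr <- central$redox_ratio[i]
    if (target_rr >= max(rr_range)) return(0)
    if (target_rr <= min(rr_range)) return(1)
    stats::uniroot(function(g) rr_of_g(g) - target_rr, c(0, 1),
                   tol = 1e-8)$root
  }, numeric(1))
  slope <- (rr_range[2] - rr_range[1])
  g_scale <- vapply(seq_along(groups), function(i) {
    row <- targets[targets$group == groups[i] & targets$metric == "redox_ratio", ]
    min(0.25, (row$q75 - row$q25) / abs(slope) / (2 * stats::qnorm(0.75)))
  }, numeric(1))

  ## stage 3: latent coupling from the pooled correlation
  withr_seed <- derive_seed(seed, 7L)
  n_mult <- 30L
  draws <- local({
    set.seed(withr_seed)
    lapply(groups, function(gr) {
      n <- GROUP_COUNTS[[gr]] * n_mult
      list(z0 = stats::rnorm(n), e_rr = stats::rnorm(n), e_rf = stats::rnorm(n))
    })
  })
  names(draws) <- groups
  pooled_r_of <- function(lambda) {
    vals <- lapply(groups, function(gr) {
      d <- draws[[gr]]
      z_rr <- -(lambda * d$z0 + sqrt(1 - lambda^2) * d$e_rr)
      z_rf <- +(lambda * d$z0 + sqrt(1 - lambda^2) * d$e_rf)
      cbind(rr = z_two_piece(z_rr, marginals[[gr]]$redox_ratio),
            rf = z_two_piece(z_rf, marginals[[gr]]$r_flavin))
    })
    m <- do.call(rbind, vals)
    stats::cor(m[, "rf"], m[, "rr"])
  }
  opt <- stats::optimize(function(l) abs(pooled_r_of(l) - pooled_r),
                         interval = c(0, 1), tol = 1e-4)
  coupling <- opt$minimum
  achieved_r <- pooled_r_of(coupling)
  if (abs(achieved_r - pooled_r) > coupling_tol) {
    stop(sprintf(paste0("coupling calibration did not converge: achieved ",
                        "pooled r = %.4f vs target %.4f"),
                 achieved_r, pooled_r))
  }

  presets <- lapply(seq_along(groups), function(i) {
    gr <- groups[i]
    structure(list(
      name = gr,
      n_points = GROUP_COUNTS[[gr]],
      marginals = marginals[[gr]],
      central_abundances = central_abundances[[gr]],
      amplitude_total = unname(amp_tot[gr]),
      g_center = g_center[i],
      g_scale = g_scale[i],
      g_skew = 0,
      spectral_noise_sd = 0.02,
      histo_props = if (gr == "CTL") c(none = 1) else
        c(TUM = 0.55, INF = 0.20, NEC = 0.15, REA = 0.10)
    ), class = "group_preset")
  })
  names(presets) <- groups

  # residual report: anchors after global-max normalization
  norm_spec <- group_central_spectra_internal(central_abundances, components)
  achieved_anchors <- t(vapply(groups, function(gr) {
    vapply(c(462, bands$peak_fmn, bands$peak_fad), function(p) {
      peak_intensity(norm_spec[[gr]], p, bands$peak_window)
    }, numeric(1))
  }, numeric(3)))
  colnames(achieved_anchors) <- colnames(anchors)
  report <- list(
    anchor_targets = anchors[groups, , drop = FALSE],
    anchor_achieved = achieved_anchors,
    anchor_residuals = achieved_anchors - anchors[groups, , drop = FALSE],
    central_metrics = central,
    coupling = coupling,
    pooled_r_target = pooled_r,
    pooled_r_achieved = achieved_r
  )

  structure(presets, class = "cohort_presets",
            coupling = coupling, components = components, bands = bands,
            f_mod = f_mod, abundance_endpoints = endpoints, report = report,
            seed = seed)
}

group_central_spectra_internal <- function(central_abundances, components,
                                           wavelengths = wavelength_grid()) {
  spectra <- lapply(central_abundances, function(ab) {
    emission_spectrum(components, ab, wavelengths)
  })
  average_group_spectra(spectra, names(spectra))
}

#' Noiseless group-average spectra of calibrated presets
#'
#' Builds the forward-model emission spectrum at each group's central
#' metabolic composition and normalizes all groups by the single global
#' maximum ("relative spectral intensity").
#'
#' @param presets A [calibrate_presets()] object.
#' @param wavelengths Wavelength grid in nm.
#' @return Named list of normalized [fl_spectrum()] objects.
#' @export
group_central_spectra <- function(presets, wavelengths = wavelength_grid()) {
  stopifnot(inherits(presets, "cohort_presets"))
  ab <- lapply(presets, function(p) p$central_abundances)
  sp <- group_central_spectra_internal(ab, attr(presets, "components"),
                                       wavelengths)
  out <- sp[names(presets)]
  attr(out, "global_max") <- attr(sp, "global_max")
  out
}

#' Default calibrated presets
#'
#' Calibrates once against the built-in targets and caches the result for
#' the session.
#'
#' @return A `cohort_presets` object.
#' @export
default_presets <- function() {
  p <- .redoxflim_cache$default_presets
  if (is.null(p)) {
    p <- calibrate_presets()
    .redoxflim_cache$default_presets <- p
    .redoxflim_cache$abundance_endpoints <- attr(p, "abundance_endpoints")
  }
  p
}

#' @export
print.cohort_presets <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("<cohort_presets: %d groups, %d data points, coupling %.3f, pooled r %.3f>\n",
              length(x), sum(vapply(x, function(p) p$n_points, integer(1))),
              attr(x, "coupling"), rep$pooled_r_achieved))
  invisible(x)
}
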