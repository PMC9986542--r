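# Synthetic cohort generation: latent metabolic states, metric-space and
# photophysics sampling modes, and cohort CSV / preset YAML interfaces.

HISTO_LEVELS <- c("TUM", "INF", "NEC", "REA", "none")

#' Draw latent metabolic states for one group
#'
#' Draws the glycolytic index `g` from the group's (two-piece normal)
#' latent distribution, clipped to `[0, 1]`, and maps it to fluorophore
#' abundances along the metabolic path. Uses the current RNG state; seed
#' upstream for reproducibility.
#'
#' @param preset A `group_preset` from [calibrate_presets()].
#' @param n Number of draws.
#' @param endpoints Abundance-path endpoints (see [abundance_map()]).
#' @return List with vector `g` and matrix `abundances` (n x fluorophores).
#' @export
sample_metabolic_state <- function(preset, n = 1,
                                   endpoints = default_abundance_endpoints()) {
  stopifnot(inherits(preset, "group_preset"), n >= 1)
  tp <- list(m = preset$g_center,
             sigma_left = preset$g_scale * (1 - preset$g_skew),
             sigma_right = preset$g_scale * (1 + preset$g_skew))
  class(tp) <- "two_piece"
  g <- pmin(pmax(r_two_piece(n, tp), 0), 1)
  list(g = g, abundances = abundance_map(g, endpoints))
}

#' Generate a synthetic cohort
#'
#' `metric_space` mode draws `(redox_ratio, r_flavin, tau_ns)` from the
#' calibrated quantile-anchored marginals, coupled through a shared latent
#' glycolytic score in a Gaussian copula (loading = the calibrated
#' `coupling`; the redox ratio loads negatively, R_flavin and the lifetime
#' positively) plus independent noise. `photophysics` mode draws the latent
#' index per sample, builds a noisy emission spectrum through the forward
#' model and computes the metrics with the spectral pipeline and the
#' FD-FLIM phasor estimator; it is structurally faithful but not
#' quantile-matched.
#'
#' @param presets A [calibrate_presets()] object covering all five groups.
#' @param seed Integer seed; fixed seeds give bit-identical cohorts.
#' @param mode `"metric_space"` (default) or `"photophysics"`.
#' @return `data.frame` with columns `sample_id`, `group` (factor in
#'   canonical order), `histo_sublabel`, `tau_ns`, `redox_ratio`,
#'   `r_flavin`, plus (photophysics mode) `g`. Attributes `seed` and
#'   `mode`.
#' @export
generate_cohort <- function(presets, seed = 1L,
                            mode = c("metric_space", "photophysics")) {
  mode <- match.arg(mode)
  stopifnot(inherits(presets, "cohort_presets"))
  missing_groups <- setdiff(GROUP_LEVELS, names(presets))
  if (length(missing_groups)) {
    stop("missing group preset(s): ", paste(missing_groups, collapse = ", "))
  }
  coupling <- attr(presets, "coupling")
  components <- attr(presets, "components")
  bands <- attr(presets, "bands")
  f_mod <- attr(presets, "f_mod")
  endpoints <- attr(presets, "abundance_endpoints")

  set.seed(derive_seed(seed, 1L))
  rows <- lapply(GROUP_LEVELS, function(gr) {
    p <- presets[[gr]]
    n <- p$n_points
    if (mode == "metric_space") {
      z0 <- stats::rnorm(n)
      noise <- matrix(stats::rnorm(3 * n), n, 3)
      shared <- function(dir, eps) {
        dir * (coupling * z0 + sqrt(1 - coupling^2) * eps)
      }
      rr <- z_two_piece(shared(METRIC_DIRECTIONS["redox_ratio"], noise[, 1]),
                        p$marginals$redox_ratio)
      rf <- z_two_piece(shared(METRIC_DIRECTIONS["r_flavin"], noise[, 2]),
                        p$marginals$r_flavin)
      tau <- z_two_piece(shared(METRIC_DIRECTIONS["tau_ns"], noise[, 3]),
                         p$marginals$tau_ns)
      g <- rep(NA_real_, n)
    } else {
      st <- sample_metabolic_state(p, n, endpoints)
      g <- st$g
      brightness <- (1 - g) * endpoints$brightness["g0"] +
        g * endpoints$brightness["g1"]
      wl <- wavelength_grid()
      rr <- rf <- tau <- numeric(n)
      for (i in seq_len(n)) {
        ab <- st$abundances[i, ] * brightness[i]
        sp <- emission_spectrum(components, ab, wl)
        noisy <- fl_spectrum(wl, pmax(sp$intensities *
          (1 + stats::rnorm(length(wl), 0, p$spectral_noise_sd)), 0))
        rr[i] <- redox_ratio(noisy, bands)
        rf[i] <- r_flavin(noisy, bands)
        tau[i] <- flavin_lifetime_of_state(ab, components, f_mod = f_mod) +
          stats::rnorm(1, 0, 0.05)
      }
    }
    histo <- sample(names(p$histo_props), n, replace = TRUE,
                    prob = p$histo_props)
    data.frame(
      sample_id = sprintf("%s_%03d", gr, seq_len(n)),
      group = gr,
      histo_sublabel = histo,
      tau_ns = pmax(tau, 0.05),
      redox_ratio = pmin(pmax(rr, 1e-3), 1 - 1e-3),
      r_flavin = pmax(rf, 1e-3),
      g = g,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = GROUP_LEVELS)
  out$histo_sublabel <- factor(out$histo_sublabel, levels = HISTO_LEVELS)
  if (mode == "metric_space") out$g <- NULL
  stopifnot(all(is.finite(out$tau_ns)), all(is.finite(out$redox_ratio)),
            all(is.finite(out$r_flavin)))
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  out
}

#' Read / write a cohort CSV
#'
#' Columns `sample_id, group, histo_sublabel, tau_ns, redox_ratio,
#' r_flavin`, header required, UTF-8, `'.'` decimal separator.
#'
#' @param cohort Cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort `data.frame` with validated schema.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("sample_id", "group", "histo_sublabel",
            "tau_ns", "redox_ratio", "r_flavin")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("sample_id", "group", "histo_sublabel",
                "tau_ns", "redox_ratio", "r_flavin")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_group <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("cohort CSV contains unknown group label(s): ",
         paste(bad_group, collapse = ", "))
  }
  for (col in c("tau_ns", "redox_ratio", "r_flavin")) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop("cohort CSV column `", col, "` must be finite numeric")
    }
  }
  if (any(df$tau_ns <= 0)) stop("cohort CSV column `tau_ns` must be positive")
  if (any(df$redox_ratio < 0 | df$redox_ratio > 1)) {
    stop("cohort CSV column `redox_ratio` must lie in [0, 1]")
  }
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df$histo_sublabel <- factor(df$histo_sublabel, levels = HISTO_LEVELS)
  df
}

two_piece_to_list <- function(tp) {
  list(m = tp$m, sigma_left = tp$sigma_left, sigma_right = tp$sigma_right)
}

#' Write / read calibrated presets as YAML
#'
#' Serializes the per-group marginals, central abundances and latent-path
#' parameters together with the coupling, modulation frequency and
#' abundance endpoints. The fluorophore library itself is reconstructed
#' from [fluorophore_library()] defaults on read.
#'
#' @param presets A `cohort_presets` object.
#' @param path File path.
#' @return `write_presets_yaml` returns `path` invisibly;
#'   `read_presets_yaml` returns a `cohort_presets` object.
#' @export
write_presets_yaml <- function(presets, path) {
  stopifnot(inherits(presets, "cohort_presets"))
  ep <- attr(presets, "abundance_endpoints")
  obj <- list(
    coupling = attr(presets, "coupling"),
    f_mod = attr(presets, "f_mod"),
    abundance_endpoints = list(
      g0 = as.list(ep$g0), g1 = as.list(ep$g1),
      brightness = as.list(ep$brightness)
    ),
    groups = lapply(presets, function(p) {
      list(name = p$name, n_points = p$n_points,
           marginals = lapply(p$marginals, two_piece_to_list),
           central_abundances = as.list(p$central_abundances),
           amplitude_total = p$amplitude_total,
           g_center = p$g_center, g_scale = p$g_scale, g_skew = p$g_skew,
           spectral_noise_sd = p$spectral_noise_sd,
           histo_props = as.list(p$histo_props))
    })
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_presets_yaml
#' @export
read_presets_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  presets <- lapply(obj$groups, function(p) {
    marg <- lapply(p$marginals, function(m) structure(m, class = "two_piece"))
    structure(list(
      name = p$name, n_points = as.integer(p$n_points), marginals = marg,
      central_abundances = unlist(p$central_abundances),
      amplitude_total = p$amplitude_total,
      g_center = p$g_center, g_scale = p$g_scale, g_skew = p$g_skew,
      spectral_noise_sd = p$spectral_noise_sd,
      histo_props = unlist(p$histo_props)
    ), class = "group_preset")
  })
  names(presets) <- vapply(presets, function(p) p$name, character(1))
  ep <- obj$abundance_endpoints
  structure(presets, class = "cohort_presets",
            coupling = obj$coupling,
            components = fluorophore_library(),
            bands = band_definition(),
            f_mod = obj$f_mod,
            abundance_endpoints = list(
              g0 = unlist(ep$g0), g1 = unlist(ep$g1),
              brightness = unlist(ep$brightness)
            ))
}
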