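# Forward photophysics: emission mixtures, the glycolytic-index abundance
# path, latent-state sampling and cohort generation.

test_that("emission_spectrum handles empty, zero and invalid mixtures", {
  lib <- fluorophore_library()
  zero <- emission_spectrum(lib, c(FMN_bound = 0, FAD = 0))
  expect_true(all(zero$intensities == 0))
  expect_error(emission_spectrum(lib, numeric(0)), "empty")
  expect_error(emission_spectrum(lib, c(FAD = -1)), "non-negative")
  expect_error(emission_spectrum(lib, c(nope = 1)), "unknown")
})

test_that("a pure protein-bound FMN spectrum peaks near 495 nm with a smaller side peak", {
  lib <- fluorophore_library()
  sp <- emission_spectrum(lib, c(FMN_bound = 1))
  # the additive 530 nm side peak red-shifts the combined mode by a few nm,
  # so the mode lands inside the 495 nm read window rather than exactly on it
  mode_nm <- sp$wavelengths[which.max(sp$intensities)]
  expect_lt(abs(mode_nm - 495), 5)
  i495 <- peak_intensity(sp, 495, 0)
  i530 <- peak_intensity(sp, 530, 0)
  expect_lt(i530, i495)
  expect_gt(i530, 0)
  # without the side peak the mode is exactly the main-peak center
  no_side <- fluorophore_library(fmn_side_amplitude = 1e-9)
  sp0 <- emission_spectrum(no_side, c(FMN_bound = 1))
  expect_equal(sp0$wavelengths[which.max(sp0$intensities)], 495)
})

test_that("mixture intensities match an independent term-by-term summation", {
  lib <- fluorophore_library()
  ab <- c(NADH_free = 0.3, FMN_bound = 0.05, FAD = 0.7)
  wl <- wavelength_grid()
  sp <- emission_spectrum(lib, ab, wl)

  # oracle: hand-written Gaussian sum with explicit quantum yields
  gauss <- function(l, c0, fwhm) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-(l - c0)^2 / (2 * s^2))
  }
  oracle <- 0.3 * 1 * gauss(wl, 462, 60) +
    0.05 * 10 * (gauss(wl, 495, 40) + 0.55 * gauss(wl, 530, 60)) +
    0.7 * 1 * gauss(wl, 530, 45)
  expect_equal(sp$intensities, oracle, tolerance = 1e-12)

  # the 10x FMN quantum yield: adding FMN at FAD's abundance raises I495 by
  # 10 * shape495 per abundance unit relative to the FMN-free case
  base <- emission_spectrum(lib, c(FAD = 0.7), wl)
  shape495 <- gauss(495, 495, 40) + 0.55 * gauss(495, 530, 60)
  expect_equal(peak_intensity(sp, 495, 0) - peak_intensity(base, 495, 0),
               0.3 * gauss(495, 462, 60) + 0.05 * 10 * shape495,
               tolerance = 1e-12)
})

test_that("the fluorophore library enforces the FMN/FAD quantum-yield ratio", {
  lib <- fluorophore_library()
  expect_equal(lib$FMN_bound$quantum_yield_rel / lib$FAD$quantum_yield_rel, 10)
  for (cc in lib) expect_equal(sum(cc$lifetime_components$fraction), 1)
})

test_that("abundance_map is affine with the documented boundary behavior", {
  ep <- list(g0 = c(NADH_free = 0.1, FMN_bound = 0.01, FAD = 0.5),
             g1 = c(NADH_free = 0.5, FMN_bound = 0.05, FAD = 0.2))
  expect_equal(abundance_map(0, ep)[1, ], ep$g0)
  expect_equal(abundance_map(1, ep)[1, ], ep$g1)
  expect_equal(abundance_map(0.5, ep)[1, ], (ep$g0 + ep$g1) / 2)
  expect_error(abundance_map(-0.1, ep), "\\[0, 1\\]")
  expect_error(abundance_map(1.1, ep), "\\[0, 1\\]")
})

test_that("the noiseless forward chain is strictly monotone in the glycolytic index", {
  presets <- cached_presets()
  lib <- attr(presets, "components")
  bands <- attr(presets, "bands")
  ep <- attr(presets, "abundance_endpoints")
  g <- seq(0, 1, length.out = 101)
  ab <- abundance_map(g, ep)
  rr <- rf <- tau <- numeric(length(g))
  for (i in seq_along(g)) {
    sp <- emission_spectrum(lib, ab[i, ])
    rr[i] <- redox_ratio(sp, bands)
    rf[i] <- r_flavin(sp, bands)
    tau[i] <- flavin_lifetime_of_state(ab[i, ], lib)
  }
  expect_true(all(diff(rr) < 0))
  expect_true(all(diff(rf) > 0))
  expect_true(all(diff(tau) > 0))
  # per-species path monotonicity: NAD(P)H and FMN rise, FAD falls
  expect_true(all(diff(ab[, "NADH_free"]) >= 0))
  expect_true(all(diff(ab[, "FMN_bound"]) >= 0))
  expect_true(all(diff(ab[, "FAD"]) <= 0))
})

test_that("latent-state sampling is deterministic and quantile-faithful", {
  presets <- cached_presets()
  hgg <- presets$HGG

  degenerate <- hgg
  degenerate$g_scale <- 0
  set.seed(1)
  expect_equal(sample_metabolic_state(degenerate, 50)$g,
               rep(hgg$g_center, 50))

  set.seed(7)
  a <- sample_metabolic_state(hgg, 100)
  set.seed(7)
  b <- sample_metabolic_state(hgg, 100)
  expect_identical(a, b)

  set.seed(11)
  g <- sample_metabolic_state(hgg, 10000)$g
  expect_lt(abs(median(g) - hgg$g_center), 0.02 * max(hgg$g_center, 0.1))
})

test_that("generate_cohort reproduces the cohort design and is seed-deterministic", {
  presets <- cached_presets()
  co <- generate_cohort(presets, seed = 5)
  expect_equal(nrow(co), 361)
  expect_equal(as.vector(table(co$group)), c(16L, 71L, 117L, 64L, 93L))
  expect_true(all(is.finite(co$tau_ns)) && all(co$tau_ns > 0))
  expect_true(all(co$redox_ratio >= 0 & co$redox_ratio <= 1))
  expect_true(all(co$r_flavin > 0))
  expect_identical(co, generate_cohort(presets, seed = 5))
  expect_false(identical(co$tau_ns, generate_cohort(presets, seed = 6)$tau_ns))

  broken <- presets[c("CTL", "LGG")]
  class(broken) <- "cohort_presets"
  expect_error(generate_cohort(broken, seed = 1), "missing group preset")
})

test_that("photophysics mode yields the same group structure through the spectral pipeline", {
  presets <- cached_presets()
  small <- presets
  for (g in names(small)) small[[g]]$n_points <- 12L
  co <- generate_cohort(small, seed = 9, mode = "photophysics")
  expect_equal(nrow(co), 60)
  expect_equal(as.vector(table(co$group)), rep(12L, 5))
  expect_true(all(is.finite(co$g)) && all(co$g >= 0 & co$g <= 1))
  med <- tapply(co$redox_ratio, co$group, median)
  # meningioma most glycolytic, control least, in forward mode too
  expect_lt(med[["MNG"]], med[["CTL"]])
  expect_identical(co, generate_cohort(small, seed = 9, mode = "photophysics"))
})

test_that("fully coupled metric draws collapse onto a monotone curve", {
  presets <- cached_presets()
  one <- presets
  attr(one, "coupling") <- 1
  for (g in names(one)) one[[g]]$n_points <- 400L
  co <- generate_cohort(one, seed = 3)
  for (g in levels(co$group)) {
    sub <- co[co$group == g, ]
    expect_equal(cor(sub$r_flavin, sub$redox_ratio, method = "spearman"), -1)
  }
  expect_lt(cor(co$r_flavin, co$redox_ratio), -0.95)
})

test_that("oversized draws recover the calibration quantiles", {
  presets <- cached_presets()
  big <- presets
  for (g in names(big)) big[[g]]$n_points <- 10000L
  co <- generate_cohort(big, seed = 13)
  targets <- table2_targets()
  ratio <- c()
  for (i in seq_len(nrow(targets))) {
    row <- targets[i, ]
    v <- co[[row$metric]][co$group == row$group]
    tp <- fit_two_piece(row$q25, row$q50, row$q75)
    for (p in c(0.25, 0.5, 0.75)) {
      q_hat <- quantile(v, p, names = FALSE)
      q_target <- q_two_piece(p, tp)
      z <- qnorm(p)
      sigma <- if (p < 0.5) tp$sigma_left else if (p > 0.5) tp$sigma_right
        else mean(c(tp$sigma_left, tp$sigma_right))
      f_q <- dnorm(if (p == 0.5) 0 else z) / max(sigma, 1e-12)
      se <- sqrt(p * (1 - p)) / (f_q * sqrt(10000))
      ratio <- c(ratio, abs(q_hat - q_target) / se)
    }
  }
  # per-cell 2 x Monte-Carlo-SE agreement, allowing the ~5% of the 45
  # simultaneous cells expected to exceed 2 SE by chance
  expect_gt(mean(ratio <= 2), 0.85)
  expect_lt(max(ratio), 3.5)
})

test_that("simulated FLIM images carry the sample lifetime, geometry and hotspots", {
  set.seed(21)
  img <- generate_flim_image(2.4, n_pixels = 32)
  expect_equal(img$pixel_size_mm, 6.5 / 32)
  expect_lt(abs(mean(img$lifetime_map) - 2.4), 0.05)

  set.seed(22)
  hot <- generate_flim_image(1.33, n_pixels = 96,
                             hotspot = list(fraction = 0.01, tau_ns = 3.61,
                                            center_mm = c(5, 5)))
  roi_bg <- flim_roi(1.5, 1.5)
  roi_hot <- flim_roi(5, 5, side_mm = 0.3)
  expect_lt(abs(roi_mean_lifetime(hot, roi_bg) - 1.33), 0.1)
  expect_lt(abs(roi_mean_lifetime(hot, roi_hot) - 3.61), 0.1)
  expect_error(generate_flim_image(2, hotspot = list(fraction = 1.2, tau_ns = 3)),
               "fraction")
})
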