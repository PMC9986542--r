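# Frequency-domain lifetime estimation and FLIM image / ROI handling.

test_that("phase and modulation lifetimes follow their closed forms", {
  r <- structure(list(phase = 0, modulation_depth = 1, f_mod = 1e7),
                 class = "modulated_response")
  expect_equal(phase_lifetime(r), 0)
  expect_equal(modulation_lifetime(r), 0)

  r45 <- structure(list(phase = pi / 4, modulation_depth = 0.5, f_mod = 1e7),
                   class = "modulated_response")
  expect_equal(phase_lifetime(r45), 1e9 / (2 * pi * 1e7))

  bad <- structure(list(phase = pi / 2, modulation_depth = 0.5, f_mod = 1e7),
                   class = "modulated_response")
  expect_error(phase_lifetime(bad), "physical")
  bad_m <- structure(list(phase = 0.3, modulation_depth = 0, f_mod = 1e7),
                     class = "modulated_response")
  expect_error(modulation_lifetime(bad_m), "modulation depth")
})

test_that("single-exponential round trips recover tau to machine precision", {
  for (f_mod in c(1e6, 1e7, 4e7, 1e8)) {
    for (tau in c(0.3, 1, 2.5, 4.7, 15)) {
      r <- forward_response(tau, 1, f_mod = f_mod)
      expect_equal(phase_lifetime(r), tau, tolerance = 1e-12)
      expect_equal(modulation_lifetime(r), tau, tolerance = 1e-7)
    }
  }
})

test_that("the phasor mixture matches an independent brute-force sum", {
  # oracle: direct evaluation of the normalized phasor sums
  omega <- 2 * pi * 1e7
  w <- c(0.5, 0.5)
  t_s <- c(0.3, 4.7) * 1e-9
  g <- sum(w / (1 + (omega * t_s)^2))
  s <- sum(w * omega * t_s / (1 + (omega * t_s)^2))
  tau_oracle <- tan(atan2(s, g)) / omega * 1e9

  r <- forward_response(c(0.3, 4.7), c(1, 1), f_mod = 1e7)
  expect_equal(phase_lifetime(r), tau_oracle, tolerance = 1e-12)
  expect_equal(tau_oracle, 2.41, tolerance = 0.005)

  # permutation invariance and error handling
  r2 <- forward_response(c(4.7, 0.3), c(1, 1), f_mod = 1e7)
  expect_equal(r$phase, r2$phase)
  expect_equal(r$modulation_depth, r2$modulation_depth)
  expect_error(forward_response(c(1, 2), c(0, 0)), "positive weight")
  expect_error(forward_response(c(1, 2), c(1, -1)), "non-negative")
})

test_that("phase lifetime never exceeds modulation lifetime, equality iff mono-exponential", {
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    taus <- runif(k, 0.2, 6)
    w <- runif(k)
    r <- forward_response(taus, w, f_mod = 1e7)
    tp <- phase_lifetime(r)
    tm <- modulation_lifetime(r)
    expect_lte(tp, tm + 1e-12)
    if (diff(range(taus)) > 0.1) expect_lt(tp, tm)
  }
})

test_that("flavin-band lifetime weights flavin species by band emission", {
  lib <- fluorophore_library()
  # pure FMN: single 4.7 ns component regardless of abundance
  expect_equal(flavin_lifetime_of_state(c(FMN_bound = 0.3), lib), 4.7,
               tolerance = 1e-10)
  # NAD(P)H alone carries no flavin signal
  expect_error(flavin_lifetime_of_state(c(NADH_free = 1), lib), "flavin")
  # increasing the FMN share strictly increases the apparent lifetime
  taus <- sapply(seq(0, 1, length.out = 21), function(w) {
    flavin_lifetime_of_state(c(FMN_bound = 0.001 + w, FAD = 10 * (1 - w)), lib)
  })
  expect_true(all(diff(taus) > 0))
})

test_that("ROI mean lifetimes are intensity-weighted and scale-invariant", {
  n <- 20
  life <- matrix(1, n, n)
  life[, (n / 2 + 1):n] <- 3
  inten <- matrix(1, n, n)
  img <- flim_image(life, inten, fov_mm = 2)
  expect_equal(img$pixel_size_mm, 0.1)

  whole <- flim_roi(1, 1, side_mm = 2)
  expect_equal(roi_mean_lifetime(img, whole), 2)

  homog <- flim_image(matrix(2.2, n, n), inten, fov_mm = 2)
  expect_equal(roi_mean_lifetime(homog, flim_roi(0.5, 0.5, 0.6)), 2.2)

  # 3:1 intensity weighting between the 1 ns and 3 ns halves
  w_inten <- inten
  w_inten[, 1:(n / 2)] <- 3
  weighted <- flim_image(life, w_inten, fov_mm = 2)
  expect_equal(roi_mean_lifetime(weighted, whole), (3 * 1 + 1 * 3) / 4)
  scaled <- flim_image(life, w_inten * 17, fov_mm = 2)
  expect_equal(roi_mean_lifetime(scaled, whole),
               roi_mean_lifetime(weighted, whole), tolerance = 1e-12)

  expect_error(roi_mean_lifetime(img, flim_roi(1.9, 1, side_mm = 0.5)),
               "outside")
  dark <- flim_image(life, matrix(0, n, n), fov_mm = 2)
  expect_error(roi_mean_lifetime(dark, whole), "zero total intensity")
})

test_that("ROI lists round-trip through YAML", {
  rois <- list(flim_roi(1.2, 3.4), flim_roi(5, 5, side_mm = 0.3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_roi_yaml(rois, path)
  back <- read_roi_yaml(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$center_x_mm, 1.2)
  expect_equal(back[[2]]$side_mm, 0.3)
})

test_that("FLIM images round-trip through the 2-page float TIFF", {
  set.seed(42)
  img <- generate_flim_image(3.2, n_pixels = 16)
  path <- withr::local_tempfile(fileext = ".tif")
  write_flim_tiff(img, path)
  back <- read_flim_tiff(path)
  expect_equal(back$lifetime_map, img$lifetime_map, tolerance = 1e-5)
  expect_equal(back$intensity_map, img$intensity_map, tolerance = 1e-4)
  expect_equal(back$pixel_size_mm, img$pixel_size_mm)
})
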