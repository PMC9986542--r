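# Shared fixtures. Calibration is cached per session by default_presets(),
# so repeated use across test files is cheap.

cached_presets <- function() default_presets()

# Flat spectrum at a constant intensity on the full 1 nm grid.
flat_spectrum <- function(level = 1) {
  fl_spectrum(wavelength_grid(), rep(level, length(wavelength_grid())))
}

# Smooth random spectrum on the 1 nm grid (sum of a few random Gaussians).
random_spectrum <- function(n_peaks = 4) {
  wl <- wavelength_grid()
  y <- rep(0.05, length(wl))
  for (i in seq_len(n_peaks)) {
    c0 <- runif(1, 440, 720)
    s0 <- runif(1, 10, 50)
    y <- y + runif(1, 0.2, 1) * exp(-(wl - c0)^2 / (2 * s0^2))
  }
  fl_spectrum(wl, y)
}

# Two well-separated Gaussian classes in 2-D.
separable_classes <- function(n_per_class = 60, gap = 8) {
  x <- rbind(
    matrix(rnorm(2 * n_per_class), ncol = 2),
    matrix(rnorm(2 * n_per_class) + gap, ncol = 2)
  )
  colnames(x) <- c("f1", "f2")
  y <- factor(rep(c("A", "B"), each = n_per_class))
  list(x = x, y = y)
}

# Exhaustive-enumeration Mann-Whitney oracle for small untied samples:
# one-sided p = share of group-1 subsets of the combined sample whose U
# statistic is at least (greater) / at most (less) as extreme as observed.
mwu_enumeration_p <- function(x, y, alternative = "greater") {
  u_stat <- function(a, b) sum(outer(a, b, ">"))
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_stat(x, y)
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  if (alternative == "greater") mean(u_all >= u_obs) else mean(u_all <= u_obs)
}

# Point-in-convex-hull test for 2-D points (cross-product sign against the
# chull polygon, boundary counted as inside).
in_convex_hull_2d <- function(points, cloud) {
  hull <- cloud[rev(grDevices::chull(cloud)), , drop = FALSE] # ccw order
  apply(points, 1, function(p) {
    k <- nrow(hull)
    all(vapply(seq_len(k), function(i) {
      a <- hull[i, ]
      b <- hull[if (i == k) 1 else i + 1, ]
      ((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])) >= -1e-9
    }, logical(1)))
  })
}
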