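#' @keywords internal
"_PACKAGE"

# Canonical group order used everywhere (tables, figures, confusion matrices).
GROUP_LEVELS <- c("CTL", "LGG", "HGG", "MNG", "MET")

# Data points per group in the default cohort design.
GROUP_COUNTS <- c(CTL = 16L, LGG = 71L, HGG = 117L, MNG = 64L, MET = 93L)

METRIC_NAMES <- c("redox_ratio", "r_flavin", "tau_ns")

# Direction in which each metric loads on the shared latent score:
# a more glycolytic state lowers the redox ratio and raises R_flavin and tau.
METRIC_DIRECTIONS <- c(redox_ratio = -1, r_flavin = 1, tau_ns = 1)

#' Derive a reproducible sub-seed from a master seed
#'
#' A small linear-congruential scramble keeping results inside the 32-bit
#' integer range, so one user-facing seed can drive independent random
#' stages (cohort draws, CV repeats, calibration) without reuse.
#'
#' @param seed Integer master seed.
#' @param k Integer stream index (>= 0).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, all arithmetic stays below 2^53 in doubles
  s <- abs(as.numeric(seed)) %% m
  as.integer(((s * 69069) %% m + (as.numeric(k) * 1000003) %% m) %% m)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
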