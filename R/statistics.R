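# Cohort statistics: group summaries, the one-sided Mann-Whitney-U battery
# against the control group, the Kolmogorov-Smirnov subgroup check, and the
# R_flavin-vs-redox-ratio regression.

#' Median and quartiles of a metric
#'
#' Linear interpolation between order statistics (type-7 quantiles by
#' default; the convention is switchable because quartile matching is
#' sensitive to it).
#'
#' @param values Numeric vector, `n >= 1`.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Named vector `(median, q25, q75)`.
#' @export
group_summary <- function(values, type = 7) {
  if (length(values) == 0) stop("group summary of an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = type, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' One-sided Mann-Whitney-U test of a tumor group against control
#'
#' Exact p-value (distribution of the U statistic over all rank
#' assignments) when `n1 + n2 <= 12` and there are no ties; otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param tumor_values,ctl_values Non-empty numeric vectors.
#' @param alternative `"greater"` (tumor stochastically larger than
#'   control) or `"less"`.
#' @return List with `U` (statistic for the tumor sample) and `p`.
#' @export
mwu_one_sided <- function(tumor_values, ctl_values,
                          alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(tumor_values) == 0 || length(ctl_values) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(tumor_values)
  n2 <- length(ctl_values)
  has_ties <- anyDuplicated(c(tumor_values, ctl_values)) > 0
  use_exact <- (n1 + n2 <= 12) && !has_ties
  ht <- suppressWarnings(stats::wilcox.test(
    tumor_values, ctl_values, alternative = alternative,
    exact = use_exact, correct = TRUE
  ))
  list(U = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}

#' Kolmogorov-Smirnov subgroup check after z-score normalization
#'
#' Each subgroup is normalized to mean 0 and standard deviation 1; the
#' two-sample KS test is applied to every pair, giving a matrix of
#' p-values for differences in distribution *shape* irrespective of group
#' location and scale.
#'
#' @param subgroup_values Named list of numeric vectors (>= 2 subgroups,
#'   each with >= 2 values and positive variance).
#' @return Symmetric matrix of pairwise KS p-values (diagonal = 1).
#' @export
ks_subgroup_check <- function(subgroup_values) {
  stopifnot(is.list(subgroup_values), length(subgroup_values) >= 2)
  z <- lapply(subgroup_values, function(v) {
    if (length(v) < 2) stop("each subgroup needs at least 2 values")
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0) stop("zero-variance subgroup")
    (v - mean(v)) / s
  })
  k <- length(z)
  nm <- names(z) %||% paste0("S", seq_len(k))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      pv <- suppressWarnings(stats::ks.test(z[[i]], z[[j]])$p.value)
      p[i, j] <- p[j, i] <- pv
    }
  }
  p
}

#' Linear regression of R_flavin on the redox ratio
#'
#' Ordinary least squares plus the Pearson correlation coefficient.
#'
#' @param r_flavin_values,rr_values Finite numeric vectors, `n >= 3`.
#' @return List with `pearson_r`, `slope`, `intercept`, `n`.
#' @export
metric_regression <- function(r_flavin_values, rr_values) {
  stopifnot(length(r_flavin_values) == length(rr_values))
  if (length(rr_values) < 3) stop("regression needs at least 3 points")
  if (any(!is.finite(r_flavin_values)) || any(!is.finite(rr_values))) {
    stop("regression inputs must be finite")
  }
  if (stats::sd(rr_values) <= 0) stop("zero variance in the redox ratio")
  fit <- stats::lm(r_flavin_values ~ rr_values)
  list(pearson_r = stats::cor(r_flavin_values, rr_values),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(rr_values))
}

#' Significance stars
#'
#' `"*"` for `p < 0.005`, `"**"` for `p < 1e-5`, `""` otherwise.
#'
#' @param p Vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 1e-5, "**", ifelse(p < 0.005, "*", "")))
}

# Alternative hypothesis direction per metric: tumors show a lower redox
# ratio and higher R_flavin and flavin lifetime than control tissue.
BATTERY_ALTERNATIVES <- c(redox_ratio = "less", r_flavin = "greater",
                          tau_ns = "greater")

#' Descriptive and inferential battery for a cohort
#'
#' For every group x metric: median and quartiles; for tumor groups
#' additionally the one-sided Mann-Whitney-U p-value against the control
#' group (alternatives: redox ratio lower, R_flavin and lifetime greater)
#' and significance stars. No multiple-testing correction is applied.
#'
#' @param cohort Cohort `data.frame` (see [generate_cohort()]); must
#'   contain a `CTL` group and at least one tumor group.
#' @param alpha Significance threshold recorded in the `significant`
#'   column.
#' @return `data.frame` with one row per group x metric.
#' @export
hypothesis_battery <- function(cohort, alpha = 0.05) {
  groups_present <- intersect(GROUP_LEVELS, as.character(unique(cohort$group)))
  if (!"CTL" %in% groups_present) stop("cohort is missing the CTL group")
  if (length(groups_present) < 2) stop("cohort needs at least one tumor group")
  rows <- list()
  for (metric in METRIC_NAMES) {
    ctl_values <- cohort[[metric]][cohort$group == "CTL"]
    for (gr in groups_present) {
      v <- cohort[[metric]][cohort$group == gr]
      s <- group_summary(v)
      if (gr == "CTL") {
        p <- NA_real_
      } else {
        p <- mwu_one_sided(v, ctl_values, BATTERY_ALTERNATIVES[[metric]])$p
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = gr, metric = metric, n = length(v),
        median = s[["median"]], q25 = s[["q25"]], q75 = s[["q75"]],
        p_value = p, stars = significance_stars(p),
        significant = !is.na(p) & p < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Battery table in the cohort-report layout
#'
#' Reshapes [hypothesis_battery()] output into metric blocks (rows:
#' median / quartiles / p-value) with one column per group.
#'
#' @param battery Output of [hypothesis_battery()].
#' @return `data.frame` with columns `metric`, `statistic` and one column
#'   per group.
#' @export
battery_table <- function(battery) {
  groups <- intersect(GROUP_LEVELS, unique(battery$group))
  blocks <- lapply(unique(battery$metric), function(me) {
    b <- battery[battery$metric == me, ]
    rownames(b) <- b$group
    stat_rows <- rbind(
      median = b[groups, "median"],
      q25 = b[groups, "q25"],
      q75 = b[groups, "q75"],
      p_value = b[groups, "p_value"]
    )
    df <- data.frame(metric = me, statistic = rownames(stat_rows),
                     stat_rows, stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- groups
    df
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
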