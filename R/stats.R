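#' Pole/centre asymmetry of a long-axis intensity profile
#'
#' Quantifies the relative enrichment of fluorescence (e.g. a ribosomal
#' fusion) at the cell poles as
#' `100 * (Pole_Max - Center_Min) / Pole_Max`, where `Pole_Max` is the
#' maximum intensity within the two pole windows and `Center_Min` the
#' minimum within the central window. The windows reuse the 20/60/20 axial
#' partition used for the diffusion analysis, keeping one regional
#' convention throughout.
#'
#' @param profile An [simulate_intensity_profile()] result, a numeric
#'   intensity vector (positions assumed equally spaced on `[0, 1]`), or a
#'   list/data frame with `positions` and `intensity`.
#' @param pole_fraction Fraction of the axis forming each pole window
#'   (default 0.2).
#' @return The asymmetry in percent; 0 for a flat profile. Scale-invariant:
#'   multiplying the profile by a positive constant leaves it unchanged.
#' @examples
#' ribosome_asymmetry(simulate_intensity_profile(65, 100, 60, 0))  # 40
#' @export
ribosome_asymmetry <- function(profile, pole_fraction = 0.2) {
  stopifnot(pole_fraction > 0, pole_fraction < 0.5)
  if (is.numeric(profile)) {
    profile <- list(positions = seq(0, 1, length.out = length(profile)),
                    intensity = profile)
  }
  pos <- profile$positions; int <- profile$intensity
  if (length(int) < 8) stop("profile needs at least 8 samples")
  if (any(int < 0)) stop("intensities must be >= 0")
  pole <- pos <= pole_fraction | pos >= 1 - pole_fraction
  center <- pos >= pole_fraction & pos <= 1 - pole_fraction
  pole_max <- max(int[pole])
  center_min <- min(int[center])
  if (!(pole_max > 0)) stop("asymmetry undefined: pole maximum intensity is 0")
  100 * (pole_max - center_min) / pole_max
}

#' Map a p-value to the star significance convention
#'
#' `ns` for p > 0.05, `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001, `****` for p < 0.0001.
#'
#' @param p A p-value.
#' @return A string.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Normality-gated two-sample comparison
#'
#' Compares the means of two samples the way the SMdM regional statistics
#' are compared: Shapiro-Wilk normality is tested on both samples at the 1%
#' level; if both retain normality (p > 0.01) a two-sided Student t-test
#' (equal variances) is used, otherwise a two-sided Mann-Whitney U-test.
#' Constant samples, for which the normality test is undefined, fall back to
#' Mann-Whitney and are flagged.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 3.
#' @param normality_alpha Shapiro-Wilk gate (default 0.01).
#' @param alpha Significance level for the comparison (default 0.05).
#' @return A list of class `smdm_comparison`: `branch` (`"t"` or
#'   `"mann_whitney"`), `p_value`, `significant`, `stars`, `shapiro_p`
#'   (length 2), `statistic`, `fallback` (normality test undefined).
#' @export
compare_groups <- function(sample_a, sample_b, normality_alpha = 0.01,
                           alpha = 0.05) {
  stopifnot(length(sample_a) >= 3, length(sample_b) >= 3)
  sw <- function(z) {
    if (length(unique(z)) < 3 || sd(z) == 0) return(NA_real_)
    tryCatch(shapiro.test(z)$p.value, error = function(e) NA_real_)
  }
  p_a <- sw(sample_a); p_b <- sw(sample_b)
  fallback <- is.na(p_a) || is.na(p_b)
  normal <- !fallback && p_a > normality_alpha && p_b > normality_alpha
  if (normal) {
    ht <- t.test(sample_a, sample_b, var.equal = TRUE)
    branch <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(sample_a, sample_b))
    branch <- "mann_whitney"
  }
  structure(
    list(branch = branch, p_value = ht$p.value,
         significant = ht$p.value < alpha,
         stars = significance_stars(ht$p.value),
         shapiro_p = c(a = p_a, b = p_b),
         statistic = unname(ht$statistic), fallback = fallback),
    class = "smdm_comparison"
  )
}

#' @export
print.smdm_comparison <- function(x, ...) {
  cat(sprintf("<smdm_comparison> %s-test: p = %.4g (%s)%s\n",
              if (x$branch == "t") "Student t" else "Mann-Whitney U",
              x$p_value, x$stars,
              if (x$fallback) " [normality test undefined; forced Mann-Whitney]" else ""))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table (e.g.
#' old/new pole versus fast/slow pole). Conditioning on both margins, the
#' two-sided p-value is the sum of hypergeometric probabilities of all
#' tables at most as probable as the observed one (the probability-mass
#' definition, as in `stats::fisher.test`).
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))  # 1/126
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("empty table: total count is 0")
  m <- table[1, 1] + table[1, 2]        # row-1 margin
  n2 <- table[2, 1] + table[2, 2]
  k <- table[1, 1] + table[2, 1]        # column-1 margin
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  obs <- dhyper(table[1, 1], m, n2, k)
  # standard relative tolerance for "as probable as observed"
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Linear regression of pole/middle diffusion ratio on probe mass
#'
#' Ordinary (or SEM-weighted) least squares of the pole/middle `D_L` ratio
#' on the molecular weight of the diffusing probe, with residual analysis:
#' residuals above zero indicate the fit underestimates the observation,
#' below zero that it overestimates. Optionally fits fast and slow poles
#' separately.
#'
#' @param points Data frame with columns `mw_kda` and `ratio`, optionally
#'   `sem` (used when `weighted = TRUE`, weights `1/sem^2`) and `pole_class`
#'   (used when `per_pole = TRUE`).
#' @param weighted Weight observations by `1/sem^2`.
#' @param per_pole Fit each `pole_class` separately and return a named list.
#' @return A list of class `smdm_regression`: `slope`, `intercept`,
#'   `r_squared`, `residuals`, `fitted`, `model` (the `lm` fit) and
#'   `predict_ratio(mw_kda)` for extrapolation. With `per_pole = TRUE`, a
#'   named list of such objects.
#' @export
mass_ratio_regression <- function(points, weighted = FALSE, per_pole = FALSE) {
  stopifnot(all(c("mw_kda", "ratio") %in% names(points)))
  if (per_pole) {
    stopifnot("pole_class" %in% names(points))
    cls <- split(as.data.frame(points), points$pole_class)
    return(lapply(cls, mass_ratio_regression, weighted = weighted))
  }
  if (nrow(points) < 3) stop("need at least 3 points for regression")
  if (var(points$mw_kda) == 0) stop("zero variance in molecular weight")
  if (any(points$mw_kda <= 0)) stop("molecular weights must be > 0")
  w <- if (weighted) {
    stopifnot("sem" %in% names(points), all(points$sem > 0))
    1 / points$sem^2
  } else NULL
  fit <- lm(ratio ~ mw_kda, data = as.data.frame(points), weights = w)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         residuals = unname(resid(fit)), fitted = unname(fitted(fit)),
         model = fit,
         predict_ratio = function(mw_kda) {
           unname(predict(fit, newdata = data.frame(mw_kda = mw_kda)))
         }),
    class = "smdm_regression"
  )
}

#' @export
print.smdm_regression <- function(x, ...) {
  cat(sprintf("<smdm_regression> ratio = %.4g + %.4g * MW(kDa), r^2 = %.3f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}
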