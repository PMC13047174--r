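#' Per-feature temporal moments of a longitudinal series
#'
#' @param series timepoints x features matrix of relative abundances (one
#'   subject's samples ordered in time); at least 3 time points.
#' @return A data.frame `(feature_id, mu, sigma)`: temporal mean and standard
#'   deviation (denominator `n - 1`) per feature.
#' @examples
#' temporal_moments(rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.7)))
#' @export
temporal_moments <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3) {
    stop(sprintf(
      "temporal moments need >= 3 time points; got %d", nrow(series)
    ))
  }
  ids <- colnames(series)
  if (is.null(ids)) ids <- paste0("feature", seq_len(ncol(series)))
  data.frame(
    feature_id = ids,
    mu = colMeans(series),
    sigma = apply(series, 2, stats::sd),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Fit Taylor's power law to temporal moments
#'
#' Ordinary least squares of `log10(sigma)` on `log10(mu)` across features:
#' the slope is the scale index `beta` and `10^intercept` is the variability
#' `V`, the dispersion attainable by a hypothetical feature of relative
#' abundance 1. A scale index of 1/2 indicates Poisson-like fluctuation, 1
#' exponential-like. Features with zero temporal mean or zero temporal SD
#' carry no information about the power law on the log scale and are
#' excluded; the fit fails if fewer than `min_features` remain.
#'
#' @param moments a [temporal_moments()] data.frame (or a timepoints x
#'   features relative-abundance matrix, which is converted first).
#' @param min_features minimum number of usable features (default 20).
#' @return An object of class `taylor_fit`: a list with `V`, `beta`, `se_V`,
#'   `se_beta`, `r_squared`, `n_features_used` and `n_excluded`.
#' @examples
#' mu <- 10^seq(-3, -1, length.out = 30)
#' fit_taylor(data.frame(feature_id = seq_along(mu), mu = mu, sigma = 0.2 * mu^0.8))
#' @export
fit_taylor <- function(moments, min_features = 20) {
  if (is.matrix(moments)) moments <- temporal_moments(moments)
  stopifnot(all(c("mu", "sigma") %in% names(moments)))
  use <- moments$mu > 0 & moments$sigma > 0
  n_used <- sum(use)
  if (n_used < min_features) {
    stop(sprintf(
      "only %d features have positive temporal mean and SD (minimum %d)",
      n_used, min_features
    ))
  }
  lx <- log10(moments$mu[use])
  ly <- log10(moments$sigma[use])
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit)) # exact power laws trip the perfect-fit warning
  co <- sm$coefficients
  structure(
    list(
      V = 10^co[1, 1],
      beta = co[2, 1],
      se_V = log(10) * 10^co[1, 1] * co[1, 2], # delta method on 10^intercept
      se_beta = co[2, 2],
      r_squared = sm$r.squared,
      n_features_used = n_used,
      n_excluded = sum(!use)
    ),
    class = "taylor_fit"
  )
}

#' @export
print.taylor_fit <- function(x, ...) {
  cat(sprintf(
    "<taylor_fit> V = %.4g (se %.2g), beta = %.4g (se %.2g), R^2 = %.3f, %d features (%d excluded)\n",
    x$V, x$se_V, x$beta, x$se_beta, x$r_squared, x$n_features_used, x$n_excluded
  ))
  invisible(x)
}

#' Fit Taylor's law for every subject of a cohort
#'
#' Counts are converted to relative abundances, each subject's samples are
#' ordered by time point, and [fit_taylor()] is applied per subject. Subjects
#' with fewer than 3 time points or too few usable features are skipped with
#' a warning.
#'
#' @param x a [feature_table] (counts or relative).
#' @param meta sample metadata covering `x`.
#' @param min_features passed to [fit_taylor()].
#' @return A data.frame with one row per fitted subject: `subject_id`,
#'   `group`, `V`, `beta`, `se_V`, `se_beta`, `r_squared`,
#'   `n_features_used`.
#' @export
fit_taylor_subjects <- function(x, meta, min_features = 20) {
  stopifnot(inherits(x, "feature_table"))
  meta <- validate_metadata(meta, x)
  rel <- to_relative(x)$values
  rows <- list()
  for (s in unique(meta$subject_id)) {
    ms <- meta[meta$subject_id == s, ]
    ms <- ms[order(ms$timepoint), ]
    if (nrow(ms) < 3) {
      warning(sprintf("subject '%s' has < 3 time points; skipped", s))
      next
    }
    series <- rel[ms$sample_id, , drop = FALSE]
    fit <- tryCatch(fit_taylor(temporal_moments(series), min_features),
      error = function(e) {
        warning(sprintf("subject '%s' skipped: %s", s, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) next
    rows[[s]] <- data.frame(
      subject_id = s, group = ms$group[1],
      V = fit$V, beta = fit$beta, se_V = fit$se_V, se_beta = fit$se_beta,
      r_squared = fit$r_squared, n_features_used = fit$n_features_used,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no subject could be fitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardize Taylor parameters against a reference group
#'
#' Expresses every subject's `(V, beta)` in standard-deviation units of the
#' reference group: `z_V = (V - mean_ref(V)) / sd_ref(V)`, likewise
#' `z_beta`, so reference subjects have mean 0 and SD 1 on both axes.
#'
#' @param fits a [fit_taylor_subjects()] data.frame.
#' @param reference_group group label used as the reference.
#' @return `fits` with added `z_V` and `z_beta` columns and a
#'   `reference_group` attribute.
#' @export
standardize_params <- function(fits, reference_group) {
  stopifnot(all(c("V", "beta", "group") %in% names(fits)))
  ref <- fits[fits$group == reference_group, ]
  if (nrow(ref) < 3) {
    stop(sprintf(
      "reference group '%s' has %d fits; at least 3 needed",
      reference_group, nrow(ref)
    ))
  }
  sdV <- stats::sd(ref$V)
  sdB <- stats::sd(ref$beta)
  if (sdV == 0 || sdB == 0) {
    stop("reference group has zero spread; cannot standardize")
  }
  fits$z_V <- (fits$V - mean(ref$V)) / sdV
  fits$z_beta <- (fits$beta - mean(ref$beta)) / sdB
  attr(fits, "reference_group") <- reference_group
  fits
}

#' Reference-coverage region in the standardized V-beta space
#'
#' Bivariate-normal confidence ellipse on the standardized coordinates
#' `(z_V, z_beta)` of the reference group, at the chi-square(2) quantile of
#' the requested coverage (e.g. the 68% inner region and the 98% outer
#' region of a parameter-space plot). Although such regions are often drawn
#' as circles, the region is an ellipse determined by the reference
#' covariance.
#'
#' @param fits a [standardize_params()] result, or any data.frame/matrix
#'   with `z_V` and `z_beta` columns; when `group` information and a
#'   `reference_group` attribute are present, only reference rows are used.
#' @param coverage target coverage probability (e.g. 0.68 or 0.98).
#' @return An object of class `reference_region`: list with `center`, `cov`,
#'   `radius2` (the chi-square quantile), `axes` (half-axis lengths),
#'   `angle` (radians of the major axis) and `coverage`.
#' @seealso [in_region()]
#' @export
reference_region <- function(fits, coverage = 0.68) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  z <- if (is.matrix(fits)) {
    as.data.frame(fits)
  } else {
    fits
  }
  ref_group <- attr(fits, "reference_group")
  if (!is.null(ref_group) && "group" %in% names(z)) {
    z <- z[z$group == ref_group, ]
  }
  stopifnot(all(c("z_V", "z_beta") %in% names(z)))
  pts <- cbind(z$z_V, z$z_beta)
  if (nrow(pts) < 5) {
    stop(sprintf("at least 5 reference fits needed; got %d", nrow(pts)))
  }
  S <- stats::cov(pts)
  if (det(S) < 1e-12) stop("degenerate reference covariance")
  r2 <- stats::qchisq(coverage, df = 2)
  ev <- eigen(S, symmetric = TRUE)
  structure(
    list(
      center = colMeans(pts),
      cov = S,
      radius2 = r2,
      axes = sqrt(ev$values * r2),
      angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
      coverage = coverage
    ),
    class = "reference_region"
  )
}

#' Test membership in a reference region
#'
#' @param region a [reference_region()].
#' @param z a two-column matrix/data.frame of `(z_V, z_beta)` points, or a
#'   data.frame with `z_V`/`z_beta` columns.
#' @return Logical vector: is each point inside (or on) the region?
#' @export
in_region <- function(region, z) {
  stopifnot(inherits(region, "reference_region"))
  if (is.data.frame(z) && all(c("z_V", "z_beta") %in% names(z))) {
    z <- cbind(z$z_V, z$z_beta)
  }
  z <- matrix(as.numeric(z), ncol = 2)
  stats::mahalanobis(z, region$center, region$cov) <= region$radius2
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf(
    "<reference_region> %.0f%% coverage, center (%.3f, %.3f), half-axes (%.3f, %.3f)\n",
    100 * x$coverage, x$center[1], x$center[2], x$axes[1], x$axes[2]
  ))
  invisible(x)
}
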