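# Absolute quantification: qPCR standard curves and radiotracer
# methane-oxidation rate arithmetic.
#
# A qPCR standard curve is the least-squares line of quantification cycle
# (Cq) on log10(template copies); amplification efficiency follows from the
# slope as E = 10^(-1/slope) - 1 (slope -3.3219 <=> 100%). Tracer rates
# follow the standard radiotracer convention: the fraction of added label
# recovered in product, times the methane pool, per incubation day, with
# the killed-control rate subtracted.

#' Fit a qPCR standard curve
#'
#' @param standards data.frame with `copies` (known template copies, > 0)
#'   and `cq`. At least 3 points over distinct copy numbers are required.
#' @return List of class `standard_curve`: `slope` (Cq per log10 copies),
#'   `intercept`, `r_squared`, `efficiency_pct`. A warning is emitted for
#'   efficiencies below 70% (reported regardless: field assays on
#'   inhibitor-rich environmental DNA can run far below ideal).
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("copies", "cq") %in% names(standards)))
  ok <- is.finite(standards$copies) & is.finite(standards$cq)
  standards <- standards[ok, , drop = FALSE]
  if (nrow(standards) < 3) stop("need at least 3 standard points")
  if (any(standards$copies <= 0)) stop("standard copies must be positive")
  lc <- log10(standards$copies)
  if (length(unique(lc)) < 2) stop("standards have zero variance in copies")
  fit <- lm(cq ~ lc, data = data.frame(cq = standards$cq, lc = lc))
  slope <- unname(coef(fit)[2])
  if (slope >= 0) stop("fitted slope is non-negative; not a valid dilution curve")
  eff <- (10^(-1 / slope) - 1) * 100
  if (eff < 70) {
    warning(sprintf("low amplification efficiency: %.1f%%", eff))
  }
  # R^2 computed directly (summary.lm warns on noiseless dilution series)
  sst <- sum((standards$cq - mean(standards$cq))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(fit$residuals^2) / sst
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    efficiency_pct = eff,
    n_standards = nrow(standards)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: Cq = %.4f %+.4f * log10(copies)\n  R^2 = %.4f, efficiency = %.1f%% (n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$efficiency_pct, x$n_standards))
  invisible(x)
}

#' Interpolate copy numbers from Cq values
#'
#' `copies = 10^((cq - intercept) / slope) * volume_basis`. Non-finite Cq
#' values are skipped with a warning and return `NA`.
#'
#' @param cq Numeric vector of quantification cycles.
#' @param curve A `standard_curve`.
#' @param volume_basis Multiplier converting reaction copies to the
#'   reporting basis (e.g. copies per mL of sample); default 1.
#' @return Numeric vector of copy numbers.
#' @export
copies_from_cq <- function(cq, curve, volume_basis = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  bad <- !is.finite(cq)
  if (any(bad)) warning(sum(bad), " non-finite Cq value(s) skipped")
  out <- 10^((cq - curve$intercept) / curve$slope) * volume_basis
  out[bad] <- NA_real_
  out
}

#' Quantify replicate sample groups against a standard curve
#'
#' @param samples data.frame with `label` and `cq` (one row per replicate).
#' @param curve A `standard_curve`.
#' @param volume_basis See [copies_from_cq()].
#' @return data.frame per label: `label`, `n`, `mean_copies`, `sd_copies`
#'   (sample SD, n-1 denominator; 0 for n = 1 with identical input, NA for
#'   a single replicate).
#' @export
quantify_samples <- function(samples, curve, volume_basis = 1) {
  stopifnot(is.data.frame(samples),
            all(c("label", "cq") %in% names(samples)))
  copies <- copies_from_cq(samples$cq, curve, volume_basis = volume_basis)
  groups <- split(copies, samples$label)
  out <- lapply(names(groups), function(lab) {
    x <- groups[[lab]][is.finite(groups[[lab]])]
    data.frame(label = lab, n = length(x),
               mean_copies = mean(x),
               sd_copies = if (length(x) > 1) sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of a target group in the total community
#'
#' `100 * target / total`, e.g. target-taxon 16S copies over total
#' prokaryotic 16S copies. Values above 100% are reported with a warning
#' (primer systems differ in efficiency, so this can happen in practice).
#'
#' @param target_copies,total_copies Copy numbers on the same volume basis.
#' @return Percent (full precision; display at 2 d.p.).
#' @export
group_fraction <- function(target_copies, total_copies) {
  if (any(total_copies == 0)) stop("total copies must be non-zero")
  pct <- 100 * target_copies / total_copies
  if (any(pct > 100)) warning("group fraction exceeds 100%")
  pct
}

#' Methane-oxidation rate from radiotracer incubations
#'
#' Per replicate, `rate = (a_product / a_total) * ch4_pool / days`: the
#' fraction of added labelled methane recovered in oxidation products,
#' scaled to the methane pool and normalized per day. The result is the
#' replicate mean minus the mean killed-control rate, with the sample SD
#' (n-1 denominator) of the live replicates. Negative control-corrected
#' rates are clamped to zero with a warning.
#'
#' @param samples data.frame of live incubations with `a_product` and
#'   `a_total` activity columns (same units).
#' @param controls Optional data.frame of killed controls, same columns.
#' @param ch4_pool Methane pool, nmol cm^-3.
#' @param days Incubation time in days (> 0).
#' @return List of class `rate_result`: `rate`, `sd`, `n`, `control_rate`
#'   (all nmol cm^-3 day^-1).
#' @export
aom_rate <- function(samples, controls = NULL, ch4_pool, days) {
  stopifnot(is.data.frame(samples),
            all(c("a_product", "a_total") %in% names(samples)))
  if (days <= 0) stop("`days` must be positive")
  if (ch4_pool <= 0) stop("`ch4_pool` must be positive")
  per_replicate <- function(df) {
    if (any(df$a_total <= 0)) stop("total activity must be positive")
    if (any(df$a_product < 0)) stop("product activity must be non-negative")
    if (any(df$a_product > df$a_total)) {
      stop("product activity exceeds total activity; rejecting record")
    }
    (df$a_product / df$a_total) * ch4_pool / days
  }
  rates <- per_replicate(samples)
  control_rate <- if (!is.null(controls) && nrow(controls) > 0) {
    mean(per_replicate(controls))
  } else {
    0
  }
  net <- mean(rates) - control_rate
  if (net < 0) {
    warning("control-corrected rate is negative; clamping to 0")
    net <- 0
  }
  structure(list(
    rate = net,
    sd = if (length(rates) > 1) sd(rates) else NA_real_,
    n = length(rates),
    control_rate = control_rate
  ), class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "AOM rate: %.3f +/- %.3f nmol cm^-3 day^-1 (+/- SD, n = %d; control %.3f)\n",
    x$rate, x$sd, x$n, x$control_rate))
  invisible(x)
}
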