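#' Amplification efficiency from a standard-curve slope
#'
#' For a 10-fold dilution series the fitted line CT = intercept +
#' slope * log10(dilution) has slope -1/log10(E), so
#' `E(%) = (10^(-1/slope) - 1) * 100`. A slope of -3.3219 (i.e.
#' -1/log10(2)) corresponds to perfect doubling, 100%.
#'
#' @param slope CT change per log10 dilution step; must be non-zero.
#' @return Efficiency in percent.
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope == 0) stop("slope must be non-zero")
  (10 ^ (-1 / slope) - 1) * 100
}

#' Fit a dilution standard curve
#'
#' Ordinary least squares of CT on log10 relative input (undiluted = 0,
#' 10-fold steps = -1, -2, ...). Efficiency is derived from the slope via
#' [efficiency_from_slope()]; a non-negative slope marks the curve invalid
#' and leaves the efficiency absent.
#'
#' @param points data frame (or list) with numeric `log10_dilution` and
#'   `ct`; at least 3 distinct dilution levels.
#' @param gene gene symbol, recorded on the result.
#' @return A `standard_curve`: `gene`, `slope`, `intercept`, `r_squared`,
#'   `efficiency_percent` (NA when invalid), `valid`, `n_points`.
#' @export
fit_standard_curve <- function(points, gene = NA_character_) {
  x <- points$log10_dilution
  y <- points$ct
  if (length(unique(x)) < 3)
    stop("standard curve needs at least 3 distinct dilution levels")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # plain coefficient of determination; avoids summary.lm's perfect-fit
  # warning on exact dilution series
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  valid <- slope < 0
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r2,
                 efficiency_percent = if (valid) efficiency_from_slope(slope)
                                      else NA_real_,
                 valid = valid, n_points = length(y)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("Standard curve", if (!is.na(x$gene)) paste0(" [", x$gene, "]"), ": ",
      "slope ", signif(x$slope, 5), ", R^2 ", signif(x$r_squared, 4),
      if (x$valid) paste0(", efficiency ", signif(x$efficiency_percent, 5), "%")
      else " (invalid: non-negative slope)", "\n", sep = "")
  invisible(x)
}

#' Fit standard curves for every gene in a dilution table
#'
#' @param df data frame with columns `gene`, `log10_dilution`, `ct`.
#' @return Named list of [fit_standard_curve()] results, one per gene.
#' @export
fit_standard_curves <- function(df) {
  stopifnot(all(c("gene", "log10_dilution", "ct") %in% names(df)))
  genes <- unique(df$gene)
  out <- lapply(genes, function(g)
    fit_standard_curve(df[df$gene == g, , drop = FALSE], gene = g))
  names(out) <- genes
  out
}
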