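#' NormFinder model-based stability
#'
#' Works on log2-scale expression (log2 relative quantities; with E = 2
#' this is CTmin - CT). Each sample is first centred across genes, removing
#' sample-specific loading, giving z_ij = y_ij - mean_i(y_ij).
#'
#' Single group: the per-gene variance s2_i of z across samples
#' overestimates the gene's own variance because the sample-centring mixes
#' in the other genes; the bias-corrected estimate is
#' `sigma2_i = max(0, (s2_i - mean(s2)/(k-1)) * k/(k-2))` with k genes, and
#' the stability value is `sigma_i`.
#'
#' Grouped (candidate groups = condition levels): per-group intergroup
#' deviations `d_ig = mean_j-in-g(z_ij) - weighted-grand-mean_i` (summing
#' to zero over genes within each group), per-group intragroup variances
#' via the single-group corrector within each group, the intergroup
#' variance `gamma2 = max(0, sum(d_ig^2) / ((k-1)(G-1)) -
#' mean(sigma2_ig / n_g))`, shrunken deviations
#' `d~_ig = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g)`, and the stability
#' value `rho_i = mean_g( |d~_ig| + sqrt( (sigma2_ig/n_g) * gamma2 /
#' (gamma2 + sigma2_ig/n_g) ) )`. Lower = more stable in both modes.
#'
#' @param y numeric matrix of log2 expression, genes x samples (at least 3
#'   genes), or a `quantity_matrix` (its log2 is taken).
#' @param groups `NULL` for single-group mode, otherwise a vector of group
#'   labels, one per sample; with 2+ groups every group needs at least 2
#'   samples.
#' @return A `stability_result` (method `"normfinder"`) with `$detail`:
#'   `groups`, `d_hat` (gene x group), `d_tilde`, `sigma2` (gene x group
#'   intragroup variances), `gamma2`.
#' @export
normfinder <- function(y, groups = NULL) {
  if (inherits(y, "quantity_matrix")) {
    mat <- log2(y$q)
  } else {
    mat <- as.matrix(y)
  }
  k <- nrow(mat)
  if (k < 3) stop("NormFinder needs at least 3 genes (bias corrector k/(k-2))")
  genes <- rownames(mat)
  if (is.null(genes)) genes <- paste0("g", seq_len(k))

  z <- sweep(mat, 2, colMeans(mat))   # centre each sample across genes

  # bias-corrected per-gene variances within one set of samples
  corrected_var <- function(zsub) {
    s2 <- apply(zsub, 1, stats::var)
    pmax(0, (s2 - mean(s2) / (k - 1)) * k / (k - 2))
  }

  if (is.null(groups) || length(unique(groups)) < 2) {
    sigma2 <- corrected_var(z)
    stab <- sqrt(sigma2)
    names(stab) <- genes
    return(stability_result("normfinder", stab,
                            detail = list(groups = NULL,
                                          sigma2 = sigma2, gamma2 = NA_real_,
                                          d_hat = NULL, d_tilde = NULL)))
  }

  groups <- as.character(groups)
  if (length(groups) != ncol(mat))
    stop("groups must have one label per sample")
  glev <- unique(groups)
  G <- length(glev)
  n_g <- stats::setNames(vapply(glev, function(g) sum(groups == g), 0L), glev)
  if (any(n_g < 2)) stop("every group needs at least 2 samples; too small: ",
                         paste(glev[n_g < 2], collapse = ", "))

  zbar_g <- sapply(glev, function(g) rowMeans(z[, groups == g, drop = FALSE]))
  grand <- as.vector(zbar_g %*% n_g) / sum(n_g)     # weighted by group size
  d_hat <- sweep(zbar_g, 1, grand)                  # gene x group

  sigma2 <- sapply(glev, function(g) corrected_var(z[, groups == g, drop = FALSE]))
  sigma2 <- matrix(sigma2, nrow = k, dimnames = list(genes, glev))

  var_term <- sweep(sigma2, 2, n_g, "/")            # sigma2_ig / n_g
  gamma2 <- max(0, sum(d_hat^2) / ((k - 1) * (G - 1)) - mean(var_term))
  shrink <- gamma2 / (gamma2 + var_term)
  shrink[!is.finite(shrink)] <- 0                   # gamma2 = 0, var 0
  d_tilde <- d_hat * shrink
  rho <- rowMeans(abs(d_tilde) + sqrt(var_term * shrink))
  names(rho) <- genes

  stability_result("normfinder", rho,
                   detail = list(groups = groups, d_hat = d_hat,
                                 d_tilde = d_tilde, sigma2 = sigma2,
                                 gamma2 = gamma2))
}

#' Default NormFinder grouping for a CT table
#'
#' Condition levels act as groups when every level has at least 2 samples;
#' otherwise single-group mode (`NULL`).
#'
#' @param t a [ct_table()].
#' @return Character vector of group labels or `NULL`.
#' @export
normfinder_groups <- function(t) {
  lab <- paste(t$samples$condition_set, t$samples$level, sep = ":")
  if (length(unique(lab)) >= 2 && all(table(lab) >= 2)) lab else NULL
}
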