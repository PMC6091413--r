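#' Comparative delta-CT stability
#'
#' For every gene pair (i, j) take the standard deviation across samples
#' (n - 1 divisor) of the per-sample CT difference CT_i - CT_j. A gene's
#' stability value is the mean of its pairwise SDs against all other
#' genes; lower = more stable. Operates on raw CT, the scale on which the
#' method is defined.
#'
#' @param t a collapsed [ct_table()] (or plain gene x sample CT matrix),
#'   at least 2 genes and 2 samples.
#' @return A `stability_result` (method `"deltact"`); `$detail$sd_matrix`
#'   is the symmetric pairwise SD matrix (zero diagonal).
#' @export
delta_ct <- function(t) {
  ct <- if (inherits(t, "ct_table")) {
    if (!isTRUE(t$collapsed)) stop("collapse technical replicates first")
    t$ct
  } else as.matrix(t)
  if (nrow(ct) < 2) stop("delta-CT needs at least 2 genes")
  if (ncol(ct) < 2) stop("delta-CT needs at least 2 samples")
  k <- nrow(ct)
  genes <- rownames(ct)
  sdm <- matrix(0, k, k, dimnames = list(genes, genes))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    sdm[a, b] <- sdm[b, a] <- stats::sd(ct[a, ] - ct[b, ])
  }
  stability <- rowSums(sdm) / (k - 1)
  names(stability) <- genes
  stability_result("deltact", stability, detail = list(sd_matrix = sdm))
}
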