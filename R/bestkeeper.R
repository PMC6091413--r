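#' BestKeeper descriptive stability on raw CT
#'
#' Per gene: arithmetic and geometric mean CT, min, max, the BestKeeper
#' "SD" — by default the mean absolute deviation of CT from its arithmetic
#' mean, the original tool's definition — and CV% = SD / mean * 100. The
#' BestKeeper index is the per-sample geometric mean CT over all candidate
#' genes; each gene's Pearson r (and p) against the index is reported.
#' The stability value used for ranking is the SD (ascending).
#'
#' @param t a collapsed [ct_table()], at least 2 genes and 3 samples.
#' @param sd_type `"mad"` (mean absolute deviation, default) or
#'   `"classic"` (n - 1 standard deviation).
#' @return A `stability_result` (method `"bestkeeper"`); `$detail` holds
#'   the per-gene descriptive table, the per-sample `index`, and `sd_type`.
#' @export
bestkeeper <- function(t, sd_type = c("mad", "classic")) {
  stopifnot(inherits(t, "ct_table"), isTRUE(t$collapsed))
  sd_type <- match.arg(sd_type)
  ct <- t$ct
  if (nrow(ct) < 2) stop("BestKeeper needs at least 2 genes")
  if (ncol(ct) < 3) stop("BestKeeper needs at least 3 samples")

  amean <- rowMeans(ct)
  gmean <- exp(rowMeans(log(ct)))
  sdv <- if (sd_type == "mad") rowMeans(abs(ct - amean))
         else apply(ct, 1, stats::sd)
  cv <- sdv / amean * 100
  index <- exp(colMeans(log(ct)))   # per-sample geometric mean CT

  cor_r <- cor_p <- rep(NA_real_, nrow(ct))
  for (i in seq_len(nrow(ct))) {
    if (stats::sd(ct[i, ]) > 0 && stats::sd(index) > 0) {
      ht <- stats::cor.test(ct[i, ], index)
      cor_r[i] <- unname(ht$estimate); cor_p[i] <- ht$p.value
    }
  }

  desc <- data.frame(gene = rownames(ct), geo_mean = gmean, ar_mean = amean,
                     min = apply(ct, 1, min), max = apply(ct, 1, max),
                     sd = sdv, cv_pct = cv, r = cor_r, p = cor_p,
                     row.names = NULL, stringsAsFactors = FALSE)
  stability <- stats::setNames(sdv, rownames(ct))
  stability_result("bestkeeper", stability,
                   detail = list(table = desc, index = index,
                                 sd_type = sd_type))
}
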