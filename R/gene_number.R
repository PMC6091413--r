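#' Per-sample normalization factor
#'
#' NF_s is the geometric mean of the relative quantities of the chosen
#' reference genes in sample s.
#'
#' @param q a `quantity_matrix` (or positive gene x sample matrix).
#' @param genes character vector of at least 2 gene symbols.
#' @return Named numeric vector, one NF per sample.
#' @export
normalization_factor <- function(q, genes) {
  mat <- if (inherits(q, "quantity_matrix")) q$q else as.matrix(q)
  if (length(genes) < 2) stop("a normalization factor needs at least 2 genes")
  miss <- setdiff(genes, rownames(mat))
  if (length(miss)) stop("gene(s) not in quantity matrix: ",
                         paste(miss, collapse = ", "))
  exp(colMeans(log(mat[genes, , drop = FALSE])))
}

#' geNorm pairwise variations V_n/n+1
#'
#' With genes ordered most stable first, V_n is the standard deviation
#' across samples of log2(NF_n / NF_{n+1}) for n = 2 ... n_genes - 1,
#' measuring how much adding the (n+1)-th gene changes the normalization
#' factor.
#'
#' @param q a `quantity_matrix`.
#' @param ordered_genes genes in stability order, best first (e.g. from
#'   [genorm_order()]).
#' @return Named numeric vector `V2_3, V3_4, ...`.
#' @export
pairwise_variations <- function(q, ordered_genes) {
  n <- length(ordered_genes)
  if (n < 3) stop("pairwise variation needs at least 3 ordered genes")
  v <- numeric(n - 2)
  names(v) <- paste0("V", 2:(n - 1), "_", 3:n)
  nf_n <- normalization_factor(q, ordered_genes[1:2])
  for (k in 3:n) {
    nf_next <- normalization_factor(q, ordered_genes[1:k])
    v[k - 2] <- stats::sd(log2(nf_n / nf_next))
    nf_n <- nf_next
  }
  v
}

#' Choose how many reference genes to use
#'
#' The geNorm rule: the smallest n with V_n below the cutoff (0.15 by
#' default) suffices; if no V falls below the cutoff, the n with the
#' lowest pairwise variation is recommended (ties to the smallest n).
#'
#' @param v numeric vector of pairwise variations for n = 2, 3, ... (as
#'   from [pairwise_variations()]).
#' @param cutoff V threshold, default 0.15.
#' @return List with `chosen_n` and `rule_used` (`"below_cutoff"` or
#'   `"lowest_V"`).
#' @export
choose_gene_count <- function(v, cutoff = 0.15) {
  if (!length(v)) stop("empty pairwise-variation list")
  below <- unname(which(v < cutoff))
  if (length(below)) {
    list(chosen_n = below[1] + 1L, rule_used = "below_cutoff")
  } else {
    list(chosen_n = unname(which.min(v)) + 1L, rule_used = "lowest_V")
  }
}

#' Correlation between two normalization factors
#'
#' Pearson correlation of two per-sample NF vectors, computed on the log2
#' scale by default (NF is a geometric-mean quantity); set
#' `log_scale = FALSE` for the linear-scale correlation. Used to check
#' that a small reference set (e.g. the top 3 genes) tracks the
#' theoretically optimal set.
#'
#' @param nf_a,nf_b numeric NF vectors of equal length >= 3.
#' @param log_scale correlate log2 NF (default) or linear NF.
#' @return Pearson r, or `NA` if either vector has zero variance.
#' @export
nf_correlation <- function(nf_a, nf_b, log_scale = TRUE) {
  if (length(nf_a) != length(nf_b)) stop("NF vectors differ in length")
  if (length(nf_a) < 3) stop("need at least 3 samples")
  if (log_scale) { nf_a <- log2(nf_a); nf_b <- log2(nf_b) }
  if (stats::sd(nf_a) == 0 || stats::sd(nf_b) == 0) return(NA_real_)
  stats::cor(nf_a, nf_b)
}

#' Full gene-count analysis for one condition set
#'
#' Runs [genorm()] for the stability ordering, computes the pairwise
#' variations, applies the count rule, and reports the correlation between
#' NF over the top 3 genes and NF over the chosen count (both log2- and
#' linear-scale r).
#'
#' @param q a `quantity_matrix` with at least 3 genes.
#' @param cutoff pairwise-variation threshold, default 0.15.
#' @return A `gene_count_result`: `ordered_genes`, `nf` (sample x n
#'   matrix of NF_2..NF_k), `v`, `cutoff`, `chosen_n`, `rule_used`,
#'   `recommended_genes`, `nf_correlation_r`, `nf_correlation_r_linear`.
#' @export
gene_count_analysis <- function(q, cutoff = 0.15) {
  g <- genorm(q)
  ord <- genorm_order(g)
  v <- pairwise_variations(q, ord)
  choice <- choose_gene_count(v, cutoff)
  n <- length(ord)
  nf <- sapply(2:n, function(k) normalization_factor(q, ord[1:k]))
  colnames(nf) <- paste0("NF", 2:n)
  chosen <- choice$chosen_n
  nf3 <- if (n >= 3) nf[, "NF3"] else nf[, 1]
  nfc <- nf[, paste0("NF", chosen)]
  structure(list(ordered_genes = ord, nf = nf, v = v, cutoff = cutoff,
                 chosen_n = chosen, rule_used = choice$rule_used,
                 recommended_genes = ord[seq_len(chosen)],
                 nf_correlation_r = nf_correlation(nf3, nfc),
                 nf_correlation_r_linear = nf_correlation(nf3, nfc,
                                                          log_scale = FALSE)),
            class = "gene_count_result")
}

#' @export
print.gene_count_result <- function(x, ...) {
  cat("Pairwise variations (cutoff ", x$cutoff, "):\n", sep = "")
  print(round(x$v, 4))
  cat("Chosen n = ", x$chosen_n, " (rule: ", x$rule_used, "); genes: ",
      paste(x$recommended_genes, collapse = ", "), "\n", sep = "")
  cat("NF3 vs NF", x$chosen_n, " correlation r = ",
      round(x$nf_correlation_r, 4), " (log2 scale)\n", sep = "")
  invisible(x)
}
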