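#' geNorm expression stability M with stepwise exclusion
#'
#' For genes j, k the pairwise variation V_jk is the standard deviation
#' across samples of log2(q_j / q_k); a gene's M is the mean of its V
#' against all other panel genes. The least stable gene (highest M) is
#' excluded and M recomputed on the shrinking panel until two genes remain.
#' The reported stability per gene is its M at the step it was excluded;
#' the final pair share the two-gene M and rank 1 — the convention behind
#' the tied top pairs in published geNorm tables.
#'
#' Ties for the current worst M are broken by excluding the
#' lexicographically last gene symbol (deterministic; recorded in the
#' detail block).
#'
#' @param q a `quantity_matrix` from [ct_to_quantity()], at least 3 genes
#'   and 2 samples.
#' @return A `stability_result` (method `"genorm"`). `$detail` holds
#'   `m_full` (full-panel M per gene), `exclusion_order`, `m_at_step`
#'   (M of the excluded gene at each step), and `final_pair`.
#' @export
genorm <- function(q) {
  mat <- if (inherits(q, "quantity_matrix")) q$q else as.matrix(q)
  if (nrow(mat) < 3) stop("geNorm needs at least 3 genes")
  if (ncol(mat) < 2) stop("geNorm needs at least 2 samples")
  if (any(mat <= 0)) stop("quantities must be positive")
  logq <- log2(mat)
  genes <- rownames(logq)

  m_of <- function(panel) {
    # mean over partners of SD(log2 ratio); n-1 divisor
    sub <- logq[panel, , drop = FALSE]
    k <- length(panel)
    v <- matrix(0, k, k, dimnames = list(panel, panel))
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      v[a, b] <- v[b, a] <- stats::sd(sub[a, ] - sub[b, ])
    }
    rowSums(v) / (k - 1)
  }

  m_full <- m_of(genes)
  panel <- genes
  stability <- stats::setNames(numeric(length(genes)), genes)
  exclusion_order <- character(0)
  m_at_step <- numeric(0)
  while (length(panel) > 2) {
    m <- m_of(panel)
    worst <- max(m)
    cand <- names(m)[m == worst]
    drop_gene <- sort(cand)[length(cand)]   # lexicographically last
    stability[drop_gene] <- m[drop_gene]
    exclusion_order <- c(exclusion_order, drop_gene)
    m_at_step <- c(m_at_step, m[drop_gene])
    panel <- setdiff(panel, drop_gene)
  }
  m_pair <- m_of(panel)                      # both equal V of the final pair
  stability[panel] <- m_pair

  res <- stability_result("genorm", stability,
                          detail = list(m_full = m_full,
                                        exclusion_order = exclusion_order,
                                        m_at_step = m_at_step,
                                        final_pair = panel,
                                        tie_rule = "exclude lexicographically last"))
  res
}

#' Full-panel geNorm M values (no exclusion)
#'
#' @inheritParams genorm
#' @return Named numeric vector of M per gene on the complete panel.
#' @export
genorm_m <- function(q) {
  genorm(q)$detail$m_full
}

#' geNorm stability ordering, most stable first
#'
#' Final pair first (alphabetical within the pair), then genes in reverse
#' exclusion order.
#'
#' @param g result of [genorm()].
#' @return Character vector of gene symbols.
#' @export
genorm_order <- function(g) {
  stopifnot(inherits(g, "stability_result"), g$method == "genorm")
  c(sort(g$detail$final_pair), rev(g$detail$exclusion_order))
}
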