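#' RefFinder-style geometric-mean consensus ranking
#'
#' Integrates per-method per-gene ranks into a comprehensive ranking: each
#' gene's consensus score is the geometric mean of its ranks across
#' methods, and genes are ordered ascending by that score (lower = more
#' stable). Ties in the geometric mean are broken by the arithmetic mean
#' rank, then by gene symbol.
#'
#' @param ranks gene x method matrix (or data frame) of positive integer
#'   ranks — every method must rank every gene — or a list of
#'   `stability_result` objects whose ranks are extracted.
#' @return A `consensus_result`: `ranks` (the input matrix), `geomean`
#'   per gene, `ordering` (symbols, most stable first), `final_rank`
#'   (min-tie ranks of the geometric means), `top3`.
#' @export
reffinder_consensus <- function(ranks) {
  if (is.list(ranks) && !is.data.frame(ranks) &&
      all(vapply(ranks, inherits, TRUE, "stability_result"))) {
    methods <- vapply(ranks, `[[`, "", "method")
    genes <- names(ranks[[1]]$rank)
    mat <- sapply(ranks, function(r) {
      if (!setequal(names(r$rank), genes))
        stop("method ", r$method, " does not rank the same gene set")
      r$rank[genes]
    })
    dimnames(mat) <- list(genes, methods)
    ranks <- mat
  }
  ranks <- as.matrix(ranks)
  if (ncol(ranks) < 2) stop("consensus needs at least 2 methods")
  if (anyNA(ranks)) {
    bad <- which(is.na(ranks), arr.ind = TRUE)[1, ]
    stop("missing rank for gene ", rownames(ranks)[bad[1]],
         " in method ", colnames(ranks)[bad[2]])
  }
  if (any(ranks < 1)) stop("ranks must be >= 1")
  genes <- rownames(ranks)
  if (is.null(genes)) stop("ranks must have gene row names")

  gm <- exp(rowMeans(log(ranks)))
  am <- rowMeans(ranks)
  ord <- order(gm, am, genes)
  structure(list(ranks = ranks,
                 geomean = gm,
                 ordering = genes[ord],
                 final_rank = assign_ranks(gm),
                 top3 = genes[ord][seq_len(min(3, length(genes)))]),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus ranking (geometric mean of method ranks), most stable first:\n")
  print(consensus_table(x))
  invisible(x)
}

#' Tidy consensus table
#'
#' @param x a `consensus_result`.
#' @return Data frame with gene, one rank column per method, `geomean`,
#'   `final_rank`, rows ordered by final rank then symbol.
#' @export
consensus_table <- function(x) {
  stopifnot(inherits(x, "consensus_result"))
  df <- data.frame(gene = rownames(x$ranks), x$ranks,
                   geomean = round(unname(x$geomean), 4),
                   final_rank = unname(x$final_rank),
                   row.names = NULL, stringsAsFactors = FALSE)
  names(df)[2:(1 + ncol(x$ranks))] <- paste0("rank_", colnames(x$ranks))
  df[match(x$ordering, df$gene), , drop = FALSE]
}
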