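#' Published per-method stability values and ranks (worked example data)
#'
#' Per-method stability values and min-tie ranks for ten candidate
#' reference genes of the oriental armyworm (*Mythimna separata*)
#' evaluated by geNorm, NormFinder, BestKeeper and the comparative
#' delta-CT method across nine condition sets (developmental stages,
#' larval tissues, adult tissues, rearing densities, photoperiod,
#' temperature, and the biotic / abiotic / overall pooled sets).
#' These serve as worked-example input for the consensus integration:
#' the raw CT data behind them are not public, so only the printed
#' statistics can be re-used.
#'
#' @param condition_set optional filter; default returns all sets.
#' @return Data frame with columns `condition_set`, `gene`, `method`,
#'   `stability`, `rank`.
#' @export
published_rank_tables <- function(condition_set = NULL) {
  path <- system.file("extdata", "mythimna_ranks.tsv", package = "refstab",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(condition_set)) {
    bad <- setdiff(condition_set, unique(df$condition_set))
    if (length(bad)) stop("unknown condition set(s): ",
                          paste(bad, collapse = ", "))
    df <- df[df$condition_set %in% condition_set, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Gene x method rank matrix for one published condition set
#'
#' @param condition_set one condition-set name from
#'   [published_rank_tables()].
#' @return Integer matrix, genes x methods, ready for
#'   [reffinder_consensus()].
#' @export
published_rank_matrix <- function(condition_set) {
  df <- published_rank_tables(condition_set)
  genes <- unique(df$gene)
  methods <- unique(df$method)
  m <- matrix(NA_integer_, length(genes), length(methods),
              dimnames = list(genes, methods))
  m[cbind(match(df$gene, genes), match(df$method, methods))] <- df$rank
  m
}
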