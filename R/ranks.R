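#' Competition ranks with the min-tie convention
#'
#' Ranks stability values so that lower = better (rank 1 = most stable) by
#' default. Ties share the smallest rank and the next distinct value skips
#' the used positions ("1, 1, 3" pattern), the convention used in published
#' reference-gene stability tables.
#'
#' @param values numeric vector (finite); names are preserved.
#' @param ascending if `TRUE` (default) the smallest value gets rank 1.
#' @return Integer vector of ranks, same names as `values`.
#' @export
assign_ranks <- function(values, ascending = TRUE) {
  if (!all(is.finite(values))) stop("stability values must be finite")
  v <- if (ascending) values else -values
  r <- rank(v, ties.method = "min")
  storage.mode(r) <- "integer"
  names(r) <- names(values)
  r
}

# shared container for the four per-method results
stability_result <- function(method, stability, detail = list()) {
  structure(list(method = method,
                 stability = stability,
                 rank = assign_ranks(stability),
                 detail = detail),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  ord <- order(x$rank, names(x$stability))
  cat("Stability (", x$method, "), most stable first:\n", sep = "")
  print(data.frame(gene = names(x$stability)[ord],
                   stability = round(x$stability[ord], 4),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}

#' Tidy one or more stability results
#'
#' @param results a `stability_result` or list of them.
#' @return Data frame with columns `gene`, `method`, `stability`, `rank`.
#' @export
stability_table <- function(results) {
  if (inherits(results, "stability_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(gene = names(r$stability), method = r$method,
               stability = unname(r$stability), rank = unname(r$rank),
               row.names = NULL, stringsAsFactors = FALSE)))
}
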