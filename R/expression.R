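#' Relative expression of a target gene by the 2^-ddCT method
#'
#' dCT_s = CT_target,s - mean(CT_refs,s) (the arithmetic mean of reference
#' CTs equals the geometric mean of reference quantities at E = 2);
#' ddCT_s = dCT_s - mean(dCT over calibrator samples); expression =
#' 2^-ddCT. The calibrator group's expression has geometric mean 1 by
#' construction. With `use_gene_efficiency = TRUE` the efficiency-corrected
#' ratio is used instead: per-gene quantities E_g^-CT are combined as
#' target / geometric-mean(references), rescaled so the calibrator group's
#' geometric mean is 1; at E = 2 for all genes the two modes coincide.
#'
#' @param t a collapsed [ct_table()].
#' @param target target gene symbol.
#' @param refs character vector of reference gene symbols (non-empty,
#'   must not contain the target).
#' @param calibrator condition level whose samples define expression 1;
#'   default first level in metadata order.
#' @param use_gene_efficiency use per-gene `E` from the assay metadata.
#' @param default_base base when efficiencies are not used, default 2.
#' @return An `expression_result`: `normalizer` (gene list), per-sample
#'   `expression`, `samples` metadata, `calibrator`, and per-group
#'   `summary` (n, mean, sd).
#' @export
ddct_expression <- function(t, target, refs, calibrator = NULL,
                            use_gene_efficiency = FALSE, default_base = 2) {
  stopifnot(inherits(t, "ct_table"), isTRUE(t$collapsed))
  if (!length(refs)) stop("at least one reference gene required")
  if (target %in% refs) stop("target gene cannot be its own reference")
  miss <- setdiff(c(target, refs), rownames(t$ct))
  if (length(miss)) stop("gene(s) not in table: ", paste(miss, collapse = ", "))
  levels_present <- unique(t$samples$level)
  if (is.null(calibrator)) calibrator <- levels_present[1]
  if (!calibrator %in% levels_present)
    stop("calibrator '", calibrator, "' is not a condition level")
  cal <- t$samples$level == calibrator

  if (use_gene_efficiency) {
    E <- gene_bases(t, default_base, TRUE)
    logq <- -t$ct * log2(E[rownames(t$ct)])      # log2 quantity, arbitrary unit
    dlog <- logq[target, ] - colMeans(logq[refs, , drop = FALSE])
    ddlog <- dlog - mean(dlog[cal])
    expr <- 2 ^ ddlog
  } else {
    dct <- t$ct[target, ] - colMeans(t$ct[refs, , drop = FALSE])
    ddct <- dct - mean(dct[cal])
    expr <- default_base ^ (-ddct)
  }

  grp <- t$samples$level
  agg <- do.call(rbind, lapply(unique(grp), function(g) {
    e <- expr[grp == g]
    data.frame(level = g, n = length(e), mean = mean(e), sd = stats::sd(e),
               stringsAsFactors = FALSE)
  }))
  structure(list(normalizer = refs, target = target,
                 expression = expr, samples = t$samples,
                 calibrator = calibrator, summary = agg),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat("2^-ddCT expression of ", x$target, " normalized by ",
      paste(x$normalizer, collapse = " + "),
      " (calibrator: ", x$calibrator, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Compare normalizers: group-mean expression ratios
#'
#' Runs [ddct_expression()] under each normalizer (gene list) and, for
#' every condition level and every pair of normalizers, reports the ratio
#' of group-mean expressions — the fold by which the choice of reference
#' set changes the apparent expression.
#'
#' @inheritParams ddct_expression
#' @param normalizers named list of at least 2 reference gene lists.
#' @return List with `expressions` (one `expression_result` per
#'   normalizer) and `ratios`: data frame level x normalizer pair.
#' @export
compare_normalizers <- function(t, target, normalizers, calibrator = NULL,
                                use_gene_efficiency = FALSE, default_base = 2) {
  if (length(normalizers) < 2) stop("need at least 2 normalizers to compare")
  if (is.null(names(normalizers)))
    names(normalizers) <- vapply(normalizers, paste, "", collapse = "+")
  ex <- lapply(normalizers, function(refs)
    ddct_expression(t, target, refs, calibrator,
                    use_gene_efficiency, default_base))
  nm <- names(normalizers)
  levels_present <- unique(t$samples$level)
  rows <- list()
  for (a in seq_len(length(nm) - 1)) for (b in (a + 1):length(nm)) {
    ma <- ex[[a]]$summary; mb <- ex[[b]]$summary
    rows[[length(rows) + 1]] <- data.frame(
      level = levels_present,
      normalizer_a = nm[a], normalizer_b = nm[b],
      ratio = ma$mean[match(levels_present, ma$level)] /
              mb$mean[match(levels_present, mb$level)],
      stringsAsFactors = FALSE)
  }
  list(expressions = ex, ratios = do.call(rbind, rows))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance.
#'
#' @param values numeric response vector.
#' @param groups group labels, at least 2 groups with at least 2 values
#'   each.
#' @return List with `F` and `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("ANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"])
}

# insert-and-absorb compact letter display from a logical significance
# matrix (TRUE = the pair differs). Returns one letter string per group.
cld_insert_absorb <- function(signif_mat, group_names) {
  k <- length(group_names)
  cols <- list(seq_len(k))           # letter columns as index sets
  pairs <- which(upper.tri(signif_mat) & signif_mat, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(pairs[, 1], pairs[, 2])
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else new_cols <- c(new_cols, list(col))
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) for (b in seq_along(new_cols)) {
        if (a != b && keep[a] && keep[b] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            !(length(new_cols[[a]]) == length(new_cols[[b]]) && a < b))
          keep[a] <- FALSE
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, 0L))]
  letters_out <- rep("", k)
  for (ci in seq_along(cols)) {
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]], LETTERS[ci])
  }
  stats::setNames(letters_out, group_names)
}

#' Tukey HSD with a compact letter display
#'
#' Runs one-way ANOVA, Tukey's honestly-significant-difference pairwise
#' comparisons, and builds the compact letter display by the
#' insert-and-absorb algorithm: groups sharing any letter do not differ at
#' `alpha`; groups sharing no letter do. Letters start at "A" for the
#' column containing the first group.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level, default 0.05.
#' @return A `group_comparison`: `F`, `p`, `alpha`, `letters` (named per
#'   group), `tukey_p` (symmetric pairwise p matrix), `group_means`.
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  an <- one_way_anova(values, groups)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  g <- levels(groups)
  k <- length(g)
  pmat <- matrix(1, k, k, dimnames = list(g, g))
  # TukeyHSD names each comparison "lev2-lev1" over combn(levels, 2)
  combos <- utils::combn(g, 2)
  expected <- paste(combos[2, ], combos[1, ], sep = "-")
  stopifnot(identical(sort(expected), sort(rownames(tk))))
  for (idx in seq_len(ncol(combos))) {
    a <- combos[1, idx]; b <- combos[2, idx]
    pmat[a, b] <- pmat[b, a] <- tk[expected[idx], "p adj"]
  }
  letters_out <- cld_insert_absorb(pmat < alpha, g)
  structure(list(F = an$F, p = an$p, alpha = alpha,
                 letters = letters_out, tukey_p = pmat,
                 group_means = tapply(values, groups, mean)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA: F = ", signif(x$F, 5), ", p = ", signif(x$p, 4),
      " (alpha = ", x$alpha, ")\n", sep = "")
  print(data.frame(group = names(x$letters),
                   mean = round(unname(x$group_means[names(x$letters)]), 4),
                   letters = unname(x$letters), row.names = NULL))
  invisible(x)
}
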