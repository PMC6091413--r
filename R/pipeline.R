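#' Run the full stability pipeline per condition set
#'
#' For each requested condition set (plus the pooled sets `all_biotic`,
#' `all_abiotic` and `all_samples` when requested): collapses technical
#' replicates, computes the four stability statistics, the RefFinder-style
#' consensus, and the gene-count analysis. Pooled sets operate on the
#' concatenated samples of their member sets, never on averaged per-set
#' results. A manifest records every design decision in force.
#'
#' @param t a [ct_table()] (collapsed or not) possibly spanning several
#'   condition sets.
#' @param sets condition sets to analyze; default all present.
#' @param pooled named list of pooled sets to add, each a character vector
#'   of member sets; `"auto"` (default) builds `all_biotic`
#'   (developmental_stages, larval_tissues, adult_tissues, densities),
#'   `all_abiotic` (photoperiod, temperature) and `all_samples` from
#'   whichever members are present; `NULL` for none.
#' @param methods stability methods to run; the consensus requires at
#'   least 2.
#' @param cutoff pairwise-variation cutoff for the gene-count rule.
#' @param groups NormFinder grouping: `"auto"` (levels as groups when all
#'   have >= 2 samples), `"levels"`, or `"single"`.
#' @param average_reps average biological replicates per level before
#'   analysis (default keeps them as samples).
#' @param use_gene_efficiency use per-gene amplification efficiencies for
#'   the CT-to-quantity transform (default: E = 2 for all genes).
#' @param default_base fold-change base when efficiencies are not used.
#' @param bestkeeper_sd BestKeeper dispersion definition, `"mad"` or
#'   `"classic"`.
#' @return A `pipeline_result`: per-set list with `stability` (the four
#'   `stability_result`s), `consensus`, `gene_count`, `n_samples`; plus
#'   `manifest`.
#' @export
run_pipeline <- function(t, sets = NULL, pooled = "auto",
                         methods = c("genorm", "normfinder",
                                     "bestkeeper", "deltact"),
                         cutoff = 0.15,
                         groups = c("auto", "levels", "single"),
                         average_reps = FALSE,
                         use_gene_efficiency = FALSE, default_base = 2,
                         bestkeeper_sd = c("mad", "classic")) {
  stopifnot(inherits(t, "ct_table"))
  groups <- match.arg(groups)
  bestkeeper_sd <- match.arg(bestkeeper_sd)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) < 2)
    stop("the consensus needs at least 2 methods; got: ",
         paste(methods, collapse = ", "))
  t <- collapse_technical_reps(t)
  if (average_reps) t <- average_bio_reps(t)

  present <- unique(t$samples$condition_set)
  if (is.null(sets)) sets <- present
  miss <- setdiff(sets, present)
  if (length(miss)) stop("condition set(s) not in data: ",
                         paste(miss, collapse = ", "))

  set_members <- stats::setNames(as.list(sets), sets)
  if (identical(pooled, "auto")) {
    biotic <- intersect(c("developmental_stages", "larval_tissues",
                          "adult_tissues", "densities"), sets)
    abiotic <- intersect(c("photoperiod", "temperature"), sets)
    pooled <- list()
    if (length(biotic) > 1) pooled$all_biotic <- biotic
    if (length(abiotic) > 1) pooled$all_abiotic <- abiotic
    if (length(sets) > 1) pooled$all_samples <- sets
  }
  if (length(pooled)) set_members <- c(set_members, pooled)

  results <- list()
  for (set_name in names(set_members)) {
    members <- set_members[[set_name]]
    res <- tryCatch({
      sub <- subset_ct(t, condition_set = members)
      q <- ct_to_quantity(sub, default_base, use_gene_efficiency)
      grp <- switch(groups,
                    auto = normfinder_groups(sub),
                    levels = paste(sub$samples$condition_set,
                                   sub$samples$level, sep = ":"),
                    single = NULL)
      stab <- list()
      if ("genorm" %in% methods) stab$genorm <- genorm(q)
      if ("normfinder" %in% methods)
        stab$normfinder <- normfinder(q, groups = grp)
      if ("bestkeeper" %in% methods)
        stab$bestkeeper <- bestkeeper(sub, sd_type = bestkeeper_sd)
      if ("deltact" %in% methods) stab$deltact <- delta_ct(sub)
      cons <- reffinder_consensus(stab)
      gc <- if ("genorm" %in% methods) gene_count_analysis(q, cutoff)
            else NULL
      list(stability = stab, consensus = cons, gene_count = gc,
           n_samples = ncol(sub$ct), members = members,
           normfinder_mode = if (is.null(grp)) "single" else "levels")
    }, error = function(e) {
      warning("condition set '", set_name, "' failed: ",
              conditionMessage(e))
      NULL
    })
    results[set_name] <- list(res)   # keep NULL entries for failed sets
  }

  manifest <- list(
    methods = methods,
    cutoff = cutoff,
    normfinder_grouping = groups,
    bestkeeper_sd = bestkeeper_sd,
    bio_rep_handling = if (average_reps) "averaged per level"
                       else "kept as samples",
    efficiency_mode = if (use_gene_efficiency) "per-gene E"
                      else paste0("uniform E = ", default_base),
    genorm_tie_rule = "exclude lexicographically last gene symbol",
    rank_ties = "min-tie competition ranking",
    sd_divisor = "n - 1 (except BestKeeper MAD)",
    sample_counts = vapply(results,
                           function(r) if (is.null(r)) NA_integer_
                                       else r$n_samples, 0L))
  structure(list(sets = results, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Reference-gene stability pipeline: ", length(x$sets),
      " condition set(s)\n", sep = "")
  for (nm in names(x$sets)) {
    r <- x$sets[[nm]]
    if (is.null(r)) { cat("  ", nm, ": FAILED\n", sep = ""); next }
    cat("  ", nm, " (n = ", r$n_samples, "): top 3 = ",
        paste(r$consensus$top3, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write the pipeline report bundle as delimited tables
#'
#' Emits per condition set `stability_<set>.tsv` (gene, method, stability,
#' rank), `consensus_<set>.tsv`, `gene_count_<set>.tsv`, plus a
#' `manifest.txt`. Tables are deterministic in row order (genes by final
#' rank, then symbol).
#'
#' @param res a `pipeline_result`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(res, dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, path)
  }
  for (nm in names(res$sets)) {
    r <- res$sets[[nm]]
    if (is.null(r)) next
    stab <- stability_table(r$stability)
    ord <- r$consensus$ordering
    stab <- stab[order(match(stab$gene, ord), stab$method), ]
    wt(stab, file.path(dir, paste0("stability_", nm, ".tsv")))
    wt(consensus_table(r$consensus),
       file.path(dir, paste0("consensus_", nm, ".tsv")))
    if (!is.null(r$gene_count)) {
      gc <- r$gene_count
      wt(data.frame(v_name = names(gc$v), v = unname(gc$v),
                    cutoff = gc$cutoff, chosen_n = gc$chosen_n,
                    rule_used = gc$rule_used,
                    nf_correlation_r = gc$nf_correlation_r,
                    nf_correlation_r_linear = gc$nf_correlation_r_linear,
                    stringsAsFactors = FALSE),
         file.path(dir, paste0("gene_count_", nm, ".tsv")))
    }
  }
  mf <- file.path(dir, "manifest.txt")
  writeLines(c("# run manifest",
               vapply(names(res$manifest), function(k)
                 paste0(k, ": ",
                        paste(format(res$manifest[[k]]), collapse = " ")),
                 "")), mf)
  paths <- c(paths, mf)
  invisible(paths)
}
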