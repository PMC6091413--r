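#' @title CT tables: construction, validation and transforms
#' @name ct_table
#' @description
#' A `ct_table` holds raw cycle-threshold (CT) values as a gene x reaction
#' matrix together with per-reaction sample metadata (condition set, level,
#' biological replicate, optional technical replicate) and per-gene assay
#' metadata (symbol, optional amplification efficiency). Technical
#' replicates live as separate columns until [collapse_technical_reps()]
#' averages them into one column per biological sample; all stability
#' statistics require a collapsed, complete table.
NULL

#' Construct a CT table
#'
#' @param ct numeric matrix of CT values, genes in rows, reactions in
#'   columns. Row names are gene symbols. `NA` cells are allowed only
#'   before technical-replicate collapse.
#' @param samples data frame with one row per matrix column: `sample_id`,
#'   `condition_set`, `level`, `bio_rep` and optionally `tech_rep`.
#' @param genes optional data frame with one row per matrix row: `symbol`,
#'   optionally `efficiency_percent` (in (50, 150]) and `accession`.
#' @param collapsed logical; `TRUE` once technical replicates have been
#'   averaged (one column per biological sample, no missing cells).
#'
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, samples, genes = NULL, collapsed = FALSE) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)

  if (is.null(genes)) {
    if (is.null(rownames(ct))) stop("gene symbols required as matrix row names")
    genes <- data.frame(symbol = rownames(ct), stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$symbol))
    stop("duplicate gene symbols: ",
         paste(unique(genes$symbol[duplicated(genes$symbol)]), collapse = ", "))
  rownames(ct) <- genes$symbol

  req <- c("sample_id", "condition_set", "level", "bio_rep")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(ct))
    stop("samples has ", nrow(samples), " rows but ct has ", ncol(ct), " columns")
  if (is.null(colnames(ct))) {
    colnames(ct) <- if (!is.null(samples$tech_rep))
      paste(samples$sample_id, samples$tech_rep, sep = ".")
    else samples$sample_id
  }
  if (!is.null(samples$tech_rep)) {
    key <- paste(samples$sample_id, samples$tech_rep)
  } else {
    key <- samples$sample_id
  }
  if (anyDuplicated(key))
    stop("duplicate reaction columns for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  # one level per sample within its condition set
  per_sample <- unique(samples[, c("sample_id", "condition_set", "level")])
  if (anyDuplicated(per_sample$sample_id))
    stop("sample(s) mapped to more than one condition level: ",
         paste(unique(per_sample$sample_id[duplicated(per_sample$sample_id)]),
               collapse = ", "))

  bad <- which(is.finite(ct) & (ct <= 0 | ct >= 45))
  if (length(bad))
    stop("CT values outside (0, 45): e.g. ct[", bad[1], "] = ", ct[bad[1]])
  if (collapsed && anyNA(ct))
    stop("collapsed CT table must have no missing cells")

  if (!is.null(genes$efficiency_percent)) {
    e <- genes$efficiency_percent
    bad_e <- !is.na(e) & (e <= 50 | e > 150)
    if (any(bad_e))
      stop("efficiency_percent outside (50, 150] for: ",
           paste(genes$symbol[bad_e], collapse = ", "))
  }

  structure(list(ct = ct, samples = samples, genes = genes,
                 collapsed = collapsed),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("CT table: ", nrow(x$ct), " genes x ", ncol(x$ct), " reactions",
      if (x$collapsed) " (collapsed)" else "", "\n", sep = "")
  cat("  condition sets: ",
      paste(unique(x$samples$condition_set), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

long_cols <- c("sample_id", "condition_set", "level", "bio_rep", "gene", "ct")

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a CT table from delimited text
#'
#' Long layout needs columns `sample_id`, `condition_set`, `level`,
#' `bio_rep`, `gene`, `ct` and optionally `tech_rep`. Wide layout has the
#' sample metadata columns followed by one numeric column per gene symbol.
#' The delimiter is auto-detected (tab vs comma) unless given.
#'
#' @param path file path.
#' @param layout `"auto"` (default), `"long"` or `"wide"`.
#' @param sep field delimiter; `NULL` auto-detects among tab and comma.
#' @return A [ct_table()]. Row order of the file never affects the result:
#'   genes and samples are sorted into first-appearance order of the long
#'   form after an internal canonical sort.
#' @export
read_ct_table <- function(path, layout = c("auto", "long", "wide"), sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (layout == "auto")
    layout <- if (all(c("gene", "ct") %in% names(df))) "long" else "wide"

  if (layout == "wide") {
    meta_cols <- intersect(c("sample_id", "condition_set", "level",
                             "bio_rep", "tech_rep"), names(df))
    gene_cols <- setdiff(names(df), meta_cols)
    if (!length(gene_cols)) stop("wide layout has no gene columns")
    df <- stats::reshape(df, direction = "long", varying = gene_cols,
                         v.names = "ct", timevar = "gene", times = gene_cols,
                         idvar = meta_cols)
    rownames(df) <- NULL
  }
  miss <- setdiff(long_cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  ct_chr <- df$ct
  ct_num <- suppressWarnings(as.numeric(ct_chr))
  bad <- which(!is.na(ct_chr) & !ct_chr %in% c("NA", "") & is.na(ct_num))
  if (length(bad))
    stop("non-numeric CT value '", ct_chr[bad[1]], "' at data line ", bad[1])
  df$ct <- ct_num
  df$bio_rep <- as.integer(df$bio_rep)
  has_tech <- "tech_rep" %in% names(df)

  cell_key <- if (has_tech) paste(df$sample_id, df$gene, df$tech_rep)
              else paste(df$sample_id, df$gene)
  if (anyDuplicated(cell_key)) {
    d <- cell_key[duplicated(cell_key)][1]
    stop("duplicate CT cell for (sample, gene",
         if (has_tech) ", tech_rep", "): ", d)
  }

  # canonical order: first appearance in the file
  gene_syms <- unique(df$gene)
  col_key <- if (has_tech) paste(df$sample_id, df$tech_rep) else df$sample_id
  col_ids <- unique(col_key)
  ct <- matrix(NA_real_, length(gene_syms), length(col_ids),
               dimnames = list(gene_syms, col_ids))
  ct[cbind(match(df$gene, gene_syms), match(col_key, col_ids))] <- df$ct

  meta_cols <- c("sample_id", "condition_set", "level", "bio_rep",
                 if (has_tech) "tech_rep")
  samples <- unique(df[, meta_cols, drop = FALSE])
  samples <- samples[match(col_ids,
                           if (has_tech) paste(samples$sample_id, samples$tech_rep)
                           else samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  ct_table(ct, samples, collapsed = FALSE)
}

#' Write a CT table as long-format delimited text
#'
#' @param t a [ct_table()].
#' @param path output file path.
#' @param sep delimiter (default tab).
#' @export
write_ct_table <- function(t, path, sep = "\t") {
  s <- t$samples
  long <- do.call(rbind, lapply(seq_len(nrow(t$ct)), function(i) {
    cbind(s, gene = rownames(t$ct)[i], ct = t$ct[i, ],
          stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$ct), , drop = FALSE]
  utils::write.table(long, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average technical replicates into one column per biological sample
#'
#' Each (gene, sample) cell becomes the arithmetic mean CT of its technical
#' replicates; missing replicates are ignored. Genes left with any empty
#' cell after averaging are dropped with a warning (all downstream
#' stability methods assume complete matrices). Idempotent: collapsing a
#' collapsed table returns it unchanged.
#'
#' @param t a [ct_table()].
#' @return A collapsed [ct_table()]; `$tech_rep_count` records how many
#'   replicates fed each cell.
#' @export
collapse_technical_reps <- function(t) {
  stopifnot(inherits(t, "ct_table"))
  if (isTRUE(t$collapsed)) return(t)
  s <- t$samples
  ids <- unique(s$sample_id)
  n_obs <- matrix(0L, nrow(t$ct), length(ids),
                  dimnames = list(rownames(t$ct), ids))
  ct <- matrix(NA_real_, nrow(t$ct), length(ids),
               dimnames = list(rownames(t$ct), ids))
  for (j in seq_along(ids)) {
    cols <- which(s$sample_id == ids[j])
    sub <- t$ct[, cols, drop = FALSE]
    n_obs[, j] <- rowSums(!is.na(sub))
    ct[, j] <- rowMeans(sub, na.rm = TRUE)
  }
  ct[n_obs == 0L] <- NA_real_

  incomplete <- rowSums(is.na(ct)) > 0
  genes <- t$genes
  if (any(incomplete)) {
    warning("dropping gene(s) with missing CT after replicate collapse: ",
            paste(rownames(ct)[incomplete], collapse = ", "))
    ct <- ct[!incomplete, , drop = FALSE]
    n_obs <- n_obs[!incomplete, , drop = FALSE]
    genes <- genes[!incomplete, , drop = FALSE]
  }
  meta <- unique(s[, c("sample_id", "condition_set", "level", "bio_rep")])
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  out <- ct_table(ct, meta, genes, collapsed = TRUE)
  out$tech_rep_count <- n_obs
  out
}

#' Per-gene fold-change base E
#'
#' @param t a [ct_table()].
#' @param default_base fold change per cycle used when per-gene
#'   efficiencies are not requested or absent (2 = perfect doubling).
#' @param use_gene_efficiency if `TRUE`, genes with a recorded
#'   `efficiency_percent` use `E = 1 + efficiency_percent / 100`.
#' @return Named numeric vector of per-gene bases.
#' @export
gene_bases <- function(t, default_base = 2, use_gene_efficiency = FALSE) {
  E <- rep(default_base, nrow(t$ct))
  names(E) <- rownames(t$ct)
  if (use_gene_efficiency && !is.null(t$genes$efficiency_percent)) {
    eff <- t$genes$efficiency_percent
    E[!is.na(eff)] <- 1 + eff[!is.na(eff)] / 100
  }
  if (any(E <= 1)) stop("amplification base E must exceed 1; got ",
                        paste(E[E <= 1], collapse = ", "))
  E
}

#' Convert CT values to relative quantities
#'
#' Computes `Q[i, s] = E_i ^ (min_s' CT[i, s'] - CT[i, s])`: each gene's
#' highest-expressing sample (minimum CT) is the unit, so `max(Q) == 1` per
#' gene. This is the quantity convention geNorm expects.
#'
#' @inheritParams gene_bases
#' @return A `quantity_matrix`: list with `q` (gene x sample matrix of
#'   positive reals), `base_per_gene`, and the sample metadata.
#' @export
ct_to_quantity <- function(t, default_base = 2, use_gene_efficiency = FALSE) {
  stopifnot(inherits(t, "ct_table"))
  if (!isTRUE(t$collapsed))
    stop("collapse technical replicates before computing quantities")
  if (anyNA(t$ct)) stop("CT table has missing cells")
  E <- gene_bases(t, default_base, use_gene_efficiency)
  dct <- apply(t$ct, 1, min) - t$ct        # CTmin - CT, per gene
  q <- E ^ dct
  structure(list(q = q, base_per_gene = E, samples = t$samples),
            class = "quantity_matrix")
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat("Relative quantities: ", nrow(x$q), " genes x ", ncol(x$q),
      " samples (per-gene max = 1)\n", sep = "")
  invisible(x)
}

#' Per-gene CT summary
#'
#' @param t a collapsed [ct_table()].
#' @return Data frame with per-gene `mean`, `min`, `max` and `sd`
#'   (n - 1 divisor) of CT across all samples.
#' @export
summarize_ct <- function(t) {
  stopifnot(inherits(t, "ct_table"))
  data.frame(gene = rownames(t$ct),
             mean = rowMeans(t$ct),
             min = apply(t$ct, 1, min),
             max = apply(t$ct, 1, max),
             sd = apply(t$ct, 1, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset a CT table by sample or gene
#'
#' @param t a [ct_table()].
#' @param condition_set keep only samples of these condition sets.
#' @param genes keep only these gene symbols.
#' @return A [ct_table()].
#' @export
subset_ct <- function(t, condition_set = NULL, genes = NULL) {
  stopifnot(inherits(t, "ct_table"))
  ct <- t$ct; s <- t$samples; g <- t$genes
  if (!is.null(condition_set)) {
    absent <- setdiff(condition_set, unique(s$condition_set))
    if (length(absent)) stop("no samples in condition set(s): ",
                             paste(absent, collapse = ", "))
    keep <- s$condition_set %in% condition_set
    ct <- ct[, keep, drop = FALSE]; s <- s[keep, , drop = FALSE]
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(ct))
    if (length(miss)) stop("gene(s) not in table: ", paste(miss, collapse = ", "))
    idx <- match(genes, rownames(ct))
    ct <- ct[idx, , drop = FALSE]; g <- g[idx, , drop = FALSE]
  }
  rownames(s) <- NULL
  out <- ct_table(ct, s, g, collapsed = t$collapsed)
  out
}

#' Average biological replicates within each condition level
#'
#' Optional pre-analysis reduction: one averaged CT column per condition
#' level instead of one per biological replicate.
#'
#' @param t a collapsed [ct_table()].
#' @return A collapsed [ct_table()] with one sample per (condition_set,
#'   level), `bio_rep = 1`.
#' @export
average_bio_reps <- function(t) {
  stopifnot(inherits(t, "ct_table"), isTRUE(t$collapsed))
  s <- t$samples
  key <- paste(s$condition_set, s$level, sep = "\r")
  keys <- unique(key)
  ct <- sapply(keys, function(k) rowMeans(t$ct[, key == k, drop = FALSE]))
  if (is.null(dim(ct))) ct <- matrix(ct, nrow = 1,
                                     dimnames = list(rownames(t$ct), keys))
  first <- match(keys, key)
  meta <- data.frame(sample_id = paste(s$condition_set[first],
                                       s$level[first], sep = "_"),
                     condition_set = s$condition_set[first],
                     level = s$level[first], bio_rep = 1L,
                     stringsAsFactors = FALSE)
  colnames(ct) <- meta$sample_id
  ct_table(ct, meta, t$genes, collapsed = TRUE)
}
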