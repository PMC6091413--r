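# shared fixture builders (all data generated in code)

# collapsed ct_table from a plain matrix; one condition set, levels l1..
make_ct <- function(mat, levels = NULL, condition_set = "test") {
  n <- ncol(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(levels)) levels <- paste0("l", seq_len(n))
  samples <- data.frame(sample_id = paste0("s", seq_len(n)),
                        condition_set = condition_set,
                        level = levels, bio_rep = 1L,
                        stringsAsFactors = FALSE)
  ct_table(mat, samples, collapsed = TRUE)
}

# random complete CT table: k genes x n samples, baselines spread 12..30
random_ct <- function(k = 5, n = 8, sd = 1, seed = 1) {
  set.seed(seed)
  base <- seq(12, 30, length.out = k)
  mat <- matrix(rnorm(k * n, base, sd), k, n)
  make_ct(mat)
}

# brute-force geNorm full-panel M: mean over partners of SD(log2 ratio)
brute_m <- function(q) {
  lq <- log2(q)
  k <- nrow(q)
  sapply(seq_len(k), function(i) {
    mean(sapply(setdiff(seq_len(k), i), function(j) sd(lq[i, ] - lq[j, ])))
  })
}

# brute-force comparative delta-CT stability
brute_deltact <- function(ct) {
  k <- nrow(ct)
  sapply(seq_len(k), function(i) {
    mean(sapply(setdiff(seq_len(k), i), function(j) sd(ct[i, ] - ct[j, ])))
  })
}

# naive min-tie competition ranks
brute_ranks <- function(v) {
  vapply(v, function(x) sum(v < x) + 1L, 0L)
}

# brute-force verifier for a compact letter display: groups share a letter
# iff they must not be declared different
check_letters <- function(letters_out, signif_mat) {
  k <- length(letters_out)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- length(intersect(strsplit(letters_out[i], "")[[1]],
                               strsplit(letters_out[j], "")[[1]])) > 0
    if (signif_mat[i, j] && shared) return(FALSE)   # differ but share
    if (!signif_mat[i, j] && !shared) return(FALSE) # same but disjoint
  }
  TRUE
}

# write a long-layout CT file and return its path
write_long_file <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
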