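test_that("geNorm: proportional profiles have zero pairwise variation", {
  q1 <- 2 ^ -(0:3)
  mat <- rbind(g1 = q1, g2 = 0.5 * q1, g3 = c(1, 0.3, 0.9, 0.2))
  g <- genorm(mat)
  # g1 and g2 are perfectly proportional: they survive to the final pair
  # with M = mean of their (equal) V against g3 ... their mutual V is 0
  lq <- log2(mat)
  expect_equal(sd(lq["g1", ] - lq["g2", ]), 0)
  expect_setequal(g$detail$final_pair, c("g1", "g2"))
})

test_that("geNorm full-panel M matches the brute-force pairwise oracle", {
  set.seed(11)
  mat <- matrix(2 ^ -runif(12, 0, 5), 3, 4,
                dimnames = list(paste0("g", 1:3), NULL))
  expect_equal(unname(genorm_m(mat)), brute_m(mat), tolerance = 1e-12)

  for (seed in 1:10) {
    t <- random_ct(k = 7, n = 9, seed = seed)
    q <- ct_to_quantity(t)
    expect_equal(unname(genorm_m(q)), brute_m(q$q), tolerance = 1e-12)
  }
})

test_that("geNorm final pair shares its stability value and rank 1", {
  for (seed in 1:5) {
    t <- random_ct(k = 6, n = 8, seed = seed)
    g <- genorm(ct_to_quantity(t))
    pair <- g$detail$final_pair
    expect_length(pair, 2)
    expect_equal(g$stability[pair[1]], g$stability[pair[2]],
                 ignore_attr = TRUE)
    expect_equal(unname(g$rank[pair]), c(1L, 1L))
    # next-best gene gets rank 3 under the min-tie convention
    expect_equal(sort(unname(g$rank))[3], 3L)
  }
})

test_that("geNorm reported stabilities are the M at each exclusion step", {
  t <- random_ct(k = 5, n = 10, seed = 3)
  q <- ct_to_quantity(t)
  g <- genorm(q)
  # recompute by hand: peel genes off with the same rule
  panel <- rownames(q$q)
  for (step in seq_along(g$detail$exclusion_order)) {
    m <- brute_m(q$q[panel, , drop = FALSE])
    names(m) <- panel
    worst <- names(m)[m == max(m)]
    drop_gene <- sort(worst)[length(worst)]
    expect_identical(g$detail$exclusion_order[step], drop_gene)
    expect_equal(g$stability[drop_gene], m[drop_gene])
    panel <- setdiff(panel, drop_gene)
  }
  expect_error(genorm(q$q[1:2, ]), "3 genes")
})

test_that("delta-CT stability equals the hand example and brute force", {
  ct <- rbind(g1 = c(20, 21), g2 = c(22, 24))
  d <- delta_ct(ct)
  expect_equal(unname(d$stability), rep(sd(c(-2, -3)), 2))
  expect_equal(unname(d$stability), rep(0.7071, 2), tolerance = 1e-4)

  ct2 <- rbind(g1 = c(20, 21, 22), g2 = c(23, 24, 25), g3 = c(18, 20, 19))
  d2 <- delta_ct(ct2)
  expect_equal(d2$detail$sd_matrix["g1", "g2"], 0)  # parallel pair
  expect_equal(d2$detail$sd_matrix, t(d2$detail$sd_matrix))
  expect_equal(unname(diag(d2$detail$sd_matrix)), rep(0, 3))
  for (seed in 1:5) {
    t <- random_ct(k = 4, n = 6, seed = seed)
    expect_equal(unname(delta_ct(t)$stability), brute_deltact(t$ct),
                 tolerance = 1e-12)
  }
})

test_that("geNorm M equals delta-CT stability on CT tables at E = 2", {
  # log2 of quantity ratios are CT differences, so the two methods coincide
  for (seed in 1:25) {
    set.seed(1000 + seed)
    t <- random_ct(k = sample(3:8, 1), n = sample(4:12, 1), seed = seed)
    m <- genorm_m(ct_to_quantity(t))
    d <- delta_ct(t)$stability
    expect_equal(m, d, tolerance = 1e-9)
  }
})

test_that("offset invariances hold where the methods promise them", {
  t <- random_ct(k = 5, n = 8, seed = 21)
  shifted_gene <- t$ct + matrix(c(1, -2, 0.5, 3, -1), 5, 8)   # per-gene
  shifted_sample <- t$ct + matrix(rnorm(8), 5, 8, byrow = TRUE) # per-sample
  tg <- make_ct(shifted_gene); ts <- make_ct(shifted_sample)

  expect_equal(genorm_m(ct_to_quantity(tg)), genorm_m(ct_to_quantity(t)),
               tolerance = 1e-9)
  expect_equal(delta_ct(tg)$stability, delta_ct(t)$stability,
               tolerance = 1e-9)
  expect_equal(delta_ct(ts)$stability, delta_ct(t)$stability,
               tolerance = 1e-9)

  # BestKeeper: permutation-invariant, but per-sample shifts change SDs
  set.seed(22)
  perm <- make_ct(t$ct[, sample(ncol(t$ct))])
  bk0 <- bestkeeper(t)$stability
  expect_equal(bestkeeper(perm)$stability, bk0, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(bestkeeper(ts)$stability, bk0)))
})

test_that("NormFinder single group: bias-corrected SDs behave", {
  # degenerate: identical genes -> all zero
  y0 <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(unname(normfinder(y0)$stability), rep(0, 4))

  # one gene with 10x the noise of the rest is the least stable
  set.seed(99)
  k <- 10; n <- 500
  sds <- c(rep(0.1, 9), 1)
  y <- matrix(rnorm(k * n, 0, sds), k, n,
              dimnames = list(paste0("g", 1:k), NULL))
  nf <- normfinder(y)
  expect_equal(which.max(nf$stability), 10L, ignore_attr = TRUE)
  expect_error(normfinder(y[1:2, ]), "3 genes")
})

test_that("NormFinder grouped: planted shift dominates and deviations sum to zero", {
  set.seed(5)
  k <- 6; n <- 12
  grp <- rep(c("a", "b"), each = n / 2)
  y <- matrix(rnorm(k * n, 0, 0.1), k, n,
              dimnames = list(paste0("g", 1:k), NULL))
  y[3, grp == "b"] <- y[3, grp == "b"] + 2
  nf <- normfinder(y, groups = grp)
  d <- nf$detail$d_hat
  expect_equal(unname(colSums(d)), c(0, 0), tolerance = 1e-9)
  expect_equal(which.max(abs(d[, "b"])), 3L, ignore_attr = TRUE)
  expect_equal(which.max(nf$stability), 3L, ignore_attr = TRUE)
  expect_true(all(nf$detail$sigma2 >= 0))
  expect_gte(nf$detail$gamma2, 0)
  expect_error(normfinder(y, groups = c("a", rep("b", n - 1))),
               "at least 2 samples")
})

test_that("BestKeeper descriptives match hand calculation", {
  t <- make_ct(matrix(c(20, 21, 22, 20, 21, 22), 2, 3, byrow = TRUE,
                      dimnames = list(c("gA", "gB"), NULL)))
  bk <- bestkeeper(t)
  tab <- bk$detail$table
  expect_equal(tab$ar_mean[1], 21)
  expect_equal(tab$sd[1], 2 / 3)
  expect_equal(tab$cv_pct[1], (2 / 3) / 21 * 100, tolerance = 1e-9)
  expect_true(all(tab$min <= tab$geo_mean & tab$geo_mean <= tab$ar_mean &
                    tab$ar_mean <= tab$max))
  # identical rows correlate perfectly with the 2-gene index
  expect_equal(tab$r, c(1, 1), tolerance = 1e-12)

  # constant gene has SD 0 and the best rank
  t2 <- make_ct(rbind(gA = c(20, 20, 20), gB = c(18, 19, 21)))
  bk2 <- bestkeeper(t2)
  expect_equal(unname(bk2$stability["gA"]), 0)
  expect_equal(unname(bk2$rank["gA"]), 1L)

  # classic option uses the n-1 SD instead of the MAD
  bk3 <- bestkeeper(t, sd_type = "classic")
  expect_equal(bk3$detail$table$sd[1], sd(c(20, 21, 22)))
})

test_that("ranks follow the min-tie competition convention", {
  vals <- c(GAPDH = 1.138, `18S` = 1.876, `28S` = 2.364, EF = 0.901,
            RPL12 = 0.375, `b-TUB` = 0.964, ATPase = 1.26, TBP = 1.377,
            `b-ACT` = 1.57, CypA = 0.375)
  expect_equal(unname(assign_ranks(vals)), c(5L, 9L, 10L, 3L, 1L, 4L, 6L,
                                             7L, 8L, 1L))
  expect_equal(unname(assign_ranks(c(2, 2, 2))), c(1L, 1L, 1L))
  expect_equal(unname(assign_ranks(1:5)), 1:5)
  expect_equal(unname(assign_ranks(1:4, ascending = FALSE)), 4:1)
  expect_error(assign_ranks(c(1, NA)), "finite")

  for (seed in 1:20) {
    set.seed(seed)
    v <- sample(round(runif(8, 0, 3), 1))  # coarse grid forces ties
    expect_equal(unname(assign_ranks(v)), unname(brute_ranks(v)))
  }
})

test_that("every method's ranks re-derive from its values", {
  t <- random_ct(k = 6, n = 9, seed = 13)
  q <- ct_to_quantity(t)
  for (r in list(genorm(q), normfinder(q), bestkeeper(t), delta_ct(t))) {
    expect_equal(r$rank, assign_ranks(r$stability))
  }
})
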