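# small two-level table: calibrator level "ctrl", test level "trt"
make_expr_ct <- function(target_ct, ref_cts, levels) {
  mat <- rbind(target = target_ct, ref_cts)
  make_ct(mat, levels = levels)
}

test_that("2^-ddCT reproduces the hand example and trivial identities", {
  # target tracks the single reference exactly -> expression 1 everywhere
  t <- make_expr_ct(c(20, 22, 24), rbind(ref = c(20, 22, 24)),
                    levels = c("ctrl", "trt", "trt"))
  ex <- ddct_expression(t, "target", "ref", calibrator = "ctrl")
  expect_equal(unname(ex$expression), c(1, 1, 1))

  # calibrator: target 24 ref 20; test: target 22 ref 20 -> ddCT -2, fold 4
  t2 <- make_expr_ct(c(24, 22), rbind(ref = c(20, 20)),
                     levels = c("ctrl", "trt"))
  ex2 <- ddct_expression(t2, "target", "ref", calibrator = "ctrl")
  expect_equal(unname(ex2$expression), c(1, 4))

  # two refs with CTs 19 and 21 behave exactly like one ref at 20
  t3 <- make_expr_ct(c(24, 22), rbind(refA = c(19, 19), refB = c(21, 21)),
                     levels = c("ctrl", "trt"))
  ex3 <- ddct_expression(t3, "target", c("refA", "refB"), calibrator = "ctrl")
  expect_equal(ex3$expression, ex2$expression, ignore_attr = TRUE)

  expect_error(ddct_expression(t, "target", "target"), "own reference")
  expect_error(ddct_expression(t, "target", "ref", calibrator = "nope"),
               "not a condition level")
})

test_that("calibrator group's expression has geometric mean 1", {
  t <- random_ct(k = 4, n = 9, seed = 61)
  t$samples$level <- rep(c("a", "b", "c"), each = 3)
  ex <- ddct_expression(t, "g1", c("g2", "g3"), calibrator = "a")
  cal <- ex$expression[t$samples$level == "a"]
  expect_equal(exp(mean(log(cal))), 1, tolerance = 1e-12)
  expect_true(all(ex$expression > 0))
})

test_that("per-sample CT shifts cancel when references are used", {
  t <- random_ct(k = 4, n = 6, seed = 62)
  t$samples$level <- rep(c("a", "b"), each = 3)
  shift <- rnorm(6)
  t2 <- t; t2$ct <- t$ct + matrix(shift, 4, 6, byrow = TRUE)
  ex1 <- ddct_expression(t, "g1", c("g2", "g4"), calibrator = "a")
  ex2 <- ddct_expression(t2, "g1", c("g2", "g4"), calibrator = "a")
  expect_equal(ex1$expression, ex2$expression, tolerance = 1e-9)
})

test_that("efficiency-corrected mode coincides with 2^-ddCT at E = 2", {
  t <- random_ct(k = 4, n = 6, seed = 63)
  t$samples$level <- rep(c("a", "b"), each = 3)
  plain <- ddct_expression(t, "g1", c("g2", "g3"), calibrator = "a")
  eff <- ddct_expression(t, "g1", c("g2", "g3"), calibrator = "a",
                         use_gene_efficiency = TRUE)
  expect_equal(plain$expression, eff$expression, tolerance = 1e-9)
})

test_that("normalizer comparison reports fold ratios between reference sets", {
  t <- random_ct(k = 4, n = 6, seed = 64)
  t$samples$level <- rep(c("a", "b"), each = 3)
  same <- compare_normalizers(t, "g1", list(A = "g2", B = "g2"),
                              calibrator = "a")
  expect_equal(same$ratios$ratio, rep(1, 2), tolerance = 1e-12)

  # reference shifted by +1 CT uniformly halves the apparent reference
  # level, doubling target expression relative to the unshifted reference
  t2 <- t
  t2$ct <- rbind(t$ct, g5 = t$ct["g2", ] + 1)
  t2 <- make_ct(t2$ct, levels = t$samples$level)
  cmp <- compare_normalizers(t2, "g1", list(shifted = "g5", plain = "g2"),
                             calibrator = "a")
  # the calibrator rescaling absorbs the uniform shift: ratios stay 1
  expect_equal(cmp$ratios$ratio, rep(1, 2), tolerance = 1e-9)

  # a level-specific drift in the reference does NOT cancel: planting a
  # +1 CT drift on the reference in level b doubles apparent expression
  t3 <- t
  drift <- ifelse(t$samples$level == "b", 1, 0)
  t3$ct <- rbind(t$ct, g5 = t$ct["g2", ] + drift)
  t3 <- make_ct(t3$ct, levels = t$samples$level)
  cmp3 <- compare_normalizers(t3, "g1", list(drifted = "g5", plain = "g2"),
                              calibrator = "a")
  r <- cmp3$ratios
  expect_equal(r$ratio[r$level == "b"], 2, tolerance = 1e-9)
  expect_error(compare_normalizers(t, "g1", list(A = "g2")), "at least 2")
})

test_that("one-way ANOVA matches its classical identities", {
  a <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(a$F, 0); expect_equal(a$p, 1)

  set.seed(71)
  v <- c(rnorm(6, 0), rnorm(7, 1))
  g <- rep(c("x", "y"), c(6, 7))
  a2 <- one_way_anova(v, g)
  tt <- t.test(v[1:6], v[7:13], var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-9)

  set.seed(72)
  a3 <- one_way_anova(c(rnorm(3, 0), rnorm(3, 100)), rep(c("x", "y"), each = 3))
  expect_lt(a3$p, 0.001)
  expect_error(one_way_anova(1:3, c("x", "x", "y")), "at least 2 values")
})

test_that("compact letter displays separate exactly the significant pairs", {
  set.seed(73)
  # all groups alike -> single letter
  same <- tukey_letters(rnorm(12), rep(letters[1:3], each = 4))
  expect_equal(unname(same$letters), rep("A", 3))

  # group a far from b and c; b ~ c -> A, B, B
  v <- c(rnorm(4, 0, 0.1), rnorm(4, 5, 0.1), rnorm(4, 5.05, 0.1))
  tl <- tukey_letters(v, rep(c("a", "b", "c"), each = 4))
  expect_equal(unname(tl$letters), c("A", "B", "B"))

  # all pairs significant -> distinct letters
  v2 <- c(rnorm(4, 0, 0.1), rnorm(4, 5, 0.1), rnorm(4, 10, 0.1))
  tl2 <- tukey_letters(v2, rep(c("a", "b", "c"), each = 4))
  expect_equal(unname(tl2$letters), c("A", "B", "C"))
})

test_that("letter displays pass the brute-force validity check on random data", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(3:5, 1)
    means <- sample(c(0, 0, 2, 4, 8), k)
    v <- rnorm(4 * k, rep(means, each = 4), 0.8)
    g <- rep(LETTERS[1:k], each = 4)
    tl <- tukey_letters(v, g)
    expect_true(check_letters(unname(tl$letters), tl$tukey_p < tl$alpha))
  }
})

test_that("letter display agrees with the multcomp reference implementation", {
  set.seed(74)
  v <- c(rnorm(5, 0), rnorm(5, 3), rnorm(5, 3.2), rnorm(5, 9))
  g <- factor(rep(c("a", "b", "c", "d"), each = 5))
  tl <- tukey_letters(v, g)
  fit <- stats::aov(v ~ g)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(glht)$mcletters$Letters
  # compare the sharing pattern, not the letter labels themselves
  share <- function(l) outer(l, l, Vectorize(function(x, y)
    length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0))
  expect_equal(unname(share(tl$letters[levels(g)])),
               unname(share(ref[levels(g)])))
})
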