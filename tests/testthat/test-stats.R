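# brute-force oracles ------------------------------------------------------

# one-tailed exact Wilcoxon p by enumerating every group assignment
enumerate_wilcoxon_p <- function(x, y, direction = "x_greater") {
  nx <- length(x)
  vals <- c(x, y)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(vals), nx)
  us <- apply(combos, 2, u_of)
  if (direction == "x_greater") mean(us >= obs) else mean(us <= obs)
}

# pairwise-counting AUC, O(n^2)
pair_count_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# --------------------------------------------------------------------------

test_that("wilcoxon U, AUC and exact p agree with enumeration", {
  res <- wilcoxon_one_tailed(c(10, 11, 12), c(1, 2, 3), "x_greater",
                             exact = TRUE)
  expect_equal(res$U, 9)
  expect_equal(res$p, 1 / 20)   # 1 of C(6,3) = 20 assignments is as extreme
  expect_equal(res$auc, 1)
  expect_equal(res$r_rank_biserial, 1)
  expect_equal(res$effect_label, "large")

  set.seed(41)
  for (i in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(100, nx); y <- sample(100, ny)  # distinct values, no ties
    dir <- sample(c("x_greater", "x_less"), 1)
    got <- wilcoxon_one_tailed(x, y, dir, exact = TRUE)
    expect_equal(got$p, enumerate_wilcoxon_p(x, y, dir))
    expect_equal(got$auc, pair_count_auc(c(x, y), rep(c(1, 0), c(nx, ny))))
  }
})

test_that("exchangeable and separated samples hit the AUC extremes", {
  same <- wilcoxon_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$auc, 0.5)
  expect_equal(same$r_rank_biserial, 0)
  sep <- wilcoxon_one_tailed(c(7, 8, 9, 10), c(1, 2, 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$r_rank_biserial, 1)
  expect_warning(deg <- wilcoxon_one_tailed(c(2, 2, 2), c(2, 2, 2)),
                 "identical")
  expect_equal(deg$p, 1)
  expect_error(wilcoxon_one_tailed(1, c(1, 2)), "at least 2")
})

test_that("r = 2 AUC - 1 holds exactly for random comparisons", {
  set.seed(42)
  for (i in 1:25) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1))
    if (i %% 3 == 0) x <- round(x)  # provoke ties
    if (i %% 3 == 0) y <- round(y)
    res <- wilcoxon_one_tailed(x, y)
    expect_identical(res$r_rank_biserial, 2 * res$auc - 1)
    expect_equal(res$auc, pair_count_auc(c(x, y),
                                         rep(c(1, 0), c(length(x), length(y)))))
  }
})

test_that("roc_auc matches the pair-counting oracle and handles edge cases", {
  expect_equal(roc_auc(c(5, 6, 7), c(0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), rep(c(0, 1), 3)), 0.5)
  set.seed(43)
  for (i in 1:10) {
    s <- sample(20, 30, replace = TRUE)  # heavy ties
    l <- rbinom(30, 1, 0.4)
    if (sum(l) == 0 || sum(l) == 30) next
    expect_equal(roc_auc(s, l), pair_count_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "Both classes")
  curve <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(attr(curve, "auc"), 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
})

test_that("chi-square applies Yates only on 2x2 and never inflates it", {
  res <- chi_square(matrix(c(31, 16, 18, 25), 2))
  expect_true(res$yates_applied)
  expect_equal(res$df, 1)
  # independence: proportional 2x3 table, no correction applied
  prop <- outer(c(2, 3), c(4, 6, 10))
  res0 <- chi_square(prop)
  expect_false(res0$yates_applied)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$df, 2)
  set.seed(44)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    yates <- chi_square(tab)$chi2
    plain <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_lte(yates, unname(plain))
  }
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_error(chi_square(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("one-way ANOVA matches the sum-of-squares oracle and t^2", {
  set.seed(45)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  got <- anova_oneway(v, g)
  # textbook decomposition
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(got$F, f_oracle, tolerance = 1e-10)
  expect_equal(got$p, pf(f_oracle, 2, 27, lower.tail = FALSE))

  x <- rnorm(12); y <- rnorm(15) + 1
  two <- anova_oneway(c(x, y), rep(c("x", "y"), c(12, 15)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)

  expect_error(anova_oneway(1:3, c("a", "a", "b")), "fewer than 2")
  expect_error(anova_oneway(rep(2, 8), rep(c("a", "b"), 4)),
               "within-group variance")
})

test_that("BH and Bonferroni match hand-worked examples and inequalities", {
  ps <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_p(ps, "bonferroni"), c(0.04, 0.08, 0.12, 0.16))
  expect_equal(adjust_p(ps, "bh"), c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_p(0.03, "bh"), 0.03)
  expect_equal(adjust_p(0.03, "bonferroni"), 0.03)
  set.seed(46)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    bh <- adjust_p(p, "bh")
    bon <- adjust_p(p, "bonferroni")
    expect_true(all(bon >= bh - 1e-15))
    o <- order(p)
    expect_true(!is.unsorted(bh[o]))
  }
  expect_error(adjust_p(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("harmonic-mean p matches hand arithmetic and its inequalities", {
  expect_equal(harmonic_mean_p(rep(0.07, 5)), 0.07)
  expect_equal(harmonic_mean_p(c(0.02, 0.2)), 2 / 55)
  set.seed(47)
  for (i in 1:10) {
    p <- runif(sample(2:20, 1))
    expect_lte(harmonic_mean_p(p), mean(p) + 1e-15)
  }
  expect_error(harmonic_mean_p(c(0, 0.5)), "zeros")
})

test_that("the Landau-calibrated harmonic p is a valid, larger significance level", {
  set.seed(48)
  ps <- runif(30, 0.001, 0.6)
  plain <- harmonic_mean_p(ps)
  cal <- harmonic_mean_p(ps, calibrated = TRUE)
  expect_gt(cal, plain)  # the plain HMP is anticonservative
  expect_lte(cal, 1)
  # calibration sanity against direct simulation of the null
  L <- 20
  set.seed(49)
  S <- replicate(4000, mean(1 / runif(L)))
  q95 <- quantile(S, 0.95)
  cal95 <- harmonic_mean_p(rep(1 / q95, L), calibrated = TRUE)
  expect_gt(cal95, 0.02)
  expect_lt(cal95, 0.09)
})

test_that("effect labels honour threshold sets", {
  expect_equal(effect_label(c(0, 0.05, 0.15, 0.32, -0.6)),
               c("trivial", "trivial", "small", "medium", "large"))
  expect_equal(effect_label(0.22), "small")
  expect_equal(effect_label(0.22, thresholds = "field"), "medium")
  expect_equal(effect_label(0.17, thresholds = "field"), "small")
  expect_equal(effect_label(0.5), "large")
  expect_error(effect_label(1.2), "exceed")
})
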