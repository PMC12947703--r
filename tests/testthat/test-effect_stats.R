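test_that("Cohen's d matches the pooled-SD hand computation", {
  es <- cohens_d(c(1, 2, 3), c(2, 3, 4))
  expect_equal(es$pooled_sd, 1)
  expect_equal(es$d, -1)
  expect_equal(es$hedges_g, -1 * (1 - 3 / (4 * 6 - 9)))
  same <- cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$d, 0)
  expect_error(cohens_d(c(0, 0), c(0, 0)), "degenerate")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("hedges_g / d equals the small-sample factor exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    es <- cohens_d(rnorm(n1), rnorm(n2, 1))
    expect_equal(es$hedges_g / es$d, 1 - 3 / (4 * (n1 + n2) - 9))
  }
})

test_that("per-trait driver signs effects as LW minus PW and skips one-treatment traits", {
  rows <- rbind(
    make_rows(4, treatment = "PW", trait = "CEW", value = c(10, 11, 9, 10)),
    make_rows(4, treatment = "LW", trait = "CEW", value = c(14, 15, 13, 14)),
    make_rows(4, treatment = "PW", trait = "LT", value = c(28, 29, 28, 29))
  )
  rows$replicate <- ave(rows$replicate, rows$treatment, rows$trait,
                        FUN = seq_along)
  tab <- trait_table(rows)
  expect_warning(eff <- effect_sizes_by_trait(tab, level = "replicate"),
                 "single treatment")
  expect_identical(eff$trait, "CEW")
  expect_gt(eff$d, 0)  # CEW planted higher under LW
})

test_that("genotype-mean level uses one value per genotype per treatment", {
  tab <- random_trait_table(3, n_genotypes = 5, n_reps = 4)
  eff <- effect_sizes_by_trait(tab, level = "genotype_mean")
  expect_true(all(eff$n_pw == 5 & eff$n_lw == 5))
  eff_rep <- effect_sizes_by_trait(tab, level = "replicate")
  expect_true(all(eff_rep$n_pw == 20))
})

test_that("Welch t matches the closed form and the brute-force formula", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, 4)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")

  for (seed in 1:20) {
    set.seed(seed)
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5, 1.7)
    w <- welch_t(a, b)
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
    df_ref <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    expect_equal(w$statistic, t_ref, tolerance = 1e-10)
    expect_equal(w$df, df_ref, tolerance = 1e-10)
    expect_equal(w$p, 2 * stats::pt(-abs(t_ref), df_ref), tolerance = 1e-10)
  }
})

test_that("Welch df reduces to 2(n-1) for equal n and equal variances", {
  for (n in c(3, 5, 8, 27)) {
    a <- rnorm(n)
    b <- a + 2.5  # identical sample variance by construction
    expect_equal(welch_t(a, b)$df, 2 * (n - 1))
  }
})

test_that("balanced two-way ANOVA reproduces the hand decomposition", {
  tab <- make_anova_table(list(
    PW.japonica = c(1, 1), LW.japonica = c(3, 3),
    PW.indica = c(5, 5), LW.indica = c(7, 7)))
  an <- anova_two_way_balanced(tab, "gs")
  ss <- setNames(an$ss, an$term)
  expect_equal(unname(ss["treatment"]), 8)
  expect_equal(unname(ss["subspecies"]), 32)
  expect_equal(unname(ss["treatment:subspecies"]), 0)
  expect_equal(unname(ss["error"]), 0)
  expect_equal(sum(an$ss), attr(an, "total_ss"))

  flat <- make_anova_table(list(
    PW.japonica = c(2, 2), LW.japonica = c(2, 2),
    PW.indica = c(2, 2), LW.indica = c(2, 2)))
  an0 <- anova_two_way_balanced(flat, "gs")
  expect_true(all(an0$ss < 1e-12))

  unbal <- make_anova_table(list(
    PW.japonica = c(1, 2, 3), LW.japonica = c(3, 3),
    PW.indica = c(5, 5), LW.indica = c(7, 7)))
  expect_error(anova_two_way_balanced(unbal, "gs"), "not balanced")
})

test_that("ANOVA SS decomposition sums to total SS on random balanced tables", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:5, 1)
    cells <- lapply(setNames(
      nm = c("PW.japonica", "LW.japonica", "PW.indica", "LW.indica")),
      function(...) rnorm(n, 10, 3))
    an <- anova_two_way_balanced(make_anova_table(cells), "gs")
    expect_equal(sum(an$ss), attr(an, "total_ss"),
                 tolerance = 1e-8)
  }
})

test_that("correlation matrix flags strong pairs and handles constants", {
  set.seed(9)
  base <- random_trait_table(9, n_genotypes = 6, n_reps = 2,
                             traits = "gs")
  dup <- as.data.frame(base)
  dup$trait <- "SD"
  dup$value <- 2 * base$value + 5       # perfectly collinear
  const <- as.data.frame(base)
  const$trait <- "LT"
  const$value <- 28
  tab <- trait_table(rbind(as.data.frame(base), dup, const))
  cm <- correlation_matrix(tab)
  expect_equal(cm$r["gs", "SD"], 1)
  pair <- paste(pmin(cm$strong_pairs$trait1, cm$strong_pairs$trait2),
                pmax(cm$strong_pairs$trait1, cm$strong_pairs$trait2))
  expect_true("SD gs" %in% pair)
  expect_true(all(is.na(cm$r["LT", ])))
  expect_false("LT" %in% c(cm$strong_pairs$trait1, cm$strong_pairs$trait2))
})

test_that("independent noise traits stay below |r| = 0.1 at n = 1000", {
  set.seed(4)
  grid <- expand.grid(replicate = 1, treatment = c("PW", "LW"),
                      genotype = sprintf("G%03d", 1:500),
                      trait = c("gs", "CEW"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$subspecies <- "japonica"; grid$trial <- "T1"; grid$week <- 10
  grid$value <- rnorm(nrow(grid))
  cm <- correlation_matrix(trait_table(grid))
  expect_lt(abs(cm$r["gs", "CEW"]), 0.1)
})

test_that("correlation PCA satisfies its algebraic identities", {
  set.seed(12)
  x <- matrix(rnorm(200), 25, 8)
  colnames(x) <- paste0("t", 1:8)
  p <- pca_correlation(x)
  expect_equal(sum(p$eigenvalues), 8, tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(p$proportions, p$eigenvalues / 8)
  # loadings orthonormal and reconstruction exact
  expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  recon <- p$loadings %*% diag(p$eigenvalues) %*% t(p$loadings)
  expect_equal(recon, cor(x), tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading entry positive
  for (k in 1:8) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
  expect_error(pca_correlation(cbind(x, const = 1)), "const")
})

test_that("two correlated traits give the closed-form eigenvalues", {
  set.seed(2)
  z <- matrix(rnorm(4000), 2000, 2)
  x <- z %*% chol(matrix(c(1, 0.6, 0.6, 1), 2))
  p <- pca_correlation(x)
  r <- cor(x)[1, 2]
  expect_equal(p$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-10)
  expect_equal(p$proportions, c(1 + r, 1 - r) / 2, tolerance = 1e-10)
  # identity correlation: all eigenvalues 1
  p_id <- pca_correlation(matrix(rnorm(3e5), 1e5, 3))
  expect_equal(p_id$eigenvalues, rep(1, 3), tolerance = 0.05)
})
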