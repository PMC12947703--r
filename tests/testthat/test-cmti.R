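test_that("trait prioritisation honours the three modes", {
  effects <- data.frame(trait = c("gs", "LT"), d = c(-1.4, 0.2))
  cfg <- cmti_config("cohens_d", d_threshold = 0.8)
  expect_identical(prioritise_traits(effects, config = cfg), "gs")

  vip <- structure(list(scores = c(gs = 1.6, FvFm = 0.7),
                        selected = "gs", threshold = 1),
                   class = "vip_result")
  cfg_v <- cmti_config("pls_vip")
  expect_identical(prioritise_traits(vip = vip, config = cfg_v), "gs")

  seven <- c("PhiPSII", "FvFm", "gs", "SD", "PhiNPQ", "NPQt", "CEW")
  cfg_e <- cmti_config("explicit", traits = seven)
  expect_setequal(prioritise_traits(config = cfg_e), seven)

  # neutral-direction traits are excluded with a warning
  cfg_n <- cmti_config("explicit", traits = c("gs", "pctC"))
  expect_warning(out <- prioritise_traits(config = cfg_n), "neutral")
  expect_identical(out, "gs")

  expect_error(
    prioritise_traits(data.frame(trait = "LT", d = 0.1), config = cfg),
    "no traits selected")
})

test_that("plasticity normalization min-max scales aligned relative change", {
  # two genotypes, CEW (+ under LW expected): +20% vs +5% -> 1 and 0
  rows <- rbind(
    make_rows(2, genotype = "G01", treatment = "PW", trait = "CEW",
              value = c(10, 10)),
    make_rows(2, genotype = "G01", treatment = "LW", trait = "CEW",
              value = c(12, 12)),
    make_rows(2, genotype = "G02", treatment = "PW", trait = "CEW",
              value = c(10, 10)),
    make_rows(2, genotype = "G02", treatment = "LW", trait = "CEW",
              value = c(10.5, 10.5)))
  tab <- trait_table(rows)
  norm <- normalize_traits(tab, "CEW")
  expect_equal(norm["G01", "CEW"], 1)
  expect_equal(norm["G02", "CEW"], 0)
})

test_that("moving against the expected direction always scores lower", {
  for (seed in 1:20) {
    set.seed(seed)
    pw <- runif(2, 5, 50)
    with_dir <- pw[1] * (1 + runif(1, 0.01, 0.5))    # CEW up under LW
    against <- pw[2] * (1 - runif(1, 0.01, 0.5))     # CEW down under LW
    rows <- rbind(
      make_rows(2, genotype = "G01", treatment = "PW", trait = "CEW",
                value = rep(pw[1], 2)),
      make_rows(2, genotype = "G01", treatment = "LW", trait = "CEW",
                value = rep(with_dir, 2)),
      make_rows(2, genotype = "G02", treatment = "PW", trait = "CEW",
                value = rep(pw[2], 2)),
      make_rows(2, genotype = "G02", treatment = "LW", trait = "CEW",
                value = rep(against, 2)))
    norm <- normalize_traits(trait_table(rows), "CEW")
    expect_gt(norm["G01", "CEW"], norm["G02", "CEW"])
  }
})

test_that("constant traits are dropped and degenerate inputs rejected", {
  rows <- rbind(
    make_rows(1, genotype = "G01", treatment = "PW", trait = "CEW",
              value = 10),
    make_rows(1, genotype = "G01", treatment = "LW", trait = "CEW",
              value = 12),
    make_rows(1, genotype = "G02", treatment = "PW", trait = "CEW",
              value = 10),
    make_rows(1, genotype = "G02", treatment = "LW", trait = "CEW",
              value = 12))
  expect_warning(expect_error(normalize_traits(trait_table(rows), "CEW"),
                              "no usable traits"),
                 "constant")
  one <- trait_table(make_rows(2, trait = "CEW"))
  expect_error(normalize_traits(one, "CEW"), "at least 2 genotypes")
})

test_that("CMTI is the row mean, bounded, and symmetric in trait order", {
  m <- rbind(G01 = c(0.2, 0.4, 0.6), G02 = c(1, 1, 1), G03 = c(0, 0.5, 1))
  colnames(m) <- c("gs", "SD", "CEW")
  res <- compute_cmti(m)
  expect_equal(res$cmti[res$genotype == "G01"], 0.4)
  expect_equal(res$cmti[res$genotype == "G02"], 1.0)
  expect_equal(res$rank[res$genotype == "G02"], 1L)
  expect_setequal(res$rank, 1:3)
  perm <- compute_cmti(m[, c(3, 1, 2)])
  expect_equal(perm$cmti, res$cmti)
  expect_error(compute_cmti(m[, 0]), "empty")
  expect_error(compute_cmti(m * 2), "0, 1")
})

test_that("CMTI absorbs unit changes of a raw trait", {
  tab <- random_trait_table(6, n_genotypes = 5, n_reps = 4,
                            traits = c("gs", "CEW"))
  # plasticity mode is built on relative change, so any positive rescaling
  # (a unit conversion) leaves it untouched
  base <- compute_cmti(normalize_traits(tab, c("gs", "CEW")))
  scaled <- as.data.frame(tab)
  sel <- scaled$trait == "CEW"
  scaled$value[sel] <- 3.7 * scaled$value[sel]
  res <- compute_cmti(normalize_traits(trait_table(scaled), c("gs", "CEW")))
  expect_equal(res$cmti, base$cmti, tolerance = 1e-10)
  expect_true(all(base$cmti >= 0 & base$cmti <= 1))

  # treatment-level mode min-max scales per trait, so it additionally
  # absorbs strictly increasing affine maps (offset changes included)
  base_tl <- compute_cmti(normalize_traits(tab, c("gs", "CEW"),
                                           mode = "treatment_level"))
  affine <- as.data.frame(tab)
  affine$value[sel] <- 3.7 * affine$value[sel] + 210
  res_tl <- compute_cmti(normalize_traits(trait_table(affine),
                                          c("gs", "CEW"),
                                          mode = "treatment_level"))
  expect_equal(res_tl$cmti, base_tl$cmti, tolerance = 1e-10)
})

test_that("classification matches the worked splits", {
  v <- c(a = 0.10, b = 0.15, c = 0.20, d = 0.80, e = 0.85)
  cls <- classify_genotypes(v)
  expect_identical(unname(cls[c("a", "b", "c")]), rep("stable", 3))
  expect_identical(unname(cls[c("d", "e")]), rep("plastic", 2))
  two <- classify_genotypes(c(x = 0.1, y = 0.9))
  expect_identical(unname(two), c("stable", "plastic"))
  expect_warning(flat <- classify_genotypes(c(a = 0.5, b = 0.5)),
                 "identical")
  expect_identical(unname(flat), c("stable", "stable"))
})

test_that("classification equals brute-force exhaustive two-class minimization", {
  for (seed in 1:25) {
    set.seed(seed)
    g <- sample(3:9, 1)
    v <- setNames(runif(g), paste0("G", seq_len(g)))
    expect_identical(classify_genotypes(v), setNames(
      brute_force_two_class(v), names(v)))
  }
})

test_that("effect-size and VIP prioritisation classify synthetic genotypes alike", {
  agree <- vapply(1:10, function(s) {
    sim <- generate_dataset(simulation_config(seed = s))
    mat <- trait_means_matrix(sim$table)
    X <- mat[, setdiff(colnames(mat), "delta13C")]
    vip <- vip_scores(fit_pls1(X, mat[, "delta13C"], 2))
    d_cls <- suppressWarnings(run_cmti(sim$table, cmti_config("cohens_d")))
    v_cls <- suppressWarnings(
      run_cmti(sim$table, cmti_config("pls_vip"), vip = vip))
    mean(d_cls$class == v_cls$class[match(d_cls$genotype, v_cls$genotype)])
  }, 0)
  expect_gte(mean(agree), 0.8)
})

test_that("treatment-level normalization reflects decrease traits", {
  # gs is expected to fall under LW: the genotype with the lowest gs should
  # receive the highest treatment-level score
  rows <- rbind(
    make_rows(2, genotype = "G01", treatment = "PW", trait = "gs",
              value = c(300, 300)),
    make_rows(2, genotype = "G01", treatment = "LW", trait = "gs",
              value = c(250, 250)),
    make_rows(2, genotype = "G02", treatment = "PW", trait = "gs",
              value = c(450, 450)),
    make_rows(2, genotype = "G02", treatment = "LW", trait = "gs",
              value = c(440, 440)))
  norm <- normalize_traits(trait_table(rows), "gs",
                           mode = "treatment_level")
  expect_gt(norm["G01", "gs"], norm["G02", "gs"])
  expect_true(all(norm >= 0 & norm <= 1))
})
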