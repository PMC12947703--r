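# Fixture builders shared across the suite. All synthetic, built in code.

# Minimal valid long-format data frame, n rows of a single genotype/trait.
make_rows <- function(n = 4, genotype = "G01", subspecies = "japonica",
                      treatment = "PW", trial = "T1", trait = "gs",
                      week = 10, value = seq_len(n)) {
  data.frame(genotype = genotype, subspecies = subspecies,
             treatment = treatment, trial = trial,
             replicate = seq_len(n), trait = trait, week = week,
             value = value, stringsAsFactors = FALSE)
}

# Balanced two-genotype (one per subspecies) x two-treatment table with
# fixed cell values; used for the ANOVA decomposition example.
make_anova_table <- function(cells) {
  # cells: named list PW.japonica, LW.japonica, PW.indica, LW.indica
  rows <- do.call(rbind, lapply(names(cells), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    subsp <- parts[2]
    make_rows(n = length(cells[[key]]),
              genotype = ifelse(subsp == "japonica", "G01", "G02"),
              subspecies = subsp, treatment = parts[1],
              value = cells[[key]])
  }))
  trait_table(rows)
}

# Random valid trait table for property tests.
random_trait_table <- function(seed, n_genotypes = 4, n_reps = 3,
                               traits = c("gs", "CEW")) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_reps),
                      treatment = c("PW", "LW"),
                      genotype = sprintf("G%02d", seq_len(n_genotypes)),
                      trait = traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$subspecies <- ifelse(grid$genotype == "G01", "indica", "japonica")
  grid$trial <- "T1"
  grid$week <- 10
  grid$value <- rnorm(nrow(grid), mean = 100, sd = 10)
  trait_table(grid)
}

# Exhaustive two-class 1-D clustering over all bipartitions; independent
# oracle for classify_genotypes at small G.
brute_force_two_class <- function(values) {
  g <- length(values)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^g - 2)) {
    in_a <- as.logical(bitwAnd(mask, 2^(seq_len(g) - 1)))
    a <- values[in_a]; b <- values[!in_a]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- in_a
    }
  }
  cls <- ifelse(best, "A", "B")
  # label the lower-mean cluster stable
  if (mean(values[best]) > mean(values[!best])) {
    cls <- ifelse(best, "B", "A")
  }
  ifelse(cls == "A", "stable", "plastic")
}
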