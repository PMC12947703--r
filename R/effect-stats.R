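#' Cohen's d and Hedges' g for a treatment contrast
#'
#' Pooled-standard-deviation standardized mean difference, with the
#' small-sample (Hedges) correction `g = d * (1 - 3 / (4N - 9))`. The sign
#' convention is first group minus second group; the per-trait driver
#' [effect_sizes_by_trait()] passes LW first so that positive d means the
#' trait rose under limited water.
#'
#' @param lw,pw Numeric vectors of at least 2 values each.
#' @return A list of class `effect_size` with the group summaries,
#'   `pooled_sd`, `d` and `hedges_g`.
#' @export
cohens_d <- function(lw, pw) {
  n_lw <- length(lw); n_pw <- length(pw)
  if (n_lw < 2L || n_pw < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  sd_lw <- stats::sd(lw); sd_pw <- stats::sd(pw)
  pooled <- sqrt(((n_lw - 1) * sd_lw^2 + (n_pw - 1) * sd_pw^2) /
                 (n_lw + n_pw - 2))
  if (pooled == 0) {
    stop("degenerate contrast: pooled standard deviation is zero",
         call. = FALSE)
  }
  d <- (mean(lw) - mean(pw)) / pooled
  g <- d * (1 - 3 / (4 * (n_lw + n_pw) - 9))
  structure(list(mean_lw = mean(lw), mean_pw = mean(pw),
                 sd_lw = sd_lw, sd_pw = sd_pw,
                 n_lw = n_lw, n_pw = n_pw,
                 pooled_sd = pooled, d = d, hedges_g = g),
            class = "effect_size")
}

#' Per-trait Cohen's d across treatments
#'
#' Computes the LW-minus-PW effect size for every trait in a table. At the
#' default `genotype_mean` level each group holds one value per genotype
#' (replicates and trials averaged), avoiding pseudo-replication;
#' `replicate` level uses raw plant values.
#'
#' @param table A [trait_table()].
#' @param level `"genotype_mean"` (default) or `"replicate"`.
#' @return A data frame, one row per trait, with columns `trait`,
#'   `mean_pw`, `mean_lw`, `sd_pw`, `sd_lw`, `n_pw`, `n_lw`, `pooled_sd`,
#'   `d`, `hedges_g`. Traits observed under a single treatment are skipped
#'   with a warning.
#' @export
effect_sizes_by_trait <- function(table,
                                  level = c("genotype_mean", "replicate")) {
  level <- match.arg(level)
  stopifnot(inherits(table, "trait_table"))
  traits <- sort(unique(table$trait))
  rows <- lapply(traits, function(tr) {
    sub <- table[table$trait == tr, , drop = FALSE]
    if (length(unique(sub$treatment)) < 2L) {
      warning("trait ", tr, " observed under a single treatment; skipped",
              call. = FALSE)
      return(NULL)
    }
    if (level == "genotype_mean") {
      lw_vals <- tapply(sub$value[sub$treatment == "LW"],
                        sub$genotype[sub$treatment == "LW"], mean)
      pw_vals <- tapply(sub$value[sub$treatment == "PW"],
                        sub$genotype[sub$treatment == "PW"], mean)
    } else {
      lw_vals <- sub$value[sub$treatment == "LW"]
      pw_vals <- sub$value[sub$treatment == "PW"]
    }
    es <- cohens_d(as.numeric(lw_vals), as.numeric(pw_vals))
    data.frame(trait = tr, mean_pw = es$mean_pw, mean_lw = es$mean_lw,
               sd_pw = es$sd_pw, sd_lw = es$sd_lw,
               n_pw = es$n_pw, n_lw = es$n_lw,
               pooled_sd = es$pooled_sd, d = es$d, hedges_g = es$hedges_g,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no trait had both treatments", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Welch unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom, two-sided p-value), returning
#' only the statistic triple.
#'
#' @param a,b Numeric vectors of at least 2 values each.
#' @return A list of class `welch_test` with `statistic`, `df` and `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both groups have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value),
            class = "welch_test")
}

#' Balanced two-way ANOVA for one trait
#'
#' Fits the fixed-effects two-way model with interaction via [stats::aov()]
#' on a strictly balanced design (equal cell counts of at least 2) and
#' returns the sums-of-squares decomposition. Unbalanced designs are
#' rejected: the multi-trial hierarchical cases belong to mixed-effects
#' modelling, which this package deliberately does not re-implement.
#'
#' @param table A [trait_table()].
#' @param trait Trait to analyse.
#' @param factor_a,factor_b Column names of the two crossed factors
#'   (defaults `"treatment"` and `"subspecies"`).
#' @return A data frame with rows for factor A, factor B, the interaction
#'   and error, columns `term`, `ss`, `df`, `ms`, `F`, `p`, plus a
#'   `total_ss` attribute.
#' @export
anova_two_way_balanced <- function(table, trait, factor_a = "treatment",
                                   factor_b = "subspecies") {
  stopifnot(inherits(table, "trait_table"))
  sub <- table[table$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("trait not present: ", trait, call. = FALSE)
  fa <- factor(sub[[factor_a]]); fb <- factor(sub[[factor_b]])
  counts <- table(fa, fb)
  if (length(unique(as.vector(counts))) != 1L || min(counts) < 2L) {
    stop("design is not balanced with cell counts >= 2; ",
         "unbalanced designs are unsupported (use mixed models instead)",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ A * B, data = data.frame(value = sub$value,
                                                     A = fa, B = fb))
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  term_labels <- c("A" = factor_a, "B" = factor_b,
                   "A:B" = paste(factor_a, factor_b, sep = ":"),
                   "Residuals" = "error")
  out <- data.frame(term = unname(term_labels[terms]),
                    ss = tab[["Sum Sq"]],
                    df = tab[["Df"]],
                    ms = tab[["Mean Sq"]],
                    F = tab[["F value"]],
                    p = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total_ss") <- sum((sub$value - mean(sub$value))^2)
  out
}

#' Trait correlation matrix with strong-pair flagging
#'
#' Pearson correlations between traits on genotype-mean values, with pairs
#' at `|r| >= threshold` listed separately. Constant traits get `NA`
#' rows/columns and are excluded from the strong-pair list.
#'
#' @param table A [trait_table()].
#' @param threshold Absolute-correlation flagging threshold (default 0.5).
#' @param by `"pooled"` (default; genotype x treatment mean rows) or
#'   `"treatment"` (one matrix per treatment, genotype mean rows).
#' @return For `by = "pooled"` a list of class `trait_correlations` with
#'   elements `traits`, `r` and `strong_pairs`; for `by = "treatment"` a
#'   named list of such objects.
#' @export
correlation_matrix <- function(table, threshold = 0.5,
                               by = c("pooled", "treatment")) {
  by <- match.arg(by)
  stopifnot(inherits(table, "trait_table"))
  if (by == "treatment") {
    out <- lapply(c("PW", "LW"), function(trt) {
      correlation_matrix(
        trait_table(as.data.frame(table[table$treatment == trt, ])),
        threshold = threshold, by = "pooled")
    })
    names(out) <- c("PW", "LW")
    return(out)
  }
  mat <- trait_means_matrix(table, unit = "genotype_treatment")
  if (nrow(mat) < 3L) {
    stop("need at least 3 complete samples per trait pair", call. = FALSE)
  }
  sds <- apply(mat, 2, stats::sd)
  r <- suppressWarnings(stats::cor(mat))
  constant <- sds == 0
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r)[!constant] <- 1
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  strong <- data.frame(trait1 = colnames(r)[pairs[, 1]],
                       trait2 = colnames(r)[pairs[, 2]],
                       r = r[pairs], stringsAsFactors = FALSE)
  structure(list(traits = colnames(r), r = r, strong_pairs = strong,
                 threshold = threshold),
            class = "trait_correlations")
}

#' Correlation-matrix principal component analysis
#'
#' Eigen-decomposition of the trait Pearson correlation matrix. Each
#' eigenvalue's share of variance is `lambda / p`, where `p` is the trait
#' count (eigenvalues of a correlation matrix sum to `p`). Loading columns
#' are oriented so their largest-magnitude entry is positive; scores are
#' standardized samples projected on the loadings.
#'
#' @param x A numeric sample x trait matrix with at least 3 rows and 2
#'   columns and no constant column.
#' @return A list of class `correlation_pca` with `eigenvalues`
#'   (non-increasing), `proportions`, `loadings`, `scores` and `n_traits`.
#' @seealso [eigenvalue_variance_pct()]
#' @export
pca_correlation <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 3L) {
    stop("need at least 3 samples and 2 traits", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  dimnames(vectors) <- list(colnames(x), paste0("PC", seq_along(values)))
  scores <- scale(x) %*% vectors
  structure(list(eigenvalues = values,
                 proportions = values / ncol(x),
                 loadings = vectors,
                 scores = scores,
                 n_traits = ncol(x)),
            class = "correlation_pca")
}

#' Percent variance explained by a correlation-PCA eigenvalue
#'
#' For PCA on a correlation matrix of `p` traits the total variance equals
#' `p`, so an eigenvalue `lambda` explains `100 * lambda / p` percent.
#'
#' @param lambda Eigenvalue(s).
#' @param n_traits Number of traits `p`.
#' @return Percentage(s).
#' @examples
#' eigenvalue_variance_pct(4.22, 8)  # 52.75
#' @export
eigenvalue_variance_pct <- function(lambda, n_traits) {
  stopifnot(n_traits >= 1, all(lambda >= 0))
  100 * lambda / n_traits
}
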