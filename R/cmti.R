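#' Configuration for the Composite Multi-Trait Index
#'
#' The CMTI summarizes each genotype's adjustment to limited water as the
#' unweighted mean of directionally adjusted, 0-1 normalized trait scores.
#' Traits enter the index through one of three prioritisation modes:
#' effect-size screening (`|d| >= d_threshold`), PLS-VIP selection
#' (`VIP > vip_threshold`), or an explicit list.
#'
#' @param prioritisation `"cohens_d"`, `"pls_vip"` or `"explicit"`.
#' @param d_threshold Absolute Cohen's d cutoff for `cohens_d` mode. The
#'   default 0.8 is the conventional "large effect" benchmark.
#' @param vip_threshold VIP cutoff for `pls_vip` mode (default 1).
#' @param traits Explicit trait list for `explicit` mode.
#' @param normalization_mode `"plasticity"` (default; index built from the
#'   treatment-induced relative change per genotype) or `"treatment_level"`
#'   (per-treatment genotype means, min-max scaled and reflected for
#'   decrease-under-LW traits, then averaged over treatments).
#' @param registry Trait registry supplying the expected LW directions.
#' @return A list of class `cmti_config`.
#' @export
cmti_config <- function(prioritisation = c("cohens_d", "pls_vip", "explicit"),
                        d_threshold = 0.8, vip_threshold = 1,
                        traits = NULL,
                        normalization_mode = c("plasticity", "treatment_level"),
                        registry = default_registry()) {
  prioritisation <- match.arg(prioritisation)
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(d_threshold > 0, vip_threshold > 0)
  if (prioritisation == "explicit" && length(traits) == 0L) {
    stop("explicit mode requires a non-empty trait list", call. = FALSE)
  }
  structure(list(prioritisation = prioritisation,
                 d_threshold = d_threshold,
                 vip_threshold = vip_threshold,
                 traits = traits,
                 normalization_mode = normalization_mode,
                 registry = registry),
            class = "cmti_config")
}

#' Select the traits entering the CMTI
#'
#' @param effects Output of [effect_sizes_by_trait()] (required in
#'   `cohens_d` mode).
#' @param vip A [vip_scores()] result (required in `pls_vip` mode).
#' @param config A [cmti_config()].
#' @return Character vector of selected trait names. Traits with a neutral
#'   registry direction are dropped with a warning, since they cannot be
#'   directionally adjusted.
#' @export
prioritise_traits <- function(effects = NULL, vip = NULL, config) {
  stopifnot(inherits(config, "cmti_config"))
  selected <- switch(config$prioritisation,
    cohens_d = {
      if (is.null(effects) || nrow(effects) == 0L) {
        stop("cohens_d mode needs a non-empty effects table", call. = FALSE)
      }
      effects$trait[abs(effects$d) >= config$d_threshold]
    },
    pls_vip = {
      if (is.null(vip)) stop("pls_vip mode needs a vip result", call. = FALSE)
      vip$selected
    },
    explicit = config$traits
  )
  known <- selected %in% config$registry$trait
  if (any(!known)) {
    stop("selected trait(s) not in registry: ",
         paste(selected[!known], collapse = ", "), call. = FALSE)
  }
  dirs <- lw_direction(config$registry, selected)
  if (any(dirs == "neutral")) {
    warning("excluding neutral-direction trait(s): ",
            paste(selected[dirs == "neutral"], collapse = ", "),
            call. = FALSE)
    selected <- selected[dirs != "neutral"]
  }
  if (length(selected) == 0L) {
    stop("no traits selected; lower the threshold or register directions",
         call. = FALSE)
  }
  selected
}

#' Directionally adjusted 0-1 trait normalization
#'
#' In `plasticity` mode each genotype's raw score for a trait is its signed
#' relative change under limited water, `(LW - PW) / |PW|`, multiplied by
#' +1 when the registry expects the trait to increase under LW and -1 when
#' it expects a decrease, then min-max scaled to 0-1 across genotypes. A
#' genotype moving with the expected direction therefore always outranks
#' one moving against it. In `treatment_level` mode the per-treatment
#' genotype means are min-max scaled per trait within each treatment,
#' decrease-under-LW traits are reflected (`1 - scaled`), and the two
#' treatment matrices are averaged (both are kept as an attribute).
#'
#' @param table A [trait_table()].
#' @param traits Traits to normalize.
#' @param registry Trait registry.
#' @param mode `"plasticity"` or `"treatment_level"`.
#' @return A genotype x trait matrix with entries in 0-1. Traits constant
#'   across genotypes are dropped with a warning.
#' @export
normalize_traits <- function(table, traits, registry = default_registry(),
                             mode = c("plasticity", "treatment_level")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "trait_table"))
  genotypes <- sort(unique(table$genotype))
  if (length(genotypes) < 2L) {
    stop("need at least 2 genotypes to normalize", call. = FALSE)
  }
  dirs <- lw_direction(registry, traits)
  if (any(dirs == "neutral")) {
    warning("dropping neutral-direction trait(s): ",
            paste(traits[dirs == "neutral"], collapse = ", "), call. = FALSE)
    traits <- traits[dirs != "neutral"]
    dirs <- dirs[dirs != "neutral"]
  }
  dsign <- ifelse(dirs == "increase", 1, -1)

  mean_by <- function(trt, tr) {
    sub <- table[table$trait == tr & table$treatment == trt, , drop = FALSE]
    out <- tapply(sub$value, sub$genotype, mean)
    if (!all(genotypes %in% names(out))) {
      stop("genotype(s) missing ", trt, " observations for trait ", tr,
           call. = FALSE)
    }
    as.numeric(out[genotypes])
  }
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(NA_real_, length(x)))
    (x - rng[1]) / diff(rng)
  }

  if (mode == "plasticity") {
    raw <- do.call(cbind, lapply(seq_along(traits), function(j) {
      pw <- mean_by("PW", traits[j]); lw <- mean_by("LW", traits[j])
      if (any(pw == 0)) {
        stop("PW mean is zero for trait ", traits[j], ", genotype ",
             genotypes[which(pw == 0)[1]],
             "; relative change undefined", call. = FALSE)
      }
      dsign[j] * (lw - pw) / abs(pw)
    }))
    norm <- apply(raw, 2, minmax)
  } else {
    norm_trt <- lapply(c("PW", "LW"), function(trt) {
      m <- do.call(cbind, lapply(traits, function(tr) minmax(mean_by(trt, tr))))
      m[, dsign == -1] <- 1 - m[, dsign == -1, drop = FALSE]
      m
    })
    names(norm_trt) <- c("PW", "LW")
    norm <- (norm_trt$PW + norm_trt$LW) / 2
  }
  dimnames(norm) <- list(genotypes, traits)
  constant <- apply(norm, 2, function(col) anyNA(col))
  if (any(constant)) {
    warning("dropping trait(s) constant across genotypes: ",
            paste(traits[constant], collapse = ", "), call. = FALSE)
    norm <- norm[, !constant, drop = FALSE]
  }
  if (ncol(norm) == 0L) stop("no usable traits after normalization",
                             call. = FALSE)
  if (mode == "treatment_level") {
    attr(norm, "by_treatment") <- lapply(norm_trt, function(m) {
      dimnames(m) <- list(genotypes, traits); m[, colnames(norm), drop = FALSE]
    })
  }
  norm
}

#' Compute the Composite Multi-Trait Index
#'
#' `CMTI_i = mean_j(normalized[i, j])` over the selected traits. Rank 1 is
#' the highest index, i.e. the strongest adaptive adjustment under limited
#' water.
#'
#' @param normalized Genotype x trait matrix from [normalize_traits()],
#'   entries in 0-1.
#' @return A data frame of class `cmti_result` with columns `genotype`,
#'   `cmti` and `rank`, and attributes `traits_used` and
#'   `normalized_matrix`.
#' @export
compute_cmti <- function(normalized) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) == 0L) stop("empty trait set", call. = FALSE)
  if (any(normalized < -1e-9) || any(normalized > 1 + 1e-9)) {
    stop("normalized values must lie in [0, 1]", call. = FALSE)
  }
  cmti <- rowMeans(normalized)
  out <- data.frame(genotype = rownames(normalized), cmti = cmti,
                    rank = rank(-cmti, ties.method = "first"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "traits_used") <- colnames(normalized)
  attr(out, "normalized_matrix") <- normalized
  class(out) <- c("cmti_result", "data.frame")
  out
}

#' Split genotypes into stable and plastic classes
#'
#' Deterministic one-dimensional two-class clustering: genotypes are sorted
#' by CMTI and every one of the G - 1 contiguous split points is scored by
#' total within-class sum of squares; the minimizing split wins, with exact
#' ties broken toward the more balanced class sizes. The lower-CMTI class
#' is labelled `stable` (limited trait deviation), the higher one `plastic`
#' (pronounced adaptive adjustment). This is the global optimum of the
#' two-cluster problem, since an optimal 1-D two-class partition is always
#' contiguous in sorted order.
#'
#' @param cmti_values Named numeric vector of CMTI values (or any 1-D
#'   score), one per genotype.
#' @return Named character vector mapping genotype to `"stable"` or
#'   `"plastic"`. If all values are identical a single-class `"stable"`
#'   result is returned with a warning.
#' @export
classify_genotypes <- function(cmti_values) {
  values <- as.numeric(cmti_values)
  g <- length(values)
  if (g < 2L) stop("need at least 2 genotypes", call. = FALSE)
  if (diff(range(values)) == 0) {
    warning("all CMTI values identical; returning a single class",
            call. = FALSE)
    return(stats::setNames(rep("stable", g), names(cmti_values)))
  }
  ord <- order(values)
  sorted <- values[ord]
  wss <- function(x) if (length(x) < 2L) 0 else sum((x - mean(x))^2)
  splits <- seq_len(g - 1)
  total <- vapply(splits, function(s) {
    wss(sorted[seq_len(s)]) + wss(sorted[(s + 1):g])
  }, 0)
  best <- which(total <= min(total) + 1e-12)
  if (length(best) > 1L) {
    balance <- abs(best - (g - best))
    best <- best[which.min(balance)]
  }
  cls <- rep("plastic", g)
  cls[ord[seq_len(best)]] <- "stable"
  stats::setNames(cls, names(cmti_values))
}

#' Run the full CMTI analysis on a trait table
#'
#' Convenience wrapper chaining trait prioritisation, directional
#' normalization, index computation and stable/plastic classification.
#'
#' @param table A [trait_table()].
#' @param config A [cmti_config()].
#' @param effects Optional precomputed [effect_sizes_by_trait()] table;
#'   computed from `table` when needed.
#' @param vip Optional precomputed [vip_scores()] result (required for
#'   `pls_vip` prioritisation).
#' @return A `cmti_result` data frame with an added `class` column.
#' @export
run_cmti <- function(table, config = cmti_config(), effects = NULL,
                     vip = NULL) {
  stopifnot(inherits(config, "cmti_config"))
  if (config$prioritisation == "cohens_d" && is.null(effects)) {
    effects <- effect_sizes_by_trait(table)
  }
  traits <- prioritise_traits(effects, vip, config)
  traits <- intersect(traits, unique(table$trait))
  norm <- normalize_traits(table, traits, config$registry,
                           config$normalization_mode)
  res <- compute_cmti(norm)
  cls <- classify_genotypes(stats::setNames(res$cmti, res$genotype))
  res$class <- unname(cls[res$genotype])
  res
}
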