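#' Simulation configuration for the synthetic phenotyping generator
#'
#' Builds the configuration for [generate_dataset()]. Defaults emulate the
#' glasshouse study design the package targets: 21 genotypes (2 *indica*,
#' 19 *japonica*-type), two irrigation treatments (PW/LW), two trials and
#' 8 replicates per genotype x treatment x trial, with nine leaf traits plus
#' a leaf delta13C response linearly coupled to a known trait subset.
#'
#' Treatment effects are parameterized directly in Cohen's-d units: the LW
#' shift of a trait equals `d * residual_sd`, signed along the registry's
#' limited-water direction, with `d` taken from `d_stable` or `d_plastic`
#' according to the genotype's planted class. The default split is 10 stable
#' genotypes (|d| = 0.2) and 11 plastic ones (|d| = 1.5) on the seven
#' responsive traits (gs, SD, CEW, PhiPSII, FvFm, PhiNPQ, NPQt), while LT
#' and RCh respond weakly (|d| = 0.3) in both classes.
#'
#' Per-plant delta13C is `intercept + sum(coef_j * z_j) + noise` over the
#' informative traits (standardized within the dataset), with default
#' coefficients of magnitude 0.8 (gs), 0.6 (CEW), 0.5 (SD) and 0.4
#' (PhiPSII), each signed along the trait's LW direction so simulated
#' delta13C is less negative under LW, and noise chosen so the linear signal
#' explains roughly 70% of delta13C variance.
#'
#' @param n_genotypes,n_indica,n_trials,n_replicates Design dimensions.
#' @param class_assignment Named character vector genotype -> `"stable"` or
#'   `"plastic"`; `NULL` assigns the first `floor(n/2)` genotypes to stable.
#' @param trait_effects Named list trait -> `list(d_stable=, d_plastic=)`
#'   giving unsigned planted Cohen's d magnitudes.
#' @param baseline,residual_sd Named numeric vectors of trait means and
#'   within-cell standard deviations.
#' @param genotype_sd Genotype baseline-offset spread, in residual-sd units.
#' @param trial_shift_sd Additive trial-shift spread, in residual-sd units.
#' @param delta13c_coefficients Named numeric vector of signed coefficients
#'   on standardized informative traits.
#' @param delta13c_intercept,delta13c_noise_sd delta13C intercept (permil)
#'   and residual noise sd.
#' @param registry Trait registry supplying LW directions.
#' @param seed Master integer seed; every random stream is derived from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genotypes = 21, n_indica = 2, n_trials = 2,
                              n_replicates = 8,
                              class_assignment = NULL,
                              trait_effects = default_trait_effects(),
                              baseline = default_trait_baselines(),
                              residual_sd = default_trait_sds(),
                              genotype_sd = 0.5,
                              trial_shift_sd = 0.3,
                              delta13c_coefficients = default_delta13c_coefficients(),
                              delta13c_intercept = -28.9,
                              delta13c_noise_sd = 0.78,
                              registry = default_registry(),
                              seed = 1L) {
  stopifnot(n_genotypes >= 1, n_indica >= 0, n_indica <= n_genotypes,
            n_trials >= 1, n_replicates >= 1,
            trial_shift_sd >= 0, genotype_sd >= 0, delta13c_noise_sd > 0)
  traits <- names(trait_effects)
  unknown <- setdiff(c(traits, names(delta13c_coefficients)), registry$trait)
  if (length(unknown) > 0L) {
    stop("config names trait(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(traits %in% names(baseline)) ||
      !all(traits %in% names(residual_sd))) {
    stop("baseline and residual_sd must cover every trait in trait_effects",
         call. = FALSE)
  }
  informative <- names(delta13c_coefficients)[delta13c_coefficients != 0]
  if (!all(informative %in% traits)) {
    stop("delta13c_coefficients reference trait(s) not simulated: ",
         paste(setdiff(informative, traits), collapse = ", "), call. = FALSE)
  }
  if (any(residual_sd[traits] <= 0)) {
    stop("residual sds must be strictly positive", call. = FALSE)
  }
  genotypes <- sprintf("G%02d", seq_len(n_genotypes))
  if (is.null(class_assignment)) {
    n_stable <- floor(n_genotypes / 2)
    class_assignment <- stats::setNames(
      rep(c("stable", "plastic"), c(n_stable, n_genotypes - n_stable)),
      genotypes)
  } else {
    if (!all(sort(names(class_assignment)) == sort(genotypes))) {
      stop("class_assignment must name exactly the simulated genotypes",
           call. = FALSE)
    }
    class_assignment <- class_assignment[genotypes]
  }
  stopifnot(all(class_assignment %in% c("stable", "plastic")))
  cfg <- list(
    n_genotypes = as.integer(n_genotypes), n_indica = as.integer(n_indica),
    n_trials = as.integer(n_trials), n_replicates = as.integer(n_replicates),
    genotypes = genotypes, class_assignment = class_assignment,
    trait_effects = trait_effects, baseline = baseline,
    residual_sd = residual_sd, genotype_sd = genotype_sd,
    trial_shift_sd = trial_shift_sd,
    delta13c_coefficients = delta13c_coefficients,
    delta13c_intercept = delta13c_intercept,
    delta13c_noise_sd = delta13c_noise_sd,
    registry = registry, seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' @rdname simulation_config
#' @param d_stable,d_plastic Planted unsigned Cohen's d magnitudes for the
#'   two genotype classes on the responsive traits.
#' @param d_insensitive Planted magnitude for the weakly responding LT and
#'   RCh traits (both classes).
#' @export
default_trait_effects <- function(d_stable = 0.2, d_plastic = 1.5,
                                  d_insensitive = 0.3) {
  responsive <- c("gs", "SD", "CEW", "PhiPSII", "FvFm", "PhiNPQ", "NPQt")
  out <- lapply(responsive, function(t)
    list(d_stable = d_stable, d_plastic = d_plastic))
  names(out) <- responsive
  out$LT <- list(d_stable = d_insensitive, d_plastic = d_insensitive)
  out$RCh <- list(d_stable = d_insensitive, d_plastic = d_insensitive)
  out
}

#' @rdname simulation_config
#' @export
default_trait_baselines <- function() {
  c(gs = 420, SD = 440, CEW = 20, PhiPSII = 0.60, FvFm = 0.78,
    PhiNPQ = 0.25, NPQt = 1.5, LT = 28, RCh = 40)
}

#' @rdname simulation_config
#' @export
default_trait_sds <- function() {
  c(gs = 60, SD = 30, CEW = 3, PhiPSII = 0.05, FvFm = 0.03,
    PhiNPQ = 0.05, NPQt = 0.3, LT = 1.2, RCh = 4)
}

#' @rdname simulation_config
#' @export
default_delta13c_coefficients <- function() {
  c(gs = -0.8, CEW = 0.6, SD = -0.5, PhiPSII = -0.4)
}

# Deterministic 31-bit sub-seed for a named random stream, so that adding
# streams never perturbs existing ones.
substream_seed <- function(master, key) {
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(master) * 48271) %% 2147483647)
}

direction_sign <- function(direction) {
  c(increase = 1, decrease = -1, neutral = 0)[direction]
}

#' Generate a synthetic genotype x treatment phenotyping dataset
#'
#' Draws replicate trait values as
#' `baseline + genotype offset + trial shift + treatment shift + noise`,
#' where the LW treatment shift is `planted d x residual sd` signed along
#' the registry direction and scaled by the genotype's planted class, then
#' couples per-plant delta13C linearly to the standardized informative
#' traits. Identical seeds give identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `table` (a [trait_table()] including
#'   `delta13C` rows) and `truth` (planted class assignment, informative
#'   traits and realized signed planted d per trait and class).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  traits <- names(cfg$trait_effects)
  genotypes <- cfg$genotypes
  subspecies <- stats::setNames(
    rep(c("indica", "japonica"),
        c(cfg$n_indica, cfg$n_genotypes - cfg$n_indica)), genotypes)

  design <- expand.grid(
    replicate = seq_len(cfg$n_replicates),
    trial = sprintf("T%d", seq_len(cfg$n_trials)),
    treatment = c("PW", "LW"),
    genotype = genotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n_plants <- nrow(design)
  dirs <- lw_direction(cfg$registry, traits)
  dsign <- stats::setNames(direction_sign(dirs), traits)

  plant_values <- matrix(NA_real_, n_plants, length(traits),
                         dimnames = list(NULL, traits))
  class_of <- cfg$class_assignment[design$genotype]
  is_lw <- design$treatment == "LW"

  for (j in seq_along(traits)) {
    tr <- traits[j]
    sd_t <- cfg$residual_sd[[tr]]
    rs <- substream_seed(cfg$seed, paste0("trait:", tr))
    set.seed(rs)
    geno_offset <- stats::setNames(
      stats::rnorm(cfg$n_genotypes, 0, cfg$genotype_sd * sd_t), genotypes)
    trial_shift <- stats::setNames(
      stats::rnorm(cfg$n_trials, 0, cfg$trial_shift_sd * sd_t),
      sprintf("T%d", seq_len(cfg$n_trials)))
    d_geno <- ifelse(class_of == "plastic",
                     cfg$trait_effects[[tr]]$d_plastic,
                     cfg$trait_effects[[tr]]$d_stable)
    shift <- ifelse(is_lw, dsign[[tr]] * d_geno * sd_t, 0)
    plant_values[, j] <- cfg$baseline[[tr]] +
      geno_offset[design$genotype] + trial_shift[design$trial] +
      shift + stats::rnorm(n_plants, 0, sd_t)
  }

  informative <- names(cfg$delta13c_coefficients)[
    cfg$delta13c_coefficients != 0]
  z <- scale(plant_values[, informative, drop = FALSE])
  set.seed(substream_seed(cfg$seed, "delta13C"))
  delta13c <- cfg$delta13c_intercept +
    as.numeric(z %*% cfg$delta13c_coefficients[informative]) +
    stats::rnorm(n_plants, 0, cfg$delta13c_noise_sd)

  all_values <- cbind(plant_values, delta13C = delta13c)
  long <- do.call(rbind, lapply(colnames(all_values), function(tr) {
    data.frame(design, trait = tr, value = all_values[, tr],
               stringsAsFactors = FALSE)
  }))
  long$subspecies <- subspecies[long$genotype]
  long$week <- 10L
  table <- trait_table(long, provenance = sprintf("simulated, seed %d",
                                                  cfg$seed))

  planted_d <- lapply(stats::setNames(traits, traits), function(tr) {
    c(stable = dsign[[tr]] * cfg$trait_effects[[tr]]$d_stable,
      plastic = dsign[[tr]] * cfg$trait_effects[[tr]]$d_plastic)
  })
  truth <- list(
    class_assignment = cfg$class_assignment,
    informative_traits = informative,
    planted_d = planted_d,
    subspecies = subspecies,
    seed = cfg$seed
  )
  list(table = table, truth = truth)
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic ATR-FTIR-like spectrum
#'
#' Gaussian peaks on a linear baseline across an ascending wavenumber grid,
#' with optional Gaussian noise.
#'
#' @param peaks A list of `list(center=, height=, width=)` entries
#'   (width = Gaussian sd, cm-1). May be empty.
#' @param range Wavenumber interval, default `c(400, 4000)` cm-1.
#' @param step Grid step in cm-1.
#' @param baseline Linear baseline coefficients `c(intercept, slope)`.
#' @param noise_sd Absorbance noise sd; 0 disables noise.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An `ftir_spectrum` (see [ftir_spectrum()]).
#' @export
generate_spectrum <- function(peaks = list(), range = c(400, 4000), step = 2,
                              baseline = c(0, 0), noise_sd = 0, seed = 1L) {
  stopifnot(step > 0)
  if (range[2] <= range[1]) stop("empty wavenumber range", call. = FALSE)
  wn <- seq(range[1], range[2], by = step)
  absorb <- baseline[1] + baseline[2] * wn
  for (p in peaks) {
    if (p$center < range[1] || p$center > range[2]) {
      stop("peak at ", p$center, " cm-1 outside spectrum range", call. = FALSE)
    }
    absorb <- absorb + p$height * exp(-(wn - p$center)^2 / (2 * p$width^2))
  }
  if (noise_sd > 0) {
    set.seed(substream_seed(seed, "spectrum"))
    absorb <- absorb + stats::rnorm(length(wn), 0, noise_sd)
  }
  ftir_spectrum(wn, absorb)
}

#' Generate a detached-leaf water-loss weighing series
#'
#' Weights decline exponentially at a given hourly retention rate with
#' optional multiplicative log-normal noise; the initial weight is exact.
#'
#' @param initial_weight Initial leaf weight (g), > 0.
#' @param retention_rate Fraction of weight retained per hour, in (0, 1].
#' @param times Sampling times in minutes, non-negative ascending,
#'   starting at 0.
#' @param noise_sd Log-scale noise sd; 0 disables noise.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A `water_loss_series` (see [water_loss_series()]).
#' @export
generate_water_loss_series <- function(initial_weight, retention_rate, times,
                                       noise_sd = 0, seed = 1L) {
  stopifnot(initial_weight > 0)
  if (retention_rate <= 0 || retention_rate > 1) {
    stop("retention_rate must lie in (0, 1]", call. = FALSE)
  }
  if (any(diff(times) <= 0) || any(times < 0) || times[1] != 0) {
    stop("times must be non-negative, ascending, starting at 0",
         call. = FALSE)
  }
  weights <- initial_weight * retention_rate^(times / 60)
  if (noise_sd > 0) {
    set.seed(substream_seed(seed, "waterloss"))
    noise <- exp(stats::rnorm(length(times), 0, noise_sd))
    noise[1] <- 1
    weights <- weights * noise
  }
  water_loss_series(times, weights)
}
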