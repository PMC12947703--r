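#' Convert a count in a microscope region to a density per mm^2
#'
#' Stomata (or papillae) counted in a fixed region of `width x height`
#' micrometres are converted to a count per square millimetre. The default
#' region is the 600 um x 450 um field used for stomatal counts at 200x
#' magnification.
#'
#' @param count Non-negative count(s).
#' @param region_width_um,region_height_um Region dimensions in um.
#' @return Density in counts per mm^2.
#' @examples
#' density_per_mm2(100)  # 370.37 per mm^2 in the 0.27 mm^2 default region
#' @export
density_per_mm2 <- function(count, region_width_um = 600,
                            region_height_um = 450) {
  if (region_width_um <= 0 || region_height_um <= 0) {
    stop("region dimensions must be positive", call. = FALSE)
  }
  stopifnot(all(count >= 0))
  count / (region_width_um * region_height_um * 1e-6)
}

#' Detached-leaf water-loss series
#'
#' Percent retained at each time point is the leaf weight divided by the
#' initial weight, times 100 (the convention used for detached-leaf
#' weighing assays; note that this formula yields percent *retained*, so
#' the complementary percent *lost* is also returned under an unambiguous
#' name). A monotonicity flag records whether percent retained never
#' increases, which can fail with balance noise.
#'
#' @param times Minutes, ascending, starting at 0.
#' @param weights Positive weights (g), same length as `times`.
#' @return A data frame of class `water_loss_series` with columns `time`,
#'   `weight`, `pct_retained`, `pct_lost`, and attribute `monotone`.
#' @export
water_loss_series <- function(times, weights) {
  if (length(times) != length(weights)) {
    stop("times and weights must have equal length", call. = FALSE)
  }
  if (times[1] != 0) stop("times must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be ascending", call. = FALSE)
  if (weights[1] <= 0) stop("initial weight must be positive", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  pct <- 100 * weights / weights[1]
  out <- data.frame(time = times, weight = weights,
                    pct_retained = pct, pct_lost = 100 - pct)
  attr(out, "monotone") <- all(diff(pct) <= 0)
  class(out) <- c("water_loss_series", "data.frame")
  out
}

#' Yield metrics: filled-grain percentage, harvest index, thousand-grain weight
#'
#' `filled_pct = 100 * filled / total spikelets`;
#' `harvest_index = filled-grain dry weight / above-ground shoot dry
#' biomass`; `tgw` scales the dry mass of a counted grain sample to 1000
#' grains (the standard protocol counts exactly 1000, the default).
#'
#' @param filled_grains,total_spikelets Counts with
#'   `filled_grains <= total_spikelets`, `total_spikelets > 0`.
#' @param grain_dry_weight,shoot_dry_biomass Dry masses (g),
#'   `shoot_dry_biomass > 0`.
#' @param tgw_sample_mass Dry mass (g) of the counted grain sample.
#' @param tgw_sample_count Number of grains in the sample (default 1000).
#' @return A list with `filled_pct`, `harvest_index` and `tgw`.
#' @export
yield_metrics <- function(filled_grains, total_spikelets,
                          grain_dry_weight, shoot_dry_biomass,
                          tgw_sample_mass, tgw_sample_count = 1000) {
  if (total_spikelets <= 0) stop("total_spikelets must be > 0", call. = FALSE)
  if (filled_grains > total_spikelets) {
    stop("filled_grains cannot exceed total_spikelets", call. = FALSE)
  }
  if (shoot_dry_biomass <= 0) stop("shoot biomass must be > 0", call. = FALSE)
  if (tgw_sample_count < 1) stop("tgw_sample_count must be >= 1",
                                 call. = FALSE)
  list(filled_pct = 100 * filled_grains / total_spikelets,
       harvest_index = grain_dry_weight / shoot_dry_biomass,
       tgw = 1000 * tgw_sample_mass / tgw_sample_count)
}

#' Milling metrics: brown, milled and head rice yields
#'
#' All three are percentages of the initial paddy mass: `BRY` for brown
#' rice after dehusking, `MRY` for milled (polished) rice, and `HRR` for
#' intact whole kernels (>= 75% of full grain length). HRR is computed
#' against paddy mass, not milled mass; both conventions exist in the
#' literature, and the paddy-mass one is used here.
#'
#' @param paddy_mass,brown_mass,milled_mass,head_mass Masses (g) with
#'   `head <= milled <= brown <= paddy` and `paddy > 0`.
#' @return A list with `bry`, `mry` and `hrr` (percent).
#' @export
milling_metrics <- function(paddy_mass, brown_mass, milled_mass, head_mass) {
  if (paddy_mass <= 0) stop("paddy mass must be > 0", call. = FALSE)
  if (!(head_mass <= milled_mass && milled_mass <= brown_mass &&
        brown_mass <= paddy_mass)) {
    stop("mass ordering violated: need head <= milled <= brown <= paddy",
         call. = FALSE)
  }
  list(bry = 100 * brown_mass / paddy_mass,
       mry = 100 * milled_mass / paddy_mass,
       hrr = 100 * head_mass / paddy_mass)
}

#' Field-capacity target from a soil dry-down curve
#'
#' The limited-water target moisture content is the midpoint between the
#' initial (saturated) soil moisture and the moisture at the observed
#' wilting day: `target_mc = (MC[1] + MC[wilting]) / 2`. The target is also
#' expressed as a percentage of the initial field capacity.
#'
#' @param moisture Daily soil moisture contents (percent, 0-100).
#' @param wilting_index Index into `moisture` of the first day showing
#'   wilting symptoms (> 1).
#' @param days Optional day labels, ascending, same length as `moisture`.
#' @return A list with `target_mc` (percent) and `pct_of_initial_fc`.
#' @export
drydown_fc_target <- function(moisture, wilting_index, days = NULL) {
  if (any(moisture < 0 | moisture > 100)) {
    stop("moisture values must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(days) && (length(days) != length(moisture) ||
                         any(diff(days) <= 0))) {
    stop("days must be ascending and match moisture length", call. = FALSE)
  }
  if (wilting_index <= 1 || wilting_index > length(moisture)) {
    stop("wilting_index must point past the first observation", call. = FALSE)
  }
  target <- (moisture[1] + moisture[wilting_index]) / 2
  list(target_mc = target,
       pct_of_initial_fc = 100 * target / moisture[1])
}

#' Percent change of a value relative to a reference
#'
#' `100 * (value - reference) / reference`; used, for example, to express
#' papillae apex-area enlargement under limited water relative to the
#' ponded-water mean.
#'
#' @param reference Reference value(s), non-zero.
#' @param value New value(s).
#' @return Percent change.
#' @examples
#' percent_change(3.97, 4.78)  # ~20.4% papillae apex enlargement
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be non-zero", call. = FALSE)
  100 * (value - reference) / reference
}
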