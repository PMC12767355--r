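# Generator configuration and named presets.
#
# Presets are calibrated to printed cohort statistics: per-order gap
# probabilities, per-region gap totals, division/rosette failure rates,
# and constriction checkpoints. Intensity levels (a.u.) are nominal since
# absolute junctional intensities are not reported anywhere; they are fully
# exposed here.

#' Construct a generator configuration
#'
#' All parameters of the synthetic epithelium in one validated object. Most
#' users will start from [preset()] and tweak fields.
#'
#' @param preset_name label carried through outputs.
#' @param n_cells cells per field.
#' @param field_um field size, um (length 1 or 2).
#' @param seed base RNG seed.
#' @param pixel_size_um raster sampling, um/px.
#' @param n_order4,n_order5 4-cell and 5-cell vertices built into each field.
#' @param polarity_factor ML-edge over AP-edge intensity ratio (unitless).
#' @param tcj_enrichment vertex-disk over edge intensity ratio (unitless).
#' @param edge_intensity_base junctional signal above background, a.u.
#' @param background_level cytoplasmic background, a.u.
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param gap_prob_by_order named vector `c("3"=,"4"=,"5"=)`: probability
#'   that a vertex of that order carries a junctional gap.
#' @param gap_radius_um `c(mean, sd)` of the truncated-normal gap radius.
#' @param gap_radius_min_um lower truncation of the gap radius; gaps below
#'   the raster resolution are not resolvable, so this stays above ~1.5 px.
#' @param tj_gap_prob probability that an AJ gap site also carries a (smaller)
#'   tight-junction gap.
#' @param gaps_per_region_target expected merged gap count per 50x50 um
#'   region; used to scale `gap_prob_by_order` when the latter is `NULL`
#'   (see [scale_gap_probs()]), otherwise recorded as metadata.
#' @param division_rate_per_hour scheduled divisions per cell per hour.
#' @param p_no_new_interface probability a completed division never acquires
#'   junctional signal at the daughter-daughter interface.
#' @param p_neighbor_gap probability a division loses junctional signal at a
#'   neighbor contact (not restored within the movie).
#' @param rosette_count rosettes (5-cell vertices formed by T1-like edge
#'   contraction) scheduled per movie.
#' @param p_rosette_gap probability a rosette carries a central gap.
#' @param rosette_fate_probs named vector `c(repaired=, persistent=,
#'   expanding=)`, conditional on the rosette being gapped; must sum to 1.
#' @param constriction_fraction_at named vector of fractional apical-area
#'   decrease at checkpoint times, e.g. `c("90" = 0.17, "180" = 0.22)`
#'   (minutes).
#' @param frame_interval_min movie frame spacing, minutes.
#' @param duration_min movie length, minutes.
#' @param recoil list `L0_um, A_um, tau_s, dt_s, T_s, noise_sd_um` for the
#'   exponential (Kelvin-Voigt) post-ablation recoil trace.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(preset_name = "custom",
                             n_cells = 100L,
                             field_um = c(50, 50),
                             seed = 1L,
                             pixel_size_um = 0.25,
                             n_order4 = 25L,
                             n_order5 = 8L,
                             polarity_factor = 1.5,
                             tcj_enrichment = 1.5,
                             edge_intensity_base = 100,
                             background_level = 50,
                             noise_sd = 4,
                             gap_prob_by_order = c("3" = 0, "4" = 0, "5" = 0),
                             gap_radius_um = c(0.6, 0.2),
                             gap_radius_min_um = 0.45,
                             tj_gap_prob = 0,
                             gaps_per_region_target = NULL,
                             division_rate_per_hour = 0,
                             p_no_new_interface = 0,
                             p_neighbor_gap = 0,
                             rosette_count = 0L,
                             p_rosette_gap = 0,
                             rosette_fate_probs = c(repaired = 0.6, persistent = 0.2, expanding = 0.2),
                             constriction_fraction_at = c("90" = 0.17, "180" = 0.22),
                             frame_interval_min = 6,
                             duration_min = 180,
                             recoil = list(L0_um = 10, A_um = 1.2, tau_s = 4,
                                           dt_s = 2, T_s = 8, noise_sd_um = 0.05)) {
  if (length(field_um) == 1L) field_um <- rep(field_um, 2L)
  if (is.null(gap_prob_by_order) && !is.null(gaps_per_region_target)) {
    stop("gap_prob_by_order is NULL: derive it first with scale_gap_probs()")
  }
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$gap_prob_by_order, cfg$p_no_new_interface, cfg$p_neighbor_gap,
             cfg$p_rosette_gap, cfg$tj_gap_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (!setequal(names(cfg$gap_prob_by_order), c("3", "4", "5")))
    stop("gap_prob_by_order must have names '3', '4', '5'")
  if (abs(sum(cfg$rosette_fate_probs) - 1) > 1e-8)
    stop("rosette_fate_probs must sum to 1")
  if (!setequal(names(cfg$rosette_fate_probs), c("repaired", "persistent", "expanding")))
    stop("rosette_fate_probs must have names repaired/persistent/expanding")
  if (cfg$recoil$tau_s <= 0) stop("recoil tau_s must be > 0")
  if (cfg$frame_interval_min <= 0) stop("frame_interval_min must be > 0")
  if (cfg$recoil$dt_s <= 0 || cfg$recoil$T_s < cfg$recoil$dt_s)
    stop("recoil sampling requires dt_s > 0 and T_s >= dt_s")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config '%s': %d cells / %g x %g um, seed %d>\n",
              x$preset_name, x$n_cells, x$field_um[1], x$field_um[2], x$seed))
  cat(sprintf("  polarity %.2f, TCJ enrichment %.2f, gap probs (%.3f, %.3f, %.3f)\n",
              x$polarity_factor, x$tcj_enrichment,
              x$gap_prob_by_order[["3"]], x$gap_prob_by_order[["4"]],
              x$gap_prob_by_order[["5"]]))
  invisible(x)
}

#' Scale per-order gap probabilities to a target per-region count
#'
#' Given an order profile (relative gap propensities of 3-, 4- and 5+-cell
#' junctions), the expected per-region junction census, and a target expected
#' number of gaps per region, returns probabilities with the same profile
#' whose expected total matches the target. This is how per-region totals
#' printed without per-order fractions are turned into generator settings.
#'
#' @param profile named probabilities `c("3"=,"4"=,"5"=)` defining the shape.
#' @param census_mean expected junctions per region per order class.
#' @param target expected gaps per region.
#' @return scaled probability vector.
#' @export
scale_gap_probs <- function(profile, census_mean, target) {
  expected <- sum(profile * census_mean)
  p <- profile * (target / expected)
  if (any(p > 1)) stop("target is unreachable with this census/profile")
  p
}

# Mean per-region junction census of the two mesh densities, measured over
# generator meshes (within the printed 81-175 / 21-57 / 7-19 ranges).
.census_sparse <- c(91, 25, 8)    # 100 cells / 50x50 um
.census_dense  <- c(148, 45, 15)  # 165 cells / 50x50 um

#' Named generator presets
#'
#' Fully populated configurations for the study's cohorts. Late-stage static
#' presets carry the printed per-order gap fractions; early-stage presets
#' carry the same order profile scaled to the printed per-region totals
#' (12 and 4 gaps/region). Movie presets carry the printed division and
#' rosette failure rates and the apical constriction checkpoints. The
#' `zero_polarity` preset (contractility-inhibited analogue) has unit
#' polarity and no tricellular enrichment.
#'
#' @param name one of `control_early`, `control_late`, `mutant_early`,
#'   `mutant_late`, `control_movie`, `mutant_movie`, `zero_polarity`.
#' @param seed RNG seed stored in the config.
#' @return a [generator_config()].
#' @export
preset <- function(name, seed = 1L) {
  presets <- c("control_early", "control_late", "mutant_early", "mutant_late",
               "control_movie", "mutant_movie", "zero_polarity")
  if (!name %in% presets) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(presets, collapse = ", ")))
  }
  p_mut <- c("3" = 0.18, "4" = 0.49, "5" = 0.78)
  p_ctl <- c("3" = 0.05, "4" = 0.14, "5" = 0.32)
  switch(name,
    mutant_late = generator_config(
      preset_name = name, seed = seed, n_cells = 100L, n_order4 = 25L, n_order5 = 8L,
      polarity_factor = 1.3, gap_prob_by_order = p_mut,
      gaps_per_region_target = 35, tj_gap_prob = 56 / 498),
    control_late = generator_config(
      preset_name = name, seed = seed, n_cells = 165L, n_order4 = 45L, n_order5 = 15L,
      polarity_factor = 1.5, gap_prob_by_order = p_ctl,
      gaps_per_region_target = 18, tj_gap_prob = 9 / 150),
    mutant_early = generator_config(
      preset_name = name, seed = seed, n_cells = 100L, n_order4 = 25L, n_order5 = 8L,
      polarity_factor = 1.2,
      gap_prob_by_order = scale_gap_probs(p_mut, .census_sparse, 12),
      gaps_per_region_target = 12, tj_gap_prob = 56 / 498),
    control_early = generator_config(
      preset_name = name, seed = seed, n_cells = 165L, n_order4 = 45L, n_order5 = 15L,
      polarity_factor = 1.2,
      gap_prob_by_order = scale_gap_probs(p_ctl, .census_dense, 4),
      gaps_per_region_target = 4, tj_gap_prob = 9 / 150),
    mutant_movie = generator_config(
      preset_name = name, seed = seed, n_cells = 220L, field_um = c(100, 100),
      n_order4 = 0L, n_order5 = 0L, polarity_factor = 1.2,
      division_rate_per_hour = 0.20, p_no_new_interface = 0.49,
      p_neighbor_gap = 0.73, rosette_count = 26L, p_rosette_gap = 0.71,
      rosette_fate_probs = c(repaired = 20 / 33, persistent = 7 / 33,
                             expanding = 6 / 33),
      constriction_fraction_at = c("90" = 0.17, "180" = 0.22)),
    control_movie = generator_config(
      preset_name = name, seed = seed, n_cells = 220L, field_um = c(100, 100),
      n_order4 = 0L, n_order5 = 0L, polarity_factor = 1.4,
      division_rate_per_hour = 0.08, p_no_new_interface = 0.01,
      p_neighbor_gap = 0.08, rosette_count = 10L, p_rosette_gap = 0.11,
      rosette_fate_probs = c(repaired = 0.2, persistent = 0.8, expanding = 0),
      constriction_fraction_at = c("90" = 0.17, "180" = 0.22)),
    zero_polarity = generator_config(
      preset_name = name, seed = seed, n_cells = 100L, n_order4 = 25L, n_order5 = 8L,
      polarity_factor = 1, tcj_enrichment = 1)
  )
}
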