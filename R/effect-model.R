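#' Disease-effect model for the synthetic generators
#'
#' Describes how carrier status and EYO shape the synthetic data: intensity
#' trends in affected regions, regional atrophy, random-effect scales, and
#' the latent pathology process that couples tau uptake to intensity change.
#'
#' Two trend shapes are available. `"ramp"` (default) switches the effect on
#' at `effect_onset_eyo` and grows it linearly toward onset; it is the shape
#' used for image phantoms, where presymptomatic carriers far from onset
#' should look normal. `"linear"` makes the effect exactly linear in EYO
#' (plus an optional quadratic term), which is the generating model used by
#' the statistical recovery and calibration simulations.
#'
#' @param affected_regions integer region labels carrying the effect.
#' @param flair_mu_slope FLAIR-mean change, intensity units per EYO year
#'   (negative: signal drops approaching onset).
#' @param t1_mu_slope T1-mean change per EYO year (default 0).
#' @param sigma_slope T1/FLAIR standard-deviation change per EYO year
#'   (positive: heterogeneity rises).
#' @param quadratic_coef curvature added as `sign(slope) * coef * g^2`;
#'   0 disables it.
#' @param trend `"ramp"` or `"linear"` (see above).
#' @param effect_onset_eyo EYO at which the ramp trend switches on.
#' @param atrophy_rate fractional thickness/volume loss per EYO year in
#'   affected carrier regions; must be in [0, 0.2].
#' @param atrophy_onset_eyo EYO at which atrophy begins.
#' @param family_sd,subject_sd,resid_sd random-intercept and residual scales
#'   (intensity units) of the regional metric generator.
#' @param tau_coupling,amyloid_coupling SUVR units per unit of latent
#'   pathology; tau > amyloid by default, mirroring the late, symptom-locked
#'   rise of tau.
#' @param latent_iim named vector: intensity units per unit latent pathology
#'   entering each metric.
#' @param thickness_coupling_iim,thickness_coupling_pet optional couplings
#'   that drive intensity metrics / SUVR from morphometry (used to test
#'   confound removal); default 0.
#' @return list of class `effect_model`.
#' @export
effect_model <- function(affected_regions = default_affected_regions(),
                         flair_mu_slope = -0.8,
                         t1_mu_slope = 0,
                         sigma_slope = 0.4,
                         quadratic_coef = 0,
                         trend = c("ramp", "linear"),
                         effect_onset_eyo = -15,
                         atrophy_rate = 0.02,
                         atrophy_onset_eyo = -8,
                         family_sd = 4, subject_sd = 3, resid_sd = 6,
                         tau_coupling = 0.3, amyloid_coupling = 0.08,
                         latent_iim = c(t1_mu = 0, t1_sigma = 2,
                                        flair_mu = -4, flair_sigma = 2),
                         thickness_coupling_iim = 0,
                         thickness_coupling_pet = 0) {
  trend <- match.arg(trend)
  stopifnot(atrophy_rate >= 0, atrophy_rate <= 0.2,
            family_sd >= 0, subject_sd >= 0, resid_sd > 0)
  structure(list(affected_regions = as.integer(affected_regions),
                 flair_mu_slope = flair_mu_slope, t1_mu_slope = t1_mu_slope,
                 sigma_slope = sigma_slope, quadratic_coef = quadratic_coef,
                 trend = trend, effect_onset_eyo = effect_onset_eyo,
                 atrophy_rate = atrophy_rate,
                 atrophy_onset_eyo = atrophy_onset_eyo,
                 family_sd = family_sd, subject_sd = subject_sd,
                 resid_sd = resid_sd,
                 tau_coupling = tau_coupling,
                 amyloid_coupling = amyloid_coupling,
                 latent_iim = latent_iim,
                 thickness_coupling_iim = thickness_coupling_iim,
                 thickness_coupling_pet = thickness_coupling_pet),
            class = "effect_model")
}

# effect size g(eyo) shared by phantom and table generators
.effect_gain <- function(effect, eyo) {
  if (effect$trend == "ramp") pmax(0, eyo - effect$effect_onset_eyo) else eyo
}

# per-metric intensity deltas for one (eyo, carrier) at each region
effect_deltas <- function(effect, eyo, carrier, region_ids) {
  g <- .effect_gain(effect, eyo)
  aff <- as.numeric(region_ids %in% effect$affected_regions) * as.numeric(carrier)
  curve <- function(slope)
    aff * (slope * g + sign(slope) * effect$quadratic_coef * g^2)
  data.frame(region_id = region_ids,
             t1_mu = curve(effect$t1_mu_slope),
             t1_sigma = curve(effect$sigma_slope),
             flair_mu = curve(effect$flair_mu_slope),
             flair_sigma = curve(effect$sigma_slope))
}

# deterministic per-subject RNG substream: hash subject id with the seed
subject_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.double(seed) * 69069 + h * 2654435) %% 2147483647)
}

# latent pathology score per (visit, region): carrier-only, scaled from 0 at
# effect onset EYO to 1 at symptom onset, with a fixed subject x region
# standard-normal field derived from the seed. Shared by the intensity-metric
# and PET generators so their noise is correlated.
latent_pathology <- function(visits, participants, effect, seed,
                             region_table = default_region_table()) {
  n_reg <- nrow(region_table)
  subj <- unique(visits$subject_id)
  field <- matrix(0, length(subj), n_reg, dimnames = list(subj, NULL))
  for (s in subj) {
    set.seed(subject_seed(seed, s))
    field[s, ] <- rnorm(n_reg)
  }
  carrier <- participants$mutation_status[match(visits$subject_id,
                                                participants$subject_id)] == "carrier"
  ramp01 <- pmin(1, pmax(0, (visits$eyo - effect$effect_onset_eyo) /
                            (0 - effect$effect_onset_eyo)))
  aff <- as.numeric(region_table$region_id %in% effect$affected_regions)
  out <- sweep(field[visits$subject_id, , drop = FALSE], 1L,
               ramp01 * as.numeric(carrier), "*")
  sweep(out, 2L, aff, "*")
}
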