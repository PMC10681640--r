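#' Simulate a dominantly inherited Alzheimer disease cohort
#'
#' Generates participant and visit tables with the structure the trajectory
#' models assume: sibling groups sharing a family (and its mutation mean age
#' at onset), a carrier/non-carrier mix, baseline EYO spread over roughly
#' [-25, +10] years, biennial visits that become annual within 5 years of
#' expected onset, and CDR that turns positive as carriers pass their own
#' (randomly perturbed) onset age. A small Dutch APP E693Q fraction is
#' included so the exclusion filter has work to do.
#'
#' @param n_participants number of participants (>= 2).
#' @param carrier_fraction probability that a participant carries the family
#'   mutation; strictly between 0 and 1.
#' @param visits_per_subject visits simulated per participant.
#' @param seed integer RNG seed; identical seeds give identical tables.
#' @param dutch_fraction probability a family carries the Dutch APP E693Q
#'   mutation (default 0.037).
#' @param background_cdr_rate probability of mutation-independent mild
#'   impairment (persistent CDR 0.5), applied to any participant.
#' @param eyo_range range baseline EYO is drawn from.
#' @return list with data frames `participants` (subject_id, family_id,
#'   mutation_status, gene, is_dutch_E693Q, own_onset_age,
#'   mutation_mean_onset_age, parental_onset_age, apoe4_carrier, sex) and
#'   `visits` (subject_id, session_id, visit_date, age, cdr_global, eyo,
#'   time_since_baseline, baseline_eyo).
#' @export
simulate_cohort <- function(n_participants, carrier_fraction = 0.6,
                            visits_per_subject = 3L, seed = 1L,
                            dutch_fraction = 0.037,
                            background_cdr_rate = 0.05,
                            eyo_range = c(-25, 10)) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (carrier_fraction <= 0 || carrier_fraction >= 1)
    stop("carrier_fraction must be strictly between 0 and 1")
  if (visits_per_subject < 1) stop("visits_per_subject must be >= 1")
  set.seed(as.integer(seed))

  # families of 1-3 siblings
  fam_sizes <- integer(0)
  while (sum(fam_sizes) < n_participants)
    fam_sizes <- c(fam_sizes, sample(1:3, 1, prob = c(0.4, 0.4, 0.2)))
  fam_sizes[length(fam_sizes)] <-
    fam_sizes[length(fam_sizes)] - (sum(fam_sizes) - n_participants)
  fam_sizes <- fam_sizes[fam_sizes > 0]
  n_fam <- length(fam_sizes)
  fam_id <- rep(sprintf("F%04d", seq_len(n_fam)), fam_sizes)

  fam_gene <- sample(c("PSEN1", "PSEN2", "APP"), n_fam, replace = TRUE,
                     prob = c(0.712, 0.083, 0.205))
  fam_dutch <- runif(n_fam) < dutch_fraction
  fam_gene[fam_dutch] <- "APP"
  fam_ao <- pmin(60, pmax(35, rnorm(n_fam, 47, 5)))

  idx_fam <- rep(seq_len(n_fam), fam_sizes)
  carrier <- runif(n_participants) < carrier_fraction
  p <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_participants)),
    family_id = fam_id,
    mutation_status = ifelse(carrier, "carrier", "non_carrier"),
    gene = ifelse(carrier, fam_gene[idx_fam], "none"),
    is_dutch_E693Q = carrier & fam_dutch[idx_fam],
    mutation_mean_onset_age = fam_ao[idx_fam],
    parental_onset_age = fam_ao[idx_fam] + rnorm(n_participants, 0, 2),
    apoe4_carrier = runif(n_participants) < 0.295,
    sex = sample(c("M", "F"), n_participants, replace = TRUE,
                 prob = c(0.435, 0.565)),
    stringsAsFactors = FALSE)

  # disease onset: carriers develop symptoms near the mutation mean AO
  true_onset <- ifelse(carrier, p$mutation_mean_onset_age +
                         rnorm(n_participants, 0, 3), Inf)
  bg_impaired <- runif(n_participants) < background_cdr_rate

  eyo0 <- runif(n_participants, eyo_range[1], eyo_range[2])
  base_age <- pmax(18, p$mutation_mean_onset_age + eyo0)
  base_date <- as.Date("2010-01-01") + round(runif(n_participants, 0, 8 * 365.25))

  visit_rows <- vector("list", n_participants)
  own_ao <- rep(NA_real_, n_participants)
  for (i in seq_len(n_participants)) {
    age <- base_age[i]
    ages <- numeric(visits_per_subject)
    for (k in seq_len(visits_per_subject)) {
      ages[k] <- age
      near_onset <- (age - p$mutation_mean_onset_age[i]) > -5 || age >= true_onset[i]
      age <- age + (if (near_onset) 1 else 2) + rnorm(1, 0, 0.1)
    }
    sympt <- ages >= true_onset[i]
    cdr <- ifelse(!sympt, 0,
                  ifelse(ages - true_onset[i] < 3, 0.5,
                         ifelse(ages - true_onset[i] < 6, 1,
                                ifelse(ages - true_onset[i] < 9, 2, 3))))
    if (bg_impaired[i]) cdr <- pmax(cdr, 0.5)
    sympt <- cdr > 0
    if (any(sympt))
      own_ao[i] <- if (is.finite(true_onset[i])) true_onset[i]
                   else ages[which(sympt)[1]]
    visit_rows[[i]] <- data.frame(
      subject_id = p$subject_id[i],
      session_id = sprintf("%s_v%02d", p$subject_id[i], seq_len(visits_per_subject)),
      visit_date = base_date[i] + round((ages - ages[1]) * 365.25),
      age = ages,
      cdr_global = cdr,
      symptomatic = sympt,
      stringsAsFactors = FALSE)
  }
  p$own_onset_age <- own_ao
  v <- do.call(rbind, visit_rows)

  m <- match(v$subject_id, p$subject_id)
  v$eyo <- compute_eyo(v$age, v$symptomatic,
                       own_onset_age = p$own_onset_age[m],
                       mutation_mean_onset_age = p$mutation_mean_onset_age[m],
                       parental_onset_age = p$parental_onset_age[m],
                       mutation_status = p$mutation_status[m])
  v$time_since_baseline <- stats::ave(v$age, v$subject_id, FUN = function(a) a - a[1])
  v$baseline_eyo <- stats::ave(v$eyo, v$subject_id, FUN = function(e) e[1])
  rownames(v) <- NULL
  p <- p[, c("subject_id", "family_id", "mutation_status", "gene",
             "is_dutch_E693Q", "own_onset_age", "mutation_mean_onset_age",
             "parental_onset_age", "apoe4_carrier", "sex")]
  list(participants = p, visits = v)
}

.visit_carrier <- function(visits, participants) {
  participants$mutation_status[match(visits$subject_id,
                                     participants$subject_id)] == "carrier"
}

#' Simulate regional morphometry (cortical thickness, subcortical volume)
#'
#' Carriers in affected regions lose thickness/volume at `atrophy_rate`
#' (fractional loss per EYO year) once past `atrophy_onset_eyo`; everything
#' else is stable up to subject-level and visit-level multiplicative noise.
#'
#' @param visits,participants tables from [simulate_cohort()].
#' @param effect an [effect_model()].
#' @param seed integer seed.
#' @param region_table from [default_region_table()].
#' @return data frame: `session_id`, `subject_id`, `region_id`, `class`,
#'   `value` (mm for cortical thickness, mm^3 for subcortical volume).
#' @export
simulate_morphometry <- function(visits, participants, effect, seed = 1L,
                                 region_table = default_region_table()) {
  set.seed(subject_seed(seed, "morphometry"))
  n_reg <- nrow(region_table)
  vol_base <- c(Thalamus = 7000, Caudate = 3800, Putamen = 4500,
                Pallidum = 1800, Hippocampus = 4000, Amygdala = 1600)
  base <- ifelse(region_table$class == "cortical",
                 2.5 + 0.2 * sin(region_table$region_id),
                 unname(vol_base[region_table$name]) *
                   (1 + 0.02 * sin(region_table$region_id)))
  subj <- unique(visits$subject_id)
  subj_mult <- matrix(rnorm(length(subj) * n_reg, 1, 0.04), length(subj), n_reg,
                      dimnames = list(subj, NULL))
  carrier <- .visit_carrier(visits, participants)
  aff <- region_table$region_id %in% effect$affected_regions
  n_vis <- nrow(visits)
  yrs <- pmax(0, visits$eyo - effect$atrophy_onset_eyo)
  # n_vis x n_reg shrinkage: atrophy only in affected carrier regions
  shrink <- 1 - outer(as.numeric(carrier) *
                        (1 - (1 - effect$atrophy_rate)^yrs), aff)
  vals <- shrink *
    matrix(base, n_vis, n_reg, byrow = TRUE) *
    subj_mult[visits$subject_id, , drop = FALSE] *
    matrix(rnorm(n_vis * n_reg, 1, 0.02), n_vis, n_reg)
  out <- data.frame(session_id = rep(visits$session_id, each = n_reg),
                    subject_id = rep(visits$subject_id, each = n_reg),
                    region_id = rep(region_table$region_id, n_vis),
                    class = rep(region_table$class, n_vis),
                    value = as.vector(t(vals)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# reference regional intensity parameters shared by the phantom and the
# table generator: deterministic per-region variation around GM values
.region_tissue_params <- function(region_table) {
  r <- region_table$region_id
  n <- max(r)
  data.frame(region_id = r,
             t1_mu = 96 + 8 * (r - 1) / max(1, n - 1),
             t1_sd = 10,
             flair_mu = 124 + 12 * ((r * 0.6180339887) %% 1),
             flair_sd = 12)
}

#' Simulate a regional image-intensity-metric table directly
#'
#' Statistical emulation of the measurement pipeline's output: draws the
#' four regional metrics (T1-mu, T1-sigma, FLAIR-mu, FLAIR-sigma) per
#' session from the mixed-effects structure the trajectory models assume -
#' region baselines, carrier-by-EYO effects in affected regions, family and
#' subject random intercepts, latent-pathology coupling, and residual noise.
#' Used wherever the image path itself is not the thing under test.
#'
#' @inheritParams simulate_morphometry
#' @param morphometry optional morphometry table; only used when the effect
#'   model's `thickness_coupling_iim` is nonzero.
#' @return data frame: `session_id`, `subject_id`, `region_id`, `t1_mu`,
#'   `t1_sigma`, `flair_mu`, `flair_sigma`.
#' @export
simulate_iim_table <- function(visits, participants, effect, seed = 1L,
                               region_table = default_region_table(),
                               morphometry = NULL) {
  n_reg <- nrow(region_table)
  base <- .region_tissue_params(region_table)
  base_vals <- cbind(t1_mu = base$t1_mu, t1_sigma = base$t1_sd,
                     flair_mu = base$flair_mu, flair_sigma = base$flair_sd)

  fam <- unique(participants$family_id)
  subj <- unique(visits$subject_id)
  set.seed(subject_seed(seed, "iim-family"))
  fam_int <- matrix(rnorm(length(fam) * n_reg, 0, effect$family_sd),
                    length(fam), n_reg, dimnames = list(fam, NULL))
  subj_int <- matrix(rnorm(length(subj) * n_reg, 0, effect$subject_sd),
                     length(subj), n_reg, dimnames = list(subj, NULL))
  latent <- latent_pathology(visits, participants, effect, seed, region_table)
  carrier <- .visit_carrier(visits, participants)
  fam_of <- participants$family_id[match(visits$subject_id, participants$subject_id)]

  morph_dev <- NULL
  if (effect$thickness_coupling_iim != 0) {
    if (is.null(morphometry))
      stop("thickness_coupling_iim != 0 requires a morphometry table")
    morph_dev <- .morph_deviation(morphometry, region_table)
  }

  set.seed(subject_seed(seed, "iim-noise"))
  metrics <- c("t1_mu", "t1_sigma", "flair_mu", "flair_sigma")
  n_vis <- nrow(visits)
  g <- .effect_gain(effect, visits$eyo)
  aff <- as.numeric(region_table$region_id %in% effect$affected_regions)
  cv <- as.numeric(carrier)
  slope_of <- c(t1_mu = effect$t1_mu_slope, t1_sigma = effect$sigma_slope,
                flair_mu = effect$flair_mu_slope,
                flair_sigma = effect$sigma_slope)
  re_part <- fam_int[fam_of, , drop = FALSE] +
    subj_int[visits$subject_id, , drop = FALSE]
  morph_mat <- NULL
  if (!is.null(morph_dev))
    morph_mat <- do.call(rbind, morph_dev[visits$session_id])
  out <- data.frame(session_id = rep(visits$session_id, each = n_reg),
                    subject_id = rep(visits$subject_id, each = n_reg),
                    region_id = rep(region_table$region_id, n_vis),
                    stringsAsFactors = FALSE)
  for (m in metrics) {
    sl <- slope_of[[m]]
    trend <- cv * (sl * g + sign(sl) * effect$quadratic_coef * g^2)
    vals <- outer(trend, aff) +
      matrix(base_vals[, m], n_vis, n_reg, byrow = TRUE) +
      re_part + effect$latent_iim[[m]] * latent +
      matrix(rnorm(n_vis * n_reg, 0, effect$resid_sd), n_vis, n_reg)
    if (!is.null(morph_mat))
      vals <- vals + effect$thickness_coupling_iim * morph_mat
    out[[m]] <- as.vector(t(vals))
  }
  rownames(out) <- NULL
  out
}

# standardized per-session regional morphometry deviation (z within region)
.morph_deviation <- function(morphometry, region_table) {
  mu <- stats::ave(morphometry$value, morphometry$region_id)
  s <- stats::ave(morphometry$value, morphometry$region_id,
                  FUN = function(x) if (length(x) > 1) sd(x) else 1)
  z <- (morphometry$value - mu) / ifelse(s > 0, s, 1)
  split(z, morphometry$session_id)
}

#' Simulate amyloid and tau PET SUVR tables
#'
#' Carriers follow the canonical staging: cortical amyloid uptake rises
#' sigmoidally from roughly EYO -20, tau rises late (from roughly EYO -5)
#' and is concentrated in the affected regions; non-carriers are flat at an
#' SUVR of ~1 with noise. Tau additionally loads on the same latent
#' pathology score as the intensity metrics (via `tau_coupling`), so
#' partial-correlation recovery is testable by construction; the amyloid
#' loading is smaller.
#'
#' @inheritParams simulate_iim_table
#' @param morphometry optional; used when `thickness_coupling_pet` is
#'   nonzero.
#' @return list with data frames `amyloid` and `tau`, each with
#'   `pet_session_id`, `subject_id`, `date`, `region_id`, `suvr`.
#' @export
simulate_pet_tables <- function(visits, participants, effect, seed = 1L,
                                region_table = default_region_table(),
                                morphometry = NULL) {
  stopifnot(all(c("eyo", "session_id") %in% names(visits)))
  n_reg <- nrow(region_table)
  carrier <- .visit_carrier(visits, participants)
  latent <- latent_pathology(visits, participants, effect, seed, region_table)
  aff <- region_table$region_id %in% effect$affected_regions
  cortical <- region_table$class == "cortical"

  morph_dev <- NULL
  if (effect$thickness_coupling_pet != 0) {
    if (is.null(morphometry))
      stop("thickness_coupling_pet != 0 requires a morphometry table")
    morph_dev <- .morph_deviation(morphometry, region_table)
  }

  make_table <- function(tracer) {
    set.seed(subject_seed(seed, paste0("pet-", tracer)))
    rows <- vector("list", nrow(visits))
    for (i in seq_len(nrow(visits))) {
      e <- visits$eyo[i]
      if (tracer == "amyloid") {
        amp <- ifelse(cortical, 1.2, 0.6)
        trend <- amp * plogis((e + 12) / 3)
        load <- effect$amyloid_coupling
      } else {
        amp <- ifelse(aff, 0.9, 0.2)
        trend <- amp * plogis((e + 1) / 1.5)
        load <- effect$tau_coupling
      }
      suvr <- 1 + as.numeric(carrier[i]) * trend + load * latent[i, ] +
        rnorm(n_reg, 0, 0.08)
      if (!is.null(morph_dev))
        suvr <- suvr + effect$thickness_coupling_pet * morph_dev[[visits$session_id[i]]]
      rows[[i]] <- data.frame(
        pet_session_id = sprintf("%s_%s", visits$session_id[i],
                                 substr(tracer, 1, 3)),
        subject_id = visits$subject_id[i],
        date = visits$visit_date[i] + sample(-30:30, 1),
        region_id = region_table$region_id,
        suvr = suvr, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  list(amyloid = make_table("amyloid"), tau = make_table("tau"))
}
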