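#' Pipeline configuration
#'
#' Validated configuration for an end-to-end synthetic run. Every field has
#' an actionable default; invalid values raise an error naming the field.
#'
#' @param out_dir output directory (created if needed); required.
#' @param seed integer seed driving every random stage.
#' @param n_participants,carrier_fraction,visits_per_subject cohort size.
#' @param grid_shape phantom grid (small by default: this is a demonstration
#'   pipeline, not a production image run).
#' @param n_regions parcellation size for the phantom run.
#' @param bins histogram bins per axis.
#' @param n_reference reference-population sessions used for the atlas.
#' @param alpha significance level.
#' @param amyloid_window_days,tau_window_days PET-MR matching windows.
#' @param min_voxels minimum voxels per region in metric extraction.
#' @param models `"baseline"`, `"longitudinal"` or both.
#' @param effect an [effect_model()]; defaults to the standard one
#'   restricted to the configured regions.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_participants = 40L,
                            carrier_fraction = 0.6, visits_per_subject = 2L,
                            grid_shape = c(24, 24, 24), n_regions = 16L,
                            bins = 128L, n_reference = 6L, alpha = 0.05,
                            amyloid_window_days = 365L,
                            tau_window_days = 548L, min_voxels = 10L,
                            models = "baseline", effect = NULL) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("config field 'out_dir' is required")
  num_checks <- list(n_participants = n_participants >= 4,
                     carrier_fraction = carrier_fraction > 0 && carrier_fraction < 1,
                     visits_per_subject = visits_per_subject >= 1,
                     bins = bins >= 16, alpha = alpha > 0 && alpha < 1,
                     amyloid_window_days = amyloid_window_days > 0,
                     tau_window_days = tau_window_days > 0,
                     min_voxels = min_voxels >= 1,
                     n_reference = n_reference >= 2)
  for (f in names(num_checks))
    if (!isTRUE(num_checks[[f]])) stop("config field '", f, "' is invalid")
  if (!all(models %in% c("baseline", "longitudinal")))
    stop("config field 'models' must be 'baseline' and/or 'longitudinal'")
  region_table <- default_region_table(n_regions)
  if (is.null(effect))
    effect <- effect_model(
      affected_regions = default_affected_regions(region_table))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 carrier_fraction = carrier_fraction,
                 visits_per_subject = as.integer(visits_per_subject),
                 grid_shape = grid_shape, n_regions = as.integer(n_regions),
                 region_table = region_table, bins = as.integer(bins),
                 n_reference = as.integer(n_reference), alpha = alpha,
                 amyloid_window_days = as.integer(amyloid_window_days),
                 tau_window_days = as.integer(tau_window_days),
                 min_voxels = as.integer(min_voxels), models = models,
                 effect = effect),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  flat <- config[setdiff(names(config), c("region_table", "effect"))]
  flat$effect <- unclass(config$effect)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(flat, tmp, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_stage <- function(x, config, name) {
  x$config_hash <- attr(config, "hash")
  write_cohort_table(x, file.path(config$out_dir, paste0(name, ".tsv")))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in dependency order on seeded synthetic data:
#' cohort simulation (with Dutch-mutation exclusion), phantom generation
#' and bispectral normalization of every session against a reference atlas,
#' regional metric extraction, trajectory models with FDR and the quadratic
#' comparison, and PET partial correlations in the carrier subset. All
#' tables, QC records and a manifest (seed, config hash, package version)
#' are written under `config$out_dir`; a rerun with the same config
#' reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  attr(config, "hash") <- .config_hash(config)

  ## stage 1: cohort ---------------------------------------------------
  cohort <- simulate_cohort(config$n_participants, config$carrier_fraction,
                            config$visits_per_subject, seed = config$seed)
  participants <- apply_exclusions(cohort$participants)
  visits <- cohort$visits[cohort$visits$subject_id %in%
                            participants$subject_id, , drop = FALSE]
  morph <- simulate_morphometry(visits, participants, config$effect,
                                seed = config$seed,
                                region_table = config$region_table)
  pet <- simulate_pet_tables(visits, participants, config$effect,
                             seed = config$seed,
                             region_table = config$region_table)

  ## stage 2: reference atlas + normalization --------------------------
  spec0 <- phantom_spec(config$grid_shape, config$n_regions,
                        region_table = config$region_table)
  ref_hists <- lapply(seq_len(config$n_reference), function(i)
    histogram_from_samples(
      sample_reference_mixture(20000, spec0, seed = config$seed + i),
      bins = config$bins))
  reference <- build_reference(ref_hists, n_iterations = 2)

  status <- participants$mutation_status[match(visits$subject_id,
                                               participants$subject_id)]
  qc_rows <- list(); iim_rows <- list()
  for (i in seq_len(nrow(visits))) {
    scanner <- random_scanner_affine(subject_seed(config$seed,
                                                   visits$session_id[i]))
    ph <- simulate_phantom_pair(
      list(eyo = visits$eyo[i], mutation_status = status[i]),
      spec0, config$effect,
      seed = subject_seed(config$seed, paste0("ph", visits$session_id[i])),
      scanner_affine = scanner)
    ns <- normalize_session(ph$t1, ph$flair, ph$mask, reference,
                            session_id = visits$session_id[i])
    qc_rows[[i]] <- ns$qc
    iim_rows[[i]] <- extract_iim(ns$t1, ns$flair, ph$labels,
                                 config$region_table,
                                 min_voxels = config$min_voxels,
                                 session_id = visits$session_id[i])
  }
  qc <- do.call(rbind, qc_rows)
  iim <- do.call(rbind, iim_rows)
  iim$subject_id <- visits$subject_id[match(iim$session_id, visits$session_id)]

  ## stage 3: models ----------------------------------------------------
  model_data <- assemble_model_data(iim, visits, participants, morph,
                                    config$region_table)
  models_out <- lapply(config$models, function(des)
    fit_cohort_models(model_data, design = des, alpha = config$alpha))
  names(models_out) <- config$models

  ## stage 4: PET associations ------------------------------------------
  mr_sessions <- data.frame(session_id = visits$session_id,
                            subject_id = visits$subject_id,
                            date = visits$visit_date)
  assoc <- list()
  for (tracer in c("amyloid", "tau")) {
    tab <- pet[[tracer]]
    pet_sessions <- unique(tab[, c("pet_session_id", "subject_id", "date")])
    window <- if (tracer == "amyloid") config$amyloid_window_days
              else config$tau_window_days
    prs <- match_pet_to_mr(mr_sessions, pet_sessions, tracer, window)
    assoc[[tracer]] <- run_associations(iim, tab, prs, morph, visits,
                                        participants, tracer = tracer,
                                        subset = "carriers")
  }

  ## outputs -------------------------------------------------------------
  .write_stage(participants, config, "participants")
  .write_stage(visits, config, "visits")
  .write_stage(morph, config, "morphometry")
  .write_stage(iim, config, "iim")
  .write_stage(qc, config, "normalization_qc")
  for (des in config$models) {
    .write_stage(models_out[[des]]$linear, config, paste0("models_", des, "_linear"))
    if (!is.null(models_out[[des]]$comparison))
      .write_stage(models_out[[des]]$comparison, config,
                   paste0("models_", des, "_comparison"))
  }
  for (tracer in names(assoc))
    if (nrow(assoc[[tracer]]))
      .write_stage(assoc[[tracer]], config, paste0("assoc_", tracer))
  manifest <- list(package_version = as.character(utils::packageVersion("iimkit")),
                   seed = config$seed, config_hash = attr(config, "hash"),
                   n_participants_after_exclusion = nrow(participants),
                   n_sessions = nrow(visits),
                   created = "see file mtime")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(participants = participants, visits = visits, morph = morph,
                 iim = iim, qc = qc, models = models_out, assoc = assoc,
                 reference = reference, config = config))
}

#' Draw a random scanner intensity affine
#'
#' Deterministic given the seed: moderate scales (0.75-1.35), small shears,
#' offsets within +/-20 intensity units - a plausible spread of arbitrary
#' per-scanner intensity scales with condition number well below 10.
#'
#' @param seed integer seed.
#' @return an [iaffine2].
#' @export
random_scanner_affine <- function(seed) {
  set.seed(seed)
  iaffine2(matrix(c(runif(1, 0.75, 1.35), runif(1, -0.12, 0.12),
                    runif(1, -0.12, 0.12), runif(1, 0.75, 1.35)), 2, 2),
           c(runif(1, -20, 20), runif(1, -20, 20)))
}
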