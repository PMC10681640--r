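#' Default grey-matter parcellation table
#'
#' The standard 80-region grey-matter set used throughout: 68 cortical
#' regions (34 Desikan-Killiany parcels per hemisphere) and 12 subcortical
#' structures (6 per hemisphere). Cortical regions carry a thickness
#' covariate downstream, subcortical regions a volume covariate.
#'
#' @param n_regions number of regions; the default 80 gives the standard
#'   set. Smaller values (used for small test phantoms) take the first
#'   `n_regions` rows, preserving the cortical/subcortical mix.
#' @return data frame with `region_id` (integer label, 1-based), `name`,
#'   `hemisphere`, `class` (`"cortical"`/`"subcortical"`).
#' @export
default_region_table <- function(n_regions = 80L) {
  cortical <- c(
    "Banks of superior temporal sulcus", "Caudal anterior cingulate",
    "Caudal middle frontal", "Cuneus", "Entorhinal", "Fusiform",
    "Inferior parietal", "Inferior temporal", "Isthmus cingulate",
    "Lateral occipital", "Lateral orbitofrontal", "Lingual",
    "Medial orbitofrontal", "Middle temporal", "Parahippocampal",
    "Paracentral", "Pars opercularis", "Pars orbitalis", "Pars triangularis",
    "Pericalcarine", "Postcentral", "Posterior cingulate", "Precentral",
    "Precuneus", "Rostral anterior cingulate", "Rostral middle frontal",
    "Superior frontal", "Superior parietal", "Superior temporal",
    "Supramarginal", "Frontal pole", "Temporal pole", "Transverse temporal",
    "Insula")
  subcortical <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
                   "Hippocampus", "Amygdala")
  tab <- rbind(
    data.frame(name = rep(cortical, 2),
               hemisphere = rep(c("Left", "Right"), each = length(cortical)),
               class = "cortical", stringsAsFactors = FALSE),
    data.frame(name = rep(subcortical, 2),
               hemisphere = rep(c("Left", "Right"), each = length(subcortical)),
               class = "subcortical", stringsAsFactors = FALSE))
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 1L, n_regions <= nrow(tab))
  if (n_regions < nrow(tab)) {
    n_sub <- max(1L, round(n_regions * 12 / 80))
    n_cor <- n_regions - n_sub
    tab <- rbind(tab[tab$class == "cortical", ][seq_len(n_cor), ],
                 tab[tab$class == "subcortical", ][seq_len(n_sub), ])
  }
  tab$region_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[, c("region_id", "name", "hemisphere", "class")]
}

#' Region labels planted with disease effects by default
#'
#' The default affected set mirrors where intensity change is most
#' prominent in dominantly inherited Alzheimer disease: both supramarginal
#' gyri, right postcentral, right superior temporal, and bilateral caudate,
#' putamen, thalamus and amygdala.
#'
#' @param region_table from [default_region_table()].
#' @return integer vector of region ids.
#' @export
default_affected_regions <- function(region_table = default_region_table()) {
  pick <- with(region_table,
    (name == "Supramarginal") |
    (name == "Postcentral" & hemisphere == "Right") |
    (name == "Superior temporal" & hemisphere == "Right") |
    (name %in% c("Caudate", "Putamen", "Thalamus", "Amygdala")))
  region_table$region_id[pick]
}
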