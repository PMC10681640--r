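#' Estimated years to symptom onset (EYO)
#'
#' EYO at a visit is the participant's age minus the predicted age at
#' symptom onset (AO), so presymptomatic visits have negative EYO. The AO
#' source follows the standard precedence for dominantly inherited Alzheimer
#' cohorts: (1) the participant's own AO if they are symptomatic; (2) the
#' mean AO of their specific mutation if mutation status is known; (3) the
#' parental AO if mutation status is unknown.
#'
#' All arguments are vectorized; scalars are recycled.
#'
#' @param age age in years at the visit.
#' @param symptomatic logical; symptomatic (global CDR > 0) at/by this visit.
#' @param own_onset_age participant's own AO (years), `NA` if never
#'   symptomatic.
#' @param mutation_mean_onset_age mean AO of the family mutation (years).
#' @param parental_onset_age parental AO (years).
#' @param mutation_status `"carrier"`, `"non_carrier"` or `"unknown"`.
#' @return numeric EYO in years (negative before expected onset).
#' @examples
#' compute_eyo(40, TRUE, own_onset_age = 45)                        # -5
#' compute_eyo(50, FALSE, mutation_mean_onset_age = 45)             # +5
#' @export
compute_eyo <- function(age, symptomatic,
                        own_onset_age = NA_real_,
                        mutation_mean_onset_age = NA_real_,
                        parental_onset_age = NA_real_,
                        mutation_status = "carrier") {
  n <- max(length(age), length(symptomatic), length(own_onset_age),
           length(mutation_mean_onset_age), length(parental_onset_age),
           length(mutation_status))
  age <- rep_len(as.numeric(age), n)
  symptomatic <- rep_len(as.logical(symptomatic), n)
  own <- rep_len(as.numeric(own_onset_age), n)
  mut <- rep_len(as.numeric(mutation_mean_onset_age), n)
  par <- rep_len(as.numeric(parental_onset_age), n)
  status <- rep_len(as.character(mutation_status), n)
  bad <- !status %in% c("carrier", "non_carrier", "unknown")
  if (any(bad)) stop("unknown mutation_status value: ",
                     paste(unique(status[bad]), collapse = ", "))
  ao <- ifelse(symptomatic & !is.na(own), own,
               ifelse(status != "unknown", mut, par))
  tier <- ifelse(symptomatic & !is.na(own), 1L,
                 ifelse(status != "unknown", 2L, 3L))
  if (anyNA(ao)) {
    i <- which(is.na(ao))[1]
    lab <- c("own onset age (symptomatic participant)",
             "mutation mean onset age (known mutation status)",
             "parental onset age (unknown mutation status)")[tier[i]]
    stop("missing age-at-onset source required by precedence tier ", tier[i],
         ": ", lab)
  }
  age - ao
}

#' Exclude participants from Dutch APP E693Q families
#'
#' This mutation causes hereditary cerebral hemorrhage with amyloidosis;
#' blood products distort MR signal, so these families are removed before
#' any intensity analysis. The operation is idempotent and order-preserving.
#'
#' @param participants data frame with a logical `is_dutch_E693Q` column.
#' @return the data frame without Dutch-mutation families; the number
#'   excluded is reported via `message()`.
#' @export
apply_exclusions <- function(participants) {
  stopifnot(is.data.frame(participants),
            "is_dutch_E693Q" %in% names(participants))
  drop <- participants$is_dutch_E693Q %in% TRUE
  message(sprintf("apply_exclusions: removed %d of %d participants (Dutch APP E693Q)",
                  sum(drop), nrow(participants)))
  participants[!drop, , drop = FALSE]
}

#' Match PET sessions to their nearest MR session within a window
#'
#' Each PET session is matched, within participant, to the MR session
#' minimizing the absolute acquisition-date gap; pairs whose gap exceeds the
#' tracer window are left unmatched. Ties are broken toward the earlier MR
#' date, deterministically.
#'
#' Default windows: 365 days for amyloid, 548 days (18 months) for tau.
#'
#' @param mr_sessions data frame with `session_id`, `subject_id`, `date`
#'   (Date or ISO-8601 string).
#' @param pet_sessions data frame with `pet_session_id`, `subject_id`, `date`.
#' @param tracer `"amyloid"` or `"tau"`.
#' @param window_days maximum |gap| in days; defaults by tracer.
#' @return data frame of session pairs: `mr_session_id`, `pet_session_id`,
#'   `subject_id`, `tracer`, `gap_days`, plus attribute `"unmatched"` listing
#'   PET sessions with no in-window MR.
#' @export
match_pet_to_mr <- function(mr_sessions, pet_sessions,
                            tracer = c("amyloid", "tau"),
                            window_days = NULL) {
  tracer <- match.arg(tracer)
  if (is.null(window_days))
    window_days <- if (tracer == "amyloid") 365L else 548L
  stopifnot(window_days > 0)
  mr_sessions$date <- as.Date(mr_sessions$date)
  pet_sessions$date <- as.Date(pet_sessions$date)

  rows <- vector("list", nrow(pet_sessions))
  unmatched <- character(0)
  for (i in seq_len(nrow(pet_sessions))) {
    cand <- mr_sessions[mr_sessions$subject_id == pet_sessions$subject_id[i], ,
                        drop = FALSE]
    if (!nrow(cand)) { unmatched <- c(unmatched, pet_sessions$pet_session_id[i]); next }
    gap <- as.integer(pet_sessions$date[i] - cand$date)
    ok <- abs(gap) <= window_days
    if (!any(ok)) { unmatched <- c(unmatched, pet_sessions$pet_session_id[i]); next }
    cand <- cand[ok, , drop = FALSE]; gap <- gap[ok]
    o <- order(abs(gap), cand$date)
    rows[[i]] <- data.frame(mr_session_id = cand$session_id[o[1]],
                            pet_session_id = pet_sessions$pet_session_id[i],
                            subject_id = pet_sessions$subject_id[i],
                            tracer = tracer,
                            gap_days = gap[o[1]],
                            pet_date = pet_sessions$date[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(mr_session_id = character(0), pet_session_id = character(0),
                      subject_id = character(0), tracer = character(0),
                      gap_days = integer(0), pet_date = as.Date(character(0)),
                      stringsAsFactors = FALSE)
  attr(out, "unmatched") <- unmatched
  out
}

#' Read participant / visit / regional tables from TSV
#'
#' Header contract: tab-separated, first row names, ISO-8601 dates. Columns
#' are passed through unchanged; `date` columns are parsed to `Date`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_cohort_table <- function(path) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (cl in intersect(c("date", "visit_date", "pet_date"), names(d)))
    d[[cl]] <- as.Date(d[[cl]])
  d
}

#' Worked-example baseline composition counts
#'
#' Printed baseline descriptive counts of a dominantly inherited Alzheimer
#' disease observational cohort (n = 517 at baseline), bundled as a
#' worked example for descriptive-statistics checks: each row is a category
#' count out of the baseline total, from which the corresponding percentage
#' is recomputed as `100 * count / total`.
#'
#' @return data frame with `variable`, `count`, `total` and a computed
#'   `pct` column.
#' @export
baseline_count_table <- function() {
  d <- read.delim(system.file("extdata", "adad_cohort_baseline_counts.tsv",
                              package = "iimkit"), sep = "\t",
                  stringsAsFactors = FALSE)
  d$pct <- 100 * d$count / d$total
  d
}

#' Write a table as TSV
#' @param x data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
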