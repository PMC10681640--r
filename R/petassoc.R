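#' Partial correlation controlling for covariates
#'
#' Correlation between `x` and `y` after linearly removing the covariate(s)
#' `z` from both, computed by inversion of the joint correlation matrix
#' (equivalent to correlating the residuals of the two regressions, and to
#' the first-order recursion formula for a single covariate). The two-sided
#' p-value uses `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k`
#' degrees of freedom, with `k` covariates.
#'
#' @param x,y numeric vectors.
#' @param z numeric vector or matrix of covariates (columns).
#' @return list: `r` (partial correlation in [-1, 1]), `p`, `n` (complete
#'   cases used), `df`.
#' @examples
#' # all pairwise correlations 0.5 gives partial r = 1/3
#' @export
partial_correlation <- function(x, y, z) {
  z <- as.matrix(z)
  k <- ncol(z)
  cc <- complete.cases(x, y, z)
  x <- x[cc]; y <- y[cc]; z <- z[cc, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2) stop("need n > k + 2 complete cases (n = ", n, ", k = ", k, ")")
  m <- cbind(x, y, z)
  if (any(apply(m, 2, sd) == 0))
    stop("zero variance in x, y, or a covariate: partial correlation undefined")
  R <- cor(m)
  # Schur complement of the covariate block: the conditional correlation of
  # (x, y) given z; only the covariate block needs inverting, so x = y stays
  # well defined (r = 1)
  rz <- R[1:2, -(1:2), drop = FALSE]
  Rzz <- R[-(1:2), -(1:2), drop = FALSE]
  S <- R[1:2, 1:2] - rz %*% tryCatch(solve(Rzz, t(rz)), error = function(e)
    stop("collinear covariates: partial correlation undefined"))
  if (S[1, 1] < 1e-12 || S[2, 2] < 1e-12)
    stop("zero variance in x or y after removing covariates: ",
         "partial correlation undefined")
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  r <- max(-1, min(1, r))
  df <- n - 2 - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Regional partial correlations between PET uptake and intensity metrics
#'
#' For each region and intensity metric, the partial correlation between
#' regional SUVR and the metric, controlling for the regional morphometry
#' covariate (cortical thickness or subcortical volume), in a chosen subset:
#' all mutation carriers, or symptomatic (global CDR > 0) carriers. PET
#' scans must already be matched to MR sessions (see [match_pet_to_mr()]);
#' when a subject has several matched PET scans, only the earliest enters,
#' so rows are independent across subjects.
#'
#' @param iim intensity-metric table (`session_id`, `region_id`, metrics).
#' @param suvr PET table (`pet_session_id`, `subject_id`, `region_id`,
#'   `suvr`).
#' @param pairs matched session pairs from [match_pet_to_mr()].
#' @param morphometry regional morphometry table (`session_id`, `region_id`,
#'   `value`).
#' @param visits,participants cohort tables (for carrier status and CDR).
#' @param tracer label recorded on the output (`"amyloid"`/`"tau"`).
#' @param subset `"carriers"` or `"symptomatic_carriers"`.
#' @param metrics metric columns to correlate.
#' @param min_n minimum complete pairs per region (default 10); regions
#'   below it are returned with `NA` statistics.
#' @return data frame, one row per region x metric: `partial_r`, `p`,
#'   `fdr_p` (BH within metric x tracer), `n`, `tracer`, `subset`. Empty
#'   (zero-row) result if the subset selects no sessions.
#' @export
run_associations <- function(iim, suvr, pairs, morphometry, visits,
                             participants, tracer = "amyloid",
                             subset = c("carriers", "symptomatic_carriers"),
                             metrics = c("t1_mu", "t1_sigma",
                                         "flair_mu", "flair_sigma"),
                             min_n = 10L) {
  subset <- match.arg(subset)
  empty <- data.frame(region_id = integer(0), metric = character(0),
                      tracer = character(0), subset = character(0),
                      partial_r = numeric(0), p = numeric(0),
                      fdr_p = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE)
  carriers <- participants$subject_id[participants$mutation_status == "carrier"]
  pairs <- pairs[pairs$subject_id %in% carriers, , drop = FALSE]
  if (subset == "symptomatic_carriers") {
    cdr <- visits$cdr_global[match(pairs$mr_session_id, visits$session_id)]
    pairs <- pairs[!is.na(cdr) & cdr > 0, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  # one PET scan per subject: the earliest
  if ("pet_date" %in% names(pairs)) {
    pairs <- pairs[order(pairs$subject_id, pairs$pet_date), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$subject_id), , drop = FALSE]
  }

  d <- merge(pairs[, c("mr_session_id", "pet_session_id", "subject_id")],
             suvr[, c("pet_session_id", "region_id", "suvr")],
             by = "pet_session_id")
  d <- merge(d, iim[, c("session_id", "region_id", metrics)],
             by.x = c("mr_session_id", "region_id"),
             by.y = c("session_id", "region_id"))
  d <- merge(d, morphometry[, c("session_id", "region_id", "value")],
             by.x = c("mr_session_id", "region_id"),
             by.y = c("session_id", "region_id"))
  if (!nrow(d)) return(empty)

  rows <- list()
  dropped <- 0L
  for (met in metrics) {
    for (r in sort(unique(d$region_id))) {
      dr <- d[d$region_id == r, , drop = FALSE]
      cc <- complete.cases(dr$suvr, dr[[met]], dr$value)
      if (sum(cc) < max(min_n, 4L)) {
        rows[[length(rows) + 1L]] <-
          data.frame(region_id = r, metric = met, tracer = tracer,
                     subset = subset, partial_r = NA_real_, p = NA_real_,
                     n = sum(cc), stringsAsFactors = FALSE)
        dropped <- dropped + 1L
        next
      }
      pc <- partial_correlation(dr$suvr[cc], dr[[met]][cc], dr$value[cc])
      rows[[length(rows) + 1L]] <-
        data.frame(region_id = r, metric = met, tracer = tracer,
                   subset = subset, partial_r = pc$r, p = pc$p, n = pc$n,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_p <- NA_real_
  for (met in metrics) {
    i <- out$metric == met
    out$fdr_p[i] <- fdr_adjust(out$p[i])
  }
  if (dropped > 0)
    message(sprintf("run_associations: %d region x metric cells below min_n", dropped))
  rownames(out) <- NULL
  out[, c("region_id", "metric", "tracer", "subset", "partial_r", "p",
          "fdr_p", "n")]
}
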