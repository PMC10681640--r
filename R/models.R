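#' Mixed-effects trajectory models of regional intensity metrics
#'
#' Four model shapes relate a regional image-intensity metric (IIM) to
#' disease stage, fit with `lmer`. Coefficient estimates, Satterthwaite
#' degrees of freedom and p-values come from the REML fit; alongside it an
#' ML refit's log-likelihood is stored so that likelihood-ratio tests
#' between nested fixed-effect structures remain valid (the convention
#' lme4's `anova()` applies to REML fits):
#'
#' * **M1** (baseline sessions): `IIM ~ EYO * Mutation + covariate +
#'   (1 | family)`.
#' * **M2** (all sessions): `IIM ~ Time * BaselineEYO * Mutation +
#'   Time * covariate + (1 | family) + (1 | subject)`.
#' * **M3**: M1 plus `EYO^2 * Mutation`.
#' * **M4**: M2 plus `Time * BaselineEYO^2 * Mutation`.
#'
#' The covariate is regional cortical thickness for cortical regions and
#' subcortical volume for subcortical regions, absorbing concurrent atrophy.
#' EYO is already centred at expected symptom onset, so the quadratic term
#' is the plain square.
#'
#' @param data data frame for one region with columns `value` (the metric),
#'   `eyo`, `baseline_eyo`, `time` (years since first MR), `mutation`
#'   (factor, reference `"non_carrier"`), `covariate`, `family_id`,
#'   `subject_id`. For M1/M3 only `time == 0` rows are used.
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param region_id,metric identifiers carried into the result.
#' @return object of class `iim_fit`: coefficient table (estimate, SE,
#'   Satterthwaite df, t, p per fixed term, from the REML fit), `logLik`
#'   (of the ML refit, for LRTs), number of fixed effects, `converged`
#'   (optimizer success), `singular` (a random-effect variance estimated at
#'   zero), `n_obs`.
#' @export
fit_region <- function(data, model = c("M1", "M2", "M3", "M4"),
                       region_id = NA_integer_, metric = NA_character_) {
  model <- match.arg(model)
  need <- c("value", "eyo", "mutation", "covariate", "family_id")
  if (model %in% c("M2", "M4"))
    need <- c(need, "baseline_eyo", "time", "subject_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  d <- data
  if (model %in% c("M1", "M3") && "time" %in% names(d))
    d <- d[!is.na(d$time) & d$time == 0, , drop = FALSE]
  d <- d[complete.cases(d[, need]), , drop = FALSE]
  if (!is.factor(d$mutation))
    d$mutation <- factor(d$mutation, levels = c("non_carrier", "carrier"))
  d$eyo_sq <- d$eyo^2
  if ("baseline_eyo" %in% names(d)) d$beyo_sq <- d$baseline_eyo^2
  if (length(unique(d$family_id)) < 2) stop("need at least 2 families")

  form <- switch(model,
    M1 = value ~ eyo * mutation + covariate + (1 | family_id),
    M3 = value ~ (eyo + eyo_sq) * mutation + covariate + (1 | family_id),
    M2 = value ~ time * baseline_eyo * mutation + time * covariate +
      (1 | family_id) + (1 | subject_id),
    M4 = value ~ time * (baseline_eyo + beyo_sq) * mutation +
      time * covariate + (1 | family_id) + (1 | subject_id))

  # REML for coefficient inference (better-calibrated variance components),
  # then an ML refit whose log-likelihood feeds the nested-model LRT - the
  # same convention lme4's anova() applies when handed REML fits
  converged <- TRUE
  warn_msgs <- character(0)
  quietly <- function(expr) withCallingHandlers(
    expr,
    warning = function(w) {
      warn_msgs <<- c(warn_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  fit <- tryCatch(quietly(lmerTest::lmer(form, data = d, REML = TRUE)),
                  error = function(e) e)
  if (!inherits(fit, "error"))
    fit_ml <- tryCatch(quietly(lme4::refitML(fit)), error = function(e) e)
  if (inherits(fit, "error") || inherits(fit_ml, "error")) {
    err <- if (inherits(fit, "error")) fit else fit_ml
    return(structure(list(region_id = region_id, metric = metric,
                          model_id = model, coefficients = NULL,
                          logLik = NA_real_, n_fixed = NA_integer_,
                          converged = FALSE, singular = NA,
                          n_obs = nrow(d), error = conditionMessage(err)),
                     class = "iim_fit"))
  }
  if (any(grepl("failed to converge", warn_msgs))) converged <- FALSE
  singular <- lme4::isSingular(fit)

  ct <- as.data.frame(summary(fit)$coefficients)
  names(ct) <- c("estimate", "se", "df", "t", "p")
  ct$term <- rownames(ct)
  rownames(ct) <- NULL
  ct <- ct[, c("term", "estimate", "se", "df", "t", "p")]

  structure(list(region_id = region_id, metric = metric, model_id = model,
                 coefficients = ct,
                 logLik = as.numeric(logLik(fit_ml)),
                 n_fixed = length(lme4::fixef(fit)),
                 converged = converged, singular = singular,
                 n_obs = nobs(fit)),
            class = "iim_fit")
}

#' @export
print.iim_fit <- function(x, ...) {
  cat(sprintf("<iim_fit> %s  region %s  metric %s  n=%s  logLik=%.2f%s%s\n",
              x$model_id, x$region_id, x$metric, x$n_obs, x$logLik,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]",
              if (isTRUE(x$singular)) "  [singular]" else ""))
  if (!is.null(x$coefficients)) print(x$coefficients, digits = 4)
  invisible(x)
}

#' Name of the stage-by-mutation interaction term of interest
#'
#' The coefficient whose signed -log10 p is mapped: the EYO x Mutation
#' interaction (M1), the Time x BaselineEYO x Mutation three-way interaction
#' (M2), or the corresponding quadratic interactions (M3/M4).
#'
#' @param model `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @param quadratic for M3/M4, return the quadratic interaction term.
#' @return coefficient name as it appears in the fit.
#' @export
interaction_term <- function(model, quadratic = model %in% c("M3", "M4")) {
  switch(model,
    M1 = "eyo:mutationcarrier",
    M2 = "time:baseline_eyo:mutationcarrier",
    M3 = if (quadratic) "eyo_sq:mutationcarrier" else "eyo:mutationcarrier",
    M4 = if (quadratic) "time:beyo_sq:mutationcarrier"
         else "time:baseline_eyo:mutationcarrier",
    stop("unknown model id: ", model))
}

# pull (estimate, p) of a term from an iim_fit
fit_term <- function(fit, term) {
  ct <- fit$coefficients
  if (is.null(ct) || !term %in% ct$term)
    return(c(estimate = NA_real_, p = NA_real_, se = NA_real_))
  i <- match(term, ct$term)
  c(estimate = ct$estimate[i], p = ct$p[i], se = ct$se[i])
}

#' Likelihood-ratio comparison of linear vs quadratic trajectory models
#'
#' Compares a nested ML model pair (M1 vs M3, or M2 vs M4) fit on the same
#' rows: statistic `2 * (logLik_quad - logLik_lin)`, chi-square p on the
#' number of added fixed-effect terms. Whether the quadratic model is
#' *declared* an improvement additionally requires, per the analysis
#' convention: (a) the linear model's interaction FDR-significant, (b) the
#' FDR-adjusted ANOVA p below `alpha`, and (c) the quadratic-by-mutation
#' interaction itself significant (raw p) - conditions applied downstream in
#' [fit_cohort_models()].
#'
#' @param fit_lin,fit_quad `iim_fit` objects of a nested pair.
#' @return one-row data frame: `region_id`, `metric`, `lrt_statistic`,
#'   `df_diff`, `p_anova`, `quad_beta`, `quad_p`.
#' @export
compare_linear_quadratic <- function(fit_lin, fit_quad) {
  stopifnot(inherits(fit_lin, "iim_fit"), inherits(fit_quad, "iim_fit"))
  pair_ok <- (fit_lin$model_id == "M1" && fit_quad$model_id == "M3") ||
             (fit_lin$model_id == "M2" && fit_quad$model_id == "M4")
  if (!pair_ok)
    stop("non-nested inputs: expected (M1, M3) or (M2, M4), got (",
         fit_lin$model_id, ", ", fit_quad$model_id, ")")
  if (!identical(fit_lin$n_obs, fit_quad$n_obs))
    stop("non-nested inputs: models were fit on different numbers of rows")
  if (!isTRUE(fit_lin$converged) || !isTRUE(fit_quad$converged))
    stop("both fits must have converged")
  df_diff <- fit_quad$n_fixed - fit_lin$n_fixed
  lrt <- 2 * (fit_quad$logLik - fit_lin$logLik)
  if (lrt < -1e-6)
    warning("negative likelihood-ratio statistic (", format(lrt),
            "): quadratic fit worse than nested linear fit")
  lrt <- max(0, lrt)
  qt <- fit_term(fit_quad, interaction_term(fit_quad$model_id, quadratic = TRUE))
  data.frame(region_id = fit_lin$region_id, metric = fit_lin$metric,
             lrt_statistic = lrt, df_diff = df_diff,
             p_anova = pchisq(lrt, df_diff, lower.tail = FALSE),
             quad_beta = unname(qt["estimate"]), quad_p = unname(qt["p"]),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values across a family of tests. Missing entries are
#' excluded from the family (they do not count toward its size) and returned
#' missing.
#'
#' @param p numeric vector of p-values in [0, 1], `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Signed -log10 p map of an interaction term
#'
#' The region-map convention: `-log10(p)` of the chosen term times the sign
#' of its coefficient, so regions where carriers decline with advancing EYO
#' score negative and regions where they rise score positive. p-values are
#' floored at 1e-300 before the log.
#'
#' @param fits list of `iim_fit` objects.
#' @param term coefficient name; defaults to each fit's own interaction
#'   term via [interaction_term()].
#' @return data frame: `region_id`, `metric`, `beta`, `p`, `signed_logp`
#'   (`NA` for failed fits).
#' @export
signed_logp_map <- function(fits, term = NULL) {
  rows <- lapply(fits, function(f) {
    tm <- if (is.null(term)) interaction_term(f$model_id) else term
    v <- fit_term(f, tm)
    score <- if (is.na(v["p"])) NA_real_
             else -log10(max(v["p"], 1e-300)) * sign(v["estimate"])
    if (!is.na(score) && v["estimate"] == 0) score <- 0
    data.frame(region_id = f$region_id, metric = f$metric,
               beta = unname(v["estimate"]), p = unname(v["p"]),
               signed_logp = unname(score), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the merged per-region modelling table
#'
#' Joins the intensity-metric table with visits, participants and
#' morphometry into the long table the trajectory models consume. The
#' atrophy covariate is regional thickness for cortical regions and volume
#' for subcortical ones, both taken from the morphometry table.
#'
#' @param iim table from [extract_iim()] (stacked over sessions) or
#'   [simulate_iim_table()].
#' @param visits,participants cohort tables.
#' @param morphometry table from [simulate_morphometry()] or equivalent.
#' @param region_table parcellation metadata.
#' @return data frame with one row per (session, region): the four metrics,
#'   `eyo`, `baseline_eyo`, `time`, `mutation`, `covariate`, `family_id`,
#'   `subject_id`, `region_id`, `cdr_global`.
#' @export
assemble_model_data <- function(iim, visits, participants, morphometry,
                                region_table = default_region_table()) {
  keep <- participants$mutation_status %in% c("carrier", "non_carrier")
  participants <- participants[keep, , drop = FALSE]
  d <- merge(iim, visits[, c("subject_id", "session_id", "eyo",
                             "baseline_eyo", "time_since_baseline",
                             "cdr_global")],
             by = c("session_id", "subject_id"))
  d <- merge(d, participants[, c("subject_id", "family_id", "mutation_status")],
             by = "subject_id")
  d <- merge(d, morphometry[, c("session_id", "region_id", "value")],
             by = c("session_id", "region_id"))
  names(d)[names(d) == "value"] <- "covariate"
  names(d)[names(d) == "time_since_baseline"] <- "time"
  d$mutation <- factor(d$mutation_status, levels = c("non_carrier", "carrier"))
  d <- merge(d, region_table[, c("region_id", "class")], by = "region_id")
  d[order(d$region_id, d$subject_id, d$time), ]
}

#' Fit trajectory models across all regions and metrics with FDR control
#'
#' Runs the region-wise linear (and optionally quadratic) trajectory model
#' for each metric, adjusts interaction p-values across regions separately
#' within each metric (BH-FDR), performs the linear-vs-quadratic
#' likelihood-ratio comparison, and applies the quadratic decision rule:
#' declare improvement only where (a) the linear interaction is
#' FDR-significant, (b) the FDR-adjusted ANOVA p is below `alpha`, and
#' (c) the quadratic-by-mutation coefficient is itself significant (raw p).
#' Regions whose fit fails are excluded from the FDR family and reported.
#'
#' @param model_data from [assemble_model_data()].
#' @param metrics metric columns to model.
#' @param design `"baseline"` (M1/M3) or `"longitudinal"` (M2/M4).
#' @param quadratic also fit the quadratic pair and compare.
#' @param alpha significance level (default 0.05).
#' @return list: `linear` (per region x metric: interaction beta, p, fdr_p,
#'   signed_logp, convergence flags), `comparison` (LRT results with fdr
#'   and `quadratic_improvement`), `failed` (region/metric fits excluded).
#' @export
fit_cohort_models <- function(model_data,
                              metrics = c("t1_mu", "t1_sigma",
                                          "flair_mu", "flair_sigma"),
                              design = c("baseline", "longitudinal"),
                              quadratic = TRUE, alpha = 0.05) {
  design <- match.arg(design)
  lin_id <- if (design == "baseline") "M1" else "M2"
  quad_id <- if (design == "baseline") "M3" else "M4"
  regions <- sort(unique(model_data$region_id))

  lin_rows <- list(); cmp_rows <- list(); failed <- list()
  for (met in metrics) {
    for (r in regions) {
      d <- model_data[model_data$region_id == r, , drop = FALSE]
      d$value <- d[[met]]
      f_lin <- tryCatch(fit_region(d, lin_id, region_id = r, metric = met),
                        error = function(e) e)
      ok <- inherits(f_lin, "iim_fit") && isTRUE(f_lin$converged)
      if (!ok) {
        failed[[length(failed) + 1L]] <-
          data.frame(region_id = r, metric = met, model_id = lin_id,
                     stringsAsFactors = FALSE)
        next
      }
      tv <- fit_term(f_lin, interaction_term(lin_id))
      row <- data.frame(region_id = r, metric = met, model_id = lin_id,
                        beta = unname(tv["estimate"]), se = unname(tv["se"]),
                        p = unname(tv["p"]),
                        singular = f_lin$singular, n_obs = f_lin$n_obs,
                        stringsAsFactors = FALSE)
      lin_rows[[length(lin_rows) + 1L]] <- row
      if (quadratic) {
        f_quad <- tryCatch(fit_region(d, quad_id, region_id = r, metric = met),
                           error = function(e) e)
        if (inherits(f_quad, "iim_fit") && isTRUE(f_quad$converged)) {
          cmp_rows[[length(cmp_rows) + 1L]] <-
            compare_linear_quadratic(f_lin, f_quad)
        } else {
          failed[[length(failed) + 1L]] <-
            data.frame(region_id = r, metric = met, model_id = quad_id,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  linear <- do.call(rbind, lin_rows)
  if (!is.null(linear)) {
    linear$fdr_p <- NA_real_
    for (met in metrics) {
      i <- linear$metric == met
      linear$fdr_p[i] <- fdr_adjust(linear$p[i])
    }
    linear$signed_logp <- -log10(pmax(linear$p, 1e-300)) * sign(linear$beta)
  }
  comparison <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL
  if (!is.null(comparison)) {
    comparison$fdr_p_anova <- NA_real_
    for (met in metrics) {
      i <- comparison$metric == met
      comparison$fdr_p_anova[i] <- fdr_adjust(comparison$p_anova[i])
    }
    key <- paste(comparison$region_id, comparison$metric)
    lin_fdr <- linear$fdr_p[match(key, paste(linear$region_id, linear$metric))]
    comparison$quadratic_improvement <-
      !is.na(lin_fdr) & lin_fdr < alpha &
      comparison$fdr_p_anova < alpha &
      !is.na(comparison$quad_p) & comparison$quad_p < alpha
  }
  list(linear = linear, comparison = comparison,
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}
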