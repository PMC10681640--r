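test_that("BH adjustment reproduces the hand step-up computation", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  expect_equal(fdr_adjust(p), c(0.005, 0.025, 1 / 30, 0.05, 0.2),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(rep(0.07, 4)), rep(0.07, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # missing entries are excluded from the family and returned missing
  withna <- fdr_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(withna[2]))
  expect_equal(withna[c(1, 3)], fdr_adjust(c(0.01, 0.04)))
})

test_that("BH adjustment matches an independent oracle on random vectors", {
  set.seed(20)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_lt(max(abs(fdr_adjust(p) - bh_oracle(p))), 1e-12)
  }
})

test_that("with zero random-effect variance the fit reduces to least squares", {
  co <- tiny_cohort()
  eff <- calib_effect(affected_regions = 1L, family_sd = 0, subject_sd = 0)
  # under a variance-free generator the variance estimate hits the zero
  # boundary in most replicates; use the first such replicate, where the
  # mixed fit collapses to ordinary least squares
  f <- NULL; md <- NULL
  for (s in 1:10) {
    iim <- simulate_iim_table(co$visits, co$participants, eff, seed = s,
                              region_table = one_region)
    morph <- simulate_morphometry(co$visits, co$participants, eff, seed = s,
                                  region_table = one_region)
    md <- assemble_model_data(iim, co$visits, co$participants, morph,
                              one_region)
    md$value <- md$flair_mu
    f <- fit_region(md, "M1", 1L, "flair_mu")
    if (isTRUE(f$singular)) break
  }
  expect_true(f$singular)
  ols <- lm(value ~ eyo * mutation + covariate,
            md[!is.na(md$time) & md$time == 0, ])
  b_lmer <- setNames(f$coefficients$estimate, f$coefficients$term)
  b_ols <- coef(ols)
  expect_equal(unname(b_lmer[names(b_ols)]), unname(b_ols),
               tolerance = 1e-3)
})

test_that("model shapes expose the expected interaction coefficients", {
  co <- tiny_cohort()
  eff <- calib_effect(affected_regions = 1L)
  fits <- lapply(c("M1", "M2", "M3", "M4"), function(m)
    sim_and_fit(co$visits, co$participants, eff, seed = 4, model = m))
  names(fits) <- c("M1", "M2", "M3", "M4")
  for (m in names(fits)) {
    expect_true(interaction_term(m) %in% fits[[m]]$coefficients$term,
                info = m)
    expect_true(fits[[m]]$converged, info = m)
    expect_true(is.finite(fits[[m]]$logLik), info = m)
    expect_true(all(fits[[m]]$coefficients$p >= 0 &
                      fits[[m]]$coefficients$p <= 1), info = m)
  }
  # M3 nests M1, M4 nests M2: superset of fixed effects, same rows
  expect_gt(fits$M3$n_fixed, fits$M1$n_fixed)
  expect_equal(fits$M1$n_obs, fits$M3$n_obs)
  expect_gt(fits$M4$n_fixed, fits$M2$n_fixed)
  expect_equal(fits$M2$n_obs, fits$M4$n_obs)
  # baseline models use one row per subject, longitudinal all rows
  expect_equal(fits$M1$n_obs, length(unique(co$visits$subject_id)))
  expect_gt(fits$M2$n_obs, fits$M1$n_obs)
})

test_that("likelihood-ratio comparison behaves at the null and rejects misuse", {
  # equal log-likelihoods: statistic 0, p = 1
  mk <- function(model_id, ll, nf) structure(
    list(region_id = 1L, metric = "m", model_id = model_id, logLik = ll,
         n_fixed = nf, converged = TRUE, n_obs = 100L,
         coefficients = data.frame(term = "eyo_sq:mutationcarrier",
                                   estimate = 0.1, se = 1, df = 90,
                                   t = 0.1, p = 0.92)),
    class = "iim_fit")
  cmp <- compare_linear_quadratic(mk("M1", -500, 5), mk("M3", -500, 7))
  expect_equal(cmp$lrt_statistic, 0)
  expect_equal(cmp$p_anova, 1)
  expect_equal(cmp$df_diff, 2)
  expect_error(compare_linear_quadratic(mk("M1", -500, 5), mk("M4", -499, 9)),
               "non-nested")
  bad <- mk("M3", -499, 7); bad$n_obs <- 99L
  expect_error(compare_linear_quadratic(mk("M1", -500, 5), bad), "non-nested")
  # LRT statistic is nonnegative on real nested fits
  co <- tiny_cohort()
  eff <- calib_effect(affected_regions = 1L)
  f1 <- sim_and_fit(co$visits, co$participants, eff, seed = 6, model = "M1")
  f3 <- sim_and_fit(co$visits, co$participants, eff, seed = 6, model = "M3")
  cmp2 <- compare_linear_quadratic(f1, f3)
  expect_gte(cmp2$lrt_statistic, -1e-6)
  expect_gte(cmp2$p_anova, 0)
})

test_that("the LRT agrees with lme4's own anova on a refit", {
  co <- tiny_cohort()
  eff <- calib_effect(affected_regions = 1L, quadratic_coef = 0.06)
  iim <- simulate_iim_table(co$visits, co$participants, eff, seed = 8,
                            region_table = one_region)
  morph <- simulate_morphometry(co$visits, co$participants, eff, seed = 8,
                                region_table = one_region)
  md <- assemble_model_data(iim, co$visits, co$participants, morph, one_region)
  md$value <- md$flair_mu
  f1 <- fit_region(md, "M1", 1L, "flair_mu")
  f3 <- fit_region(md, "M3", 1L, "flair_mu")
  cmp <- compare_linear_quadratic(f1, f3)
  bl <- md[!is.na(md$time) & md$time == 0, ]
  bl <- bl[complete.cases(bl[, c("value", "eyo", "mutation", "covariate",
                                 "family_id")]), ]
  bl$eyo_sq <- bl$eyo^2
  m1 <- lme4::lmer(value ~ eyo * mutation + covariate + (1 | family_id),
                   bl, REML = FALSE)
  m3 <- lme4::lmer(value ~ (eyo + eyo_sq) * mutation + covariate +
                     (1 | family_id), bl, REML = FALSE)
  an <- suppressMessages(anova(m1, m3))
  expect_equal(cmp$lrt_statistic, an$Chisq[2], tolerance = 1e-4)
  expect_equal(cmp$p_anova, an$`Pr(>Chisq)`[2], tolerance = 1e-4)
})

test_that("signed -log10 p scores follow the sign and magnitude convention", {
  mk <- function(p, beta) structure(
    list(region_id = 1L, metric = "flair_mu", model_id = "M1",
         coefficients = data.frame(term = "eyo:mutationcarrier",
                                   estimate = beta, se = 1, df = 10,
                                   t = beta, p = p)),
    class = "iim_fit")
  s <- signed_logp_map(list(mk(0.01, -2), mk(1, 3), mk(1e-320, 1)))
  expect_equal(s$signed_logp[1], -2)
  expect_equal(s$signed_logp[2], 0)
  expect_equal(s$signed_logp[3], 300)   # floored at 1e-300
  # missing fits propagate missing scores
  failed <- structure(list(region_id = 2L, metric = "flair_mu",
                           model_id = "M1", coefficients = NULL),
                      class = "iim_fit")
  s2 <- signed_logp_map(list(failed))
  expect_true(is.na(s2$signed_logp))
})

test_that("a planted interaction is detected and an absent one is not", {
  co <- tiny_cohort()
  eff1 <- calib_effect(affected_regions = 1L)       # flair_mu slope -0.8
  eff0 <- calib_effect(affected_regions = integer(0))
  p1 <- sapply(1:10, function(i) {
    f <- sim_and_fit(co$visits, co$participants, eff1, seed = 100 + i)
    iimkit:::fit_term(f, interaction_term("M1"))["p"]
  })
  expect_gte(mean(p1 < 0.05), 0.8)
  p0 <- sapply(1:10, function(i) {
    f <- sim_and_fit(co$visits, co$participants, eff0, seed = 200 + i)
    iimkit:::fit_term(f, interaction_term("M1"))["p"]
  })
  expect_lte(mean(p0 < 0.05), 0.3)
})

test_that("the region-wise pipeline controls FDR and finds planted regions", {
  # 80 regions, effects planted in 10; FDP averaged over replicates <= 0.10
  # at q = 0.05 and at least 7 of 10 planted regions detected on average
  rt <- default_region_table(80)
  planted <- c(4, 9, 17, 23, 30, 41, 52, 60, 68, 75)
  eff <- calib_effect(affected_regions = planted)
  co <- simulate_cohort(200, 0.6, 1, seed = 77)
  n_rep <- 50
  fdp <- numeric(n_rep); hits <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    iim <- simulate_iim_table(co$visits, co$participants, eff,
                              seed = 5000 + i, region_table = rt)
    morph <- simulate_morphometry(co$visits, co$participants, eff,
                                  seed = 5000 + i, region_table = rt)
    md <- assemble_model_data(iim, co$visits, co$participants, morph, rt)
    res <- fit_cohort_models(md, metrics = "flair_mu", design = "baseline",
                             quadratic = FALSE)
    sig <- res$linear$region_id[res$linear$fdr_p < 0.05]
    fdp[i] <- if (length(sig)) mean(!sig %in% planted) else 0
    hits[i] <- sum(planted %in% sig)
  }
  expect_lte(mean(fdp), 0.10)
  expect_gte(mean(hits), 7)
})
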