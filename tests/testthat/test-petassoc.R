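test_that("all pairwise correlations 0.5 give partial r exactly 1/3", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  X <- exact_corr_data(R)
  pc <- partial_correlation(X[, 1], X[, 2], X[, 3])
  expect_equal(pc$r, 1 / 3, tolerance = 1e-12)
  expect_equal(pc$n, 40)
})

test_that("perfectly dependent variables give partial r of one", {
  set.seed(2)
  x <- rnorm(30); z <- rnorm(30)
  pc <- partial_correlation(x, x, z)
  expect_equal(pc$r, 1, tolerance = 1e-8)
  expect_lt(pc$p, 1e-10)
})

test_that("degenerate inputs raise undefined-result errors", {
  expect_error(partial_correlation(rep(1, 20), rnorm(20), rnorm(20)),
               "zero variance")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "complete cases")
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(3)
  worst <- 0
  for (i in 1:200) {
    n <- sample(15:80, 1)
    k <- sample(1:3, 1)
    z <- matrix(rnorm(n * k), n, k)
    x <- rnorm(n) + z %*% rnorm(k)
    y <- rnorm(n) + z %*% rnorm(k) + 0.3 * x
    pc <- partial_correlation(x, y, z)
    r_oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    worst <- max(worst, abs(pc$r - r_oracle))
    # and the t-based p-value against the textbook formula
    df <- n - 2 - k
    t0 <- r_oracle * sqrt(df / (1 - r_oracle^2))
    expect_equal(pc$p, 2 * pt(-abs(t0), df), tolerance = 1e-8)
  }
  expect_lt(worst, 1e-10)
})

test_that("results are invariant to affine rescaling of any input", {
  set.seed(4)
  z <- rnorm(50); x <- rnorm(50) + z; y <- rnorm(50) - z
  a <- partial_correlation(x, y, z)
  b <- partial_correlation(100 + 7 * x, -3 * y + 2, 0.1 * z - 5)
  expect_equal(abs(b$r), abs(a$r), tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("an irrelevant covariate leaves the plain correlation unchanged", {
  set.seed(5)
  n <- 10000
  z <- rnorm(n)
  x <- rnorm(n); y <- 0.3 * x + rnorm(n)
  pc <- partial_correlation(x, y, z)
  expect_lt(abs(pc$r - cor(x, y)), 0.02)
})

# shared synthetic association setup
assoc_setup <- function(eff, seed = 3, n = 200) {
  rt <- default_region_table(20)
  co <- simulate_cohort(n, 0.65, 2, seed = seed)
  v <- co$visits; p <- co$participants
  morph <- simulate_morphometry(v, p, eff, seed = seed, region_table = rt)
  iim <- simulate_iim_table(v, p, eff, seed = seed, region_table = rt,
                            morphometry = morph)
  pet <- simulate_pet_tables(v, p, eff, seed = seed, region_table = rt,
                             morphometry = morph)
  mr <- data.frame(session_id = v$session_id, subject_id = v$subject_id,
                   date = v$visit_date)
  list(rt = rt, v = v, p = p, morph = morph, iim = iim, pet = pet, mr = mr)
}

match_tracer <- function(s, tracer) {
  tab <- s$pet[[tracer]]
  pets <- unique(tab[, c("pet_session_id", "subject_id", "date")])
  match_pet_to_mr(s$mr, pets, tracer)
}

test_that("planted negative tau coupling to FLAIR-mu is recovered in sign", {
  eff <- effect_model(affected_regions = 1:6)
  hits <- sapply(1:10, function(i) {
    s <- assoc_setup(eff, seed = 300 + i)
    prs <- match_tracer(s, "tau")
    a <- run_associations(s$iim, s$pet$tau, prs, s$morph, s$v, s$p,
                          tracer = "tau", subset = "carriers")
    r_aff <- a$partial_r[a$metric == "flair_mu" & a$region_id %in% 1:6]
    mean(r_aff < 0)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("coupling through atrophy alone is removed by the covariate", {
  # SUVR and intensity metrics both driven solely by regional morphometry
  eff <- effect_model(affected_regions = integer(0),
                      flair_mu_slope = 0, t1_mu_slope = 0, sigma_slope = 0,
                      tau_coupling = 0, amyloid_coupling = 0,
                      latent_iim = c(t1_mu = 0, t1_sigma = 0,
                                     flair_mu = 0, flair_sigma = 0),
                      thickness_coupling_iim = 6,
                      thickness_coupling_pet = 0.4)
  s <- assoc_setup(eff, seed = 11)
  prs <- match_tracer(s, "tau")
  a <- run_associations(s$iim, s$pet$tau, prs, s$morph, s$v, s$p,
                        tracer = "tau", subset = "carriers")
  # without the covariate the shared driver produces strong correlation
  d <- merge(merge(prs[, c("mr_session_id", "pet_session_id")],
                   s$pet$tau, by = "pet_session_id"),
             s$iim, by.x = c("mr_session_id", "region_id"),
             by.y = c("session_id", "region_id"))
  raw_r <- sapply(unique(d$region_id), function(r)
    cor(d$suvr[d$region_id == r], d$flair_mu[d$region_id == r]))
  r_adj <- a$partial_r[a$metric == "flair_mu"]
  expect_gt(mean(abs(raw_r)), 3 * mean(abs(r_adj)))
  expect_lt(abs(mean(r_adj)), 2 * sd(r_adj) / sqrt(length(r_adj)) + 0.05)
})

test_that("an all-asymptomatic cohort yields an empty symptomatic subset", {
  eff <- effect_model(affected_regions = 1:6)
  rt <- default_region_table(10)
  co <- simulate_cohort(30, 0.5, 1, seed = 17, background_cdr_rate = 0,
                        eyo_range = c(-25, -15))   # far from onset: CDR 0
  v <- co$visits; p <- co$participants
  expect_true(all(v$cdr_global == 0))
  morph <- simulate_morphometry(v, p, eff, seed = 17, region_table = rt)
  iim <- simulate_iim_table(v, p, eff, seed = 17, region_table = rt)
  pet <- simulate_pet_tables(v, p, eff, seed = 17, region_table = rt)
  mr <- data.frame(session_id = v$session_id, subject_id = v$subject_id,
                   date = v$visit_date)
  pets <- unique(pet$tau[, c("pet_session_id", "subject_id", "date")])
  prs <- match_pet_to_mr(mr, pets, "tau")
  out <- run_associations(iim, pet$tau, prs, morph, v, p, tracer = "tau",
                          subset = "symptomatic_carriers")
  expect_equal(nrow(out), 0)
})

test_that("tau couples more strongly than amyloid in symptomatic carriers", {
  eff <- effect_model(affected_regions = 1:6)   # tau_coupling > amyloid_coupling
  s <- assoc_setup(eff, seed = 23, n = 300)
  a_tau <- run_associations(s$iim, s$pet$tau, match_tracer(s, "tau"),
                            s$morph, s$v, s$p, tracer = "tau",
                            subset = "symptomatic_carriers")
  a_amy <- run_associations(s$iim, s$pet$amyloid, match_tracer(s, "amyloid"),
                            s$morph, s$v, s$p, tracer = "amyloid",
                            subset = "symptomatic_carriers")
  aff <- a_tau$region_id %in% 1:6
  expect_gt(mean(abs(a_tau$partial_r[aff]), na.rm = TRUE),
            mean(abs(a_amy$partial_r[a_amy$region_id %in% 1:6]), na.rm = TRUE))
})

test_that("one PET scan per subject enters the correlation rows", {
  eff <- effect_model(affected_regions = 1:6)
  s <- assoc_setup(eff, seed = 29)
  prs <- match_tracer(s, "tau")
  a <- run_associations(s$iim, s$pet$tau, prs, s$morph, s$v, s$p,
                        tracer = "tau", subset = "carriers")
  n_carriers <- sum(s$p$mutation_status == "carrier")
  expect_true(all(a$n <= n_carriers))
})
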