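test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(60, 0.5, 2, seed = 11)
  b <- simulate_cohort(60, 0.5, 2, seed = 11)
  expect_identical(a, b)
  c <- simulate_cohort(60, 0.5, 2, seed = 12)
  expect_false(identical(a$visits$eyo, c$visits$eyo))
})

test_that("carrier count stays within the binomial 99% interval", {
  co <- simulate_cohort(500, 0.6, 1, seed = 21)
  k <- sum(co$participants$mutation_status == "carrier")
  half <- qnorm(0.995) * sqrt(500 * 0.6 * 0.4)
  expect_gt(k, 300 - half)
  expect_lt(k, 300 + half)
  expect_error(simulate_cohort(100, 1.2, 1, seed = 1), "carrier_fraction")
  expect_error(simulate_cohort(1, 0.5, 1, seed = 1), "n_participants")
})

test_that("CDR above zero arises only from the carrier symptom model", {
  co <- simulate_cohort(150, 0.5, 2, seed = 5, background_cdr_rate = 0)
  carrier <- co$participants$mutation_status[
    match(co$visits$subject_id, co$participants$subject_id)] == "carrier"
  expect_true(all(co$visits$cdr_global[!carrier] == 0))
  # symptomatic probability increases toward and past expected onset
  bl <- co$visits[carrier, ]
  late <- bl$cdr_global[bl$eyo > 0]
  early <- bl$cdr_global[bl$eyo < -10]
  expect_gt(mean(late > 0), mean(early > 0))
  # own onset age recorded only for ever-symptomatic participants
  sympt_subj <- unique(co$visits$subject_id[co$visits$cdr_global > 0])
  has_ao <- !is.na(co$participants$own_onset_age)
  expect_setequal(co$participants$subject_id[has_ao], sympt_subj)
})

test_that("phantom regional means match generating parameters within 3 SE", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), n_regions = 8)
  ph <- simulate_phantom_pair(list(eyo = -30, mutation_status = "non_carrier"),
                              spec, effect_model(), seed = 3)
  for (r in 1:8) {
    idx <- which(ph$labels == r)
    n <- length(idx)
    expect_gt(n, 100)
    se_t1 <- ph$truth$t1_sd[r] / sqrt(n)
    se_fl <- ph$truth$flair_sd[r] / sqrt(n)
    expect_lt(abs(mean(ph$t1[idx]) - ph$truth$t1_mu[r]), 3 * se_t1)
    expect_lt(abs(mean(ph$flair[idx]) - ph$truth$flair_mu[r]), 3 * se_fl)
  }
})

test_that("scanner affines act jointly and invertibly on phantom intensities", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20), n_regions = 8)
  visit <- list(eyo = -5, mutation_status = "carrier")
  A <- iaffine2(matrix(c(1.3, 0.05, -0.1, 0.85), 2, 2), c(25, -10))
  p0 <- simulate_phantom_pair(visit, spec, effect_model(), seed = 9)
  pA <- simulate_phantom_pair(visit, spec, effect_model(), seed = 9,
                              scanner_affine = A)
  idx <- which(spec$mask)
  undone <- affine_apply(affine_invert(A), cbind(pA$t1[idx], pA$flair[idx]))
  expect_equal(undone[, 1], p0$t1[idx], tolerance = 1e-10)
  expect_equal(undone[, 2], p0$flair[idx], tolerance = 1e-10)
})

test_that("carriers near onset have lower planted FLAIR means in affected regions", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20), n_regions = 8)
  eff <- effect_model(affected_regions = c(1L, 2L))
  at0 <- simulate_phantom_pair(list(eyo = 0, mutation_status = "carrier"),
                               spec, eff, seed = 1)
  far <- simulate_phantom_pair(list(eyo = -20, mutation_status = "carrier"),
                               spec, eff, seed = 1)
  expect_true(all(at0$truth$flair_mu[1:2] < far$truth$flair_mu[1:2]))
  expect_true(all(at0$truth$t1_sd[1:2] > far$truth$t1_sd[1:2]))
  # unaffected regions and non-carriers are untouched
  expect_equal(at0$truth$flair_mu[3:8], far$truth$flair_mu[3:8])
  nc <- simulate_phantom_pair(list(eyo = 0, mutation_status = "non_carrier"),
                              spec, eff, seed = 1)
  expect_equal(nc$truth$flair_mu, far$truth$flair_mu)
})

test_that("generated volumes round-trip bit-exactly through NIfTI", {
  spec <- phantom_spec(grid_shape = c(16, 16, 16), n_regions = 8)
  ph <- simulate_phantom_pair(list(eyo = -10, mutation_status = "carrier"),
                              spec, effect_model(), seed = 2)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ph$t1, f)
  expect_identical(read_volume(f), ph$t1)
  fl <- tempfile(fileext = ".nii.gz")
  write_volume(ph$labels, fl)
  expect_equal(read_volume(fl), ph$labels * 1)
})

test_that("non-carrier PET uptake is flat in EYO", {
  co <- simulate_cohort(150, 0.5, 1, seed = 31)
  rt <- default_region_table(4)
  eff <- effect_model(affected_regions = 1:2)
  pet <- simulate_pet_tables(co$visits, co$participants, eff, seed = 31,
                             region_table = rt)
  nc <- co$participants$subject_id[co$participants$mutation_status == "non_carrier"]
  for (tab in pet) {
    d <- tab[tab$subject_id %in% nc & tab$region_id == 1, ]
    d$eyo <- co$visits$eyo[match(substr(d$pet_session_id, 1, 9),
                                 co$visits$session_id)]
    sl <- summary(lm(suvr ~ eyo, d))$coefficients["eyo", ]
    expect_gt(sl["Pr(>|t|)"], 0.01)        # slope CI covers 0
    expect_lt(abs(mean(d$suvr) - 1), 0.1)  # near baseline SUVR of 1
  }
})

test_that("carrier tau uptake in affected regions rises approaching onset", {
  rt <- default_region_table(4)
  eff <- effect_model(affected_regions = 1:2)
  v <- data.frame(subject_id = c("S1", "S2"), session_id = c("S1_v1", "S2_v1"),
                  visit_date = as.Date("2015-01-01"), eyo = c(5, -20),
                  stringsAsFactors = FALSE)
  p <- data.frame(subject_id = c("S1", "S2"), mutation_status = "carrier",
                  stringsAsFactors = FALSE)
  # average over seeds: expectation, not a single draw
  diffs <- sapply(1:30, function(s) {
    tau <- simulate_pet_tables(v, p, eff, seed = s, region_table = rt)$tau
    mean(tau$suvr[tau$subject_id == "S1" & tau$region_id %in% 1:2]) -
      mean(tau$suvr[tau$subject_id == "S2" & tau$region_id %in% 1:2])
  })
  expect_gt(mean(diffs), 0.5)
  pet1 <- simulate_pet_tables(v, p, eff, seed = 4, region_table = rt)
  pet2 <- simulate_pet_tables(v, p, eff, seed = 4, region_table = rt)
  expect_identical(pet1, pet2)
})

test_that("morphometry shows atrophy only when and where planted", {
  co <- simulate_cohort(120, 0.5, 1, seed = 13)
  rt <- default_region_table(8)
  carrier <- co$participants$mutation_status[
    match(co$visits$subject_id, co$participants$subject_id)] == "carrier"

  # atrophy_rate 0: carrier and non-carrier thickness indistinguishable
  m0 <- simulate_morphometry(co$visits, co$participants,
                             effect_model(affected_regions = 1:4,
                                          atrophy_rate = 0),
                             seed = 13, region_table = rt)
  pvals <- sapply(1:8, function(r) {
    d <- m0[m0$region_id == r, ]
    t.test(d$value[carrier], d$value[!carrier])$p.value
  })
  expect_lte(sum(pvals < 0.01), 2)  # about chance at alpha = .01

  # planted atrophy: carriers near onset lower than far from onset
  m1 <- simulate_morphometry(co$visits, co$participants,
                             effect_model(affected_regions = 1:4,
                                          atrophy_rate = 0.05),
                             seed = 13, region_table = rt)
  d <- m1[m1$region_id == 1, ]
  d$eyo <- co$visits$eyo[match(d$session_id, co$visits$session_id)]
  near <- d$value[carrier & d$eyo > -3]
  far <- d$value[carrier & d$eyo < -12]
  expect_gt(length(near), 3)
  expect_lt(mean(near), mean(far))
  expect_identical(m1, simulate_morphometry(co$visits, co$participants,
                                            effect_model(affected_regions = 1:4,
                                                         atrophy_rate = 0.05),
                                            seed = 13, region_table = rt))
})

test_that("the default parcellation has 68 cortical and 12 subcortical regions", {
  rt <- default_region_table()
  expect_equal(nrow(rt), 80)
  expect_equal(sum(rt$class == "cortical"), 68)
  expect_equal(sum(rt$class == "subcortical"), 12)
  expect_equal(rt$region_id, 1:80)
  expect_true(all(c("Supramarginal", "Thalamus") %in% rt$name))
})
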