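test_that("the CLD generator respects density and determinism", {
  B <- generate_cld(2, arc_density = 1, seed = 1)
  expect_equal(B, matrix(c(0L, 1L, 1L, 0L), 2, 2))

  m <- sum(generate_cld(58, arc_density = 0.03, hub_bias = 1, seed = 2))
  n_slots <- 58 * 57
  se <- sqrt(n_slots * 0.03 * 0.97)
  expect_lt(abs(m - n_slots * 0.03), 4 * se)

  expect_identical(generate_cld(20, 0.05, 1, seed = 9),
                   generate_cld(20, 0.05, 1, seed = 9))
  expect_error(generate_cld(1, 0.1), "n_B")
  expect_error(generate_cld(10, 1.5), "arc_density")
})

test_that("hub bias skews in-degrees relative to uniform attachment", {
  set.seed(41)
  vr_flat <- replicate(60, var(colSums(generate_cld(20, 0.1, hub_bias = 0))))
  vr_hub <- replicate(60, var(colSums(generate_cld(20, 0.1, hub_bias = 3))))
  # uniform targets: in-degrees near-binomial, variance ~ mean
  mdeg <- mean(replicate(20, mean(colSums(generate_cld(20, 0.1, 0)))))
  expect_lt(abs(mean(vr_flat) - mdeg), 0.35 * mdeg)
  expect_gt(mean(vr_hub), 1.5 * mean(vr_flat))
})

test_that("attribute generation follows the declared probabilities", {
  prof <- community_profile(
    org_probs = setNames(c(1, 0, 0, 0, 0, 0), org_type_levels()),
    edu_probs = setNames(rep(1 / 6, 6), education_levels()))
  a <- generate_attributes(6, prof, seed = 5)
  expect_equal(nrow(a), 6)
  expect_true(all(a$org_type == "Local Government"))
  expect_named(a, c("actor", "org_type", "education", "gender"))

  prof1 <- community1_profile()
  big <- generate_attributes(10000, prof1, seed = 6)
  emp <- table(factor(big$org_type, levels = org_type_levels())) / 10000
  p <- prof1$org_probs
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))

  a18 <- generate_attributes(18, prof1, seed = 7)
  expect_equal(anyDuplicated(a18$actor), 0)
})

test_that("generated communities satisfy the data-model invariants", {
  m <- generate_community(community_profile(respondents = 10, n_B = 12,
                                            mean_outdegree = 3,
                                            mean_actions = 2, seed = 8))
  expect_s3_class(m, "mlnet")          # constructor validates all invariants
  expect_equal(diag(m$A), setNames(rep(0L, 10), m$actors))
  expect_true(all(m$X %in% 0:1))
  expect_equal(nrow(m$Y), 10)
})

test_that("calibration hits the degree targets within fifteen percent", {
  prof <- community1_profile(seed = 44)
  m <- generate_community(prof)
  s <- descriptive_summary(m, prof$invited)
  expect_lt(abs(s$outdegree$mean - 7.1), 0.15 * 7.1)
  expect_lt(abs(s$actions$mean - 5.4), 0.15 * 5.4)
  expect_equal(s$n_respondents, 18)
  expect_equal(s$n_cld_variables, 58)

  m2 <- generate_community(prof)  # same profile, same seed
  m3 <- generate_community(community1_profile(seed = 44))
  expect_identical(m2$A, m3$A)
  expect_identical(m2$X, m3$X)
})

test_that("raising the density parameter raises the mean out-degree", {
  set.seed(45)
  nA <- 12
  empty <- empty_mnet(nA, 4)
  means <- sapply(c(-2, -1, 0, 1), function(th) {
    s <- mcmc_sample(empty, model_spec(spec_list("Density"), th),
                     mcmc_settings(burnin = 3000, interval = 150), 200)
    mean(s$stats[, "Density"]) / nA
  })
  expect_true(all(diff(means) > 0))
})

test_that("a dyad-independent truth gives Bernoulli reciprocity counts", {
  prof <- community_profile(respondents = 14, n_B = 6,
                            mean_outdegree = 4, mean_actions = 2,
                            effects = c("Density", "DensityX"),
                            theta = c(Density = 0, DensityX = 0), seed = 46)
  set.seed(46)
  recips <- replicate(40, {
    p <- prof; p$seed <- sample.int(1e6, 1)
    m <- generate_community(p)
    c(sum(m$A * t(m$A)) / 2, sum(m$A) / (14 * 13))
  })
  obs <- mean(recips[1, ])
  phat <- mean(recips[2, ])
  expected <- choose(14, 2) * phat^2
  se <- sd(recips[1, ]) / sqrt(40)
  expect_lt(abs(obs - expected), 3 * se + 0.5)
})

test_that("the recovery harness reports bias, spread and coverage", {
  prof <- community_profile(respondents = 10, n_B = 4,
                            mean_outdegree = 3, mean_actions = 1.5,
                            effects = c("Density", "DensityX"),
                            theta = c(Density = 0, DensityX = 0), seed = 47)
  rec <- recovery_experiment(prof, n_reps = 2,
                             settings = estimation_settings(
                               phase1_n = 100, iter_per_subphase = 30,
                               phase3_n = 200, polish_max = 2),
                             refits = 0)
  expect_equal(nrow(rec$report), 2)
  expect_named(rec$report, c("effect", "mean_estimate", "mean_truth",
                             "bias", "sd_estimate", "mc_se",
                             "coverage_2se"))
  expect_equal(dim(rec$estimates), c(2, 2))
  expect_true(all(is.finite(rec$report$bias)))
  expect_error(recovery_experiment(prof, 1), "n_reps")
})

test_that("profiles validate their inputs", {
  expect_error(community_profile(respondents = 30, invited = 27), "invited")
  expect_error(community_profile(org_probs = setNames(rep(0.5, 6),
                                                      org_type_levels())),
               "sum to 1")
  expect_error(community_profile(effects = c("Density", "Reciprocity"),
                                 theta = c(0, 0)),
               "DensityX")
})
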