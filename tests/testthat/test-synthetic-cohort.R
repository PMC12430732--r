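test_that("generation is deterministic given the config", {
  cfg <- scenario_config(n_participants = 500, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$diet, b$diet)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1, g2)
  eta <- rep(0, nrow(a$participants))
  s1 <- simulate_survival(a$participants, eta, cfg, baseline_hazard = 0.01)
  s2 <- simulate_survival(a$participants, eta, cfg, baseline_hazard = 0.01)
  expect_identical(s1, s2)
})

test_that("an empty cohort keeps the schema intact", {
  cfg <- scenario_config(n_participants = 0, seed = 1)
  raw <- generate_cohort(cfg)
  expect_equal(nrow(raw$participants), 0)
  expect_equal(nrow(raw$diet), 0)
  expect_true(all(c("id", "sex", "age", "bmi", "baseline_cancer",
                    paste0("pc", 1:10)) %in% names(raw$participants)))
  expect_true(all(phd_components() %in% names(raw$diet)))
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(maf_range = c(0, 0.3)), "maf_range")
  expect_error(scenario_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(scenario_config(n_participants = -5), "n_participants")
  expect_error(scenario_config(target_incidence = 1.2),
               "target_incidence")
  expect_error(scenario_config(censor_date = as.Date("2008-01-01")),
               "recruitment window")
})

test_that("dosages are binomial with mean 2*MAF and respect limits", {
  cfg <- scenario_config(n_participants = 10000, seed = 5,
                         n_sites = 1, variants_per_site = 1,
                         maf_range = c(0.25, 0.25))
  g <- generate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  se <- sqrt(2 * 0.25 * 0.75 / 10000)
  expect_lt(abs(mean(g$dosages) - 0.5), 3 * se)

  cfg0 <- scenario_config(n_participants = 200, seed = 5,
                          n_sites = 1, variants_per_site = 1,
                          maf_range = c(1e-9, 1e-9))
  expect_true(all(generate_genotypes(cfg0)$dosages == 0))

  # each variant carries exactly one site and one effect size
  cfg2 <- scenario_config(n_participants = 10, seed = 2, n_sites = 3,
                          variants_per_site = 4)
  w <- generate_genotypes(cfg2)$weights
  expect_equal(nrow(w), 12)
  expect_equal(anyDuplicated(w$variant_id), 0)
  expect_equal(as.vector(table(w$site)), rep(4, 3))
})

test_that("survival simulation follows the exponential PH model", {
  cfg <- scenario_config(n_participants = 20000, seed = 9)
  raw <- generate_cohort(cfg)
  p <- raw$participants
  admin <- as.numeric(cfg$censor_date - p$entry_date) / 365.25
  eta <- rep(0, nrow(p))

  # null hazard: no events, follow-up equals administrative time
  s0 <- simulate_survival(p, eta, cfg, baseline_hazard = 0)
  expect_equal(sum(s0$event), 0)
  expect_equal(s0$follow_up_years, admin)

  # closed-form incidence: 1 - E[exp(-h * T_admin)]
  h <- 0.09 / mean(admin)
  s1 <- simulate_survival(p, eta, cfg, baseline_hazard = h)
  expected <- mean(1 - exp(-h * admin))
  se <- sqrt(expected * (1 - expected) / nrow(p))
  expect_lt(abs(mean(s1$event) - expected), 3 * se)

  # doubling the hazard strictly increases incidence
  s2 <- simulate_survival(p, eta, cfg, baseline_hazard = 2 * h)
  expect_gt(mean(s2$event), mean(s1$event))

  expect_error(simulate_survival(p, c(eta[-1], Inf), cfg,
                                 baseline_hazard = h), "finite")
})

test_that("baseline hazard calibration hits and orders its targets", {
  cfg <- scenario_config(n_participants = 5000, seed = 10)
  raw <- generate_cohort(cfg)
  admin <- as.numeric(cfg$censor_date - raw$participants$entry_date) /
    365.25
  set.seed(1)
  eta <- rnorm(nrow(raw$participants), 0, 0.5)
  h <- vapply(c(0.02, 0.05, 0.10),
              function(tg) calibrate_baseline_hazard(tg, eta, admin),
              numeric(1))
  expect_true(all(diff(h) > 0))           # increasing in the target
  for (i in seq_along(h)) {
    achieved <- mean(1 - exp(-h[i] * exp(eta) * admin))
    expect_equal(achieved, c(0.02, 0.05, 0.10)[i], tolerance = 1e-6)
  }
  # vanishing target forces a vanishing hazard
  expect_lt(calibrate_baseline_hazard(1e-6, eta, admin), 1e-6)
  expect_error(calibrate_baseline_hazard(1, eta, admin), "target")
})

test_that("dietary intakes are right-skewed with the configured medians", {
  cfg <- scenario_config(n_participants = 50000, seed = 13)
  raw <- generate_cohort(cfg)
  veg <- raw$diet$vegetables
  expect_lt(abs(median(veg) - 284.75) / 284.75, 0.10)
  expect_gt(mean(veg), median(veg))   # right skew
  expect_true(all(raw$diet[phd_components()] >= 0))
  expect_true(all(raw$diet$energy > 0))

  # assessments per participant stay within 0..5
  expect_true(all(raw$participants$n_assessments %in% 0:5))
})

test_that("the flowchart fixture reproduces the selection cascade exactly", {
  fx <- build_flowchart_fixture()
  expect_equal(nrow(fx$participants), 502411)
  ex <- apply_exclusions(fx)
  expect_equal(ex$audit$removed,
               c(44825L, 265106L, 9169L, 3611L, 11L, 2248L))
  expect_equal(nrow(ex$participants), 177441)
  expect_equal(502411 - 44825 - 265106 - 9169 - 3611 - 11 - 2248, 177441)

  # flags are mutually exclusive by construction
  p <- fx$participants
  flags <- cbind(p$baseline_cancer, p$n_assessments == 0, !p$european,
                 !p$has_prs, p$lost_followup,
                 p$sex == "male" & !is.na(p$mean_energy) &
                   (p$mean_energy < 800 | p$mean_energy > 4000))
  expect_true(all(rowSums(flags) <= 1))
})

test_that("quintile sizes on a 177441-value fixture match 35489/35488", {
  set.seed(99)
  q <- assign_quintiles(sample(seq_len(177441)))
  expect_equal(as.vector(table(q)), c(35489, rep(35488, 4)))
})

test_that("true joint effects hit the configured extreme contrast", {
  cfg <- scenario_config(n_participants = 10, seed = 1, sex = "men",
                         effect_set = "joint")
  eff <- phdcox:::joint_true_effects(cfg)
  expect_length(eff, 15)
  expect_equal(unname(eff["Q1.high"]), 0)
  expect_equal(unname(eff["Q5.low"]), log(0.39), tolerance = 1e-12)
})
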