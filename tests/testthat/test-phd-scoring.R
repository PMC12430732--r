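test_that("assessment averaging is the arithmetic mean and is symmetric", {
  comps <- phd_components()
  one <- as.data.frame(as.list(setNames(seq(10, 140, by = 10), comps)))
  one$id <- 1
  one$energy <- 2000

  # single assessment returned unchanged
  avg1 <- average_assessments(one)
  expect_equal(avg1$n_assessments, 1L)
  expect_equal(unlist(avg1[comps]), unlist(one[comps]),
               ignore_attr = TRUE)

  # (100, 300) averages to 200, for every component and energy
  two <- rbind(one, one)
  two[comps] <- rbind(rep(100, 14), rep(300, 14))
  two$energy <- c(1500, 2500)
  avg2 <- average_assessments(two)
  expect_equal(unname(unlist(avg2[comps])), rep(200, 14))
  expect_equal(avg2$energy, 2000)

  # permutation invariance over assessment order
  set.seed(5)
  many <- one[rep(1, 4), ]
  many[comps] <- matrix(runif(56, 0, 300), 4)
  many$energy <- runif(4, 1500, 2500)
  a <- average_assessments(many)
  b <- average_assessments(many[sample(4), ])
  expect_equal(a[c(comps, "energy")], b[c(comps, "energy")])

  expect_error(average_assessments(one[0, ]), "no dietary assessments")
})

test_that("energy adjustment rescales to the 2500 kcal reference", {
  expect_equal(energy_adjust(100, 2500), 100)
  expect_equal(energy_adjust(100, 1250), 200)
  expect_equal(energy_adjust(0, 1800), 0)
  expect_error(energy_adjust(100, 0), "energy must be positive")
  expect_error(energy_adjust(100, -10), "energy must be positive")
})

test_that("the three scoring rules hit their anchor values", {
  T <- 137  # arbitrary positive reference; rules are symbolic in T
  # adequacy: full marks at or beyond the recommendation, linear below
  expect_equal(score_component(T, "adequacy", T), 10)
  expect_equal(score_component(2 * T, "adequacy", T), 10)
  expect_equal(score_component(T / 2, "adequacy", T), 5)
  expect_equal(score_component(0, "adequacy", T), 0)
  # moderation: inverse scale from 10 at zero to 0 at the limit
  expect_equal(score_component(0, "moderation", T), 10)
  expect_equal(score_component(T, "moderation", T), 0)
  expect_equal(score_component(1.5 * T, "moderation", T), 0)
  expect_equal(score_component(T / 2, "moderation", T), 5)
  # balanced: tent peaking at the target, half marks at 50%/150%
  expect_equal(score_component(T, "balanced", T), 10)
  expect_equal(score_component(0.5 * T, "balanced", T), 5)
  expect_equal(score_component(1.5 * T, "balanced", T), 5)
  expect_equal(score_component(2 * T, "balanced", T), 0)
  expect_error(score_component(10, "bogus", T), "unknown rule class")
})

test_that("total score sums the 14 components with known worked profiles", {
  rules <- phd_rules()
  comps <- rules$component
  optimum <- setNames(rules$reference_amount, comps)
  optimum[rules$rule_class == "moderation"] <- 0
  best <- as.data.frame(as.list(optimum))
  best$energy <- 2500
  expect_equal(compute_phd(best)$phd_total, 140)

  worst <- best
  worst[comps[rules$rule_class != "moderation"]] <- 0
  lims <- rules$reference_amount[rules$rule_class == "moderation"]
  worst[comps[rules$rule_class == "moderation"]] <- as.list(lims * 2)
  expect_equal(compute_phd(worst)$phd_total, 0)

  # vegetables at T/2 (adequacy, -5) and red meat at L/2 (moderation, -5)
  mixed <- best
  mixed$vegetables <- rules$reference_amount[comps == "vegetables"] / 2
  mixed$red_meat <- rules$reference_amount[comps == "red_meat"] / 2
  expect_equal(compute_phd(mixed)$phd_total, 130)

  noveg <- best[setdiff(names(best), "vegetables")]
  expect_error(compute_phd(noveg), "vegetables")
})

test_that("scores are bounded, energy-scale invariant and match a loop oracle", {
  d <- random_intake_profiles(1000, seed = 11)
  res <- compute_phd(d)
  sc <- as.matrix(res[paste0("score_", phd_components())])
  expect_true(all(sc >= 0 & sc <= 10))
  expect_true(all(res$phd_total >= 0 & res$phd_total <= 140))

  # multiplying all intakes and energy by one constant changes nothing
  d2 <- d
  d2[] <- lapply(d2, function(x) x * 3.7)
  expect_equal(compute_phd(d2), res)

  # independent per-component scoring oracle, bit-exact
  rules <- phd_rules()
  oracle <- numeric(nrow(d))
  for (j in seq_len(nrow(rules))) {
    adj <- d[[rules$component[j]]] * 2500 / d$energy
    oracle <- oracle + score_component(adj, rules$rule_class[j],
                                       rules$reference_amount[j])
  }
  expect_identical(res$phd_total, oracle)
})

test_that("rule classes are monotone in the documented directions", {
  x <- seq(0, 600, by = 1)
  ad <- score_component(x, "adequacy", 250)
  mo <- score_component(x, "moderation", 250)
  ba <- score_component(x, "balanced", 250)
  expect_true(all(diff(ad) >= 0))
  expect_true(all(diff(mo) <= 0))
  expect_equal(which.max(ba), which(x == 250))
  expect_true(all(diff(ba[x <= 250]) >= 0))
  expect_true(all(diff(ba[x >= 250]) <= 0))
})
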