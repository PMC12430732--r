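# A small hand-built raw cohort for exclusion tests.
mini_cohort <- function(n = 10) {
  p <- data.frame(id = seq_len(n),
                  sex = factor(rep(c("male", "female"),
                                   length.out = n),
                               levels = c("female", "male")),
                  baseline_cancer = FALSE, european = TRUE,
                  has_prs = TRUE, lost_followup = FALSE,
                  n_assessments = 1L, mean_energy = 2000)
  structure(list(participants = p, diet = NULL, config = NULL),
            class = "raw_cohort")
}

test_that("a clean cohort passes the cascade unchanged", {
  ex <- apply_exclusions(mini_cohort(8))
  expect_equal(nrow(ex$participants), 8)
  expect_equal(ex$audit$removed, rep(0L, 6))
  expect_equal(ex$audit$remaining[6], 8)
})

test_that("energy plausibility bounds are sex-specific", {
  ch <- mini_cohort(4)
  ch$participants$sex <- factor(c("male", "female", "male", "female"),
                                levels = c("female", "male"))
  ch$participants$mean_energy <- c(799, 799, 4001, 3400)
  ex <- apply_exclusions(ch)
  # man at 799 excluded, woman at 799 retained; man above 4000 excluded
  expect_equal(ex$participants$id, c(2, 4))
  expect_equal(ex$audit$removed[ex$audit$rule == "implausible_energy"], 2L)

  ch2 <- mini_cohort(2)
  ch2$participants$sex <- factor(c("female", "female"),
                                 levels = c("female", "male"))
  ch2$participants$mean_energy <- c(499, 3501)
  expect_equal(nrow(apply_exclusions(ch2)$participants), 0)
})

test_that("audit counts conserve and attribute to the first matching rule", {
  ch <- mini_cohort(10)
  ch$participants$baseline_cancer[1:3] <- TRUE
  ch$participants$n_assessments[3:5] <- 0L   # id 3 overlaps both rules
  ch$participants$european[6] <- FALSE
  ex <- apply_exclusions(ch)
  a <- ex$audit
  expect_equal(a$removed, c(3L, 2L, 1L, 0L, 0L, 0L))
  expect_equal(a$entering - a$removed, a$remaining)
  expect_equal(a$entering[-1], a$remaining[-6])
  expect_equal(sum(a$removed) + nrow(ex$participants), 10)
})

test_that("permuting rules changes attribution but not the survivors", {
  ch <- mini_cohort(12)
  ch$participants$baseline_cancer[1:4] <- TRUE
  ch$participants$n_assessments[3:7] <- 0L
  ch$participants$has_prs[c(4, 8)] <- FALSE
  ex1 <- apply_exclusions(ch)
  ex2 <- apply_exclusions(ch, rule_order = rev(ex1$audit$rule))
  expect_false(identical(ex1$audit$removed,
                         rev(ex2$audit$removed)))
  expect_setequal(ex1$participants$id, ex2$participants$id)
})

test_that("missing predicate fields are rejected by name", {
  ch <- mini_cohort(3)
  ch$participants$has_prs <- NULL
  expect_error(apply_exclusions(ch), "has_prs")
})

test_that("quintile assignment matches a sort-and-slice oracle", {
  q <- assign_quintiles(1:100)
  expect_equal(as.vector(table(q)), rep(20, 5))
  expect_equal(as.character(q[1]), "Q1")
  expect_equal(as.character(q[100]), "Q5")

  # affine transforms and general monotone maps keep the labels
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(50:500, 1))
    q0 <- assign_quintiles(x)
    expect_equal(as.integer(assign_quintiles(3 * x - 7)),
                 as.integer(q0))
    expect_equal(as.integer(assign_quintiles(exp(x))), as.integer(q0))
    # oracle: rank-based slicing with boundary ties to the lower group
    n <- length(x)
    cuts <- sort(x)[pmin(n, floor(1 + (n - 1) * c(.2, .4, .6, .8)))]
    oracle <- findInterval(x, cuts, left.open = TRUE) + 1
    # type-7 cuts interpolate upward from the same order statistic,
    # so both constructions bound the same rank sets
    expect_equal(as.integer(q0), oracle)
  }
  expect_error(assign_quintiles(rep(1:2, 10)), "distinct")
})

test_that("stratified quintiles are computed within stratum", {
  x <- c(1:50, 1001:1050)
  s <- rep(c("a", "b"), each = 50)
  q <- assign_quintiles(x, strata = s)
  expect_equal(as.vector(table(q[s == "a"])), rep(10, 5))
  expect_equal(as.vector(table(q[s == "b"])), rep(10, 5))
})

test_that("exposure standardisation uses the sample SD", {
  z <- standardize_exposure(c(0, 10))
  expect_equal(as.numeric(z), c(-0.7071068, 0.7071068), tolerance = 1e-6)
  set.seed(2)
  x <- rnorm(200, 50, 9)
  z2 <- standardize_exposure(x)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
  expect_equal(as.numeric(standardize_exposure(x * 13)),
               as.numeric(z2))
  expect_error(standardize_exposure(rep(3, 10)), "zero variance")
  expect_error(standardize_exposure(1), "at least 2")
})

test_that("analysis dataset assembly derives exposures and checks joins", {
  st <- small_study()
  d <- st$data
  expect_s3_class(d, "analysis_dataset")
  expect_equal(mean(d$phd_z), 0, tolerance = 1e-10)
  expect_equal(sd(d$phd_z), 1, tolerance = 1e-10)
  expect_true(all(abs(table(d$phd_q) - nrow(d) / 5) <= 1))
  expect_true(all(paste0("pc", 1:10) %in% names(d)))

  # disjoint ids are rejected with a count
  ph <- data.frame(id = -(1:5), phd_total = 1:5)
  expect_error(
    build_analysis_dataset(st$data[1:5, c("id", "sex", "age")], ph,
                           NULL, ph, model = "crude"),
    "unmatched")
})

test_that("model covariate sets grow crude -> model1 -> model2", {
  expect_length(model_covariates("crude"), 0)
  m1 <- model_covariates("model1")
  expect_true(all(c("sex", "age", "bmi", "energy") %in% m1))
  expect_length(grep("^pc", m1), 10)
  m2 <- model_covariates("model2")
  expect_true(all(m1 %in% m2))
  expect_true(all(c("income", "education", "townsend", "alcohol",
                    "smoking", "family_history") %in% m2))
  expect_false("sex" %in% model_covariates("model2",
                                           sex_stratified = TRUE))
})
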