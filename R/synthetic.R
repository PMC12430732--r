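# Deterministic per-stream seeds so changing one generator block does not
# perturb the draws of another.
stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 113 + stream * 10007) %% 2147483647)
}

#' Default dietary component distributions
#'
#' Marginal intake model for the synthetic cohort: each component is
#' zero-inflated log-normal. `p_zero` is the probability a participant
#' never consumes the component; consumers draw per-assessment intakes
#' from a log-normal with the given median and log-scale SD, shifted by
#' a shared latent "diet quality" factor through `loading` (positive for
#' plant foods, negative for red meat and added sugar), which induces the
#' joint gradient across diet-quality quintiles seen in real cohorts.
#' Medians are calibrated to a large UK cohort's intake table.
#'
#' @return Data frame with columns `component`, `median`, `sdlog`,
#'   `p_zero`, `loading`.
#' @export
default_diet_components <- function() {
  data.frame(
    component = phd_components(),
    median = c(284.75, 280, 30, 120, 60, 13.17,
               150, 95, 50, 175, 130,
               28.2, 92, 8),
    sdlog = c(0.8, 0.8, 0.9, 0.7, 0.9, 0.45,
              0.9, 0.9, 0.6, 0.7, 0.6,
              0.45, 0.8, 1.0),
    p_zero = c(0.03, 0.03, 0.55, 0.55, 0.35, 0.01,
               0.10, 0.05, 0.60, 0.20, 0.60,
               0.01, 0.25, 0.70),
    loading = c(0.5, 0.5, 0.4, 0.3, 0.4, 0.3,
                0.3, 0.1, 0.0, 0.0, 0.0,
                -0.1, -0.3, -0.2),
    stringsAsFactors = FALSE
  )
}

#' Default true log-hazard effects for a scenario
#'
#' Named generating effects for the synthetic cohort, calibrated to the
#' headline estimates of a large diet-and-cancer biobank analysis:
#' per-SD PHD log HR `log(0.96)`; CPRS intermediate/high group contrasts
#' (men `log(1.54)`/`log(2.50)`, women `log(1.26)`/`log(1.72)`); joint
#' 15-group effects additive in a per-quintile PHD step and a CPRS group
#' level chosen so the (Q5 PHD, low CPRS) vs (Q1 PHD, high CPRS)
#' contrast equals the reported extreme-group value (men `log(0.39)`,
#' women `log(0.55)`); plus modest covariate effects (age, BMI, sex,
#' deprivation, smoking, family history) that the adjusted models
#' absorb.
#'
#' @param sex `"both"`, `"men"` or `"women"`.
#' @return List with elements `phd_per_sd`, `cprs` (length-2:
#'   intermediate, high), `joint_phd_step`, `joint_extreme`, and
#'   `covar` (named vector).
#' @export
default_true_effects <- function(sex = c("both", "men", "women")) {
  sex <- match.arg(sex)
  cprs <- switch(sex,
                 men = c(intermediate = log(1.54), high = log(2.50)),
                 women = c(intermediate = log(1.26), high = log(1.72)),
                 both = c(intermediate = log(1.39), high = log(2.07)))
  q5 <- switch(sex, men = log(0.92), women = log(0.96), both = log(0.95))
  extreme <- switch(sex, men = log(0.39), women = log(0.55),
                    both = log(0.46))
  list(phd_per_sd = log(0.96),
       cprs = cprs,
       joint_phd_step = q5 / 4,
       joint_extreme = extreme,
       covar = c(age = 0.07, bmi = 0.015, sex_male = log(1.35),
                 townsend = 0.02, smoking_current = 0.45,
                 smoking_previous = 0.12, family_history_yes = 0.25))
}

#' Scenario configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator. Defaults emulate the design of
#' a large UK prospective cohort: recruitment 2006-01-01 to 2010-12-31,
#' administrative censoring on 2022-05-31, ~46% men, ~8.72% cumulative
#' cancer incidence, right-skewed dietary intakes, and binomial genotype
#' dosages for a multi-site variant panel.
#'
#' @param n_participants Cohort size (>= 0).
#' @param seed Integer seed; every generator stream derives from it.
#' @param sex `"both"` (mixed cohort), `"men"` or `"women"`.
#' @param sex_ratio Fraction of men when `sex = "both"`.
#' @param effect_set Which exposure truth enters the hazard:
#'   `"phd"` (per-SD PHD effect), `"cprs"` (genetic-risk group
#'   contrasts), `"joint"` (15 joint-group effects), or `"none"`.
#' @param true_effects As [default_true_effects()]; any element may be
#'   overridden.
#' @param baseline_hazard Events per person-year for a reference
#'   participant, or `NULL` to calibrate to `target_incidence`.
#' @param target_incidence Cumulative incidence the baseline hazard is
#'   calibrated to when `baseline_hazard` is `NULL`.
#' @param recruitment_window Length-2 `Date` vector (entry dates drawn
#'   uniformly over it).
#' @param censor_date Administrative censoring date.
#' @param n_sites,variants_per_site Genotype panel dimensions.
#' @param maf_range Minor-allele-frequency interval, within (0, 0.5).
#' @param assessment_dist Probabilities of completing 0..5 dietary
#'   assessments.
#' @param diet_components As [default_diet_components()].
#' @param exclusion_rates Named list of flag probabilities:
#'   `baseline_cancer`, `non_european`, `missing_prs`, `lost_followup`.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_participants = 10000,
                            seed = 1,
                            sex = c("both", "men", "women"),
                            sex_ratio = 0.4629,
                            effect_set = c("phd", "cprs", "joint", "none"),
                            true_effects = NULL,
                            baseline_hazard = NULL,
                            target_incidence = 0.0872,
                            recruitment_window = as.Date(c("2006-01-01",
                                                           "2010-12-31")),
                            censor_date = as.Date("2022-05-31"),
                            n_sites = 20,
                            variants_per_site = 10,
                            maf_range = c(0.05, 0.45),
                            assessment_dist = c(0.05, 0.43, 0.24,
                                                0.14, 0.09, 0.05),
                            diet_components = default_diet_components(),
                            exclusion_rates = list(baseline_cancer = 0.02,
                                                   non_european = 0.02,
                                                   missing_prs = 0.01,
                                                   lost_followup = 1e-4)) {
  sex <- match.arg(sex)
  effect_set <- match.arg(effect_set)
  if (n_participants < 0) stop("n_participants must be >= 0")
  if (!is.null(baseline_hazard) && baseline_hazard < 0)
    stop("baseline_hazard must be >= 0")
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within the open interval (0, 0.5)")
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("sex_ratio must be a fraction in [0, 1]")
  if (recruitment_window[2] >= censor_date)
    stop("recruitment window must precede the censor date")
  if (!is.null(target_incidence) &&
      (target_incidence <= 0 || target_incidence >= 1))
    stop("target_incidence must lie in (0, 1)")
  if (abs(sum(assessment_dist) - 1) > 1e-8)
    stop("assessment_dist must sum to 1")
  if (is.null(true_effects)) {
    true_effects <- default_true_effects(sex)
  } else {
    base <- default_true_effects(sex)
    base[names(true_effects)] <- true_effects
    true_effects <- base
  }
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), sex = sex,
                 sex_ratio = sex_ratio, effect_set = effect_set,
                 true_effects = true_effects,
                 baseline_hazard = baseline_hazard,
                 target_incidence = target_incidence,
                 recruitment_window = recruitment_window,
                 censor_date = censor_date,
                 n_sites = as.integer(n_sites),
                 variants_per_site = as.integer(variants_per_site),
                 maf_range = maf_range,
                 assessment_dist = assessment_dist,
                 diet_components = diet_components,
                 exclusion_rates = exclusion_rates),
            class = "scenario_config")
}

#' Generate a synthetic raw cohort
#'
#' Draws participant covariates (age, sex, BMI, deprivation, ten genetic
#' principal components, income, education, smoking, alcohol, family
#' history of cancer - categorical fields carry an explicit `"unknown"`
#' level), entry dates, exclusion flags, and 0-5 dietary assessments per
#' participant with zero-inflated log-normal component intakes linked by
#' a latent diet-quality factor. Reproducible: identical config (and
#' seed) gives identical output.
#'
#' @param config A [scenario_config()].
#' @return List of class `"raw_cohort"` with elements `participants`
#'   (one row per participant), `diet` (one row per assessment) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_participants

  set.seed(stream_seed(config$seed, 1))          # covariate stream
  sex <- switch(config$sex,
                both = ifelse(stats::runif(n) < config$sex_ratio,
                              "male", "female"),
                men = rep("male", n),
                women = rep("female", n))
  sex <- factor(sex, levels = c("female", "male"))
  age <- pmin(73, pmax(37, stats::rnorm(n, 56.3, 8.1)))
  bmi <- stats::rlnorm(n, log(26.25), 0.16)
  townsend <- stats::rnorm(n, -2.0, 2.8)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  samp <- function(levels, probs)
    factor(levels[sample.int(length(levels), n, replace = TRUE,
                             prob = probs)], levels = levels)
  income <- samp(c("lt_18k", "18_30k", "30_52k", "52_100k", "gt_100k",
                   "unknown"),
                 c(0.1344, 0.2166, 0.2586, 0.2251, 0.0663, 0.0990))
  education <- samp(c("high", "middle", "none", "unknown"),
                    c(0.4243, 0.4869, 0.0850, 0.0038))
  smoking <- samp(c("never", "previous", "current", "unknown"),
                  c(0.5642, 0.3571, 0.0766, 0.0021))
  alcohol <- samp(c("current", "never", "previous", "unknown"),
                  c(0.9451, 0.0256, 0.0289, 0.0004))
  family_history <- samp(c("no", "yes", "unknown"),
                         c(0.5628, 0.3535, 0.0837))
  rw <- as.numeric(config$recruitment_window)
  entry_date <- as.Date(stats::runif(n, rw[1], rw[2]),
                        origin = "1970-01-01")
  er <- config$exclusion_rates
  participants <- data.frame(
    id = seq_len(n), sex = sex, age = age, bmi = bmi,
    townsend = townsend, income = income, education = education,
    smoking = smoking, alcohol = alcohol,
    family_history = family_history, entry_date = entry_date,
    baseline_cancer = stats::runif(n) < er$baseline_cancer,
    european = stats::runif(n) >= er$non_european,
    has_prs = stats::runif(n) >= er$missing_prs,
    lost_followup = stats::runif(n) < er$lost_followup,
    stringsAsFactors = FALSE)
  participants <- cbind(participants, as.data.frame(pcs))

  set.seed(stream_seed(config$seed, 2))          # diet stream
  quality <- stats::rnorm(n)
  participants$diet_quality <- quality
  n_assess <- sample.int(6, n, replace = TRUE,
                         prob = config$assessment_dist) - 1L
  participants$n_assessments <- n_assess
  idx <- rep.int(seq_len(n), n_assess)           # one row per assessment
  total <- length(idx)
  dc <- config$diet_components
  diet <- data.frame(id = idx,
                     assessment = sequence(n_assess),
                     stringsAsFactors = FALSE)
  consumer <- matrix(stats::runif(n * nrow(dc)), n, nrow(dc))
  for (j in seq_len(nrow(dc))) {
    x <- stats::rlnorm(total,
                       log(dc$median[j]) + dc$loading[j] * quality[idx],
                       dc$sdlog[j])
    x[consumer[idx, j] < dc$p_zero[j]] <- 0
    diet[[dc$component[j]]] <- x
  }
  diet$energy <- stats::rlnorm(total, log(2008) + 0.06 * quality[idx],
                               0.25)
  diet$recall_date <- participants$entry_date[idx] +
    round(stats::runif(total, 0, 730))
  me <- rep(NA_real_, n)
  if (total > 0) {
    mtab <- tapply(diet$energy, factor(diet$id, levels = seq_len(n)),
                   mean)
    me <- as.numeric(mtab)
  }
  participants$mean_energy <- me

  structure(list(participants = participants, diet = diet,
                 config = config),
            class = "raw_cohort")
}

#' Generate genotype dosages and a per-site weight table
#'
#' Dosages are drawn binomially per variant (Hardy-Weinberg counts in
#' {0, 1, 2} with minor-allele frequency uniform over `maf_range`), so
#' the mean dosage of a variant converges to 2*MAF. The weight table
#' assigns each variant to one cancer site with one per-allele effect
#' size, the shape consumed by [compute_site_prs()]; the companion
#' incidence table supplies the site weights for [compute_cprs()].
#'
#' @param config A [scenario_config()] (uses `n_participants`,
#'   `n_sites`, `variants_per_site`, `maf_range`, `seed`).
#' @return List with `dosages` (participants x variants integer matrix),
#'   `weights` (`variant_id`, `effect_allele`, `beta`, `site`, `maf`)
#'   and `incidence` (site incidence-weight config).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_sites < 1 || config$variants_per_site < 1)
    stop("n_sites and variants_per_site must be >= 1")
  mr <- config$maf_range
  if (mr[1] <= 0 || mr[2] >= 0.5)
    stop("maf_range must lie within the open interval (0, 0.5)")
  n <- config$n_participants
  m <- config$n_sites * config$variants_per_site
  sites <- sprintf("site%02d", seq_len(config$n_sites))

  set.seed(stream_seed(config$seed, 4))          # genotype stream
  maf <- stats::runif(m, mr[1], mr[2])
  dosages <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  vids <- sprintf("v%04d", seq_len(m))
  colnames(dosages) <- vids
  rownames(dosages) <- seq_len(n)
  weights <- data.frame(
    variant_id = vids,
    effect_allele = sample(c("A", "C", "G", "T"), m, replace = TRUE),
    beta = stats::rnorm(m, 0.04, 0.02),
    site = rep(sites, each = config$variants_per_site),
    maf = maf,
    stringsAsFactors = FALSE)
  list(dosages = dosages, weights = weights,
       incidence = default_incidence_weights(sites))
}

#' Simulate proportional-hazards survival outcomes
#'
#' Event times follow an exponential proportional-hazards model
#' `T ~ Exp(h0 * exp(eta))`; follow-up is administratively censored at
#' the configured censor date, so `event = 1` iff the event time falls
#' before the participant's administrative time.
#'
#' @param participants Data frame with `id` and `entry_date`.
#' @param eta Per-participant linear predictor (finite).
#' @param config A [scenario_config()] (uses `censor_date`, `seed`).
#' @param baseline_hazard Events per person-year (>= 0); overrides
#'   `config$baseline_hazard`.
#' @return Data frame: `id`, `follow_up_years`, `event`, `entry_date`,
#'   `exit_date`.
#' @export
simulate_survival <- function(participants, eta, config,
                              baseline_hazard = config$baseline_hazard) {
  if (any(!is.finite(eta))) stop("linear predictor must be finite")
  if (is.null(baseline_hazard) || baseline_hazard < 0)
    stop("baseline_hazard must be supplied and >= 0")
  n <- nrow(participants)
  if (length(eta) != n) stop("eta must have one entry per participant")
  admin <- as.numeric(config$censor_date - participants$entry_date) / 365.25
  set.seed(stream_seed(config$seed, 5))          # survival stream
  rate <- baseline_hazard * exp(eta)
  tt <- rep(Inf, n)
  pos <- rate > 0
  tt[pos] <- stats::rexp(sum(pos), rate[pos])
  event <- as.integer(tt < admin)
  fu <- pmin(tt, admin)
  data.frame(id = participants$id, follow_up_years = fu, event = event,
             entry_date = participants$entry_date,
             exit_date = participants$entry_date + round(fu * 365.25))
}

#' Calibrate the baseline hazard to a target cumulative incidence
#'
#' Root-finds the constant baseline hazard h0 such that the expected
#' cumulative incidence `mean(1 - exp(-h0 * exp(eta) * t_admin))` over
#' the supplied effect distribution equals the target. The map is
#' strictly increasing in h0, so the root is unique.
#'
#' @param target_incidence Fraction in (0, 1).
#' @param eta Per-participant linear predictors (the configured effect
#'   distribution).
#' @param admin_years Per-participant administrative follow-up times in
#'   years.
#' @param tol Tolerance on the achieved expected incidence.
#' @return Baseline hazard h0 (events per person-year).
#' @export
calibrate_baseline_hazard <- function(target_incidence, eta, admin_years,
                                      tol = 1e-6) {
  if (target_incidence <= 0 || target_incidence >= 1)
    stop("target_incidence must lie in (0, 1)")
  f <- function(h) mean(1 - exp(-h * exp(eta) * admin_years)) -
    target_incidence
  upper <- 1
  while (f(upper) < 0) upper <- upper * 10
  r <- stats::uniroot(f, c(0, upper), tol = .Machine$double.eps^0.75)
  h0 <- r$root
  if (abs(f(h0)) > max(tol, 1e-4))
    stop("calibration failed to reach the target incidence")
  h0
}

#' Flowchart fixture cohort
#'
#' A deterministic cohort of 502 411 records whose exclusion flags are
#' assigned sequentially so the audit reproduces the selection flowchart
#' of a large UK cohort study exactly: 44 825 with cancer at baseline,
#' then 265 106 without dietary questionnaires, 9 169 of non-European
#' ancestry, 3 611 missing polygenic-score inputs, 11 lost to follow-up,
#' 2 248 with implausible energy intake, leaving 177 441.
#'
#' @return A `raw_cohort`-style list with `participants` only
#'   (assessment counts and mean energy are carried as columns).
#' @export
build_flowchart_fixture <- function() {
  counts <- c(baseline_cancer = 44825, no_diet = 265106,
              non_european = 9169, missing_prs = 3611,
              lost = 11, implausible_energy = 2248)
  n <- 502411
  ends <- cumsum(counts)
  starts <- c(1, utils::head(ends, -1) + 1)
  block <- function(k) starts[k]:ends[k]

  p <- data.frame(
    id = seq_len(n),
    sex = factor(rep(c("male", "female"), length.out = n),
                 levels = c("female", "male")),
    baseline_cancer = FALSE, european = TRUE, has_prs = TRUE,
    lost_followup = FALSE, n_assessments = 1L, mean_energy = 2000,
    stringsAsFactors = FALSE)
  p$baseline_cancer[block(1)] <- TRUE
  p$n_assessments[block(2)] <- 0L
  p$mean_energy[block(2)] <- NA_real_
  p$european[block(3)] <- FALSE
  p$has_prs[block(4)] <- FALSE
  p$lost_followup[block(5)] <- TRUE
  p$sex[block(6)] <- "male"
  p$mean_energy[block(6)] <- 700           # < 800 kcal/day, male bound
  structure(list(participants = p, diet = NULL, config = NULL),
            class = "raw_cohort")
}

#' True linear predictor under a scenario's generating effects
#'
#' Builds the per-participant log-hazard contribution used by the
#' generator: the configured exposure truth (per-SD PHD, CPRS group
#' contrasts, or additive joint 15-group effects) plus the covariate
#' effects. Continuous covariates are centred at their scenario-typical
#' values so the baseline hazard refers to a reference participant.
#'
#' @param data Data frame carrying the covariates and whichever exposure
#'   columns the effect set needs (`phd_z`, `cprs_group`, `phd_q`).
#' @param config A [scenario_config()].
#' @return Numeric vector of linear predictors.
#' @export
true_linear_predictor <- function(data, config) {
  fx <- config$true_effects
  cv <- fx$covar
  eta <- cv[["age"]] * (data$age - 57) +
    cv[["bmi"]] * (data$bmi - 26.25) +
    cv[["sex_male"]] * (data$sex == "male") +
    cv[["townsend"]] * (data$townsend + 2.4) +
    cv[["smoking_current"]] * (data$smoking == "current") +
    cv[["smoking_previous"]] * (data$smoking == "previous") +
    cv[["family_history_yes"]] * (data$family_history == "yes")
  eta <- as.numeric(eta)
  if (config$effect_set == "phd") {
    eta <- eta + fx$phd_per_sd * data$phd_z
  } else if (config$effect_set == "cprs") {
    eta <- eta + fx$cprs[["intermediate"]] *
      (data$cprs_group == "intermediate") +
      fx$cprs[["high"]] * (data$cprs_group == "high")
  } else if (config$effect_set == "joint") {
    eta <- eta + joint_true_effects(config)[joint_group_label(
      data$phd_q, data$cprs_group)]
  }
  unname(eta)
}

# Label of the 15 joint (PHD quintile x CPRS group) cells.
joint_group_label <- function(phd_q, cprs_group) {
  paste0(as.character(phd_q), ".", as.character(cprs_group))
}

# Additive true effects of the 15 joint groups, relative to the
# (Q1, high) reference cell: a per-quintile PHD step plus a CPRS group
# level with gamma_high = 0 and gamma_low set so the (Q5, low) contrast
# equals the configured extreme value.
joint_true_effects <- function(config) {
  fx <- config$true_effects
  step <- fx$joint_phd_step
  g_low <- fx$joint_extreme - 4 * step
  gam <- c(high = 0, intermediate = g_low / 2, low = g_low)
  eff <- outer(step * (0:4), gam, `+`)
  labels <- as.vector(outer(paste0("Q", 1:5), names(gam),
                            function(q, g) paste0(q, ".", g)))
  stats::setNames(as.vector(eff), labels)
}

#' Run the full synthetic study pipeline
#'
#' Generates a raw cohort, applies the exclusion cascade, averages the
#' dietary assessments, computes PHD scores and (unless the effect set
#' makes them irrelevant) site PRS / CPRS / genetic-risk groups, builds
#' the true linear predictor, calibrates the baseline hazard to the
#' target incidence when not fixed, simulates survival, and assembles
#' the analysis dataset.
#'
#' @param config A [scenario_config()].
#' @param with_genotypes Generate genotypes and CPRS columns; default
#'   `TRUE` except when `effect_set = "phd"` or `"none"`, where the
#'   genetic columns play no role in the hazard.
#' @return List: `data` (analysis dataset), `audit` (exclusion audit),
#'   `baseline_hazard`, `eta` (true linear predictors) and `config`.
#' @export
simulate_study <- function(config,
                           with_genotypes =
                             config$effect_set %in% c("cprs", "joint")) {
  raw <- generate_cohort(config)
  ex <- apply_exclusions(raw)
  kept <- ex$participants

  avg <- average_assessments(ex$diet)
  phd <- compute_phd(avg)
  phd$n_assessments <- avg$n_assessments
  if (!is.null(avg$last_recall_date))
    phd$last_recall_date <- avg$last_recall_date
  phd$energy <- avg$energy
  kept$energy <- avg$energy[match(kept$id, avg$id)]

  cprs_df <- NULL
  if (with_genotypes) {
    geno <- generate_genotypes(config)
    dos <- geno$dosages[kept$id, , drop = FALSE]
    prs <- compute_site_prs(dos, geno$weights)
    z <- standardize_site_prs(prs, kept$sex)
    cprs_val <- compute_cprs(z, geno$incidence,
                             as.character(kept$sex))
    grp <- assign_risk_groups(cprs_val, kept$sex)
    cprs_df <- data.frame(id = kept$id, cprs = cprs_val,
                          cprs_group = grp)
  }

  entry <- kept[, c("id", "entry_date")]
  outcomes0 <- data.frame(id = kept$id, follow_up_years = 0, event = 0L,
                          entry_date = kept$entry_date,
                          exit_date = kept$entry_date)
  d <- build_analysis_dataset(kept, phd, cprs_df, outcomes0,
                              model = "model2")
  eta <- true_linear_predictor(d, config)

  h0 <- config$baseline_hazard
  if (is.null(h0)) {
    admin <- as.numeric(config$censor_date - d$entry_date) / 365.25
    h0 <- calibrate_baseline_hazard(config$target_incidence, eta, admin)
  }
  out <- simulate_survival(entry, eta, config, baseline_hazard = h0)
  d$follow_up_years <- out$follow_up_years
  d$event <- out$event
  d$exit_date <- out$exit_date

  list(data = d, audit = ex$audit, baseline_hazard = h0, eta = eta,
       config = config)
}
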