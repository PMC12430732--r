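#' Exclusion cascade with audit trail
#'
#' Applies the study exclusion rules strictly in flowchart order with
#' sequential (first-match) attribution: a participant failing several
#' rules is counted under the first one. Rules, in order:
#'
#' 1. cancer at baseline;
#' 2. did not complete any dietary questionnaire (0 assessments);
#' 3. not of white European ancestry;
#' 4. missing data for constructing the polygenic risk score;
#' 5. withdrawn or lost to follow-up;
#' 6. implausible energy intake (men: <800 or >4000 kcal/day; women:
#'    <500 or >3500 kcal/day), judged on the mean energy across
#'    assessments.
#'
#' Because attribution is sequential but retention is a set difference,
#' permuting the rule order changes the per-step audit counts but never
#' the surviving cohort.
#'
#' @param cohort A raw cohort list as from [generate_cohort()] or
#'   [build_flowchart_fixture()]: `$participants` must carry `id`, `sex`,
#'   `baseline_cancer`, `european`, `has_prs`, `lost_followup`, and
#'   either `n_assessments`+`mean_energy` columns or a `$diet` table
#'   from which both are derived.
#' @param rule_order Optional permutation of the rule names (audit
#'   attribution only; the surviving set is order-invariant).
#' @return List with `participants` (the retained rows), `diet` (their
#'   assessments, when present) and `audit`, a data frame with one row
#'   per rule: `rule`, `entering`, `removed`, `remaining`.
#' @export
apply_exclusions <- function(cohort, rule_order = NULL) {
  p <- cohort$participants
  needed <- c("id", "sex", "baseline_cancer", "european", "has_prs",
              "lost_followup")
  missing_cols <- setdiff(needed, names(p))
  if (length(missing_cols))
    stop("participants table lacks field(s): ",
         paste(missing_cols, collapse = ", "))

  if (is.null(p$n_assessments) || is.null(p$mean_energy)) {
    if (is.null(cohort$diet))
      stop("participants table lacks field(s): n_assessments, mean_energy ",
           "(and no diet table to derive them from)")
    tab <- table(factor(cohort$diet$id, levels = p$id))
    p$n_assessments <- as.integer(tab)
    me <- tapply(cohort$diet$energy, factor(cohort$diet$id, levels = p$id),
                 mean)
    p$mean_energy <- as.numeric(me)
  }

  implausible <- ifelse(p$sex == "male",
                        p$mean_energy < 800 | p$mean_energy > 4000,
                        p$mean_energy < 500 | p$mean_energy > 3500)
  implausible[is.na(implausible)] <- FALSE   # no assessments: caught earlier

  rules <- list(
    baseline_cancer = p$baseline_cancer,
    no_dietary_questionnaire = p$n_assessments == 0,
    non_european_ancestry = !p$european,
    missing_prs_data = !p$has_prs,
    lost_to_followup = p$lost_followup,
    implausible_energy = implausible
  )
  if (!is.null(rule_order)) {
    if (!setequal(rule_order, names(rules)))
      stop("rule_order must be a permutation of the rule names")
    rules <- rules[rule_order]
  }

  alive <- rep(TRUE, nrow(p))
  audit <- data.frame(rule = names(rules), entering = NA_integer_,
                      removed = NA_integer_, remaining = NA_integer_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(rules)) {
    entering <- sum(alive)
    hit <- alive & rules[[i]]
    alive <- alive & !rules[[i]]
    audit$entering[i] <- entering
    audit$removed[i] <- sum(hit)
    audit$remaining[i] <- sum(alive)
  }

  kept <- p[alive, , drop = FALSE]
  rownames(kept) <- NULL
  out <- list(participants = kept, audit = audit)
  if (!is.null(cohort$diet))
    out$diet <- cohort$diet[cohort$diet$id %in% kept$id, , drop = FALSE]
  out
}

#' Quintile assignment with ties to the lower group
#'
#' Empirical 20/40/60/80 percentile cut points (type-7 quantiles),
#' boundary values assigned to the lower quintile, optionally computed
#' within strata. Labels run Q1 (lowest) to Q5.
#'
#' @param values Numeric vector.
#' @param strata Optional stratification vector (e.g. sex); cut points
#'   are computed within each stratum.
#' @return Factor Q1..Q5 with the cut points attached as attribute
#'   `"cutpoints"` (a list when stratified).
#' @export
assign_quintiles <- function(values, strata = NULL) {
  one <- function(x) {
    if (length(unique(x)) < 5)
      stop("need at least 5 distinct values to form quintiles")
    cuts <- stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7,
                            names = FALSE)
    idx <- findInterval(x, cuts, left.open = TRUE) + 1L
    list(q = idx, cuts = cuts)
  }
  if (is.null(strata)) {
    r <- one(values)
    out <- factor(paste0("Q", r$q), levels = paste0("Q", 1:5))
    attr(out, "cutpoints") <- r$cuts
    return(out)
  }
  idx <- integer(length(values))
  cuts <- list()
  for (s in unique(strata)) {
    rows <- which(strata == s)
    r <- one(values[rows])
    idx[rows] <- r$q
    cuts[[as.character(s)]] <- r$cuts
  }
  out <- factor(paste0("Q", idx), levels = paste0("Q", 1:5))
  attr(out, "cutpoints") <- cuts
  out
}

#' Standardise a continuous exposure to z-scores
#'
#' Centres and scales by the sample standard deviation (n-1
#' denominator), the "per 1-SD" exposure used for continuous hazard
#' ratios.
#'
#' @param values Numeric vector with at least 2 values and nonzero
#'   variance.
#' @return Numeric z-scores with the SD used attached as attribute
#'   `"sd"` and the mean as `"mean"`.
#' @export
standardize_exposure <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: cannot standardise")
  out <- (values - mean(values)) / s
  attr(out, "sd") <- s
  attr(out, "mean") <- mean(values)
  out
}

#' Covariate sets of the three adjustment models
#'
#' `crude` has no covariates; `model1` adjusts for age, sex, BMI, total
#' energy intake and the first ten genetic principal components;
#' `model2` additionally adjusts for income, education, Townsend
#' deprivation index, alcohol status, smoking status and family history
#' of cancer.
#'
#' @param model `"crude"`, `"model1"` or `"model2"`.
#' @param sex_stratified Drop the sex covariate (for single-sex fits).
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model = c("crude", "model1", "model2"),
                             sex_stratified = FALSE) {
  model <- match.arg(model)
  if (model == "crude") return(character(0))
  m1 <- c("age", "bmi", "energy", paste0("pc", 1:10))
  if (!sex_stratified) m1 <- c("sex", m1)
  if (model == "model1") return(m1)
  c(m1, "income", "education", "townsend", "alcohol", "smoking",
    "family_history")
}

#' Assemble the analysis dataset
#'
#' Joins the filtered cohort, PHD scores, CPRS results and survival
#' outcomes by participant id and derives the analysis variables:
#' pooled PHD quintiles, the per-SD PHD z-score, and (for single-sex or
#' stratified use) the genetic-risk grouping. Categorical covariates keep
#' their explicit `"unknown"` level; they are dummy-encoded at model
#' time, not here.
#'
#' @param participants Filtered participant table (from
#'   [apply_exclusions()]).
#' @param phd PHD results with `id` and `phd_total` (from
#'   [compute_phd()]); may also carry `n_assessments` and
#'   `last_recall_date`.
#' @param cprs Data frame with `id`, `cprs`, `cprs_group`, or `NULL`.
#' @param outcomes Data frame with `id`, `follow_up_years`, `event` and
#'   optionally `entry_date`, `exit_date`.
#' @param model Adjustment model whose covariates must be present:
#'   `"crude"`, `"model1"` or `"model2"`.
#' @param quintile_strata Optional stratification vector name (e.g.
#'   `"sex"`) for the PHD quintiles; default pooled.
#' @return Data frame with class `"analysis_dataset"`; the covariate set
#'   is recorded in attribute `"model"`.
#' @export
build_analysis_dataset <- function(participants, phd, cprs = NULL,
                                   outcomes, model = "model2",
                                   quintile_strata = NULL) {
  model <- match.arg(model, c("crude", "model1", "model2"))
  ids <- participants$id
  chk_join <- function(tab, what) {
    unmatched <- sum(!(ids %in% tab$id))
    if (unmatched > 0)
      stop(unmatched, " participant id(s) unmatched in ", what,
           " (", round(100 * unmatched / length(ids), 1), "% of cohort)")
    tab[match(ids, tab$id), , drop = FALSE]
  }
  phd <- chk_join(phd, "PHD results")
  outcomes <- chk_join(outcomes, "outcomes")

  d <- participants
  d$phd_total <- phd$phd_total
  if (!is.null(phd$n_assessments)) d$n_assessments <- phd$n_assessments
  if (!is.null(phd$last_recall_date))
    d$last_recall_date <- phd$last_recall_date
  z <- standardize_exposure(d$phd_total)
  d$phd_z <- as.numeric(z)
  strata <- if (is.null(quintile_strata)) NULL else d[[quintile_strata]]
  d$phd_q <- assign_quintiles(d$phd_total, strata = strata)

  if (!is.null(cprs)) {
    cprs <- chk_join(cprs, "CPRS results")
    d$cprs <- cprs$cprs
    d$cprs_group <- cprs$cprs_group
  }
  d$follow_up_years <- outcomes$follow_up_years
  d$event <- outcomes$event
  if (!is.null(outcomes$entry_date)) d$entry_date <- outcomes$entry_date
  if (!is.null(outcomes$exit_date)) d$exit_date <- outcomes$exit_date

  covs <- model_covariates(model)
  missing_cols <- setdiff(covs, names(d))
  if (length(missing_cols))
    stop("covariate(s) required by ", model, " missing: ",
         paste(missing_cols, collapse = ", "))
  attr(d, "model") <- model
  class(d) <- c("analysis_dataset", "data.frame")
  d
}
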