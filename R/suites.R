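# Shared report-row constructor so every suite emits the same columns.
report_row <- function(suite, stratum, term, n = NA, events = NA,
                       hr = NA, ci_low = NA, ci_high = NA, p = NA,
                       p_trend = NA, p_nonlinearity = NA,
                       ph_global_p = NA) {
  data.frame(suite = suite, stratum = stratum, term = term,
             n = n, events = events, hr = hr, ci_low = ci_low,
             ci_high = ci_high, p = p, p_trend = p_trend,
             p_nonlinearity = p_nonlinearity,
             ph_global_p = ph_global_p, stringsAsFactors = FALSE)
}

subset_sex <- function(data, sex = c("all", "men", "women")) {
  sex <- match.arg(sex)
  if (sex == "all") return(data)
  data[data$sex == if (sex == "men") "male" else "female", ,
       drop = FALSE]
}

# Drop covariates with a single observed level (e.g. sex in a stratified
# run, or an "unknown" level absent from a subgroup).
usable_covariates <- function(data, covs) {
  keep <- vapply(covs, function(v) {
    x <- data[[v]]
    if (is.factor(x)) length(unique(as.character(x))) > 1
    else stats::sd(x) > 0
  }, logical(1))
  covs[keep]
}

# Binary dummy columns whose carriers (or non-carriers) have no events
# give an infinite coefficient MLE; such columns are merged into the
# reference level by dropping them from the design.
drop_eventless_columns <- function(Z, event) {
  if (ncol(Z) == 0) return(Z)
  keep <- vapply(seq_len(ncol(Z)), function(j) {
    col <- Z[, j]
    u <- unique(col)
    if (length(u) < 2) return(FALSE)
    if (length(u) == 2 && all(u %in% c(0, 1)))
      return(sum(event[col == 1]) > 0 && sum(event[col == 0]) > 0)
    TRUE
  }, logical(1))
  Z[, keep, drop = FALSE]
}

fit_exposure_model <- function(data, exposure_design, covs) {
  Z <- drop_eventless_columns(design_from_columns(data, covs),
                              data$event)
  cox_fit_engine(data$follow_up_years, data$event,
                 cbind(exposure_design, Z))
}

wald_rows <- function(fit, terms, suite, stratum, n_by = NULL,
                      ev_by = NULL) {
  co <- fit$coefficients[terms]
  se <- fit$se[terms]
  p <- 2 * stats::pnorm(-abs(co / se))
  report_row(suite, stratum, terms,
             n = if (is.null(n_by)) fit$n else n_by,
             events = if (is.null(ev_by)) fit$nevent else ev_by,
             hr = exp(co), ci_low = exp(co - 1.96 * se),
             ci_high = exp(co + 1.96 * se), p = p)
}

#' Main PHD-cancer analysis suite
#'
#' Reproduces the primary analysis layout: quintile contrasts of the
#' PHD score (Q1 reference, HR fixed at 1), the per-SD continuous
#' contrast with its trend test across quintiles, the restricted cubic
#' spline nonlinearity p-value, and the global Schoenfeld
#' proportional-hazards p-value, for the whole cohort or one sex (the
#' sex covariate is dropped in sex-stratified runs).
#'
#' @param data An analysis dataset (see [build_analysis_dataset()] or
#'   [simulate_study()]).
#' @param sex `"all"`, `"men"` or `"women"`.
#' @param model `"crude"`, `"model1"` or `"model2"`.
#' @param n_knots Knots for the spline dose-response.
#' @return Report data frame: columns `suite`, `stratum`, `term`, `n`,
#'   `events`, `hr`, `ci_low`, `ci_high`, `p`, `p_trend`,
#'   `p_nonlinearity`, `ph_global_p`.
#' @export
run_main_suite <- function(data, sex = "all", model = "model2",
                           n_knots = 4) {
  d <- subset_sex(data, sex)
  covs <- usable_covariates(d, model_covariates(model, sex != "all"))

  # quintile contrasts
  Q <- design_from_columns(d, "phd_q")
  qfit <- fit_exposure_model(d, Q, covs)
  ntab <- table(d$phd_q)
  etab <- tapply(d$event, d$phd_q, sum)
  tt <- trend_test(d, "phd_q", covs)
  rows <- report_row("main", sex, "phd_qQ1", n = ntab[["Q1"]],
                     events = etab[["Q1"]], hr = 1, ci_low = 1,
                     ci_high = 1)
  qterms <- colnames(Q)
  qlabs <- sub("phd_q", "", qterms)
  qr <- wald_rows(qfit, qterms, "main", sex,
                  n_by = as.integer(ntab[qlabs]),
                  ev_by = as.numeric(etab[qlabs]))
  qr$p_trend <- tt$p_trend
  rows <- rbind(rows, qr)

  # per-SD contrast + diagnostics on the continuous model
  zfit <- fit_exposure_model(d, cbind(phd_z = d$phd_z), covs)
  zr <- wald_rows(zfit, "phd_z", "main", sex)
  rc <- rcs_dose_response(d, "phd_total", covs, n_knots = n_knots)
  zr$p_nonlinearity <- rc$p_nonlinearity
  zr$ph_global_p <- tryCatch(cox_zph(zfit)$table["GLOBAL", "p"],
                             error = function(e) NA_real_)
  rbind(rows, zr)
}

#' Joint PHD-quintile by genetic-risk-group suite
#'
#' Classifies participants into the 15 joint groups (PHD quintiles Q1-Q5
#' by CPRS low/intermediate/high), with PHD quintiles recomputed within
#' sex for sex-stratified runs, and fits one dummy per non-reference
#' group against the (Q1 PHD, high CPRS) reference. Empty joint cells
#' are reported as NA rows and excluded from the fit.
#'
#' @inheritParams run_main_suite
#' @return Report data frame with 15 rows (the reference row carries
#'   HR = 1 exactly) plus the model columns.
#' @export
run_joint_suite <- function(data, sex = "all", model = "model2") {
  d <- subset_sex(data, sex)
  if (is.null(d$cprs_group))
    stop("dataset has no cprs_group column; joint analysis needs both ",
         "groupings")
  covs <- usable_covariates(d, model_covariates(model, sex != "all"))
  strata <- if (sex == "all") d$sex else NULL
  qq <- assign_quintiles(d$phd_total, strata = strata)
  lab <- joint_group_label(qq, d$cprs_group)
  levels_all <- as.vector(outer(paste0("Q", 1:5),
                                c("high", "intermediate", "low"),
                                function(q, g) paste0(q, ".", g)))
  grp <- factor(lab, levels = levels_all)   # reference: Q1.high
  counts <- table(grp)
  events <- tapply(d$event, grp, sum)

  present <- names(counts)[counts > 0]
  grp2 <- factor(as.character(grp), levels = present)
  D <- design_from_columns(data.frame(joint = grp2), "joint")
  fit <- fit_exposure_model(d, D, covs)

  rows <- report_row("joint", sex, "Q1.high",
                     n = as.integer(counts[["Q1.high"]]),
                     events = as.numeric(events[["Q1.high"]]),
                     hr = 1, ci_low = 1, ci_high = 1)
  for (g in setdiff(levels_all, "Q1.high")) {
    if (counts[[g]] == 0) {
      rows <- rbind(rows, report_row("joint", sex, g, n = 0, events = 0))
      next
    }
    term <- paste0("joint", g)
    r <- wald_rows(fit, term, "joint", sex,
                   n_by = as.integer(counts[[g]]),
                   ev_by = as.numeric(events[[g]]))
    r$term <- g
    rows <- rbind(rows, r)
  }
  rows
}

subgroup_bins <- function(data, stratifier) {
  switch(stratifier,
         bmi = cut(data$bmi, c(-Inf, 24 - 1e-9, 28, Inf),
                   labels = c("<24", "24-28", ">28")),
         age = factor(ifelse(data$age < 60, "<60", ">=60"),
                      levels = c("<60", ">=60")),
         smoking = factor(as.character(data$smoking),
                          levels = c("never", "previous", "current")),
         alcohol = factor(as.character(data$alcohol),
                          levels = c("never", "previous", "current")),
         stop("unknown stratifier: ", stratifier))
}

#' Subgroup analysis suite
#'
#' Refits the per-SD PHD model within strata of BMI (<24, 24-28, >28,
#' boundaries in the middle bin), age (<60, >=60), smoking status and
#' alcohol status; the stratifier is removed from the covariate set
#' inside its own strata. Strata with no events yield NA rows.
#'
#' @inheritParams run_main_suite
#' @param stratifiers Subset of `c("bmi", "age", "smoking", "alcohol")`.
#' @return Report data frame, one per-SD row per stratum.
#' @export
run_subgroup_suite <- function(data, sex = "all", model = "model2",
                               stratifiers = c("bmi", "age", "smoking",
                                               "alcohol")) {
  d <- subset_sex(data, sex)
  covs_all <- model_covariates(model, sex != "all")
  rows <- NULL
  for (s in stratifiers) {
    bins <- subgroup_bins(d, s)
    covs <- setdiff(covs_all, s)
    for (lv in levels(bins)) {
      di <- d[!is.na(bins) & bins == lv, , drop = FALSE]
      label <- paste0(s, "=", lv)
      if (nrow(di) == 0 || sum(di$event) == 0) {
        rows <- rbind(rows, report_row("subgroup", label, "phd_z",
                                       n = nrow(di),
                                       events = sum(di$event)))
        next
      }
      fit <- fit_exposure_model(di, cbind(phd_z = di$phd_z),
                                usable_covariates(di, covs))
      rows <- rbind(rows, wald_rows(fit, "phd_z", "subgroup", label))
    }
  }
  rows
}

#' Sensitivity analysis suite
#'
#' Three per-SD refits probing the robustness of the main association:
#' (a) a 2-year washout excluding participants whose cancer was
#' diagnosed within 2 years of their last dietary recall (guards against
#' reverse causation); (b) restriction to participants with at least 2
#' completed assessments; (c) a pluggable alternative scoring rule set -
#' when `rules` and the per-participant averaged intakes (`intakes`) are
#' supplied the PHD score is recomputed and re-standardised, otherwise
#' the default-rule analysis is re-run unchanged.
#'
#' @inheritParams run_main_suite
#' @param rules Optional alternative scoring-rule table (see
#'   [phd_rules()]).
#' @param intakes Optional averaged-intake table (output of
#'   [average_assessments()]) needed to apply `rules`.
#' @return Report data frame, one per-SD row per sensitivity analysis.
#' @export
run_sensitivity_suite <- function(data, sex = "all", model = "model2",
                                  rules = NULL, intakes = NULL) {
  d <- subset_sex(data, sex)
  one <- function(di, label) {
    covs <- usable_covariates(di, model_covariates(model, sex != "all"))
    z <- standardize_exposure(di$phd_total)
    fit <- fit_exposure_model(di, cbind(phd_z = as.numeric(z)), covs)
    wald_rows(fit, "phd_z", "sensitivity", label)
  }

  if (is.null(d$last_recall_date) || is.null(d$exit_date))
    stop("washout analysis needs last_recall_date and exit_date columns")
  washed_out <- d$event == 1 &
    as.numeric(d$exit_date - d$last_recall_date) / 365.25 < 2
  rows <- one(d[!washed_out, , drop = FALSE], "washout_2y")

  if (is.null(d$n_assessments))
    stop("repeat-assessment filter needs an n_assessments column")
  rows <- rbind(rows, one(d[d$n_assessments >= 2, , drop = FALSE],
                          "min_2_assessments"))

  if (!is.null(rules)) {
    if (is.null(intakes))
      stop("alternative scoring needs the averaged intake table")
    rescored <- compute_phd(intakes, rules = rules)
    d2 <- d
    d2$phd_total <- rescored$phd_total[match(d2$id, rescored$id)]
    rows <- rbind(rows, one(d2, "alternative_rules"))
  } else {
    rows <- rbind(rows, one(d, "default_rules_rerun"))
  }
  rows
}
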