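#' The 14 planetary health diet components and their scoring rules
#'
#' Default scoring-rule table for the planetary health diet (PHD) score.
#' Each of the 14 components belongs to one of three rule classes:
#'
#' * `adequacy` - linearly rewarded intake: 10 * min(1, intake / T),
#'   full marks at or above the recommended amount T;
#' * `balanced` - tent-shaped reward peaking at the target T:
#'   10 * max(0, 1 - |intake - T| / T), so 50% or 150% of the target
#'   earns half marks and 0 or 2T earns none;
#' * `moderation` - linearly penalised intake: 10 * max(0, 1 - intake/L),
#'   full marks at zero intake, none at or above the limit L.
#'
#' Reference amounts are g/day at a 2500 kcal/day reference energy and
#' follow the EAT-Lancet 2500-kcal reference diet; every value can be
#' overridden by supplying a modified table to [compute_phd()].
#'
#' @return Data frame with columns `component`, `rule_class`,
#'   `reference_amount`.
#' @examples
#' phd_rules()
#' @export
phd_rules <- function() {
  data.frame(
    component = c("vegetables", "fruits", "nuts", "fish", "legumes",
                  "unsaturated_fats", "whole_grains", "dairy", "eggs",
                  "potatoes", "poultry", "saturated_fats", "red_meat",
                  "added_sugars"),
    rule_class = c(rep("adequacy", 6), rep("balanced", 5),
                   rep("moderation", 3)),
    reference_amount = c(300, 200, 50, 28, 75, 40,
                         232, 250, 13, 50, 29,
                         11.8, 14, 31),
    stringsAsFactors = FALSE
  )
}

#' Names of the 14 PHD dietary components
#' @return Character vector of length 14.
#' @export
phd_components <- function() phd_rules()$component

#' Average dietary assessments within participant
#'
#' For participants with several 24-hour dietary assessments, the intake
#' of each component (and total energy) is the arithmetic mean across all
#' assessments.
#'
#' @param diet Data frame with one row per assessment: `id`, the 14
#'   component columns (g/day), `energy` (kcal/day), and optionally
#'   `recall_date`.
#' @return Data frame with one row per participant: `id`,
#'   `n_assessments`, mean component intakes, mean `energy`, and
#'   `last_recall_date` when recall dates are present.
#' @export
average_assessments <- function(diet) {
  if (nrow(diet) == 0) stop("no dietary assessments supplied")
  comps <- phd_components()
  missing_cols <- setdiff(c("id", comps, "energy"), names(diet))
  if (length(missing_cols))
    stop("missing assessment column(s): ",
         paste(missing_cols, collapse = ", "))
  ids <- diet$id
  grp <- factor(ids, levels = unique(ids))
  n <- as.integer(table(grp))
  M <- rowsum(as.matrix(diet[, c(comps, "energy")]), grp, reorder = FALSE)
  M <- M / n
  out <- data.frame(id = levels(grp), n_assessments = n,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(M))
  if (!is.null(diet$recall_date)) {
    last <- tapply(as.numeric(diet$recall_date), grp, max)
    out$last_recall_date <- as.Date(as.numeric(last),
                                    origin = "1970-01-01")
  }
  rownames(out) <- NULL
  # ids may be numeric in the input; preserve their type
  if (is.numeric(diet$id)) out$id <- as.numeric(out$id)
  out
}

#' Normalise an intake to the 2500 kcal/day reference energy
#'
#' @param intake Intake in g/day (>= 0).
#' @param energy Total energy intake in kcal/day (> 0).
#' @return Energy-adjusted intake: `intake * 2500 / energy`.
#' @examples
#' energy_adjust(100, 1250)  # 200 g at the reference energy
#' @export
energy_adjust <- function(intake, energy) {
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("energy must be positive")
  if (any(intake < 0, na.rm = TRUE)) stop("intakes must be nonnegative")
  intake * 2500 / energy
}

#' Score one dietary component
#'
#' Applies the scoring rule for one component class to an
#' energy-adjusted intake; see [phd_rules()] for the three rules.
#' Vectorised over `adjusted_intake`.
#'
#' @param adjusted_intake Intake in g/day at 2500 kcal (>= 0).
#' @param rule_class One of `"adequacy"`, `"balanced"`, `"moderation"`.
#' @param reference_amount The rule's reference amount T (or limit L).
#' @return Score(s) in \[0, 10\].
#' @examples
#' score_component(150, "adequacy", 300)    # 5
#' score_component(348, "balanced", 232)    # 5 (150% of target)
#' score_component(0, "moderation", 14)     # 10
#' @export
score_component <- function(adjusted_intake, rule_class, reference_amount) {
  if (any(adjusted_intake < 0, na.rm = TRUE))
    stop("adjusted intakes must be nonnegative")
  if (reference_amount <= 0) stop("reference amount must be positive")
  switch(rule_class,
         adequacy = 10 * pmin(1, adjusted_intake / reference_amount),
         moderation = 10 * pmax(0, 1 - adjusted_intake / reference_amount),
         balanced = 10 * pmax(0, 1 - abs(adjusted_intake - reference_amount) /
                                reference_amount),
         stop("unknown rule class: ", rule_class))
}

#' Compute the planetary health diet score
#'
#' Energy-adjusts each of the 14 component intakes to 2500 kcal/day,
#' scores each component on its 0-10 rule, and sums to the 0-140 total.
#' Vectorised over participants (rows).
#'
#' @param assessment Data frame (or single-row list) with the 14
#'   component columns in g/day and `energy` in kcal/day; typically the
#'   output of [average_assessments()].
#' @param rules Scoring-rule table as from [phd_rules()]; reference
#'   amounts may be overridden.
#' @return Data frame with `id` (if present in the input), one
#'   `score_<component>` column per component, and `phd_total`.
#' @export
compute_phd <- function(assessment, rules = phd_rules()) {
  assessment <- as.data.frame(assessment)
  missing_cols <- setdiff(rules$component, names(assessment))
  if (length(missing_cols))
    stop("missing component intake(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(assessment$energy)) stop("missing component intake(s): energy")
  n <- nrow(assessment)
  scores <- matrix(NA_real_, n, nrow(rules),
                   dimnames = list(NULL, paste0("score_", rules$component)))
  for (j in seq_len(nrow(rules))) {
    adj <- energy_adjust(assessment[[rules$component[j]]],
                         assessment$energy)
    scores[, j] <- score_component(adj, rules$rule_class[j],
                                   rules$reference_amount[j])
  }
  # left-to-right accumulation so the total is bit-identical to summing
  # independently scored components
  total <- scores[, 1]
  for (j in 2:ncol(scores)) total <- total + scores[, j]
  out <- cbind(as.data.frame(scores), data.frame(phd_total = total))
  if (!is.null(assessment$id)) out <- cbind(id = assessment$id, out)
  out
}
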