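#' Per-site additive polygenic risk scores
#'
#' For each cancer site k, the polygenic risk score of participant i is
#' the weighted allele count `PRS_ik = sum_j dosage_ij * beta_jk` over
#' the variants assigned to that site: each risk-allele dosage multiplied
#' by its per-variant effect size and summed.
#'
#' @param dosages Numeric matrix, participants x variants, entries in
#'   \[0, 2\]; column names are variant ids.
#' @param weights Data frame with columns `variant_id`, `beta`, `site`
#'   (and optionally `effect_allele`). Every `(variant, site)` pair must
#'   be unique.
#' @param sites Sites to score; default all sites in `weights`.
#' @return Numeric matrix, participants x sites, of raw PRS values.
#' @export
compute_site_prs <- function(dosages, weights, sites = NULL) {
  if (is.null(colnames(dosages)))
    stop("dosage matrix must carry variant ids as column names")
  if (anyDuplicated(weights[, c("variant_id", "site")]))
    stop("duplicated (variant, site) pair in the weight table")
  missing_v <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing_v))
    stop("variant(s) absent from the dosage matrix: ",
         paste(missing_v, collapse = ", "))
  if (anyNA(dosages))
    stop("dosage matrix contains missing entries; no silent imputation")
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(sites)) sites <- unique(weights$site)

  # sparse site-indicator weight matrix: variants x sites
  W <- matrix(0, ncol(dosages), length(sites),
              dimnames = list(colnames(dosages), sites))
  w <- weights[weights$site %in% sites, ]
  W[cbind(match(w$variant_id, colnames(dosages)),
          match(w$site, sites))] <- w$beta
  prs <- dosages %*% W
  rownames(prs) <- rownames(dosages)
  prs
}

#' Standardise site PRS within sex strata
#'
#' z-transforms each site's raw PRS to mean 0, sample SD 1 within each
#' sex stratum, making sites comparable before incidence weighting.
#'
#' @param prs Participants x sites matrix of raw PRS values.
#' @param sex Per-participant sex vector (any two-or-more level coding).
#' @return Matrix of the same shape with standardised values.
#' @export
standardize_site_prs <- function(prs, sex) {
  prs <- as.matrix(prs)
  if (length(sex) != nrow(prs))
    stop("sex must have one entry per participant")
  out <- prs
  for (s in unique(sex)) {
    rows <- which(sex == s)
    if (length(rows) < 2)
      stop("need at least 2 participants per sex stratum")
    block <- prs[rows, , drop = FALSE]
    sds <- apply(block, 2, stats::sd)
    if (any(sds == 0))
      stop("zero variance for site(s) ",
           paste(colnames(prs)[sds == 0], collapse = ", "),
           " within a sex stratum")
    out[rows, ] <- scale(block)
  }
  out
}

#' Incidence-weighted composite cancer polygenic risk score
#'
#' Combines standardised site PRS into a single composite,
#' `CPRS_i = sum_k h_k * PRS_ik`, where h_k is the age-standardised
#' incidence of cancer site k (cases per 100 000 person-years) in the
#' participant's sex. Sites are restricted to the participant's
#' sex-specific site list (sites with `sex = "both"` apply to everyone).
#'
#' @param site_prs Participants x sites matrix (standardised values).
#' @param incidence Data frame with columns `site`, `sex` (`"male"`,
#'   `"female"` or `"both"`), `rate` (>= 0, per 100 000 person-years).
#' @param sex Per-participant sex, `"male"` / `"female"`.
#' @return Numeric vector of CPRS values.
#' @export
compute_cprs <- function(site_prs, incidence, sex) {
  site_prs <- as.matrix(site_prs)
  if (length(sex) != nrow(site_prs))
    stop("sex must have one entry per participant")
  if (any(incidence$rate < 0)) stop("incidence rates must be nonnegative")
  cprs <- numeric(nrow(site_prs))
  for (s in c("male", "female")) {
    rows <- which(sex == s)
    if (!length(rows)) next
    inc_s <- incidence[incidence$sex %in% c(s, "both"), ]
    if (!any(inc_s$rate > 0))
      stop("no positive incidence weight for sex '", s, "'")
    missing_s <- setdiff(inc_s$site, colnames(site_prs))
    if (length(missing_s))
      stop("site(s) in the incidence table without PRS values: ",
           paste(missing_s, collapse = ", "))
    h <- inc_s$rate
    cprs[rows] <- drop(site_prs[rows, inc_s$site, drop = FALSE] %*% h)
  }
  cprs
}

#' Assign genetic risk groups from CPRS quintiles
#'
#' Participants are grouped within sex by CPRS quintile: low risk
#' (lowest quintile), intermediate risk (quintiles 2-4), high risk
#' (highest quintile). Boundary ties go to the lower group.
#'
#' @param cprs Numeric CPRS vector.
#' @param sex Per-participant sex stratum (a single-level vector is a
#'   single stratum).
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
assign_risk_groups <- function(cprs, sex = rep("all", length(cprs))) {
  out <- factor(rep(NA_character_, length(cprs)),
                levels = c("low", "intermediate", "high"))
  for (s in unique(sex)) {
    rows <- which(sex == s)
    q <- assign_quintiles(cprs[rows])
    qi <- as.integer(q)
    out[rows[qi == 1]] <- "low"
    out[rows[qi %in% 2:4]] <- "intermediate"
    out[rows[qi == 5]] <- "high"
  }
  out
}

#' Default incidence-weight table for a synthetic site panel
#'
#' An editable config table of age-standardised incidence rates (cases
#' per 100 000 person-years) for a panel of cancer sites. The rates are
#' synthetic defaults spanning the range of common-cancer incidence;
#' the first two sites are sex-specific (breast-like, prostate-like) so
#' sex-restricted site lists are exercised.
#'
#' @param sites Character vector of site names.
#' @return Data frame with columns `site`, `sex`, `rate`.
#' @export
default_incidence_weights <- function(sites) {
  n <- length(sites)
  rate <- round(seq(170, 10, length.out = n), 1)
  sex <- rep("both", n)
  if (n >= 1) sex[1] <- "female"
  if (n >= 2) sex[2] <- "male"
  data.frame(site = sites, sex = sex, rate = rate,
             stringsAsFactors = FALSE)
}
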