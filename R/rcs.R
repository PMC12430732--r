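#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power
#' parameterisation: a linear column plus k-2 nonlinear columns that are
#' exactly linear (in fact constant-slope) beyond the boundary knots.
#'
#' @param x Numeric vector.
#' @param knots Increasing knot locations (k of them, k >= 3).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  if (k < 3) stop("at least 3 knots are required")
  if (anyDuplicated(knots)) stop("knots must be distinct")
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  sc <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(x, ncol = 1)
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B <- cbind(B, (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / sc)
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2)))
  B
}

# Harrell's default knot quantiles by knot count.
rcs_knot_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         seq(0.05, 0.95, length.out = n_knots))
}

#' Restricted cubic spline dose-response for a Cox model
#'
#' Fits the exposure through a restricted cubic spline (default 4 knots
#' at the 5/35/65/95 percentiles) alongside any adjustment covariates,
#' tests for nonlinearity by a likelihood-ratio test of the nonlinear
#' spline terms against the linear-exposure model, and returns the
#' predicted log hazard ratio curve (zero at the reference exposure,
#' default the median) with pointwise Wald confidence bands.
#'
#' @param data Data frame with follow-up, event and exposure columns.
#' @param exposure Name of the continuous exposure column.
#' @param covariates Character vector of adjustment column names (may be
#'   empty); factors are dummy-encoded.
#' @param time_col,event_col Names of the follow-up time and event
#'   indicator columns.
#' @param n_knots Number of knots (>= 3).
#' @param ref Reference exposure value; default the median.
#' @param grid_length Number of curve evaluation points.
#' @return An object of class `"rcs_fit"`: knots, spline coefficient
#'   estimates, `p_nonlinearity` (LRT with `n_knots - 2` df), and a
#'   `curve` data frame (exposure, log_hr, hr, ci_low, ci_high).
#' @export
rcs_dose_response <- function(data, exposure, covariates = character(),
                              time_col = "follow_up_years",
                              event_col = "event",
                              n_knots = 4, ref = NULL, grid_length = 100) {
  x <- data[[exposure]]
  if (is.null(x)) stop("exposure column '", exposure, "' not found")
  qs <- rcs_knot_quantiles(n_knots)
  knots <- unname(stats::quantile(x, qs, type = 7))
  if (anyDuplicated(knots))
    stop("coincident knots: exposure has too few distinct values")
  if (length(unique(x)) < n_knots)
    stop("exposure must have at least n_knots distinct values")
  if (is.null(ref)) ref <- stats::median(x)

  B <- rcs_basis(x, knots)
  colnames(B) <- paste0(exposure, "_", colnames(B))
  tm <- data[[time_col]]
  ev <- data[[event_col]]
  Z <- drop_eventless_columns(design_from_columns(data, covariates), ev)

  full <- cox_fit_engine(tm, ev, cbind(B, Z))
  lin <- cox_fit_engine(tm, ev, cbind(B[, 1, drop = FALSE], Z))
  lrt <- 2 * (full$loglik["final"] - lin$loglik["final"])
  df <- n_knots - 2
  p_nl <- stats::pchisq(lrt, df, lower.tail = FALSE)

  grid <- seq(min(x), max(x), length.out = grid_length)
  D <- rcs_basis(grid, knots) -
    matrix(rcs_basis(ref, knots), nrow = grid_length,
           ncol = n_knots - 1, byrow = TRUE)
  bs <- full$coefficients[seq_len(n_knots - 1)]
  Vs <- full$var[seq_len(n_knots - 1), seq_len(n_knots - 1)]
  log_hr <- drop(D %*% bs)
  se <- sqrt(rowSums((D %*% Vs) * D))
  curve <- data.frame(exposure = grid, log_hr = log_hr, hr = exp(log_hr),
                      ci_low = exp(log_hr - 1.96 * se),
                      ci_high = exp(log_hr + 1.96 * se))
  out <- list(knots = knots, ref = ref, coefficients = full$coefficients,
              var = full$var, spline_coef = bs,
              lrt_nonlinearity = unname(lrt), df_nonlinearity = df,
              p_nonlinearity = unname(p_nl), curve = curve,
              n = full$n, nevent = full$nevent)
  class(out) <- "rcs_fit"
  out
}

#' @export
print.rcs_fit <- function(x, digits = 4, ...) {
  cat("Restricted cubic spline dose-response (Cox model)\n")
  cat("knots:", paste(signif(x$knots, 4), collapse = ", "),
      " reference:", signif(x$ref, 4), "\n")
  cat(sprintf("nonlinearity LRT = %.3f on %d df, p = %.4g\n",
              x$lrt_nonlinearity, x$df_nonlinearity, x$p_nonlinearity))
  invisible(x)
}

#' @export
plot.rcs_fit <- function(x, xlab = "exposure", ylab = "hazard ratio", ...) {
  cv <- x$curve
  graphics::plot(cv$exposure, cv$hr, type = "l", log = "y",
                 ylim = range(cv$ci_low, cv$ci_high),
                 xlab = xlab, ylab = ylab, ...)
  graphics::lines(cv$exposure, cv$ci_low, lty = 2)
  graphics::lines(cv$exposure, cv$ci_high, lty = 2)
  graphics::abline(h = 1, col = "grey")
  graphics::rug(x$knots)
  invisible(x)
}

#' Ordinal trend test across ordered exposure groups
#'
#' Wald test of an integer-coded ordered group variable in a Cox model,
#' the conventional "P for trend" across quintiles or risk groups.
#'
#' @param data Data frame.
#' @param group_col Name of the ordered factor (or integer) column.
#' @param covariates Adjustment column names.
#' @param time_col,event_col Follow-up time / event indicator columns.
#' @return List with `coef` (log HR per one group step), `se`, `z` and
#'   `p_trend`.
#' @export
trend_test <- function(data, group_col, covariates = character(),
                       time_col = "follow_up_years", event_col = "event") {
  g <- data[[group_col]]
  if (is.factor(g)) g <- as.integer(g) else g <- as.integer(as.factor(g))
  if (length(unique(g)) < 2) stop("at least 2 ordered groups are required")
  Z <- drop_eventless_columns(design_from_columns(data, covariates),
                              data[[event_col]])
  X <- cbind(trend = as.numeric(g), Z)
  fit <- cox_fit_engine(data[[time_col]], data[[event_col]], X)
  b <- fit$coefficients["trend"]
  se <- fit$se[["trend"]]
  z <- b / se
  list(coef = unname(b), se = se, z = unname(z),
       p_trend = unname(2 * stats::pnorm(-abs(z))))
}

# Dummy-encode a set of data-frame columns into a numeric design matrix
# (no intercept column; first factor level is the reference).
design_from_columns <- function(data, columns) {
  if (length(columns) == 0) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  f <- stats::as.formula(paste("~", paste(columns, collapse = " + ")))
  X <- stats::model.matrix(f, data = data)
  X[, colnames(X) != "(Intercept)", drop = FALSE]
}
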