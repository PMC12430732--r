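#' Right-censored survival response
#'
#' Builds the two-column response used on the left-hand side of a
#' [cox_ph()] formula: follow-up time and an event indicator.
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator: 1 (or `TRUE`) if the event was observed,
#'   0 (or `FALSE`) if censored.
#' @return A numeric matrix with columns `time` and `event`, of class
#'   `"event_time"`.
#' @examples
#' event_time(c(2.3, 5.1), c(1, 0))
#' @export
event_time <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event))
    stop("'time' and 'event' must have the same length")
  if (any(!is.finite(time)) || any(time < 0))
    stop("follow-up times must be finite and nonnegative")
  if (!all(event %in% c(0, 1)))
    stop("'event' must be coded 0/1")
  out <- cbind(time = time, event = event)
  class(out) <- c("event_time", "matrix")
  out
}

# solve() with a symmetric pseudo-inverse fallback: near-singular
# information arises under monotone likelihoods, where some coefficients
# drift to infinity while the rest remain well determined.
safe_solve <- function(A, b = NULL) {
  out <- tryCatch(if (is.null(b)) solve(A) else solve(A, b),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  V <- e$vectors[, pos, drop = FALSE]
  Ainv <- V %*% ((1 / e$values[pos]) * t(V))
  if (is.null(b)) Ainv else Ainv %*% b
}

cox_control <- function(max_iter = 25, grad_tol = 1e-8, rel_tol = 1e-10,
                        beta_max = 15) {
  list(max_iter = max_iter, grad_tol = grad_tol, rel_tol = rel_tol,
       beta_max = beta_max)
}

# Core Newton-Raphson maximiser of the Efron partial likelihood.
# `X` must be a numeric matrix (no intercept); rows in any order.
cox_fit_engine <- function(time, status, X, init = NULL,
                           control = cox_control()) {
  n <- length(time)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != n || length(status) != n)
    stop("time, status and X must agree in length")
  nevent <- sum(status)
  if (nevent < 1) stop("no events in the data; cannot fit a Cox model")
  p <- ncol(X)

  # collinearity check on the full design
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  ord <- order(time)
  ts <- time[ord]
  ss <- as.integer(status[ord])
  Xs <- X[ord, , drop = FALSE]

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  d0 <- cox_loglik_deriv(ts, ss, Xs, beta)
  ll0 <- d0$loglik                      # log-likelihood at init (null if 0)
  ll <- ll0
  U <- drop(d0$score)
  I <- d0$imat
  converged <- FALSE
  monotone <- FALSE
  iter <- 0

  while (iter < control$max_iter) {
    iter <- iter + 1
    step <- drop(safe_solve(I, U))
    new_beta <- beta + step
    halving <- 0
    repeat {
      d <- cox_loglik_deriv(ts, ss, Xs, new_beta)
      if (is.finite(d$loglik) && d$loglik >= ll - 1e-12) break
      halving <- halving + 1
      if (halving > 20) break
      new_beta <- (beta + new_beta) / 2
    }
    rel_change <- abs(d$loglik - ll) / (abs(ll) + 1e-12)
    beta <- new_beta
    ll <- d$loglik
    U <- drop(d$score)
    I <- d$imat
    if (max(abs(U)) < control$grad_tol || rel_change < control$rel_tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > control$beta_max) {
      # monotone likelihood: the estimate is drifting to +/- infinity
      monotone <- TRUE
      break
    }
  }
  if (monotone) converged <- FALSE

  var <- safe_solve(I)
  names(beta) <- colnames(X)
  dimnames(var) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(var))
  list(coefficients = beta, var = var, se = se,
       loglik = c(null = ll0, final = ll), score = U, imat = I,
       iter = iter, converged = converged, monotone = monotone,
       n = n, nevent = nevent,
       sorted = list(time = ts, status = ss, X = Xs))
}

#' Cox proportional hazards regression
#'
#' Fits a Cox proportional hazards model by maximising the partial
#' likelihood with the Efron correction for tied event times, using
#' Newton-Raphson iteration. The left-hand side of `formula` must be an
#' [event_time()] object.
#'
#' Convergence is declared when the largest score component falls below
#' `grad_tol` (default 1e-8) or the relative change in partial
#' log-likelihood falls below `rel_tol` (default 1e-10). A monotone
#' partial likelihood (a coefficient drifting beyond `beta_max = 15` with
#' a non-vanishing score) is flagged via `converged = FALSE` and a
#' warning, never returned silently.
#'
#' @param formula Model formula, e.g.
#'   `event_time(fu, status) ~ x1 + x2`.
#' @param data Data frame holding the variables.
#' @param max_iter,grad_tol,rel_tol,beta_max Iteration controls; see
#'   Details.
#' @return An object of class `"cox_ph"` with components
#'   `coefficients` (log hazard ratios), `var` (inverse observed
#'   information), `loglik` (null and maximised partial log-likelihood),
#'   `n`, `nevent`, `iter`, `converged`, and the terms needed by the
#'   methods. Supported methods: `print`, `summary`, `coef`, `vcov`,
#'   `confint`, `logLik`, `predict`, `residuals` (Schoenfeld), and
#'   [cox_zph()].
#' @examples
#' d <- data.frame(fu = c(1, 2, 3, 4, 5, 6),
#'                 ev = c(1, 1, 0, 1, 0, 1),
#'                 x = c(1, 0, 1, 0, 1, 0))
#' fit <- cox_ph(event_time(fu, ev) ~ x, data = d)
#' coef(fit)
#' summary(fit)
#' @export
cox_ph <- function(formula, data, max_iter = 25, grad_tol = 1e-8,
                   rel_tol = 1e-10, beta_max = 15) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data = data, drop.unused.levels = TRUE,
                           na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!inherits(y, "event_time"))
    stop("the response must be constructed with event_time(time, event)")
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  asgn <- attr(X, "assign")
  keep <- asgn != 0                     # drop intercept
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) stop("model has no covariates")

  fit <- cox_fit_engine(y[, "time"], y[, "event"], X,
                        control = cox_control(max_iter, grad_tol,
                                              rel_tol, beta_max))
  if (fit$monotone)
    warning("monotone partial likelihood detected; estimates diverge ",
            "and the fit is flagged as not converged")
  fit$call <- cl
  fit$terms <- mt
  fit$xlevels <- stats::.getXlevels(mt, mf)
  fit$assign <- attr(stats::model.matrix(mt, mf), "assign")[keep]
  class(fit) <- "cox_ph"
  fit
}

#' @export
coef.cox_ph <- function(object, ...) object$coefficients

#' @export
vcov.cox_ph <- function(object, ...) object$var

#' @export
logLik.cox_ph <- function(object, ...) {
  ll <- object$loglik["final"]
  attr(ll, "df") <- length(object$coefficients)
  class(ll) <- "logLik"
  ll
}

#' @export
confint.cox_ph <- function(object, parm, level = 0.95, ...) {
  co <- coef(object)
  se <- object$se
  if (missing(parm)) parm <- names(co)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(co[parm] - z * se[parm], co[parm] + z * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
print.cox_ph <- function(x, digits = 4, ...) {
  cat("Cox proportional hazards model (Efron ties)\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  print(round(summary(x)$table, digits))
  cat(sprintf("n = %d, events = %d, partial logLik = %.3f (%d iterations)\n",
              x$n, x$nevent, x$loglik["final"], x$iter))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.cox_ph <- function(object, conf_level = 0.95, ...) {
  co <- coef(object)
  se <- object$se
  z <- co / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- confint(object, level = conf_level)
  tab <- cbind(coef = co, `exp(coef)` = exp(co), se = se, z = z, p = p,
               hr_low = exp(ci[, 1]), hr_high = exp(ci[, 2]))
  out <- list(table = tab, n = object$n, nevent = object$nevent,
              loglik = object$loglik, converged = object$converged,
              lrt = 2 * (object$loglik["final"] - object$loglik["null"]))
  class(out) <- "summary.cox_ph"
  out
}

#' @export
print.summary.cox_ph <- function(x, digits = 4, ...) {
  print(round(x$table, digits))
  cat(sprintf("n = %d, events = %d\n", x$n, x$nevent))
  cat(sprintf("Likelihood ratio test = %.2f on %d df\n",
              x$lrt, nrow(x$table)))
  invisible(x)
}

#' @export
predict.cox_ph <- function(object, newdata = NULL,
                           type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    # linear predictor of the (sorted) training rows, restored to the
    # original order is not tracked; recompute from stored sorted design
    lp <- drop(object$sorted$X %*% coef(object))
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                             na.action = stats::na.fail)
    X <- stats::model.matrix(tt, mf)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    lp <- drop(X %*% coef(object))
  }
  if (type == "risk") exp(lp) else lp
}

#' @export
residuals.cox_ph <- function(object, type = c("schoenfeld"), ...) {
  type <- match.arg(type)
  s <- object$sorted
  q <- cox_zph_quant(s$time, s$status, s$X, coef(object),
                     rep(0, length(s$time)))
  r <- q$schoenfeld
  dimnames(r) <- list(NULL, names(coef(object)))
  attr(r, "time") <- q$sch_time
  r
}

# Kaplan-Meier estimate over all subjects; returns the left-continuous
# survival value S(t-) evaluated at each subject's own time, so that the
# "km" transform is g(t) = 1 - S(t-).
km_transform <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  n <- length(time)
  # numbers at risk and events at each unique event time
  atrisk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  dth <- vapply(ut, function(t) sum(time == t & status == 1), numeric(1))
  surv <- cumprod(1 - dth / atrisk)
  idx <- findInterval(time, ut, left.open = TRUE)
  1 - c(1, surv)[idx + 1]
}

#' Test the proportional hazards assumption
#'
#' Score test for a time-varying coefficient, following the
#' Grambsch-Therneau construction: each covariate column x is augmented
#' by x*g(t) with g a centred transform of event time, and the score test
#' of the augmented coefficients being zero is reported per covariate and
#' globally. Schoenfeld residuals (Efron-averaged risk-set means) are
#' returned for plotting.
#'
#' @param fit A converged [cox_ph()] fit.
#' @param transform Time transform: `"km"` (default; left-continuous
#'   Kaplan-Meier scale 1 - S(t-)), `"identity"`, `"rank"`, or `"log"`.
#' @return An object of class `"cox_zph"`: a `table` with columns
#'   `chisq`, `df`, `p` (one row per covariate plus `GLOBAL`), plus the
#'   transformed times and Schoenfeld residuals.
#' @examples
#' d <- data.frame(fu = rexp(60), ev = rbinom(60, 1, 0.7),
#'                 x = rnorm(60))
#' fit <- cox_ph(event_time(fu, ev) ~ x, data = d)
#' cox_zph(fit)$table
#' @export
cox_zph <- function(fit, transform = c("km", "identity", "rank", "log")) {
  transform <- match.arg(transform)
  if (fit$nevent < 2) stop("at least 2 events are required")
  s <- fit$sorted
  ttimes <- switch(transform,
                   identity = s$time,
                   rank = rank(s$time),
                   log = log(s$time),
                   km = km_transform(s$time, s$status))
  g <- ttimes - mean(ttimes[s$status == 1])
  q <- cox_zph_quant(s$time, s$status, s$X, coef(fit), g)
  q$u2 <- drop(q$u2)
  p <- length(coef(fit))
  imat <- rbind(cbind(q$imat11, q$imat12), cbind(t(q$imat12), q$imat22))
  u0 <- rep(0, p)
  test <- numeric(p + 1)
  for (j in seq_len(p)) {
    kk <- c(seq_len(p), p + j)
    u <- c(u0, q$u2[j])
    test[j] <- drop(crossprod(u, solve(imat[kk, kk], u)))
  }
  test[p + 1] <- drop(crossprod(c(u0, q$u2), solve(imat, c(u0, q$u2))))
  df <- c(rep(1, p), p)
  tab <- cbind(chisq = test, df = df,
               p = stats::pchisq(test, df, lower.tail = FALSE))
  rownames(tab) <- c(names(coef(fit)), "GLOBAL")
  resid <- q$schoenfeld
  dimnames(resid) <- list(NULL, names(coef(fit)))
  out <- list(table = tab, transform = transform,
              time = q$sch_time, g = q$sch_g, schoenfeld = resid)
  class(out) <- "cox_zph"
  out
}

#' @export
print.cox_zph <- function(x, digits = 4, ...) {
  cat("Proportional hazards score test (transform:", x$transform, ")\n")
  print(round(x$table, digits))
  invisible(x)
}
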