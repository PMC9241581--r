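# Weibull survival extrapolation, hazard-ratio adjustment, per-cycle
# transition probabilities, and parametric fitting with AIC/BIC selection.
#
# Convention: S(t) = exp(-lambda * t^gamma) with t in MONTHS. Weekly model
# cycles convert through t_months = weeks * 7 / 30.4375.

#' Days per month used to convert weekly cycles to the monthly time scale
#' @export
DAYS_PER_MONTH <- 30.4375

#' Months elapsed after a number of weekly cycles
#' @param weeks Number of weeks.
#' @return Time in months.
#' @export
weeks_to_months <- function(weeks) weeks * 7 / DAYS_PER_MONTH

#' Weibull survival-curve parameters
#'
#' The survival function is \eqn{S(t) = e^{-\lambda t^\gamma}} with time in
#' months: \code{scale} is \eqn{\lambda} and \code{shape} is \eqn{\gamma}.
#' \code{log_chol} optionally carries the lower-triangular Cholesky factor of
#' the covariance of \eqn{(\ln\lambda, \ln\gamma)} used for joint PSA draws.
#'
#' @param scale Weibull rate-like scale \eqn{\lambda > 0} (per month^-shape).
#' @param shape Weibull shape \eqn{\gamma > 0}.
#' @param log_chol Optional 2x2 lower-triangular matrix with non-negative
#'   diagonal (Cholesky factor of the log-parameter covariance).
#' @return A \code{weibull_params} object.
#' @export
weibull_params <- function(scale, shape, log_chol = NULL) {
  scale <- as.numeric(scale); shape <- as.numeric(shape)
  if (!(scale > 0 && shape > 0)) {
    stop("weibull_params: scale and shape must be positive", call. = FALSE)
  }
  if (!is.null(log_chol)) {
    log_chol <- matrix(as.numeric(log_chol), 2, 2)
    if (any(diag(log_chol) < 0) || log_chol[1, 2] != 0) {
      stop("weibull_params: log_chol must be lower triangular with non-negative diagonal",
           call. = FALSE)
    }
  }
  structure(list(scale = scale, shape = shape, log_chol = log_chol),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("weibull_params: lambda=%g, gamma=%g%s\n", x$scale, x$shape,
              if (is.null(x$log_chol)) "" else " (+ PSA Cholesky factor)"))
  invisible(x)
}

#' Weibull survival probability
#'
#' @param params A \code{weibull_params}.
#' @param t Time in months, non-negative (vectorised).
#' @return \eqn{\exp(-\lambda t^\gamma)}.
#' @examples
#' weibull_survival(weibull_params(0.0075, 1.3601), 12)  # ~0.792
#' @export
weibull_survival <- function(params, t) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("weibull_survival: t must be >= 0", call. = FALSE)
  exp(-params$scale * t^params$shape)
}

#' Median survival time of a Weibull curve, (ln 2 / lambda)^(1/gamma) months
#' @param params A \code{weibull_params}.
#' @return Median in months.
#' @export
weibull_median <- function(params) {
  (log(2) / params$scale)^(1 / params$shape)
}

#' Mean survival time of a Weibull curve
#'
#' Closed form \eqn{(1/\lambda)^{1/\gamma}\,\Gamma(1 + 1/\gamma)} months.
#' @param params A \code{weibull_params}.
#' @return Mean in months.
#' @export
weibull_mean <- function(params) {
  (1 / params$scale)^(1 / params$shape) * gamma(1 + 1 / params$shape)
}

#' Scale a reference Weibull curve by a hazard ratio
#'
#' Under proportional hazards with a shared shape, the comparator curve keeps
#' the reference \eqn{\gamma} and multiplies \eqn{\lambda} by the hazard
#' ratio, so the implied hazard at every time is \code{hr} times the
#' reference hazard.
#'
#' @param ref Reference \code{weibull_params}.
#' @param hr Positive hazard ratio.
#' @return A \code{weibull_params} with \code{scale = ref$scale * hr}.
#' @export
apply_hazard_ratio <- function(ref, hr) {
  stopifnot(inherits(ref, "weibull_params"))
  if (!is.numeric(hr) || length(hr) != 1L || !(hr > 0)) {
    stop("apply_hazard_ratio: hr must be a positive scalar", call. = FALSE)
  }
  weibull_params(ref$scale * hr, ref$shape, ref$log_chol)
}

#' Per-cycle transition probability from a survival curve
#'
#' Probability of the event during cycle \code{k} given survival to its start:
#' \eqn{1 - S(t_{k+1})/S(t_k)} with \eqn{t_k = k \Delta}.
#'
#' @param params A \code{weibull_params}.
#' @param cycle_index Cycle index k >= 0 (vectorised).
#' @param cycle_length Cycle length in months.
#' @return Probability in [0, 1).
#' @export
cycle_transition_probability <- function(params, cycle_index, cycle_length) {
  if (any(cycle_index < 0)) stop("cycle_transition_probability: cycle_index must be >= 0", call. = FALSE)
  if (!(cycle_length > 0)) stop("cycle_transition_probability: cycle_length must be > 0", call. = FALSE)
  t0 <- cycle_index * cycle_length
  t1 <- (cycle_index + 1) * cycle_length
  1 - weibull_survival(params, t1) / weibull_survival(params, t0)
}

# ---- parametric fitting ----------------------------------------------------

.FIT_FAMILIES <- c("exponential", "weibull", "gompertz", "loglogistic", "lognormal")

#' Build a right-censored survival dataset
#' @param times Positive event/censoring times in months.
#' @param events 1 = event observed, 0 = right-censored.
#' @return A \code{survival_dataset} data frame.
#' @export
survival_dataset <- function(times, events) {
  times <- as.numeric(times); events <- as.integer(events)
  if (length(times) != length(events)) {
    stop("survival_dataset: times and events must have equal length", call. = FALSE)
  }
  if (any(times <= 0)) stop("survival_dataset: times must be positive", call. = FALSE)
  if (!all(events %in% c(0L, 1L))) stop("survival_dataset: events must be 0/1", call. = FALSE)
  structure(data.frame(time = times, event = events),
            class = c("survival_dataset", "data.frame"))
}

#' Read a survival dataset from CSV (time_months, event)
#' @param path CSV file path.
#' @return A \code{survival_dataset}.
#' @export
read_survival_dataset <- function(path) {
  df <- utils::read.csv(path)
  survival_dataset(df[[1]], df[[2]])
}

# Gompertz h(t) = a exp(b t); H(t) = a/b (exp(b t) - 1), b -> 0 gives a t.
.gompertz_nll <- function(par, time, event) {
  a <- exp(par[1]); b <- par[2]
  H <- if (abs(b) < 1e-10) a * time else a / b * (expm1(b * time))
  ll <- sum(event * (log(a) + b * time)) - sum(H)
  -ll
}

#' Fit a parametric survival model to right-censored data
#'
#' Maximises the right-censored log-likelihood
#' \eqn{\sum_{events}\ln h(t_i) + \sum_{all}\ln S(t_i)}. The exponential,
#' Weibull, log-logistic and log-normal families are fitted through
#' \code{survival::survreg}; the Gompertz family (\eqn{h(t)=a e^{bt}}), which
#' survreg does not provide, is fitted by direct numerical MLE.
#'
#' Reported natural parameters: exponential \code{rate}; Weibull
#' \code{scale} (\eqn{\lambda}) and \code{shape} (\eqn{\gamma}) of
#' \eqn{S(t)=e^{-\lambda t^\gamma}}; Gompertz \code{a}, \code{b}; log-logistic
#' \code{scale} (time at S=0.5) and \code{shape}; log-normal \code{meanlog},
#' \code{sdlog}.
#'
#' @param data A \code{survival_dataset} with at least 10 rows and 1 event.
#' @param family One of \code{"exponential"}, \code{"weibull"},
#'   \code{"gompertz"}, \code{"loglogistic"}, \code{"lognormal"}.
#' @return A \code{fit_result} with elements \code{family}, \code{params},
#'   \code{loglik}, \code{aic}, \code{bic}, \code{n}, \code{k}.
#' @export
fit_parametric <- function(data, family) {
  stopifnot(inherits(data, "survival_dataset"))
  family <- match.arg(family, .FIT_FAMILIES)
  n <- nrow(data)
  if (n < 10L) stop("fit_parametric: need >= 10 observations", call. = FALSE)
  if (sum(data$event) < 1L) stop("fit_parametric: need >= 1 event", call. = FALSE)

  if (family == "gompertz") {
    init <- c(log(sum(data$event) / sum(data$time)), 0.01)
    opt <- stats::optim(init, .gompertz_nll, time = data$time, event = data$event,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$convergence != 0) {
      stop("fit_parametric: Gompertz optimiser failed to converge (code ",
           opt$convergence, ")", call. = FALSE)
    }
    params <- c(a = exp(opt$par[1]), b = opt$par[2])
    loglik <- -opt$value
    k <- 2L
  } else {
    sr_dist <- switch(family, exponential = "exponential", weibull = "weibull",
                      loglogistic = "loglogistic", lognormal = "lognormal")
    fit <- tryCatch(
      survival::survreg(survival::Surv(time, event) ~ 1, data = data,
                        dist = sr_dist),
      error = function(e) stop("fit_parametric: survreg failed: ",
                               conditionMessage(e), call. = FALSE))
    mu <- unname(stats::coef(fit)[1])
    sigma <- fit$scale
    params <- switch(family,
      exponential = c(rate = exp(-mu)),
      weibull = c(scale = exp(-mu / sigma), shape = 1 / sigma),
      loglogistic = c(scale = exp(mu), shape = 1 / sigma),
      lognormal = c(meanlog = mu, sdlog = sigma))
    loglik <- fit$loglik[2]
    k <- if (family == "exponential") 1L else 2L
  }
  structure(list(family = family, params = params, loglik = loglik,
                 aic = -2 * loglik + 2 * k,
                 bic = -2 * loglik + k * log(n),
                 n = n, k = k),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result[%s]: loglik=%.3f AIC=%.2f BIC=%.2f; %s\n",
              x$family, x$loglik, x$aic, x$bic,
              paste(sprintf("%s=%.5g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

#' Select the best-fitting parametric family
#'
#' Minimum BIC; ties broken by AIC, then by the conventional family order
#' (exponential, weibull, gompertz, loglogistic, lognormal).
#'
#' @param fits Non-empty list of \code{fit_result} objects.
#' @return The selected \code{fit_result}.
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop("select_model: empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fit_result")))
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  fam <- match(vapply(fits, `[[`, character(1), "family"), .FIT_FAMILIES)
  fits[[order(bic, aic, fam)[1]]]
}
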