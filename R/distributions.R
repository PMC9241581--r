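# Parameter distributions for deterministic bases and PSA sampling.

.DIST_FAMILIES <- c("gamma", "lognormal", "beta", "normal", "uniform", "fixed",
                    "cholesky_mvn")

#' Specify a sampling distribution for a model parameter
#'
#' Distributions follow the conventions of probabilistic sensitivity analysis
#' in health economic models: gamma for costs, lognormal for hazard ratios,
#' beta for utilities and proportions, normal/uniform for the remainder, and
#' \code{fixed} for parameters held constant.
#'
#' Parameterizations: gamma is (shape, scale) so the mean is shape*scale;
#' lognormal is (mu, sigma) on the natural-log scale so the median is
#' exp(mu); beta is (alpha, beta) with mean alpha/(alpha+beta); normal is
#' (mean, sd); uniform is (low, high).
#'
#' @param family One of "gamma", "lognormal", "beta", "normal", "uniform",
#'   "fixed", "cholesky_mvn".
#' @param ... Named numeric parameters for the family (see Details).
#' @return A \code{dist_spec} object.
#' @examples
#' dist_spec("gamma", shape = 96.04, scale = 0.69)
#' dist_spec("beta", alpha = 15.38, beta = 2.04)
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, .DIST_FAMILIES)
  params <- list(...)
  if (length(params) == 1L && is.list(params[[1]]) && is.null(names(params)[1])) {
    params <- params[[1]]
  }
  params <- lapply(params, as.numeric)
  need <- switch(family,
    gamma = c("shape", "scale"),
    lognormal = c("mu", "sigma"),
    beta = c("alpha", "beta"),
    normal = c("mean", "sd"),
    uniform = c("low", "high"),
    fixed = character(0),
    cholesky_mvn = character(0))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("dist_spec('", family, "'): missing parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- params
  ok <- switch(family,
    gamma = p$shape > 0 && p$scale > 0,
    lognormal = p$sigma >= 0,
    beta = p$alpha > 0 && p$beta > 0,
    normal = p$sd >= 0,
    uniform = p$low <= p$high,
    TRUE)
  if (!isTRUE(ok)) stop("dist_spec('", family, "'): invalid parameters", call. = FALSE)
  structure(list(family = family, params = params), class = "dist_spec")
}

#' Central value of a distribution specification
#'
#' Returns the value a deterministic analysis would use: the mean for gamma,
#' beta, normal and uniform, and the median \eqn{e^\mu} for the lognormal
#' (hazard ratios are reported as medians of their lognormal posteriors).
#'
#' @param dist A \code{dist_spec}.
#' @return A single numeric value.
#' @examples
#' central_value(dist_spec("gamma", shape = 96.04, scale = 0.69)) # 66.27
#' @export
central_value <- function(dist) {
  stopifnot(inherits(dist, "dist_spec"))
  p <- dist$params
  switch(dist$family,
    gamma = p$shape * p$scale,
    beta = p$alpha / (p$alpha + p$beta),
    lognormal = exp(p$mu),
    normal = p$mean,
    uniform = (p$low + p$high) / 2,
    stop("central_value: unsupported family '", dist$family, "'", call. = FALSE))
}

#' Draw random samples from a distribution specification
#'
#' @param dist A \code{dist_spec}; \code{fixed} requires \code{base}.
#' @param n Number of draws.
#' @param base Value returned for the \code{fixed} family.
#' @return Numeric vector of length \code{n}.
#' @export
sample_dist <- function(dist, n = 1L, base = NULL) {
  stopifnot(inherits(dist, "dist_spec"))
  p <- dist$params
  switch(dist$family,
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(n, meanlog = p$mu, sdlog = p$sigma),
    beta = stats::rbeta(n, shape1 = p$alpha, shape2 = p$beta),
    normal = stats::rnorm(n, mean = p$mean, sd = p$sd),
    uniform = stats::runif(n, min = p$low, max = p$high),
    fixed = {
      if (is.null(base)) stop("sample_dist: fixed family needs 'base'", call. = FALSE)
      rep(base, n)
    },
    stop("sample_dist: unsupported family '", dist$family, "'", call. = FALSE))
}

#' Model parameter with base value, plausible range and PSA distribution
#'
#' @param base Deterministic (base-case) value.
#' @param low,high Plausible range used by one-way sensitivity analysis;
#'   defaults to base +/- 20\% when not given.
#' @param dist A \code{dist_spec}; defaults to \code{fixed}.
#' @param check When TRUE, verify that the distribution's central value agrees
#'   with \code{base} (transcription audit; 2\% relative or 1.0 absolute
#'   tolerance, the latter covering integer-printed currencies whose
#'   distribution parameters were rounded independently).
#' @return A \code{param_value} object.
#' @export
param_value <- function(base, low = NULL, high = NULL, dist = NULL, check = TRUE) {
  base <- as.numeric(base)
  if (is.null(dist)) dist <- dist_spec("fixed")
  if (is.null(low)) low <- base - 0.2 * abs(base)
  if (is.null(high)) high <- base + 0.2 * abs(base)
  low <- as.numeric(low); high <- as.numeric(high)
  if (!(low <= base && base <= high)) {
    stop("param_value: need low <= base <= high (got ", low, ", ", base, ", ",
         high, ")", call. = FALSE)
  }
  pv <- structure(list(base = base, low = low, high = high, dist = dist),
                  class = "param_value")
  if (check && !dist$family %in% c("fixed", "cholesky_mvn")) {
    cv <- central_value(dist)
    if (!.transcription_ok(base, cv)) {
      stop("param_value: distribution central value ", signif(cv, 6),
           " inconsistent with base ", base, call. = FALSE)
    }
  }
  pv
}

# 2% relative, with a 1.0 absolute floor for integer-printed currency values
# whose distribution scales were themselves rounded to 2 dp.
.transcription_ok <- function(base, central, tol_rel = 0.02, tol_abs = 1.0) {
  abs(central - base) <= max(tol_rel * abs(base), tol_abs * (abs(base) >= 1))
}

#' @export
print.param_value <- function(x, ...) {
  cat(sprintf("param_value: %g (%g, %g), %s\n", x$base, x$low, x$high,
              x$dist$family))
  invisible(x)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("dist_spec:", x$family,
      if (length(x$params)) paste0("(", paste(sprintf("%s=%g", names(x$params),
                                   unlist(x$params)), collapse = ", "), ")"),
      "\n")
  invisible(x)
}

is_param_value <- function(x) inherits(x, "param_value")

#' Draw one PSA realisation of a parameter
#'
#' @param pv A \code{param_value}.
#' @return Single numeric draw from the parameter's distribution (the base
#'   value for \code{fixed} parameters).
#' @export
draw_param <- function(pv) {
  stopifnot(is_param_value(pv))
  sample_dist(pv$dist, 1L, base = pv$base)
}
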