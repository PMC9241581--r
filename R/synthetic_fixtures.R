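# Seeded generators for every statistical structure the pipeline consumes:
# right-censored Weibull survival data, Gompertz-Makeham life tables, random
# cost-QALY planes, and complete randomized model input sets.

#' Generate right-censored Weibull survival data
#'
#' Event times are drawn from \eqn{S(t)=e^{-\lambda t^\gamma}} (months).
#' Censoring is independent uniform on (0, c_max) with c_max solved
#' numerically so the expected censored fraction equals the target — the
#' simplest mechanism consistent with administrative censoring.
#'
#' @param n Number of subjects.
#' @param params True \code{weibull_params}.
#' @param censor_frac Target censored fraction in [0, 1); 0 disables
#'   censoring.
#' @param seed Integer seed (bitwise reproducible).
#' @return A \code{survival_dataset}.
#' @export
gen_censored_weibull <- function(n, params, censor_frac = 0, seed = 1L) {
  stopifnot(n >= 1L, inherits(params, "weibull_params"),
            censor_frac >= 0, censor_frac < 1)
  set.seed(seed)
  r_scale <- (1 / params$scale)^(1 / params$shape)
  tt <- stats::rweibull(n, shape = params$shape, scale = r_scale)
  if (censor_frac == 0) {
    return(survival_dataset(tt, rep(1L, n)))
  }
  surv <- function(t) weibull_survival(params, t)
  exp_cens <- function(cmax) {
    stats::integrate(surv, 0, cmax, rel.tol = 1e-9)$value / cmax
  }
  hi <- r_scale
  while (exp_cens(hi) > censor_frac) hi <- hi * 2
  cmax <- stats::uniroot(function(cm) exp_cens(cm) - censor_frac,
                         c(r_scale * 1e-3, hi), tol = 1e-8)$root
  cc <- stats::runif(n, 0, cmax)
  survival_dataset(pmin(tt, cc), as.integer(tt <= cc))
}

#' Generate a Gompertz-Makeham life table
#'
#' Annual mortality \eqn{q(age) = 1 - \exp(-(a + c\,e^{b\,age}))} over the
#' given ages. Defaults are calibrated so q(71) is about 0.02, the order of
#' magnitude of all-cause mortality at the UK cohort's start age.
#'
#' @param a Age-independent hazard component (>= 0).
#' @param b Exponential ageing rate (> 0).
#' @param c Age-dependent hazard scale (>= 0).
#' @param ages Integer age grid.
#' @return A \code{life_table}; probabilities outside [0, 1] are clipped with
#'   a warning.
#' @export
gen_life_table <- function(a = 5e-4, b = 0.09, c = 3.3e-5, ages = 40:100) {
  stopifnot(a >= 0, b > 0, c >= 0)
  q <- 1 - exp(-(a + c * exp(b * ages)))
  if (any(q < 0 | q > 1)) {
    warning("gen_life_table: mortality probabilities clipped to [0, 1]")
    q <- pmin(pmax(q, 0), 1)
  }
  life_table(ages, q)
}

#' Generate a random cost-QALY plane
#'
#' Independent uniform cost and QALY pairs for frontier stress testing.
#'
#' @param n_arms Number of strategies (>= 1).
#' @param seed Integer seed.
#' @param cost_range,qaly_range Sampling ranges.
#' @return Data frame (arm, cost, qaly) compatible with
#'   \code{build_frontier}.
#' @export
gen_ce_plane <- function(n_arms, seed = 1L, cost_range = c(10000, 160000),
                         qaly_range = c(0.5, 2.0)) {
  stopifnot(n_arms >= 1L)
  set.seed(seed)
  data.frame(arm = paste0("arm", seq_len(n_arms)),
             cost = stats::runif(n_arms, cost_range[1], cost_range[2]),
             qaly = stats::runif(n_arms, qaly_range[1], qaly_range[2]),
             stringsAsFactors = FALSE)
}

#' Generate a complete randomized model input set
#'
#' A small synthetic input set (reference chemotherapy arm plus \code{n_arms}
#' comparators with random hazard ratios and costs) that passes full
#' validation; useful for end-to-end pipeline and monotonicity tests. The
#' true hazard ratios are attached as attribute \code{truth}.
#'
#' @param seed Integer seed.
#' @param n_arms Number of non-reference arms.
#' @return A validated \code{model_inputs}.
#' @export
gen_inputs <- function(seed = 1L, n_arms = 3L) {
  stopifnot(n_arms >= 1L)
  set.seed(seed)
  pv_gamma <- function(base) {
    param_value(base, 0.8 * base, 1.2 * base,
                dist_spec("gamma", shape = 96.04, scale = base / 96.04))
  }
  pv_hr <- function(hr, sigma = 0.1) {
    param_value(hr, hr * 0.8, hr * 1.25,
                dist_spec("lognormal", mu = log(hr), sigma = sigma))
  }
  pv_beta <- function(mean, n0 = 100) {
    param_value(mean, max(0, 0.8 * mean), min(1, 1.2 * mean),
                dist_spec("beta", alpha = mean * n0, beta = (1 - mean) * n0))
  }
  sae_cost <- lapply(stats::setNames(SAE_EVENTS, SAE_EVENTS),
                     function(e) pv_gamma(round(stats::runif(1, 50, 2000))))
  sae_dis <- lapply(stats::setNames(SAE_EVENTS, SAE_EVENTS),
                    function(e) pv_beta(stats::runif(1, 0.02, 0.09), n0 = 500))
  ref_sae <- stats::setNames(stats::runif(length(SAE_EVENTS), 0, 0.2), SAE_EVENTS)
  ref <- treatment_arm("Reference",
                       regimen_schedule(acq_chemo_phase = pv_gamma(100),
                                        chemo_weeks = 12L),
                       hrs = NULL, sae = ref_sae,
                       second_line_pathway = "docetaxel_only")
  hr_pfs <- stats::runif(n_arms, 0.2, 0.9)
  hr_os <- stats::runif(n_arms, 0.6, 1.1)
  arms <- c(list(ref), lapply(seq_len(n_arms), function(i) {
    treatment_arm(paste0("TKI", i),
                  regimen_schedule(acq_maintenance = pv_gamma(round(stats::runif(1, 50, 1500)))),
                  hrs = list(pfs = pv_hr(hr_pfs[i]), os = pv_hr(hr_os[i])),
                  sae = stats::setNames(stats::runif(length(SAE_EVENTS), 0, 0.05),
                                        SAE_EVENTS),
                  second_line_pathway = "pem_platinum_then_docetaxel")
  }))
  out <- model_inputs(
    country = "UK", arms = arms, reference_arm = "Reference",
    pfs_ref = weibull_params(0.0474, 1.5590),
    os_ref = weibull_params(0.0075, 1.3601),
    utilities = list(u_pf = pv_beta(0.8), u_pd = pv_beta(0.3)),
    sae_costs = sae_cost, sae_disutilities = sae_dis,
    management_costs = list(pf_per_week = pv_gamma(50),
                            pd_per_week = pv_gamma(55),
                            bsc_per_week = pv_gamma(100),
                            terminal_one_off = pv_gamma(4500)),
    admin_costs = list(tki_per_week = pv_gamma(3),
                       infusion_per_week = pv_gamma(100)),
    second_line_costs = list(pem_platinum_per_week = pv_gamma(450),
                             docetaxel_per_week = pv_gamma(10),
                             osimertinib_per_week = pv_gamma(1300)),
    second_line_uptake = pv_beta(0.6),
    start_age = 70,
    discount_rate_annual = param_value(0.035, 0, 0.06,
                                       dist_spec("uniform", low = 0, high = 0.06),
                                       check = FALSE),
    wtp_low = 20000, wtp_high = 50000,
    life_table = gen_life_table(),
    horizon_weeks = 1043L,
    meta = list(synthetic = TRUE, seed = seed))
  attr(out, "truth") <- list(hr_pfs = hr_pfs, hr_os = hr_os)
  out
}
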