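# Weekly-cycle three-state (PF / PD / dead) cohort simulation with
# discounted cost, QALY and life-year accrual.
#
# Occupancy is derived from the arm's PFS and OS curves: PF tracks the PFS
# survival function (with a background-mortality floor on PF exits),
# cumulative deaths are calibrated to the OS curve by solving the per-cycle
# PD->dead probability, clipped to [0, 1].

#' Build the cohort trace for one treatment arm
#'
#' @param arm A \code{treatment_arm} belonging to \code{inputs}.
#' @param inputs A \code{model_inputs}.
#' @param use_background_mortality When FALSE the life-table floor on PF
#'   mortality is disabled (used for curve-level validation).
#' @return A \code{cohort_trace}: list with occupancy vectors \code{pf},
#'   \code{pd}, \code{dead} at cycle starts 0..H, per-cycle \code{new_pd} and
#'   \code{new_dead} flows, the within-PD survival product \code{pd_surv},
#'   and metadata \code{clipped_cycles} / \code{clip_warning} recording how
#'   often the OS calibration had to be clipped to [0, 1].
#' @export
build_trace <- function(arm, inputs, use_background_mortality = TRUE) {
  stopifnot(inherits(arm, "treatment_arm"), inherits(inputs, "model_inputs"))
  H <- inputs$horizon_weeks
  pfs <- inputs$pfs_ref
  os <- inputs$os_ref
  if (!is.null(arm$hrs)) {
    pfs <- apply_hazard_ratio(pfs, arm$hrs$pfs$base)
    os <- apply_hazard_ratio(os, arm$hrs$os$base)
  }
  tm <- weeks_to_months(0:H)
  S_pfs <- weibull_survival(pfs, tm)
  S_os <- weibull_survival(os, tm)
  q_prog <- 1 - S_pfs[-1] / S_pfs[-(H + 1)]
  ages <- inputs$start_age + (0:(H - 1)) / WEEKS_PER_YEAR
  max_age <- max(inputs$life_table$age)
  q_bg <- if (use_background_mortality) {
    weekly_background_mortality(inputs$life_table, pmin(ages, max_age))
  } else rep(0, H)

  pf <- pd <- dead <- numeric(H + 1)
  pf[1] <- 1
  new_pd <- new_dead <- q_pd_death <- numeric(H)
  clipped <- 0L
  for (k in 1:H) {
    q_exit <- max(q_prog[k], q_bg[k])  # background mortality floors PF exits
    qd_pf <- q_bg[k]
    q_to_pd <- q_exit - qd_pf
    d_pf <- pf[k] * qd_pf
    need <- (1 - S_os[k + 1]) - dead[k] - d_pf
    qd_raw <- if (pd[k] > 1e-14) need / pd[k] else 0
    qd_pd <- min(max(qd_raw, 0), 1 - 1e-9)
    if (pd[k] > 1e-14 && (qd_raw < 0 || qd_raw > 1)) clipped <- clipped + 1L
    d_pd <- pd[k] * qd_pd
    pf[k + 1] <- pf[k] * (1 - q_exit)
    pd[k + 1] <- pd[k] * (1 - qd_pd) + pf[k] * q_to_pd
    dead[k + 1] <- dead[k] + d_pf + d_pd
    new_pd[k] <- pf[k] * q_to_pd
    new_dead[k] <- d_pf + d_pd
    q_pd_death[k] <- qd_pd
  }
  # survival product within PD: pd_surv[j] = P(alive j-1 cycles after entering
  # PD at cycle-start j), used to attribute time-in-state costs
  pd_surv <- cumprod(c(1, 1 - q_pd_death[-H]))
  structure(list(arm = arm$name, pf = pf, pd = pd, dead = dead,
                 new_pd = new_pd, new_dead = new_dead,
                 q_pd_death = q_pd_death, pd_surv = pd_surv,
                 horizon_weeks = H, clipped_cycles = clipped,
                 clip_warning = clipped > 0.05 * H),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("cohort_trace[%s]: %d weekly cycles, %.1f%% dead at horizon%s\n",
              x$arm, x$horizon_weeks, 100 * x$dead[x$horizon_weeks + 1],
              if (x$clipped_cycles) paste0(" (", x$clipped_cycles, " clipped cycles)") else ""))
  invisible(x)
}

#' Export a cohort trace as a data frame (cycle, pf, pd, dead)
#' @param x A \code{cohort_trace}.
#' @param ... Unused.
#' @return A data frame with one row per cycle start.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = 0:x$horizon_weeks, pf = x$pf, pd = x$pd, dead = x$dead)
}

#' One-off SAE burden of a treatment arm
#'
#' Incidence-weighted one-off cost and QALY loss applied at model entry:
#' \code{cost = sum(incidence_e * cost_e)},
#' \code{qaly_loss = sum(incidence_e * disutility_e)}.
#'
#' @param profile Named incidence vector over \code{SAE_EVENTS}.
#' @param costs Named numeric (or \code{param_value} list) of per-event costs.
#' @param disutilities Named numeric (or \code{param_value} list) of per-event
#'   utility decrements.
#' @return List with \code{cost} and \code{qaly_loss}.
#' @export
sae_burden <- function(profile, costs, disutilities) {
  ev <- names(profile)[profile > 0]
  as_num <- function(map, what) {
    vapply(ev, function(e) {
      x <- map[[e]]
      if (is.null(x)) stop("sae_burden: missing ", what, " for event '", e, "'",
                           call. = FALSE)
      if (is_param_value(x)) x$base else as.numeric(x)
    }, numeric(1))
  }
  if (!length(ev)) return(list(cost = 0, qaly_loss = 0))
  inc <- profile[ev]
  list(cost = sum(inc * as_num(costs, "cost")),
       qaly_loss = sum(inc * as_num(disutilities, "disutility")))
}

# Weekly cost profile by time since progression (d = 0 .. H-1 weeks),
# combining the uptake-weighted active second/third-line pathway with best
# supportive care. Disease-management cost of PD is handled separately.
.second_line_profile <- function(arm, inputs, H, second_line = "default") {
  u2 <- inputs$second_line_uptake$base
  bsc <- inputs$management_costs$bsc_per_week$base
  adm_inf <- inputs$admin_costs$infusion_per_week$base
  adm_tki <- inputs$admin_costs$tki_per_week$base
  doc <- inputs$second_line_costs$docetaxel_per_week$base
  d <- 0:(H - 1)
  if (identical(second_line, "t790m") &&
      arm$second_line_pathway == "pem_platinum_then_docetaxel") {
    osi <- inputs$second_line_costs$osimertinib_per_week
    if (is.null(osi)) {
      stop("accrue: T790M scenario needs second_line_costs$osimertinib_per_week",
           call. = FALSE)
    }
    # 60% develop T790M and receive osimertinib until death; the rest receive
    # pemetrexed-based chemotherapy (4 cycles) then BSC
    pbct_arm <- tryCatch(get_arm(inputs, "PbCT"), error = function(e) NULL)
    pbct <- if (!is.null(pbct_arm)) pbct_arm$schedule$acq_chemo_phase$base else
      inputs$second_line_costs$pem_platinum_per_week$base
    active <- 0.6 * (osi$base + adm_tki) +
      0.4 * ifelse(d < 12, pbct + adm_inf, bsc)
  } else if (arm$second_line_pathway == "pem_platinum_then_docetaxel") {
    pem <- inputs$second_line_costs$pem_platinum_per_week$base
    active <- ifelse(d < 12, pem + adm_inf, ifelse(d < 24, doc + adm_inf, bsc))
  } else {
    active <- ifelse(d < 12, doc + adm_inf, bsc)
  }
  u2 * active + (1 - u2) * bsc
}

# Expected per-cycle pathway cost attributed to PD occupancy. Entrants are
# followed through time-in-state with the common within-PD death probability.
# The weekly cost profile is piecewise constant with no break beyond
# .PD_TUNNEL_WEEKS (active lines end by 24 weeks after progression), so an
# exact short tunnel plus a pooled late-PD state suffices.
.PD_TUNNEL_WEEKS <- 24L

.pd_pathway_cost <- function(trace, profile) {
  H <- trace$horizon_weeks
  W <- min(.PD_TUNNEL_WEEKS, H)
  if (H > W && length(unique(profile[(W + 1):H])) > 1L) {
    stop(".pd_pathway_cost: profile not constant beyond the tunnel window",
         call. = FALSE)
  }
  c_head <- profile[seq_len(W)]
  c_tail <- if (H > W) profile[W + 1] else profile[W]
  q <- trace$q_pd_death
  e <- c(0, trace$new_pd[seq_len(H - 1)])  # entrants at start of cycle k
  tunnel <- numeric(W)                      # mass by weeks-in-state 0..W-1
  late <- 0
  out <- numeric(H)
  for (k in seq_len(H)) {
    tunnel[1] <- e[k]
    out[k] <- sum(tunnel * c_head) + late * c_tail
    s <- 1 - q[k]
    late <- (late + tunnel[W]) * s
    tunnel <- c(0, tunnel[seq_len(W - 1)] * s)
  }
  out
}

#' Accrue discounted costs, QALYs and life years over a cohort trace
#'
#' Per cycle: acquisition and administration costs while the regimen is
#' active and the cohort is progression-free; PF/PD disease-management costs
#' by occupancy; uptake-weighted second-line pathway costs by time since
#' progression (pemetrexed+platinum up to 4 cycles, then docetaxel, then BSC
#' for TKI-class arms; docetaxel then BSC for chemotherapy-class arms);
#' terminal-care cost on new deaths; one-off incidence-weighted SAE costs and
#' disutilities at model entry. QALY increment is
#' \code{(u_pf*pf + u_pd*pd)/52.18} per week; cycle-k increments are
#' discounted by \code{(1+r)^(-k/52.18)}.
#'
#' @param trace A \code{cohort_trace} produced for \code{arm}.
#' @param arm The \code{treatment_arm}.
#' @param inputs A \code{model_inputs}.
#' @param second_line "default" or "t790m" (osimertinib second line for 60\%
#'   of second-line-treated patients in TKI-class arms).
#' @return A one-row \code{ce_result} data frame: arm, cost, qaly, ly
#'   (discounted), undiscounted counterparts, and SAE-attributable cost and
#'   QALY loss.
#' @export
accrue <- function(trace, arm, inputs, second_line = "default") {
  stopifnot(inherits(trace, "cohort_trace"), identical(trace$arm, arm$name))
  H <- trace$horizon_weeks
  pf <- trace$pf[1:H]
  pd <- trace$pd[1:H]
  r <- inputs$discount_rate_annual$base
  disc <- (1 + r)^(-(0:(H - 1)) / WEEKS_PER_YEAR)

  u_pf <- inputs$utilities$u_pf$base
  u_pd <- inputs$utilities$u_pd$base
  qaly_w <- (u_pf * pf + u_pd * pd) / WEEKS_PER_YEAR
  ly_w <- (pf + pd) / WEEKS_PER_YEAR

  sch <- arm$schedule
  kk <- 0:(H - 1)
  phase1 <- if (!is.null(sch$acq_chemo_phase)) {
    if (sch$until_progression) rep(TRUE, H) else kk < sch$chemo_weeks
  } else rep(FALSE, H)
  acq_maint <- if (!is.null(sch$acq_maintenance)) sch$acq_maintenance$base else 0
  acq_phase1 <- if (!is.null(sch$acq_chemo_phase)) sch$acq_chemo_phase$base else 0
  acq_w <- ifelse(phase1, acq_phase1, acq_maint)
  adm_w <- (!is.null(sch$acq_maintenance)) * inputs$admin_costs$tki_per_week$base +
    phase1 * inputs$admin_costs$infusion_per_week$base

  mg <- inputs$management_costs
  pf_cost <- pf * (acq_w + adm_w + mg$pf_per_week$base)
  profile <- .second_line_profile(arm, inputs, H, second_line)
  pd_cost <- pd * mg$pd_per_week$base + .pd_pathway_cost(trace, profile)
  term_cost <- trace$new_dead * mg$terminal_one_off$base
  cost_w <- pf_cost + pd_cost + term_cost

  sae <- sae_burden(arm$sae, inputs$sae_costs, inputs$sae_disutilities)

  res <- data.frame(
    arm = arm$name,
    cost = sum(disc * cost_w) + sae$cost,
    qaly = sum(disc * qaly_w) - sae$qaly_loss,
    ly = sum(disc * ly_w),
    cost_undisc = sum(cost_w) + sae$cost,
    qaly_undisc = sum(qaly_w) - sae$qaly_loss,
    ly_undisc = sum(ly_w),
    sae_cost = sae$cost,
    sae_qaly_loss = -sae$qaly_loss,
    stringsAsFactors = FALSE)
  class(res) <- c("ce_result", class(res))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the deterministic base-case model for every arm
#'
#' @param inputs A \code{model_inputs}.
#' @param arms Optional character vector restricting the arms to run.
#' @param second_line Passed to \code{accrue}.
#' @return A \code{ce_results} data frame with one row per arm.
#' @export
run_all <- function(inputs, arms = NULL, second_line = "default") {
  validate_inputs(inputs)
  sel <- if (is.null(arms)) inputs$arms else lapply(arms, get_arm, inputs = inputs)
  rows <- lapply(sel, function(a) {
    accrue(build_trace(a, inputs), a, inputs, second_line = second_line)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("ce_results", "data.frame")
  rownames(res) <- NULL
  res
}
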