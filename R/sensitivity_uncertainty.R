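# Deterministic sensitivity analysis (one-way / tornado / scenarios) and
# probabilistic sensitivity analysis with CEAC construction.

# ---- parameter registry ----------------------------------------------------

#' Identifiers of all tunable parameters in a model input set
#'
#' Every \code{param_value} is addressable by a dotted id: utilities
#' ("utilities.u_pf"), cost maps ("management_costs.bsc_per_week",
#' "sae_costs.neutropenia", ...), global scalars ("second_line_uptake",
#' "discount_rate_annual"), and per-arm parameters
#' ("arms.<name>.hr_pfs", "arms.<name>.acq_maintenance", ...). The Weibull
#' reference parameters are not listed: they are sampled jointly through
#' their Cholesky factor in the PSA and are not varied one-way.
#'
#' @param inputs A \code{model_inputs}.
#' @return Character vector of parameter ids.
#' @export
param_ids <- function(inputs) {
  ids <- c(paste0("utilities.", names(inputs$utilities)),
           paste0("sae_costs.", names(inputs$sae_costs)),
           paste0("sae_disutilities.", names(inputs$sae_disutilities)),
           paste0("management_costs.", names(inputs$management_costs)),
           paste0("admin_costs.", names(inputs$admin_costs)),
           paste0("second_line_costs.", names(inputs$second_line_costs)),
           "second_line_uptake", "discount_rate_annual")
  for (a in inputs$arms) {
    if (!is.null(a$hrs)) {
      ids <- c(ids, paste0("arms.", a$name, ".hr_pfs"),
               paste0("arms.", a$name, ".hr_os"))
    }
    if (!is.null(a$schedule$acq_chemo_phase)) {
      ids <- c(ids, paste0("arms.", a$name, ".acq_chemo_phase"))
    }
    if (!is.null(a$schedule$acq_maintenance)) {
      ids <- c(ids, paste0("arms.", a$name, ".acq_maintenance"))
    }
  }
  ids
}

.parse_param_id <- function(inputs, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (parts[1] == "arms") {
    if (length(parts) < 3L) stop("unknown parameter id '", id, "'", call. = FALSE)
    nm <- paste(parts[2:(length(parts) - 1L)], collapse = ".")
    idx <- match(nm, arm_names(inputs))
    if (is.na(idx)) stop("unknown parameter id '", id, "' (no arm '", nm, "')",
                         call. = FALSE)
    list(kind = "arm", arm_index = idx, field = parts[length(parts)])
  } else if (length(parts) == 1L) {
    list(kind = "scalar", field = parts[1])
  } else {
    list(kind = "map", map = parts[1], field = paste(parts[-1], collapse = "."))
  }
}

#' Look up a parameter by id
#' @param inputs A \code{model_inputs}.
#' @param id Parameter id (see \code{param_ids}).
#' @return The \code{param_value}.
#' @export
get_param <- function(inputs, id) {
  p <- .parse_param_id(inputs, id)
  pv <- switch(p$kind,
    scalar = inputs[[p$field]],
    map = inputs[[p$map]][[p$field]],
    arm = {
      a <- inputs$arms[[p$arm_index]]
      switch(p$field,
        hr_pfs = a$hrs$pfs, hr_os = a$hrs$os,
        acq_chemo_phase = a$schedule$acq_chemo_phase,
        acq_maintenance = a$schedule$acq_maintenance,
        NULL)
    })
  if (!is_param_value(pv)) stop("unknown parameter id '", id, "'", call. = FALSE)
  pv
}

.pv_with_base <- function(pv, value) {
  param_value(value, min(pv$low, value), max(pv$high, value), pv$dist,
              check = FALSE)
}

#' Set a parameter's base value by id (returns modified inputs)
#' @param inputs A \code{model_inputs}.
#' @param id Parameter id.
#' @param value New base value.
#' @return The modified \code{model_inputs}.
#' @export
set_param <- function(inputs, id, value) {
  p <- .parse_param_id(inputs, id)
  pv <- .pv_with_base(get_param(inputs, id), value)
  switch(p$kind,
    scalar = inputs[[p$field]] <- pv,
    map = inputs[[p$map]][[p$field]] <- pv,
    arm = {
      a <- inputs$arms[[p$arm_index]]
      switch(p$field,
        hr_pfs = a$hrs$pfs <- pv,
        hr_os = a$hrs$os <- pv,
        acq_chemo_phase = a$schedule$acq_chemo_phase <- pv,
        acq_maintenance = a$schedule$acq_maintenance <- pv)
      inputs$arms[[p$arm_index]] <- a
    })
  inputs
}

# ---- one-way DSA -----------------------------------------------------------

#' One-way sensitivity analysis of an ICER
#'
#' Re-runs the deterministic model twice with the named parameter at its low
#' and high bound (bounds default to base +/- 20\% when the input set does
#' not state a range) and reports the ICER of the named comparison at each.
#' All other parameters are held at base.
#'
#' @param inputs A \code{model_inputs}.
#' @param param_id Parameter id (see \code{param_ids}).
#' @param comparison Character pair: (intervention, comparator) arm names.
#' @return List with \code{low_icer}, \code{high_icer} (numeric) and the
#'   corresponding \code{icer} statuses.
#' @export
one_way <- function(inputs, param_id,
                    comparison = c("Gefitinib+PbCT", "PfCT")) {
  stopifnot(length(comparison) == 2L)
  pv <- get_param(inputs, param_id)
  eval_at <- function(value) {
    res <- run_all(set_param(inputs, param_id, value), arms = comparison)
    icer(res[1, ], res[2, ])
  }
  lo <- eval_at(pv$low)
  hi <- eval_at(pv$high)
  list(low_icer = lo$value, high_icer = hi$value,
       low_status = lo$status, high_status = hi$status)
}

#' Tornado analysis: one-way ICER ranges for many parameters
#'
#' @inheritParams one_way
#' @param ids Parameter ids to vary (default: every parameter).
#' @return Data frame (param, low_icer, high_icer, spread) sorted by
#'   decreasing absolute spread, ready for a tornado diagram.
#' @export
tornado <- function(inputs, comparison = c("Gefitinib+PbCT", "PfCT"),
                    ids = NULL) {
  if (is.null(ids)) ids <- param_ids(inputs)
  rows <- lapply(ids, function(id) {
    ow <- one_way(inputs, id, comparison)
    data.frame(param = id, low_icer = ow$low_icer, high_icer = ow$high_icer,
               spread = abs(ow$high_icer - ow$low_icer),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}

# ---- scenarios -------------------------------------------------------------

.SCENARIOS <- c("flaura_os_update", "alt_utilities", "bnf_prices_uk",
                "t790m_osimertinib_second_line")

#' Run a registered scenario analysis
#'
#' Scenarios: \code{flaura_os_update} re-bases the osimertinib OS hazard
#' ratio versus reference chemotherapy on the mature FLAURA overall-survival
#' data (0.57, a documented stand-in reproducing the direction and magnitude
#' of the reported update); \code{alt_utilities} replaces
#' the progressed-disease utility with 0.473; \code{bnf_prices_uk} (UK only)
#' replaces eMIT-sourced gefitinib/erlotinib acquisition prices with BNF list
#' prices; \code{t790m_osimertinib_second_line} routes 60\% of
#' second-line-treated patients in TKI-class arms to osimertinib (remainder
#' to pemetrexed-based chemotherapy).
#'
#' @param inputs A \code{model_inputs}.
#' @param scenario_id One of the registered scenarios.
#' @return A \code{ce_results} data frame (as \code{run_all}).
#' @export
run_scenario <- function(inputs, scenario_id) {
  scenario_id <- match.arg(scenario_id, .SCENARIOS)
  switch(scenario_id,
    flaura_os_update = {
      if (!"Osimertinib" %in% arm_names(inputs)) {
        stop("run_scenario: no Osimertinib arm", call. = FALSE)
      }
      run_all(set_param(inputs, "arms.Osimertinib.hr_os", 0.57))
    },
    alt_utilities = run_all(set_param(inputs, "utilities.u_pd", 0.473)),
    bnf_prices_uk = {
      if (inputs$country != "UK") {
        stop("run_scenario: bnf_prices_uk is defined for the UK input set",
             call. = FALSE)
      }
      # BNF list prices replace eMIT procurement prices for the oral
      # components; combination rows shift by the same oral-price increment
      gef_bnf <- 505; erl_bnf <- 380
      ov <- list(
        c("arms.Gefitinib.acq_maintenance", gef_bnf),
        c("arms.Erlotinib.acq_maintenance", erl_bnf),
        c("arms.Gefitinib+Pemetrexed.acq_maintenance", gef_bnf),
        c("arms.Gefitinib+Pemetrexed.acq_chemo_phase", 510 - 66 + gef_bnf),
        c("arms.Gefitinib+PbCT.acq_maintenance", gef_bnf),
        c("arms.Gefitinib+PbCT.acq_chemo_phase", 526 - 66 + gef_bnf),
        c("arms.Erlotinib+Bevacizumab.acq_maintenance", erl_bnf),
        c("arms.Erlotinib+Bevacizumab.acq_chemo_phase", 999 - 121 + erl_bnf))
      for (o in ov) inputs <- set_param(inputs, o[[1]], as.numeric(o[[2]]))
      run_all(inputs)
    },
    t790m_osimertinib_second_line = run_all(inputs, second_line = "t790m"))
}

# ---- probabilistic sensitivity analysis ------------------------------------

.draw_weibull <- function(w) {
  if (is.null(w$log_chol)) return(w)
  z <- stats::rnorm(2)
  lp <- log(c(w$scale, w$shape)) + as.vector(w$log_chol %*% z)
  weibull_params(exp(lp[1]), exp(lp[2]), w$log_chol)
}

#' Draw one probabilistic realisation of a model input set
#'
#' Gamma draws for costs, lognormal for hazard ratios, beta for utilities and
#' proportions, uniform for the discount rate; the Weibull reference
#' parameters are drawn jointly on the log scale through their stored
#' Cholesky factor. The life table and SAE incidence proportions are held
#' fixed. Reproducible for a given seed.
#'
#' @param inputs A \code{model_inputs}.
#' @param rng_seed Integer seed.
#' @return A \code{model_inputs} with every sampled parameter's base replaced
#'   by its draw.
#' @export
sample_params <- function(inputs, rng_seed) {
  set.seed(rng_seed)
  si <- inputs
  si$pfs_ref <- .draw_weibull(inputs$pfs_ref)
  si$os_ref <- .draw_weibull(inputs$os_ref)
  for (id in param_ids(inputs)) {
    pv <- get_param(inputs, id)
    if (pv$dist$family == "fixed") next
    si <- set_param(si, id, draw_param(pv))
  }
  si
}

#' Run the probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: \code{n} independent parameter draws, each
#' followed by a full deterministic model run. A master seed spawns one
#' sub-seed per iteration (recorded in the output) so any iteration can be
#' replayed with \code{sample_params}.
#'
#' @param inputs A \code{model_inputs}.
#' @param n Number of iterations (the reference analysis uses 5000).
#' @param seed Master RNG seed.
#' @param arms Optional arm subset.
#' @return A \code{psa_samples} data frame (iteration, arm, cost, qaly) with
#'   attribute \code{seeds} holding the per-iteration sub-seeds.
#' @export
run_psa <- function(inputs, n = 5000L, seed = 1L, arms = NULL) {
  stopifnot(n >= 1L)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    si <- sample_params(inputs, iter_seeds[i])
    res <- run_all(si, arms = arms)
    rows[[i]] <- data.frame(iteration = i, arm = res$arm, cost = res$cost,
                            qaly = res$qaly, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "seeds") <- iter_seeds
  class(out) <- c("psa_samples", "data.frame")
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which each arm attains the maximum net monetary benefit (exact ties split
#' equally).
#'
#' @param samples A \code{psa_samples} data frame.
#' @param thresholds Numeric threshold grid (currency per QALY).
#' @return A \code{ceac_curve} data frame (threshold, arm, probability);
#'   probabilities sum to 1 across arms at every threshold.
#' @export
ceac <- function(samples, thresholds) {
  stopifnot(nrow(samples) > 0, length(thresholds) > 0)
  arms <- unique(samples$arm)
  iters <- sort(unique(samples$iteration))
  key_i <- match(samples$iteration, iters)
  key_a <- match(samples$arm, arms)
  C <- Q <- matrix(NA_real_, length(iters), length(arms))
  C[cbind(key_i, key_a)] <- samples$cost
  Q[cbind(key_i, key_a)] <- samples$qaly
  rows <- lapply(thresholds, function(thr) {
    N <- thr * Q - C
    best <- N == apply(N, 1, max)
    w <- best / rowSums(best)
    data.frame(threshold = thr, arm = arms, probability = colMeans(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ceac_curve", "data.frame")
  out
}
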