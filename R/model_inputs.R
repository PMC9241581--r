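# Country-specific model inputs: treatment arms, costs, utilities, survival
# reference curves, and validated JSON I/O.

#' Serious adverse event types tracked by the model
#' @export
SAE_EVENTS <- c("neutropenia", "hypertension", "rash", "anaemia", "diarrhoea",
                "leukopenia", "thrombocytopenia", "dermatitis", "fatigue",
                "nausea_vomiting", "hair_loss", "febrile_neutropenia")

#' Treatment regimen schedule
#'
#' Weekly acquisition costing for a first-line regimen. During the
#' chemotherapy / monoclonal-antibody phase the regimen is charged at
#' \code{acq_chemo_phase} per weekly cycle; outside it (oral TKI maintenance,
#' until progression) at \code{acq_maintenance}. Chemotherapy phases last
#' \code{chemo_weeks} weeks (4 three-week cycles = 12 weeks); antibody
#' components run until progression (\code{until_progression}).
#'
#' @param acq_chemo_phase \code{param_value} weekly acquisition cost during the
#'   infusion phase, or NULL when the regimen has no infusion component.
#' @param acq_maintenance \code{param_value} weekly acquisition cost of the
#'   oral component (until progression), or NULL for chemotherapy-only arms.
#' @param chemo_weeks Length of the chemotherapy phase in weeks (0 if none).
#' @param until_progression TRUE when the infusion component continues until
#'   progression (monoclonal antibodies).
#' @return A \code{regimen_schedule} object.
#' @export
regimen_schedule <- function(acq_chemo_phase = NULL, acq_maintenance = NULL,
                             chemo_weeks = 0L, until_progression = FALSE) {
  if (!is.null(acq_chemo_phase)) stopifnot(is_param_value(acq_chemo_phase))
  if (!is.null(acq_maintenance)) stopifnot(is_param_value(acq_maintenance))
  if (is.null(acq_chemo_phase) && is.null(acq_maintenance)) {
    stop("regimen_schedule: at least one acquisition component required", call. = FALSE)
  }
  chemo_weeks <- as.integer(chemo_weeks)
  if (chemo_weeks < 0L) stop("regimen_schedule: chemo_weeks must be >= 0", call. = FALSE)
  structure(list(acq_chemo_phase = acq_chemo_phase,
                 acq_maintenance = acq_maintenance,
                 chemo_weeks = chemo_weeks,
                 until_progression = isTRUE(until_progression)),
            class = "regimen_schedule")
}

#' Define a treatment arm
#'
#' @param name Arm identifier (unique within a model input set).
#' @param schedule A \code{regimen_schedule}.
#' @param hrs List with \code{pfs} and \code{os} \code{param_value} hazard
#'   ratios versus the reference arm; NULL for the reference arm itself.
#' @param sae Named numeric vector of grade 3/4 SAE incidence proportions
#'   over \code{SAE_EVENTS} (missing events default to 0).
#' @param second_line_pathway "pem_platinum_then_docetaxel" (TKI and
#'   TKI+antibody arms) or "docetaxel_only" (chemotherapy and
#'   TKI+chemotherapy arms).
#' @return A \code{treatment_arm} object.
#' @export
treatment_arm <- function(name, schedule, hrs = NULL, sae = numeric(0),
                          second_line_pathway = c("pem_platinum_then_docetaxel",
                                                  "docetaxel_only")) {
  stopifnot(is.character(name), nchar(name) > 0, inherits(schedule, "regimen_schedule"))
  second_line_pathway <- match.arg(second_line_pathway)
  if (!is.null(hrs)) {
    stopifnot(is.list(hrs), is_param_value(hrs$pfs), is_param_value(hrs$os))
    if (hrs$pfs$base <= 0 || hrs$os$base <= 0) {
      stop("treatment_arm: hazard-ratio bases must be positive", call. = FALSE)
    }
  }
  prof <- stats::setNames(rep(0, length(SAE_EVENTS)), SAE_EVENTS)
  if (length(sae)) {
    unknown <- setdiff(names(sae), SAE_EVENTS)
    if (length(unknown)) {
      stop("treatment_arm: unknown SAE event(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(sae < 0 | sae > 1)) {
      stop("treatment_arm: SAE incidences must lie in [0, 1]", call. = FALSE)
    }
    prof[names(sae)] <- sae
  }
  structure(list(name = name, schedule = schedule, hrs = hrs, sae = prof,
                 second_line_pathway = second_line_pathway),
            class = "treatment_arm")
}

#' Assemble a complete country-specific model input set
#'
#' @param country "UK" or "China".
#' @param arms List of \code{treatment_arm}s, exactly one of which (the
#'   reference) has no hazard ratios.
#' @param reference_arm Name of the reference arm.
#' @param pfs_ref,os_ref Reference-arm \code{weibull_params} for
#'   progression-free and overall survival (months time scale).
#' @param utilities List of \code{param_value}s \code{u_pf}, \code{u_pd}.
#' @param sae_costs,sae_disutilities Named lists of \code{param_value}s over
#'   \code{SAE_EVENTS} (per-event management cost; one-off utility decrement).
#' @param management_costs List of \code{param_value}s \code{pf_per_week},
#'   \code{pd_per_week}, \code{bsc_per_week}, \code{terminal_one_off}.
#' @param admin_costs List of \code{param_value}s \code{tki_per_week},
#'   \code{infusion_per_week}.
#' @param second_line_costs List of \code{param_value}s
#'   \code{pem_platinum_per_week}, \code{docetaxel_per_week} and optionally
#'   \code{osimertinib_per_week} (used by the T790M scenario).
#' @param second_line_uptake \code{param_value}: proportion of progressing
#'   patients receiving active second-line treatment.
#' @param start_age Cohort age at model entry (years).
#' @param discount_rate_annual \code{param_value} annual discount rate.
#' @param wtp_low,wtp_high Willingness-to-pay bounds (currency per QALY).
#' @param life_table A \code{life_table} for background mortality.
#' @param horizon_weeks Model horizon in weekly cycles (default 1043, i.e.
#'   20 years labelled "lifetime").
#' @param meta Optional free-form metadata list (e.g. currency note).
#' @return A validated \code{model_inputs} object.
#' @export
model_inputs <- function(country, arms, reference_arm, pfs_ref, os_ref,
                         utilities, sae_costs, sae_disutilities,
                         management_costs, admin_costs, second_line_costs,
                         second_line_uptake, start_age, discount_rate_annual,
                         wtp_low, wtp_high, life_table, horizon_weeks = 1043L,
                         meta = list()) {
  inputs <- structure(list(
    country = match.arg(country, c("UK", "China")),
    arms = arms, reference_arm = reference_arm,
    pfs_ref = pfs_ref, os_ref = os_ref,
    utilities = utilities, sae_costs = sae_costs,
    sae_disutilities = sae_disutilities,
    management_costs = management_costs, admin_costs = admin_costs,
    second_line_costs = second_line_costs,
    second_line_uptake = second_line_uptake,
    start_age = as.numeric(start_age),
    discount_rate_annual = discount_rate_annual,
    wtp_low = as.numeric(wtp_low), wtp_high = as.numeric(wtp_high),
    life_table = life_table, horizon_weeks = as.integer(horizon_weeks),
    meta = meta), class = "model_inputs")
  validate_inputs(inputs)
  inputs
}

#' Validate a model input set
#'
#' Checks structural invariants (unique arm names, single reference arm,
#' complete SAE cost/disutility maps, utilities and proportions in [0, 1],
#' non-negative costs, discount rate in [0, 0.2]) and the transcription
#' consistency of every parameter's distribution against its base value.
#'
#' @param inputs A \code{model_inputs}.
#' @return \code{inputs}, invisibly; errors name the offending field.
#' @export
validate_inputs <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  fail <- function(...) stop("validate_inputs: ", ..., call. = FALSE)
  if (!length(inputs$arms)) fail("no arms")
  if (!all(vapply(inputs$arms, inherits, logical(1), "treatment_arm"))) {
    fail("arms must be treatment_arm objects")
  }
  nm <- vapply(inputs$arms, `[[`, character(1), "name")
  if (anyDuplicated(nm)) fail("duplicate arm name: ", nm[duplicated(nm)][1])
  if (!inputs$reference_arm %in% nm) fail("reference_arm '", inputs$reference_arm, "' not among arms")
  is_ref <- vapply(inputs$arms, function(a) is.null(a$hrs), logical(1))
  if (sum(is_ref) != 1L || nm[is_ref] != inputs$reference_arm) {
    fail("exactly the reference arm must lack hazard ratios")
  }
  if (!inherits(inputs$pfs_ref, "weibull_params")) fail("pfs_ref must be weibull_params")
  if (!inherits(inputs$os_ref, "weibull_params")) fail("os_ref must be weibull_params")
  for (u in c("u_pf", "u_pd")) {
    pv <- inputs$utilities[[u]]
    if (!is_param_value(pv)) fail("utilities$", u, " missing")
    if (pv$base < 0 || pv$base > 1) fail("utilities$", u, " outside [0, 1]")
  }
  for (map in c("sae_costs", "sae_disutilities")) {
    missing <- setdiff(SAE_EVENTS, names(inputs[[map]]))
    if (length(missing)) fail(map, " missing event(s): ", paste(missing, collapse = ", "))
    if (!all(vapply(inputs[[map]][SAE_EVENTS], is_param_value, logical(1)))) {
      fail(map, " entries must be param_value objects")
    }
  }
  for (f in c("pf_per_week", "pd_per_week", "bsc_per_week", "terminal_one_off")) {
    pv <- inputs$management_costs[[f]]
    if (!is_param_value(pv)) fail("management_costs$", f, " missing")
    if (pv$base < 0) fail("management_costs$", f, " negative")
  }
  for (f in c("tki_per_week", "infusion_per_week")) {
    if (!is_param_value(inputs$admin_costs[[f]])) fail("admin_costs$", f, " missing")
  }
  for (f in c("pem_platinum_per_week", "docetaxel_per_week")) {
    if (!is_param_value(inputs$second_line_costs[[f]])) fail("second_line_costs$", f, " missing")
  }
  up <- inputs$second_line_uptake
  if (!is_param_value(up) || up$base < 0 || up$base > 1) {
    fail("second_line_uptake must be a param_value in [0, 1]")
  }
  dr <- inputs$discount_rate_annual
  if (!is_param_value(dr) || dr$base < 0 || dr$base > 0.2) {
    fail("discount_rate_annual must be a param_value in [0, 0.2]")
  }
  if (!inherits(inputs$life_table, "life_table")) fail("life_table missing")
  if (inputs$start_age < inputs$life_table$age[1]) {
    fail("start_age below life-table minimum age")
  }
  if (inputs$horizon_weeks < 1L) fail("horizon_weeks must be >= 1")
  invisible(inputs)
}

#' @export
print.model_inputs <- function(x, ...) {
  cat(sprintf("model_inputs[%s]: %d arms (reference %s), start age %.1f, r=%.3f, horizon %d weeks\n",
              x$country, length(x$arms), x$reference_arm, x$start_age,
              x$discount_rate_annual$base, x$horizon_weeks))
  invisible(x)
}

#' Names of the arms in a model input set
#' @param inputs A \code{model_inputs}.
#' @return Character vector.
#' @export
arm_names <- function(inputs) vapply(inputs$arms, `[[`, character(1), "name")

#' Retrieve an arm by name
#' @param inputs A \code{model_inputs}.
#' @param name Arm name.
#' @return A \code{treatment_arm}.
#' @export
get_arm <- function(inputs, name) {
  i <- match(name, arm_names(inputs))
  if (is.na(i)) stop("get_arm: no arm named '", name, "'", call. = FALSE)
  inputs$arms[[i]]
}

# ---- JSON serialisation ----------------------------------------------------

.pv_to_list <- function(pv) {
  if (is.null(pv)) return(NULL)
  list(base = pv$base, low = pv$low, high = pv$high,
       dist = list(family = pv$dist$family, params = pv$dist$params))
}

.pv_from_list <- function(x, field = "<param>") {
  if (is.null(x)) return(NULL)
  for (f in c("base", "low", "high", "dist")) {
    if (is.null(x[[f]])) stop("load_inputs: field '", field, "' missing '", f, "'",
                              call. = FALSE)
  }
  dist <- do.call(dist_spec, c(list(family = x$dist$family),
                               lapply(x$dist$params, as.numeric)))
  tryCatch(param_value(x$base, x$low, x$high, dist,
                       check = !isTRUE(x$no_check)),
           error = function(e) stop("load_inputs: field '", field, "': ",
                                    conditionMessage(e), call. = FALSE))
}

.wb_to_list <- function(w) {
  list(scale = w$scale, shape = w$shape,
       log_chol = if (!is.null(w$log_chol)) as.vector(w$log_chol))
}

.wb_from_list <- function(x) {
  weibull_params(x$scale, x$shape,
                 if (!is.null(x$log_chol)) matrix(as.numeric(x$log_chol), 2, 2))
}

#' Write a model input set to JSON
#'
#' The file embeds the life table, so \code{load_inputs} on the result
#' reproduces every field (round-trip identity).
#'
#' @param inputs A \code{model_inputs}.
#' @param path Output JSON path.
#' @export
write_inputs <- function(inputs, path) {
  validate_inputs(inputs)
  pv_map <- function(lst) lapply(lst, .pv_to_list)
  obj <- list(
    country = inputs$country,
    reference_arm = inputs$reference_arm,
    pfs_ref = .wb_to_list(inputs$pfs_ref),
    os_ref = .wb_to_list(inputs$os_ref),
    utilities = pv_map(inputs$utilities),
    sae_costs = pv_map(inputs$sae_costs),
    sae_disutilities = pv_map(inputs$sae_disutilities),
    management_costs = pv_map(inputs$management_costs),
    admin_costs = pv_map(inputs$admin_costs),
    second_line_costs = pv_map(inputs$second_line_costs),
    second_line_uptake = .pv_to_list(inputs$second_line_uptake),
    start_age = inputs$start_age,
    discount_rate_annual = c(.pv_to_list(inputs$discount_rate_annual),
                             list(no_check = TRUE)),
    wtp_low = inputs$wtp_low, wtp_high = inputs$wtp_high,
    horizon_weeks = inputs$horizon_weeks,
    life_table = list(age = inputs$life_table$age, qx = inputs$life_table$qx),
    meta = inputs$meta,
    arms = lapply(inputs$arms, function(a) {
      list(name = a$name,
           schedule = list(
             acq_chemo_phase = .pv_to_list(a$schedule$acq_chemo_phase),
             acq_maintenance = .pv_to_list(a$schedule$acq_maintenance),
             chemo_weeks = a$schedule$chemo_weeks,
             until_progression = a$schedule$until_progression),
           hrs = if (!is.null(a$hrs)) list(pfs = .pv_to_list(a$hrs$pfs),
                                           os = .pv_to_list(a$hrs$os)),
           sae = as.list(a$sae),
           second_line_pathway = a$second_line_pathway)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a model input set from JSON
#'
#' Applies full validation, including the transcription check that every
#' parameter's distribution central value agrees with its base value.
#'
#' @param path JSON file written by \code{write_inputs} (schema documented
#'   there).
#' @param country Optional expected country; mismatch is an error.
#' @return A validated \code{model_inputs}.
#' @export
load_inputs <- function(path, country = NULL) {
  if (!file.exists(path)) stop("load_inputs: no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("country", "reference_arm", "pfs_ref", "os_ref", "utilities",
              "arms", "life_table", "horizon_weeks")) {
    if (is.null(obj[[f]])) stop("load_inputs: missing top-level field '", f, "'",
                                call. = FALSE)
  }
  if (!is.null(country) && !identical(obj$country, country)) {
    stop("load_inputs: file is for ", obj$country, ", expected ", country,
         call. = FALSE)
  }
  pv_map <- function(lst, prefix) {
    stats::setNames(lapply(names(lst), function(nm)
      .pv_from_list(lst[[nm]], paste0(prefix, ".", nm))), names(lst))
  }
  arms <- lapply(obj$arms, function(a) {
    treatment_arm(
      name = a$name,
      schedule = regimen_schedule(
        acq_chemo_phase = .pv_from_list(a$schedule$acq_chemo_phase,
                                        paste0("arms.", a$name, ".acq_chemo_phase")),
        acq_maintenance = .pv_from_list(a$schedule$acq_maintenance,
                                        paste0("arms.", a$name, ".acq_maintenance")),
        chemo_weeks = a$schedule$chemo_weeks,
        until_progression = isTRUE(a$schedule$until_progression)),
      hrs = if (!is.null(a$hrs)) list(
        pfs = .pv_from_list(a$hrs$pfs, paste0("arms.", a$name, ".hr_pfs")),
        os = .pv_from_list(a$hrs$os, paste0("arms.", a$name, ".hr_os"))),
      sae = unlist(a$sae),
      second_line_pathway = a$second_line_pathway)
  })
  model_inputs(
    country = obj$country, arms = arms, reference_arm = obj$reference_arm,
    pfs_ref = .wb_from_list(obj$pfs_ref), os_ref = .wb_from_list(obj$os_ref),
    utilities = pv_map(obj$utilities, "utilities"),
    sae_costs = pv_map(obj$sae_costs, "sae_costs"),
    sae_disutilities = pv_map(obj$sae_disutilities, "sae_disutilities"),
    management_costs = pv_map(obj$management_costs, "management_costs"),
    admin_costs = pv_map(obj$admin_costs, "admin_costs"),
    second_line_costs = pv_map(obj$second_line_costs, "second_line_costs"),
    second_line_uptake = .pv_from_list(obj$second_line_uptake, "second_line_uptake"),
    start_age = obj$start_age,
    discount_rate_annual = .pv_from_list(obj$discount_rate_annual,
                                         "discount_rate_annual"),
    wtp_low = obj$wtp_low, wtp_high = obj$wtp_high,
    life_table = life_table(unlist(obj$life_table$age), unlist(obj$life_table$qx)),
    horizon_weeks = obj$horizon_weeks,
    meta = obj$meta)
}
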