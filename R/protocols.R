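# Treatment controllers: noisy burden measurement, response classification,
# the six dosing protocols, treatment vacations and dose clamping.
#
# Controllers see only the noisy measured burden (initiation, response
# classification, vacations, the running maximum); true cell counts are used
# only for progression scoring in the engine.

#' Protocol identifiers
#'
#' `"ST"` continuous MTD cocktail; `"DM_COCKTAIL"` dose-modulation of both
#' drugs in tandem; `"DM_PP_ALT"` ping-pong alternating drugs every cycle;
#' `"DM_PP_PROG"` ping-pong switching drugs on progression; `"FD_SKIP"`
#' fixed dose applied only when the tumor grows; `"FD_INT"` fixed dose with
#' on/off hysteresis on the absolute burden.
#'
#' @return Character vector of the six protocol ids.
#' @export
protocol_ids <- function() {
  c("ST", "DM_COCKTAIL", "DM_PP_ALT", "DM_PP_PROG", "FD_SKIP", "FD_INT")
}

#' Treatment-protocol configuration
#'
#' @param protocol One of [protocol_ids()].
#' @param delta_tumor Relative burden change that triggers a dose change
#'   (fraction).
#' @param delta_dose Multiplicative dose adjustment (fraction): doses scale
#'   by `1 + delta_dose` on growth and `1 - delta_dose` on shrinkage,
#'   relative to the last administered dose of the same drug.
#' @param vacation_threshold Measured burden (cells) at or below which DM
#'   protocols suspend dosing for the cycle.
#' @param fd_dose Fixed dose per drug for the FD protocols (units; 75% of
#'   the cocktail MTD by default).
#' @param fd_stop_fraction FD Intermittent stops once the burden has fallen
#'   by this fraction of the initiation burden.
#' @param fd_restart_fraction FD Intermittent restarts once the burden
#'   reaches this fraction of the initiation burden.
#' @param measurement_period Hours between burden measurements (3 days).
#' @param measurement_noise_sd Gaussian SD of the burden measurement (cells).
#' @param initiation_threshold Measured burden (cells) that starts treatment.
#' @param mtd_single MTD of one drug administered alone (units), the cap for
#'   ping-pong protocols.
#' @param mtd_combo MTD per drug in a cocktail (units), the cap for cocktail
#'   protocols.
#' @param min_dose Smallest non-zero dose (units); DM adjustments are floored
#'   here.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(protocol = "DM_COCKTAIL",
                            delta_tumor = 0.1, delta_dose = 0.5,
                            vacation_threshold = 2500,
                            fd_dose = 2.25,
                            fd_stop_fraction = 0.5, fd_restart_fraction = 1,
                            measurement_period = 72,
                            measurement_noise_sd = 5,
                            initiation_threshold = 5000,
                            mtd_single = 5, mtd_combo = 3, min_dose = 0.5) {
  protocol <- match.arg(protocol, protocol_ids())
  if (delta_tumor <= 0 || delta_dose <= 0)
    stop("delta_tumor and delta_dose must be positive")
  if (measurement_noise_sd < 0) stop("measurement_noise_sd must be non-negative")
  if (fd_stop_fraction < 0 || fd_stop_fraction > 1 || fd_restart_fraction < 0)
    stop("fd_stop_fraction must lie in [0, 1] and fd_restart_fraction be non-negative")
  if (vacation_threshold >= initiation_threshold)
    stop("vacation_threshold must be below initiation_threshold")
  structure(list(protocol = protocol, delta_tumor = delta_tumor,
                 delta_dose = delta_dose,
                 vacation_threshold = vacation_threshold, fd_dose = fd_dose,
                 fd_stop_fraction = fd_stop_fraction,
                 fd_restart_fraction = fd_restart_fraction,
                 measurement_period = measurement_period,
                 measurement_noise_sd = measurement_noise_sd,
                 initiation_threshold = initiation_threshold,
                 mtd_single = mtd_single, mtd_combo = mtd_combo,
                 min_dose = min_dose),
            class = "protocol_config")
}

#' Fresh controller state
#'
#' The controller's evolving memory: whether treatment has started, the
#' burden at initiation, the last measurement, the running maximum of
#' measured burden since initiation, the last administered dose of each drug
#' (and the measured burden when each drug last began a cycle, for
#' ping-pong), the active drug, the FD-Intermittent on/off flag and the
#' vacation flag.
#'
#' @return A list of class `controller_state`.
#' @export
controller_state <- function() {
  structure(list(treatment_started = FALSE, t_init = NA_integer_,
                 initiation_burden = NA_real_, last_measured = NA_real_,
                 max_burden = -Inf, last_dose = c(NA_real_, NA_real_),
                 burden_at_last_use = c(NA_real_, NA_real_),
                 active_drug = NA_integer_, fd_dosing_on = FALSE,
                 on_vacation = FALSE),
            class = "controller_state")
}

#' Noisy burden measurement
#'
#' Gaussian measurement error around the true count, rounded to whole cells
#' and clamped at zero.
#'
#' @param true_count True number of tumor cells.
#' @param sd Measurement noise SD in cells.
#' @return Measured burden (non-negative integer-valued).
#' @export
measure_burden <- function(true_count, sd = 5) {
  if (true_count < 0) stop("true_count must be non-negative")
  max(0, round(rnorm(1, mean = true_count, sd = sd)))
}

#' Classify the tumor's response between two measurements
#'
#' `GREW` if the relative increase exceeds `delta_tumor`; `SHRANK` if the
#' relative decrease is at least `delta_tumor`; `STABLE` otherwise.
#'
#' @param previous,current Measured burdens (cells); `previous` must be
#'   positive.
#' @param delta_tumor Relative-change threshold (fraction).
#' @return One of `"GREW"`, `"SHRANK"`, `"STABLE"`.
#' @export
#' @examples
#' classify_response(5000, 5600, 0.10)  # GREW
classify_response <- function(previous, current, delta_tumor = 0.1) {
  if (previous <= 0) stop("previous burden must be positive")
  change <- (current - previous) / previous
  if (change > delta_tumor) "GREW"
  else if (-change >= delta_tumor) "SHRANK"
  else "STABLE"
}

# Response since the last measurement, with the maximum-tolerable-burden
# override: exceeding the running maximum counts as growth.
response_with_override <- function(previous, measured, state, cfg) {
  resp <- classify_response(previous, measured, cfg$delta_tumor)
  if (measured > state$max_burden) resp <- "GREW"
  resp
}

# Clamp a non-zero dose into [min_dose, cap].
clamp_dose <- function(dose, cap, min_dose) {
  ifelse(dose > 0, pmin(pmax(dose, min_dose), cap), 0)
}

#' Treatment vacation and dose clamping (DM protocols)
#'
#' If the measured burden is at or below the vacation threshold, no drug is
#' given this cycle (the dose memory is frozen by the caller). Otherwise
#' non-zero doses are clamped into `[min_dose, cap]`.
#'
#' @param decision Length-2 proposed doses.
#' @param measured Measured burden (cells).
#' @param cfg A [protocol_config()].
#' @param state A [controller_state()] (unused fields reserved).
#' @param cap Applicable MTD (defaults to the cocktail MTD).
#' @return Length-2 dose vector.
#' @export
apply_vacation_and_clamp <- function(decision, measured, cfg,
                                     state = controller_state(),
                                     cap = cfg$mtd_combo) {
  if (measured <= cfg$vacation_threshold) return(c(0, 0))
  clamp_dose(decision, cap, cfg$min_dose)
}

#' Protocol decision rules
#'
#' One function per protocol, each mapping the controller state and the
#' current measured burden to the doses administered at every daily
#' application of the coming cycle, plus the updated state. `decide_st()`
#' always returns the cocktail MTD for both drugs. The dose-modulation
#' protocols scale doses by `1 +/- delta_dose` according to the response
#' classification (growth beyond the running maximum also counts as growth),
#' clamp to `[min_dose, MTD]`, and take a treatment vacation while the
#' measured burden sits at or below the vacation threshold: no drug is
#' administered that cycle, but the modulation bookkeeping (dose memory,
#' drug switching) continues so dosing resumes at the walked-down dose.
#' The ping-pong variants administer a single drug at a time, capped
#' at the single-drug MTD. The fixed-dose protocols emit `fd_dose` of both
#' drugs or nothing.
#'
#' @param state A [controller_state()] with `treatment_started = TRUE`.
#' @param measured Current measured burden (cells).
#' @param cfg A [protocol_config()].
#' @return `decide_st()` returns a length-2 dose vector; the others return
#'   `list(decision, state)`.
#' @name protocol_decisions
NULL

#' @rdname protocol_decisions
#' @export
decide_st <- function(state, cfg) {
  if (!state$treatment_started) return(c(0, 0))
  c(cfg$mtd_combo, cfg$mtd_combo)
}

#' @rdname protocol_decisions
#' @export
decide_dm_cocktail <- function(state, measured, cfg) {
  resp <- response_with_override(state$last_measured, measured, state, cfg)
  dose <- state$last_dose[1]
  if (resp == "GREW") dose <- dose * (1 + cfg$delta_dose)
  else if (resp == "SHRANK") dose <- dose * (1 - cfg$delta_dose)
  dose <- clamp_dose(dose, cfg$mtd_combo, cfg$min_dose)
  # modulation bookkeeping continues during a vacation; only administration
  # is suspended
  state$last_dose <- c(dose, dose)
  state$on_vacation <- measured <= cfg$vacation_threshold
  decision <- apply_vacation_and_clamp(c(dose, dose), measured, cfg, state,
                                       cap = cfg$mtd_combo)
  list(decision = decision, state = state)
}

#' @rdname protocol_decisions
#' @export
decide_dm_pingpong_alternate <- function(state, measured, cfg) {
  incoming <- 3L - state$active_drug
  if (is.na(state$burden_at_last_use[incoming])) {
    dose <- cfg$mtd_single  # first use of this drug
  } else {
    resp <- response_with_override(state$burden_at_last_use[incoming],
                                   measured, state, cfg)
    dose <- state$last_dose[incoming]
    if (resp == "GREW") dose <- dose * (1 + cfg$delta_dose)
    else if (resp == "SHRANK") dose <- dose * (1 - cfg$delta_dose)
  }
  dose <- clamp_dose(dose, cfg$mtd_single, cfg$min_dose)
  state$active_drug <- incoming
  state$last_dose[incoming] <- dose
  state$burden_at_last_use[incoming] <- measured
  state$on_vacation <- measured <= cfg$vacation_threshold
  decision <- c(0, 0); decision[incoming] <- dose
  decision <- apply_vacation_and_clamp(decision, measured, cfg, state,
                                       cap = cfg$mtd_single)
  list(decision = decision, state = state)
}

#' @rdname protocol_decisions
#' @export
decide_dm_pingpong_progression <- function(state, measured, cfg) {
  resp <- response_with_override(state$last_measured, measured, state, cfg)
  drug <- state$active_drug
  if (resp == "GREW") {
    drug <- 3L - drug  # progression on the current drug: switch
    dose <- if (is.na(state$last_dose[drug])) cfg$mtd_single
            else state$last_dose[drug] * (1 + cfg$delta_dose)
  } else if (resp == "SHRANK") {
    dose <- state$last_dose[drug] * (1 - cfg$delta_dose)
  } else {
    dose <- state$last_dose[drug]
  }
  dose <- clamp_dose(dose, cfg$mtd_single, cfg$min_dose)
  state$active_drug <- drug
  state$last_dose[drug] <- dose
  state$on_vacation <- measured <= cfg$vacation_threshold
  decision <- c(0, 0); decision[drug] <- dose
  decision <- apply_vacation_and_clamp(decision, measured, cfg, state,
                                       cap = cfg$mtd_single)
  list(decision = decision, state = state)
}

#' @rdname protocol_decisions
#' @export
decide_fd_doseskip <- function(state, measured, cfg) {
  resp <- response_with_override(state$last_measured, measured, state, cfg)
  decision <- if (resp == "GREW") c(cfg$fd_dose, cfg$fd_dose) else c(0, 0)
  list(decision = decision, state = state)
}

#' @rdname protocol_decisions
#' @export
decide_fd_intermittent <- function(state, measured, cfg) {
  stop_at <- (1 - cfg$fd_stop_fraction) * state$initiation_burden
  restart_at <- cfg$fd_restart_fraction * state$initiation_burden
  if (state$fd_dosing_on && measured <= stop_at) state$fd_dosing_on <- FALSE
  else if (!state$fd_dosing_on && measured >= restart_at) state$fd_dosing_on <- TRUE
  decision <- if (state$fd_dosing_on) c(cfg$fd_dose, cfg$fd_dose) else c(0, 0)
  list(decision = decision, state = state)
}

#' Controller update at a measurement time
#'
#' Measures the burden with noise; before initiation, starts treatment once
#' the measured burden reaches the initiation threshold (ST and DM Cocktail
#' begin at the cocktail MTD of both drugs, ping-pong protocols with drug 1
#' at the single-drug MTD, FD protocols at the fixed dose). After initiation
#' it dispatches to the protocol's decision rule and updates the measurement
#' memory and running maximum.
#'
#' @param state A [controller_state()].
#' @param true_burden True tumor cell count.
#' @param cfg A [protocol_config()].
#' @return `list(decision, state)`: the doses for each daily application of
#'   the coming cycle, and the updated state.
#' @export
controller_update <- function(state, true_burden, cfg) {
  measured <- measure_burden(true_burden, cfg$measurement_noise_sd)

  if (!state$treatment_started) {
    if (measured < cfg$initiation_threshold)
      return(list(decision = c(0, 0), state = state))
    state$treatment_started <- TRUE
    state$initiation_burden <- measured
    state$last_measured <- measured
    state$max_burden <- measured
    decision <- switch(cfg$protocol,
      ST = , DM_COCKTAIL = {
        state$last_dose <- c(cfg$mtd_combo, cfg$mtd_combo)
        c(cfg$mtd_combo, cfg$mtd_combo)
      },
      DM_PP_ALT = , DM_PP_PROG = {
        state$active_drug <- 1L
        state$last_dose[1] <- cfg$mtd_single
        state$burden_at_last_use[1] <- measured
        c(cfg$mtd_single, 0)
      },
      FD_SKIP = c(cfg$fd_dose, cfg$fd_dose),
      FD_INT = {
        state$fd_dosing_on <- TRUE
        c(cfg$fd_dose, cfg$fd_dose)
      },
      stop("unknown protocol: ", cfg$protocol))
    return(list(decision = decision, state = state))
  }

  upd <- switch(cfg$protocol,
    ST = list(decision = decide_st(state, cfg), state = state),
    DM_COCKTAIL = decide_dm_cocktail(state, measured, cfg),
    DM_PP_ALT = decide_dm_pingpong_alternate(state, measured, cfg),
    DM_PP_PROG = decide_dm_pingpong_progression(state, measured, cfg),
    FD_SKIP = decide_fd_doseskip(state, measured, cfg),
    FD_INT = decide_fd_intermittent(state, measured, cfg),
    stop("unknown protocol: ", cfg$protocol))
  upd$state$max_burden <- max(upd$state$max_burden, measured)
  upd$state$last_measured <- measured
  upd
}
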