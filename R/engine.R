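# Scheduler and replicate harness. Each step is one hour: the drug field is
# updated first (dose if scheduled, diffuse, decay), then every cell present
# at the start of the hour is visited in a fresh random order (death, then
# possible division with mutation of the daughter). Dose decisions are made
# every measurement cycle (72 h) and administered once every 24 h, anchored
# to treatment initiation. Simulations always run the full horizon;
# progression is a recorded event, not a stopping rule, so drug usage is
# accounted over the same amount of time in every arm.

#' Simulation configuration
#'
#' Bundles every model parameter with its default value. The carrying
#' capacity is the number of lattice sites; the initiation and vacation
#' thresholds default to 50% and 25% of capacity.
#'
#' @param width,height Lattice dimensions (sites).
#' @param duration Number of hourly steps (5000 h is about 208 days).
#' @param seed_radius Radius of the seeded tumor disc (lattice units).
#' @param seed_types Phenotypes drawn (uniformly) when seeding.
#' @param division_rates,death_rate,replacement_prob,mutation_rate,allow_reverse
#'   See [cell_params()].
#' @param psi1,psi2,decay_fraction,diffusion_rate,dose_period,mtd_single,mtd_combo,min_dose
#'   See [drug_params()].
#' @param protocol,delta_tumor,delta_dose,measurement_period,measurement_noise_sd,fd_dose,fd_stop_fraction,fd_restart_fraction
#'   See [protocol_config()].
#' @param initiation_threshold Measured burden starting treatment (cells);
#'   default 50% of capacity.
#' @param vacation_threshold Stop-dosing threshold (cells); default 25% of
#'   capacity.
#' @param progression_window Rolling-average window for progression scoring
#'   (steps).
#' @param burden_progression_fraction Progression when the rolling mean
#'   total burden reaches this fraction of capacity.
#' @param dr_progression_fraction Progression when the rolling mean doubly
#'   resistant count reaches this fraction of capacity.
#' @param seed RNG seed for the run (`NULL` leaves the RNG state alone).
#' @param label Arm label used in survival tables (defaults to the
#'   protocol id).
#' @return A list of class `at_config`.
#' @export
#' @examples
#' cfg <- sim_config(protocol = "DM_COCKTAIL", width = 20, height = 20,
#'                   duration = 100)
sim_config <- function(width = 100, height = 100, duration = 5000,
                       seed_radius = 10, seed_types = cell_types(),
                       division_rates = c(0.06, 0.04, 0.04, 0.02),
                       death_rate = 0.01, replacement_prob = 0.5,
                       mutation_rate = 1e-3, allow_reverse = TRUE,
                       psi1 = 0.04, psi2 = 0.04,
                       decay_fraction = 0.1, diffusion_rate = 2,
                       dose_period = 24,
                       protocol = "ST",
                       delta_tumor = 0.1, delta_dose = 0.5,
                       measurement_period = 72, measurement_noise_sd = 5,
                       initiation_threshold = NULL,
                       vacation_threshold = NULL,
                       fd_dose = NULL,
                       fd_stop_fraction = 0.5, fd_restart_fraction = 1,
                       mtd_single = 5, mtd_combo = 3, min_dose = 0.5,
                       progression_window = 500,
                       burden_progression_fraction = 0.98,
                       dr_progression_fraction = 0.2,
                       seed = NULL, label = NULL) {
  capacity <- width * height
  if (is.null(initiation_threshold)) initiation_threshold <- 0.5 * capacity
  if (is.null(vacation_threshold)) vacation_threshold <- 0.25 * capacity
  if (is.null(fd_dose)) fd_dose <- 0.75 * mtd_combo
  if (is.null(label)) label <- protocol
  cfg <- structure(list(
    width = width, height = height, duration = as.integer(duration),
    seed_radius = seed_radius, seed_types = seed_types,
    division_rates = division_rates, death_rate = death_rate,
    replacement_prob = replacement_prob, mutation_rate = mutation_rate,
    allow_reverse = allow_reverse,
    psi1 = psi1, psi2 = psi2, decay_fraction = decay_fraction,
    diffusion_rate = diffusion_rate, dose_period = as.integer(dose_period),
    protocol = protocol, delta_tumor = delta_tumor, delta_dose = delta_dose,
    measurement_period = as.integer(measurement_period),
    measurement_noise_sd = measurement_noise_sd,
    initiation_threshold = initiation_threshold,
    vacation_threshold = vacation_threshold,
    fd_dose = fd_dose, fd_stop_fraction = fd_stop_fraction,
    fd_restart_fraction = fd_restart_fraction,
    mtd_single = mtd_single, mtd_combo = mtd_combo, min_dose = min_dose,
    progression_window = as.integer(progression_window),
    burden_progression_fraction = burden_progression_fraction,
    dr_progression_fraction = dr_progression_fraction,
    seed = seed, label = label), class = "at_config")
  validate_config(cfg)
  cfg
}

# Shared validation; also used when merging user config files.
validate_config <- function(cfg) {
  with(cfg, {
    if (width < 1 || height < 1 || duration < 1) stop("lattice and duration must be positive")
    if (progression_window > duration) stop("progression window exceeds duration")
    if (burden_progression_fraction <= 0 || burden_progression_fraction > 1 ||
        dr_progression_fraction <= 0 || dr_progression_fraction > 1)
      stop("progression fractions must lie in (0, 1]")
  })
  # these constructors perform the range checks for their slices
  cell_params(cfg$division_rates, cfg$death_rate, cfg$replacement_prob,
              cfg$mutation_rate, cfg$allow_reverse)
  drug_params(cfg$psi1, cfg$psi2, cfg$decay_fraction, cfg$diffusion_rate,
              cfg$dose_period, cfg$mtd_single, cfg$mtd_combo, cfg$min_dose)
  protocol_config(cfg$protocol, cfg$delta_tumor, cfg$delta_dose,
                  cfg$vacation_threshold, cfg$fd_dose, cfg$fd_stop_fraction,
                  cfg$fd_restart_fraction, cfg$measurement_period,
                  cfg$measurement_noise_sd, cfg$initiation_threshold,
                  cfg$mtd_single, cfg$mtd_combo, cfg$min_dose)
  invisible(cfg)
}

#' One hour of world time
#'
#' Functional wrapper around the compiled step: drug update (dose if
#' `dosing_now`, diffusion, decay) followed by the randomized cell sweep.
#' Inputs are copied, not modified.
#'
#' @param cells Integer lattice matrix.
#' @param field A [drug_field()] of matching dimensions.
#' @param doses Length-2 doses (units) applied when `dosing_now`.
#' @param dosing_now Is this hour a scheduled drug application?
#' @param cfg An [sim_config()] (supplies all rates).
#' @return List with the updated `cells`, `field` and per-type `counts`.
#' @export
step_world <- function(cells, field, doses = c(0, 0), dosing_now = FALSE,
                       cfg = sim_config()) {
  cells <- cells + 0L
  c1 <- field$conc1 + 0
  c2 <- field$conc2 + 0
  counts <- step_world_cpp(cells, c1, c2, doses[1], doses[2], dosing_now,
                           cfg$division_rates, cfg$death_rate,
                           cfg$replacement_prob, cfg$mutation_rate,
                           cfg$allow_reverse, cfg$psi1, cfg$psi2,
                           cfg$decay_fraction, cfg$diffusion_rate)
  field$conc1 <- c1
  field$conc2 <- c2
  list(cells = cells, field = field,
       counts = stats::setNames(counts, cell_types()))
}

#' Naive reference implementation of one hour (plain R)
#'
#' An order-explicit restatement of the step rule, composed from the
#' exported cell-level operations ([death_probability()],
#' [attempt_division()], [drug_update()]). It is deliberately unoptimized
#' and serves as the independent oracle that the compiled engine is checked
#' against.
#'
#' @inheritParams step_world
#' @return As [step_world()].
#' @export
step_world_r <- function(cells, field, doses = c(0, 0), dosing_now = FALSE,
                         cfg = sim_config()) {
  dp <- drug_params(cfg$psi1, cfg$psi2, cfg$decay_fraction,
                    cfg$diffusion_rate, cfg$dose_period, cfg$mtd_single,
                    cfg$mtd_combo, cfg$min_dose)
  cp <- cell_params(cfg$division_rates, cfg$death_rate,
                    cfg$replacement_prob, cfg$mutation_rate,
                    cfg$allow_reverse)
  field <- drug_update(field, doses, dosing_now, dp)
  occupied <- which(cells != 0L)
  visit <- if (length(occupied) > 1) sample(occupied) else occupied
  born <- matrix(FALSE, nrow(cells), ncol(cells))
  for (k in visit) {
    type <- cells[k]
    if (type == 0L || born[k]) next  # died or replaced earlier this step
    site <- c((k - 1L) %% nrow(cells) + 1L, (k - 1L) %/% nrow(cells) + 1L)
    d <- death_probability(type, field$conc1[k], field$conc2[k], cp,
                           cfg$psi1, cfg$psi2)
    if (runif(1) < d) { cells[k] <- 0L; next }
    div <- attempt_division(cells, site, cp)
    if (div$outcome != "NO_DIVISION") {
      cells[div$site[1], div$site[2]] <- cell_type_code(div$daughter_type)
      born[div$site[1], div$site[2]] <- TRUE
    }
  }
  counts <- tabulate(cells[cells != 0L], nbins = 4L)
  list(cells = cells, field = field,
       counts = stats::setNames(counts, cell_types()))
}

#' Progression test on a recorded time series
#'
#' A run has progressed at step `t` once a full rolling window exists and
#' either the window mean of the total burden reaches
#' `burden_progression_fraction` of capacity, or the window mean of the
#' doubly resistant count reaches `dr_progression_fraction` of capacity.
#'
#' @param series Data frame as in the `series` element of [run_simulation()]
#'   (needs columns `total` and `n_doubly_resistant`).
#' @param t Step at which to evaluate.
#' @param cfg An [sim_config()].
#' @return Logical flag.
#' @export
check_progression <- function(series, t, cfg) {
  w <- cfg$progression_window
  if (t > nrow(series)) stop("t exceeds the recorded series")
  if (t < w) return(FALSE)
  capacity <- cfg$width * cfg$height
  idx <- (t - w + 1):t
  mean(series$total[idx]) >= cfg$burden_progression_fraction * capacity ||
    mean(series$n_doubly_resistant[idx]) >= cfg$dr_progression_fraction * capacity
}

# First step at which the progression criteria hold, or NA. Vectorized
# rolling means over the whole series (equivalent to check_progression at
# every step).
first_progression_step <- function(total, dr, cfg) {
  w <- cfg$progression_window
  n <- length(total)
  if (n < w) return(NA_integer_)
  capacity <- cfg$width * cfg$height
  roll <- function(x) (cumsum(x)[w:n] - c(0, cumsum(x))[1:(n - w + 1)]) / w
  hit <- roll(total) >= cfg$burden_progression_fraction * capacity |
         roll(dr) >= cfg$dr_progression_fraction * capacity
  if (!any(hit)) return(NA_integer_)
  which(hit)[1] + w - 1L
}

#' Run one simulated tumor
#'
#' Seeds the tumor, then advances hour by hour: the controller measures the
#' (noisy) burden every `measurement_period` hours and decides the doses for
#' the coming cycle; once treatment has started, doses are administered
#' every `dose_period` hours anchored at the initiation step. The run always
#' covers the full horizon; the first crossing of the progression criteria
#' is recorded.
#'
#' @param cfg An [sim_config()].
#' @return Object of class `at_sim`: list with `series` (per-step data frame
#'   of phenotype counts, total burden and administered doses), `progressed`,
#'   `progression_time` (steps; `NA` if censored), `cumulative_dose`
#'   (units per drug), the final `cells` lattice, the final `controller`
#'   state and the `config`.
#' @export
run_simulation <- function(cfg = sim_config()) {
  validate_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cells <- seed_tumor(cfg$width, cfg$height, cfg$seed_radius, cfg$seed_types)
  c1 <- matrix(0, cfg$height, cfg$width)
  c2 <- matrix(0, cfg$height, cfg$width)
  ctrl <- controller_state()
  pcfg <- protocol_config(cfg$protocol, cfg$delta_tumor, cfg$delta_dose,
                          cfg$vacation_threshold, cfg$fd_dose,
                          cfg$fd_stop_fraction, cfg$fd_restart_fraction,
                          cfg$measurement_period, cfg$measurement_noise_sd,
                          cfg$initiation_threshold, cfg$mtd_single,
                          cfg$mtd_combo, cfg$min_dose)
  duration <- cfg$duration
  counts <- matrix(0L, duration, 4L)
  dose_given <- matrix(0, duration, 2L)
  decision <- c(0, 0)
  burden <- sum(cells != 0L)

  for (h in seq_len(duration)) {
    t0 <- h - 1L
    if (t0 %% cfg$measurement_period == 0L) {
      upd <- controller_update(ctrl, burden, pcfg)
      if (upd$state$treatment_started && !ctrl$treatment_started)
        upd$state$t_init <- t0
      ctrl <- upd$state
      decision <- upd$decision
    }
    dosing_now <- ctrl$treatment_started &&
      (t0 - ctrl$t_init) %% cfg$dose_period == 0L
    cnt <- step_world_cpp(cells, c1, c2, decision[1], decision[2],
                          dosing_now, cfg$division_rates, cfg$death_rate,
                          cfg$replacement_prob, cfg$mutation_rate,
                          cfg$allow_reverse, cfg$psi1, cfg$psi2,
                          cfg$decay_fraction, cfg$diffusion_rate)
    counts[h, ] <- cnt
    burden <- sum(cnt)
    if (dosing_now) dose_given[h, ] <- decision
  }

  series <- data.frame(step = seq_len(duration),
                       n_sensitive = counts[, 1], n_res_drug1 = counts[, 2],
                       n_res_drug2 = counts[, 3],
                       n_doubly_resistant = counts[, 4],
                       total = rowSums(counts),
                       dose1 = dose_given[, 1], dose2 = dose_given[, 2])
  pstep <- first_progression_step(series$total, series$n_doubly_resistant, cfg)
  structure(list(series = series,
                 progressed = !is.na(pstep),
                 progression_time = pstep,
                 cumulative_dose = stats::setNames(colSums(dose_given),
                                                   c("drug1", "drug2")),
                 cells = cells, controller = ctrl, config = cfg),
            class = "at_sim")
}

#' Run a cohort of replicate simulations
#'
#' Runs `n` independent replicates with seeds `base_seed + 0 .. n - 1` and
#' collects one survival record per run: the progression time in days, or
#' administrative censoring at the horizon.
#'
#' @param cfg An [sim_config()].
#' @param n Number of replicates.
#' @param base_seed Integer; replicate `i` uses seed `base_seed + i - 1`.
#' @return Object of class `at_cohort`: list with `results` (the `at_sim`
#'   objects), `survival` (data frame `replicate`, `arm`, `time_days`,
#'   `event`) and `config`.
#' @export
run_replicates <- function(cfg, n = 50, base_seed = 1L) {
  stopifnot(n >= 1)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    cfg$seed <- base_seed + i - 1L
    results[[i]] <- run_simulation(cfg)
  }
  times <- vapply(results, function(r)
    if (r$progressed) r$progression_time else cfg$duration, numeric(1))
  survival <- data.frame(
    replicate = seq_len(n),
    arm = cfg$label,
    time_days = times / 24,
    event = vapply(results, function(r) r$progressed, logical(1)))
  structure(list(results = results, survival = survival, config = cfg),
            class = "at_cohort")
}
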