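# Configuration files, the experiment driver, output writing and the
# miniature test fixtures. Config files are JSON (or YAML) keyed by the
# parameter names of sim_config(); unknown keys are rejected so typos fail
# loudly, and every run's seed and resolved configuration are logged.

manifest_fields <- c("experiment", "arms", "replicates", "base_seed",
                     "output_dir", "reference_arm", "preset",
                     "config", "write_timeseries")

#' Load a run manifest from a JSON or YAML file
#'
#' A manifest names an experiment, a list of arms (each an arm `label` plus
#' parameter `overrides`), a replicate count, a base seed and an output
#' directory. Shared parameter overrides may be given under `config`;
#' `preset: "figure4_defaults"` expands to the six-protocol arm set at
#' default parameters. Overrides are merged onto the [sim_config()] defaults
#' and validated; unknown keys are an error.
#'
#' @param path Path to a `.json` (or `.yaml`/`.yml`) manifest.
#' @return A list of class `run_manifest` with resolved `at_config` objects
#'   per arm.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required for YAML manifests")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  build_manifest(raw, source = path)
}

# Resolve a raw manifest list into validated per-arm configurations.
build_manifest <- function(raw, source = "<list>") {
  unknown <- setdiff(names(raw), manifest_fields)
  if (length(unknown))
    stop("unknown manifest key(s): ", paste(unknown, collapse = ", "))
  if (identical(raw$preset, "figure4_defaults") && is.null(raw$arms))
    raw$arms <- lapply(protocol_ids(), function(p)
      list(label = p, overrides = list(protocol = p)))
  else if (!is.null(raw$preset) && is.null(raw$arms))
    stop("unknown manifest preset: ", raw$preset)
  if (is.null(raw$arms) || length(raw$arms) == 0) stop("manifest needs at least one arm")
  shared <- raw$config %||% list()
  check_overrides(shared)
  arms <- lapply(raw$arms, function(a) {
    if (is.null(a$label)) stop("every arm needs a label")
    ov <- a$overrides %||% list()
    check_overrides(ov)
    cfg <- do.call(sim_config,
                   modifyList(shared, c(ov, list(label = a$label))))
    list(label = a$label, config = cfg)
  })
  labels <- vapply(arms, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("arm labels must be unique")
  n <- as.integer(raw$replicates %||% 50L)
  if (n < 1) stop("replicate count must be >= 1")
  structure(list(experiment = raw$experiment %||% "experiment",
                 arms = arms,
                 replicates = n,
                 base_seed = as.integer(raw$base_seed %||% 1L),
                 output_dir = raw$output_dir %||% ".",
                 reference_arm = raw$reference_arm %||% labels[1],
                 write_timeseries = isTRUE(raw$write_timeseries %||% TRUE),
                 source = source),
            class = "run_manifest")
}

check_overrides <- function(ov) {
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(ov), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  invisible(ov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration or manifest back to JSON
#'
#' Round-trips with [load_config()] / [sim_config()].
#'
#' @param x An `at_config` list or a plain manifest list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run a whole experiment from a manifest
#'
#' Executes every arm for the configured number of replicates and writes,
#' under the output directory: per-run time-series CSVs
#' (`<arm>_rep<k>_timeseries.csv`: step, per-phenotype counts, total,
#' administered doses), the cohort survival table (`survival.csv`), Cox
#' hazard-ratio summaries of each arm against the reference arm
#' (`hazard_ratios.csv`), per-arm drug usage relative to the reference
#' (`drug_usage.csv`), and a log (`run_log.txt`) recording each replicate's
#' seed and the resolved configurations, from which any single run can be
#' reproduced.
#'
#' @param manifest A `run_manifest` from [load_config()], or a path to one.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the cohorts and the written file paths.
#' @export
run_command <- function(manifest, quiet = FALSE) {
  if (is.character(manifest)) manifest <- load_config(manifest)
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(manifest$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(manifest$output_dir, sprintf(...))
  log_lines <- c(sprintf("experiment: %s", manifest$experiment),
                 sprintf("replicates: %d, base_seed: %d",
                         manifest$replicates, manifest$base_seed))
  cohorts <- list()
  paths <- character()
  for (a in manifest$arms) {
    if (!quiet) message("running arm ", a$label)
    cohort <- run_replicates(a$config, n = manifest$replicates,
                             base_seed = manifest$base_seed)
    cohorts[[a$label]] <- cohort
    seeds <- manifest$base_seed + seq_len(manifest$replicates) - 1L
    log_lines <- c(log_lines,
                   sprintf("arm %s seeds: %s", a$label,
                           paste(seeds, collapse = ",")),
                   sprintf("arm %s config: %s", a$label,
                           jsonlite::toJSON(unclass(a$config),
                                            auto_unbox = TRUE, digits = NA)))
    if (manifest$write_timeseries)
      for (k in seq_along(cohort$results)) {
        p <- out("%s_rep%d_timeseries.csv", a$label, k)
        write.csv(cohort$results[[k]]$series, p, row.names = FALSE)
        paths <- c(paths, p)
      }
  }
  surv <- do.call(rbind, lapply(cohorts, `[[`, "survival"))
  p_surv <- out("survival.csv")
  write.csv(surv, p_surv, row.names = FALSE)

  ref <- manifest$reference_arm
  others <- setdiff(names(cohorts), ref)
  hr_rows <- lapply(others, function(lbl) {
    hr <- tryCatch(
      cox_hazard_ratio(rbind(cohorts[[ref]]$survival,
                             cohorts[[lbl]]$survival), reference = ref),
      error = function(e) list(hr = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, p_value = NA_real_))
    data.frame(arm_a = lbl, arm_b = ref, hr = hr$hr, ci_low = hr$ci_low,
               ci_high = hr$ci_high, p = hr$p_value)
  })
  p_hr <- out("hazard_ratios.csv")
  write.csv(do.call(rbind, hr_rows) %||%
              data.frame(arm_a = character(), arm_b = character(),
                         hr = numeric(), ci_low = numeric(),
                         ci_high = numeric(), p = numeric()),
            p_hr, row.names = FALSE)

  usage_rows <- lapply(names(cohorts), function(lbl) {
    u <- tryCatch(drug_usage_fraction(cohorts[[lbl]], cohorts[[ref]]),
                  error = function(e) c(NA_real_, NA_real_))
    data.frame(arm = lbl, reference = ref,
               drug1_fraction = u[[1]], drug2_fraction = u[[2]])
  })
  p_use <- out("drug_usage.csv")
  write.csv(do.call(rbind, usage_rows), p_use, row.names = FALSE)

  p_log <- out("run_log.txt")
  writeLines(log_lines, p_log)
  invisible(list(cohorts = cohorts,
                 paths = c(paths, p_surv, p_hr, p_use, p_log)))
}

#' Miniature deterministic fixtures for tests and examples
#'
#' `"tiny"`: a 5x5 grid run for 10 steps. `"no_drug"`: default biology with
#' both potencies zero. `"frozen"`: all rates zero, so the burden is constant.
#' `"all_sensitive_no_mutation"`: a purely sensitive, non-mutating tumor
#' (the eradication scenario).
#'
#' @param name Fixture name.
#' @return An [sim_config()].
#' @export
make_fixture <- function(name) {
  switch(name,
    tiny = sim_config(width = 5, height = 5, duration = 10, seed_radius = 1,
                      initiation_threshold = 13, vacation_threshold = 6,
                      progression_window = 5),
    no_drug = sim_config(psi1 = 0, psi2 = 0),
    frozen = sim_config(division_rates = c(0, 0, 0, 0), death_rate = 0,
                        mutation_rate = 0, psi1 = 0, psi2 = 0),
    all_sensitive_no_mutation = sim_config(
      seed_types = "DOUBLY_SENSITIVE", mutation_rate = 0),
    stop("unknown fixture: ", name))
}
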