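# Print / summary / plot methods for the result classes.

#' @export
print.at_config <- function(x, ...) {
  cat("Two-drug adaptive therapy simulation configuration\n")
  cat(sprintf("  lattice %d x %d, %d hourly steps, protocol %s\n",
              x$width, x$height, x$duration, x$protocol))
  cat(sprintf("  division rates %s /h, death %.3g /h, replacement %.2g, mu %.1g\n",
              paste(format(x$division_rates), collapse = "/"),
              x$death_rate, x$replacement_prob, x$mutation_rate))
  cat(sprintf("  potencies %.3g/%.3g per unit per h, decay %.0f%%/h, D = %.2g\n",
              x$psi1, x$psi2, 100 * x$decay_fraction, x$diffusion_rate))
  cat(sprintf("  delta tumor %.0f%%, delta dose %.0f%%, vacation <= %g cells\n",
              100 * x$delta_tumor, 100 * x$delta_dose, x$vacation_threshold))
  invisible(x)
}

#' @export
print.at_sim <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<at_sim> %s run, %d steps (%.1f days)\n",
              x$config$protocol, n, n / 24))
  cat(sprintf("  final burden %d cells (%d doubly resistant)\n",
              x$series$total[n], x$series$n_doubly_resistant[n]))
  if (x$progressed)
    cat(sprintf("  progressed at step %d (day %.1f)\n",
                x$progression_time, x$progression_time / 24))
  else cat("  controlled through the full horizon\n")
  cat(sprintf("  cumulative dose: drug 1 %.1f, drug 2 %.1f units\n",
              x$cumulative_dose[1], x$cumulative_dose[2]))
  invisible(x)
}

#' @export
summary.at_sim <- function(object, ...) {
  s <- object$series
  out <- list(protocol = object$config$protocol,
              steps = nrow(s),
              progressed = object$progressed,
              progression_time = object$progression_time,
              final_counts = unlist(s[nrow(s), 2:5]),
              peak_burden = max(s$total),
              cumulative_dose = object$cumulative_dose)
  class(out) <- "summary.at_sim"
  out
}

#' @export
print.summary.at_sim <- function(x, ...) {
  cat(sprintf("%s: %s; peak burden %d cells; drug use %.1f / %.1f units\n",
              x$protocol,
              if (x$progressed) sprintf("progressed at step %d", x$progression_time)
              else "controlled",
              x$peak_burden, x$cumulative_dose[1], x$cumulative_dose[2]))
  invisible(x)
}

#' Plot population dynamics of a single run
#'
#' Per-phenotype cell counts and total burden against time in days.
#'
#' @param x An `at_sim` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.at_sim <- function(x, ...) {
  s <- x$series
  days <- s$step / 24
  graphics::matplot(days, cbind(s$total, s$n_sensitive, s$n_res_drug1,
                                s$n_res_drug2, s$n_doubly_resistant),
                    type = "l", lty = 1, lwd = c(2, 1, 1, 1, 1),
                    col = c("grey40", "darkorange", "skyblue3",
                            "seagreen", "red"),
                    xlab = "Time (days)", ylab = "Cells",
                    main = x$config$label, ...)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = c("grey40", "darkorange", "skyblue3", "seagreen", "red"),
                   legend = c("Total", "Doubly sensitive", "Res drug 1",
                              "Res drug 2", "Doubly resistant"))
  invisible(x)
}

#' @export
print.at_cohort <- function(x, ...) {
  n <- nrow(x$survival)
  cat(sprintf("<at_cohort> arm %s: %d replicates, %d progressed (%.0f%%)\n",
              x$config$label, n, sum(x$survival$event),
              100 * mean(x$survival$event)))
  if (any(x$survival$event))
    cat(sprintf("  median time to progression among events: %.1f days\n",
                stats::median(x$survival$time_days[x$survival$event])))
  invisible(x)
}

#' @export
summary.at_cohort <- function(object, ...) {
  km <- kaplan_meier(object$survival)
  list(arm = object$config$label,
       n = nrow(object$survival),
       events = sum(object$survival$event),
       km = km,
       mean_cumulative_dose = colMeans(do.call(
         rbind, lapply(object$results, `[[`, "cumulative_dose"))))
}

#' Kaplan-Meier plot of one or more cohorts
#'
#' @param x An `at_cohort` object.
#' @param ... Further `at_cohort` objects to overlay.
#' @export
plot.at_cohort <- function(x, ...) {
  cohorts <- c(list(x), Filter(function(o) inherits(o, "at_cohort"), list(...)))
  surv <- do.call(rbind, lapply(cohorts, `[[`, "survival"))
  fit <- survival::survfit(survival::Surv(time_days, event) ~ arm, data = surv)
  cols <- seq_along(cohorts)
  graphics::plot(fit, col = cols, lwd = 2, xlab = "Time (days)",
                 ylab = "Fraction unprogressed")
  graphics::legend("bottomleft", bty = "n", lwd = 2, col = cols,
                   legend = vapply(cohorts, function(o) o$config$label, ""))
  invisible(x)
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("Cox HR (%s vs %s): %.3g [%.3g-%.3g], p = %.3g (%d events)\n",
              x$arm, x$reference, x$hr, x$ci_low, x$ci_high, x$p_value,
              x$n_events))
  invisible(x)
}
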