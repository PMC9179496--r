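# Scheduler, progression scoring and the replicate harness.

test_that("frozen dynamics leave the burden constant and empty lattices empty", {
  cfg <- make_fixture("frozen")
  cfg$duration <- 60L
  cfg$progression_window <- 30L
  cfg$seed <- 1
  r <- run_simulation(cfg)
  expect_true(all(r$series$total == 317))
  expect_false(r$progressed)
  st <- step_world(matrix(0L, 10, 10), drug_field(10, 10), cfg = sim_config())
  expect_equal(sum(st$counts), 0)
})

test_that("per-type counts always sum to the occupied-site count", {
  set.seed(41)
  cells <- seed_tumor(30, 30, 6)
  f <- drug_field(30, 30)
  cfg <- sim_config(width = 30, height = 30)
  for (h in 1:30) {
    st <- step_world(cells, f, doses = c(1, 1), dosing_now = h %% 24 == 1, cfg = cfg)
    cells <- st$cells; f <- st$field
    expect_equal(sum(st$counts), sum(cells != 0))
    expect_true(all(cells %in% 0:4))
  }
})

test_that("replaying a seed reproduces the run bit-exactly", {
  cfg <- sim_config(width = 30, height = 30, duration = 250, seed_radius = 5,
                    progression_window = 100, initiation_threshold = 450,
                    vacation_threshold = 225, protocol = "DM_COCKTAIL", seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$cells, b$cells)
  co1 <- run_replicates(cfg, n = 2, base_seed = 5)
  co2 <- run_replicates(cfg, n = 2, base_seed = 5)
  expect_identical(co1$survival, co2$survival)
})

test_that("progression is scored on full rolling windows of burden or resistance", {
  cfg <- sim_config()  # capacity 10000, window 500
  mk <- function(total, dr) data.frame(total = total, n_doubly_resistant = dr)
  s <- mk(rep(9800, 600), rep(0, 600))
  expect_true(check_progression(s, 600, cfg))
  expect_false(check_progression(mk(rep(9700, 600), rep(0, 600)), 600, cfg))
  expect_true(check_progression(mk(rep(0, 600), rep(2000, 600)), 600, cfg))
  expect_false(check_progression(s, 499, cfg))  # incomplete window
  expect_error(check_progression(s, 601, cfg), "series")
  # a single-step spike is diluted by the rolling mean
  spike <- mk(c(rep(5000, 550), 10000, rep(5000, 49)), rep(0, 600))
  expect_false(check_progression(spike, 600, cfg))
})

test_that("the recorded progression time is the first rolling-window crossing", {
  cfg <- sim_config(width = 20, height = 20, duration = 700, seed_radius = 4,
                    progression_window = 200, protocol = "ST", psi1 = 0, psi2 = 0,
                    burden_progression_fraction = 0.9,
                    initiation_threshold = 200, vacation_threshold = 100, seed = 42)
  r <- run_simulation(cfg)
  expect_true(r$progressed)  # potency 0: growth to capacity
  flags <- vapply(seq_len(nrow(r$series)), function(t)
    check_progression(r$series, t, cfg), logical(1))
  expect_equal(which(flags)[1], r$progression_time)
})

test_that("ST accumulates exactly the cocktail MTD per daily application", {
  cfg <- sim_config(width = 30, height = 30, duration = 400, seed_radius = 5,
                    progression_window = 200, initiation_threshold = 450,
                    vacation_threshold = 225, protocol = "ST", seed = 8)
  r <- run_simulation(cfg)
  n_apps <- sum(r$series$dose1 > 0)
  expect_gt(n_apps, 0)
  expect_equal(unname(r$cumulative_dose), c(3, 3) * n_apps)
  expect_true(all(r$series$dose1 %in% c(0, 3)))
  # applications are daily, anchored at initiation
  apps <- which(r$series$dose1 > 0)
  expect_true(all(diff(apps) == 24))
})

test_that("unconstrained growth matches the analytic doubling time within 5%", {
  set.seed(43)
  cfg <- sim_config(replacement_prob = 0, mutation_rate = 0, psi1 = 0, psi2 = 0)
  n0 <- 0; n24 <- 0
  sites <- as.matrix(expand.grid(seq(6, 66, by = 12), seq(6, 66, by = 12)))
  for (rep in 1:30) {
    cells <- matrix(0L, 72, 72)
    cells[sites] <- 1L
    f <- drug_field(72, 72)
    n0 <- n0 + sum(cells != 0)
    for (h in 1:24) { st <- step_world(cells, f, cfg = cfg); cells <- st$cells }
    n24 <- n24 + sum(cells != 0)
  }
  rate <- log(n24 / n0) / 24
  expect_equal(log(2) / rate, doubling_time("DOUBLY_SENSITIVE"), tolerance = 0.05)
})

test_that("without drug or mutation, selection favors the doubly sensitive type", {
  set.seed(44)
  cfg <- sim_config(width = 30, height = 30, mutation_rate = 0, psi1 = 0, psi2 = 0)
  final_frac <- replicate(10, {
    cells <- seed_tumor(30, 30, 5)
    f <- drug_field(30, 30)
    for (h in 1:240) { st <- step_world(cells, f, cfg = cfg); cells <- st$cells }
    counts <- tabulate(cells[cells != 0], 4)
    counts[1] / sum(counts)
  })
  expect_gt(mean(final_frac), 0.4)  # clear increase from the seeded 25%
})

test_that("standard treatment eradicates a sensitive, non-mutating tumor", {
  cfg <- make_fixture("all_sensitive_no_mutation")
  cfg$protocol <- "ST"
  cfg$duration <- 1500L
  cfg$progression_window <- 500L
  for (i in 1:20) {
    cfg$seed <- 4000 + i
    r <- run_simulation(cfg)
    expect_equal(r$series$total[nrow(r$series)], 0)
  }
})

test_that("with zero potency all six protocols are statistically indistinguishable", {
  tabs <- lapply(seq_along(protocol_ids()), function(i) {
    cfg <- sim_config(width = 40, height = 40, duration = 2000, seed_radius = 6,
                      psi1 = 0, psi2 = 0, protocol = protocol_ids()[i],
                      burden_progression_fraction = 0.9,
                      initiation_threshold = 800, vacation_threshold = 400)
    # distinct seeds per arm so the comparison is a genuine two-sample test
    run_replicates(cfg, n = 10, base_seed = 600 + 40 * i)$survival
  })
  surv <- do.call(rbind, tabs)
  expect_true(all(surv$event))  # unchecked growth always progresses
  fit <- survival::survdiff(survival::Surv(time_days, event) ~ arm, data = surv)
  p <- pchisq(fit$chisq, df = length(fit$n) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("cohorts censor at the horizon and label arms", {
  cfg <- make_fixture("frozen")
  cfg$duration <- 50L
  cfg$progression_window <- 25L
  cfg$label <- "inert"
  co <- run_replicates(cfg, n = 3, base_seed = 1)
  expect_equal(co$survival$arm, rep("inert", 3))
  expect_true(all(!co$survival$event))
  expect_true(all(co$survival$time_days == 50 / 24))
})
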