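# Shared helpers: an explicit finite-difference diffusion oracle and small
# utilities for distribution comparisons.

# Explicit-Euler diffusion of one matrix with zero-flux boundaries,
# sub-stepped for accuracy. Independent of the ADI solver.
explicit_diffuse <- function(m, D, time = 1, nsub = 100) {
  dt <- time / nsub
  nr <- nrow(m); nc <- ncol(m)
  for (s in seq_len(nsub)) {
    up    <- m[c(1, 1:(nr - 1)), ]
    down  <- m[c(2:nr, nr), ]
    left  <- m[, c(1, 1:(nc - 1))]
    right <- m[, c(2:nc, nc)]
    m <- m + D * dt * (up + down + left + right - 4 * m)
  }
  m
}

# Chi-square homogeneity test between two samples of categorical outcomes,
# lumping rare categories so expected counts stay reasonable.
chisq_two_sample <- function(a, b, min_count = 20) {
  lev <- union(unique(a), unique(b))
  ta <- table(factor(a, levels = lev))
  tb <- table(factor(b, levels = lev))
  keep <- (ta + tb) >= min_count
  if (any(!keep)) {
    ta <- c(ta[keep], other = sum(ta[!keep]))
    tb <- c(tb[keep], other = sum(tb[!keep]))
  }
  suppressWarnings(chisq.test(rbind(ta, tb)))
}

# Small config used by several engine tests.
tiny_mixed_cfg <- function() {
  sim_config(width = 3, height = 3, duration = 1, seed_radius = 0,
             division_rates = c(0.5, 0.4, 0.4, 0.3), death_rate = 0.05,
             replacement_prob = 0.5, mutation_rate = 0.05,
             progression_window = 1,
             initiation_threshold = 5, vacation_threshold = 2)
}

tiny_mixed_cells <- function() {
  cells <- matrix(0L, 3, 3)
  cells[1, 1] <- 1L; cells[2, 2] <- 1L; cells[3, 3] <- 1L
  cells[1, 3] <- 2L; cells[3, 1] <- 4L
  cells
}
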