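# Cell-level model: phenotypes, death/division/mutation rules, tumor seeding.
#
# The lattice is an integer matrix; 0 marks an empty site and 1..4 the four
# phenotypes in the order of `cell_types()`.

#' The four cell phenotypes
#'
#' Returns the phenotype names in their fixed internal order. Doubly
#' sensitive cells respond to both drugs, singly resistant cells to one, and
#' doubly resistant cells to neither.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' cell_types()
cell_types <- function() {
  c("DOUBLY_SENSITIVE", "RES_DRUG1", "RES_DRUG2", "DOUBLY_RESISTANT")
}

#' @rdname cell_types
#' @param type Character phenotype name(s).
#' @return `cell_type_code()`: integer code(s) in 1..4.
#' @export
cell_type_code <- function(type) {
  code <- match(type, cell_types())
  if (anyNA(code)) stop("unknown cell type: ", paste(type[is.na(code)], collapse = ", "))
  code
}

#' Drug-sensitivity indicators of a phenotype
#'
#' @param type Phenotype name or integer code.
#' @return Named integer vector `c(S1, S2)`; 1 means sensitive to that drug,
#'   0 resistant.
#' @export
#' @examples
#' cell_sensitivity("RES_DRUG1")
cell_sensitivity <- function(type) {
  code <- if (is.character(type)) cell_type_code(type) else as.integer(type)
  if (length(code) != 1L || is.na(code) || code < 1L || code > 4L)
    stop("'type' must be a single phenotype")
  c(S1 = as.integer(!code %in% c(2L, 4L)),
    S2 = as.integer(!code %in% c(3L, 4L)))
}

#' Cell population parameters
#'
#' Bundles the per-hour division rates of the four phenotypes, the background
#' death rate, the neighbor-replacement probability and the mutation rate.
#' Defaults give the doubly sensitive cells a five-fold net growth advantage
#' over doubly resistant cells (0.05/h vs 0.01/h).
#'
#' @param division_rates Per-hour division probabilities, ordered as
#'   [cell_types()]. Must be non-increasing in the pattern
#'   sensitive >= singly resistant (equal) >= doubly resistant.
#' @param death_rate Background per-hour death probability, shared by all
#'   phenotypes.
#' @param replacement_prob Probability `r` that a dividing cell with no empty
#'   neighbor replaces a random neighbor (0 = contact inhibition, 1 =
#'   neighbor killing).
#' @param mutation_rate Probability per division, per target phenotype, that
#'   the daughter switches type.
#' @param allow_reverse If `FALSE`, transitions that would remove a
#'   resistance are forbidden (a model of irreversible genetic resistance).
#' @return A list of class `cell_params`.
#' @export
cell_params <- function(division_rates = c(0.06, 0.04, 0.04, 0.02),
                        death_rate = 0.01,
                        replacement_prob = 0.5,
                        mutation_rate = 1e-3,
                        allow_reverse = TRUE) {
  stopifnot(length(division_rates) == 4L)
  rates <- c(division_rates, death_rate, replacement_prob, mutation_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("all rates must lie in [0, 1]")
  if (!(division_rates[1] >= division_rates[2] &&
        division_rates[2] == division_rates[3] &&
        division_rates[3] >= division_rates[4]))
    stop("division rates must satisfy sensitive >= singly resistant (equal) >= doubly resistant")
  if (3 * mutation_rate > 1) stop("mutation rate too large: 3*mu must be <= 1")
  structure(list(division_rates = as.numeric(division_rates),
                 death_rate = death_rate,
                 replacement_prob = replacement_prob,
                 mutation_rate = mutation_rate,
                 allow_reverse = isTRUE(allow_reverse)),
            class = "cell_params")
}

#' Per-hour death probability of a cell
#'
#' Background death plus a term per drug the cell is sensitive to,
#' `S_k * conc_k * psi_k`, clamped at 1 as a safety contract.
#'
#' @param type Phenotype name or code.
#' @param conc1,conc2 Local drug concentrations (units), non-negative.
#' @param params A [cell_params()] object (supplies the background rate).
#' @param psi1,psi2 Drug potencies (death probability per unit concentration
#'   per hour), non-negative.
#' @return Death probability per hour.
#' @export
#' @examples
#' death_probability("DOUBLY_SENSITIVE", 5, 0, cell_params())
death_probability <- function(type, conc1, conc2, params = cell_params(),
                              psi1 = 0.04, psi2 = 0.04) {
  if (any(c(conc1, conc2) < 0)) stop("drug concentrations must be non-negative")
  if (any(c(psi1, psi2) < 0)) stop("drug potencies must be non-negative")
  s <- cell_sensitivity(type)
  min(1, params$death_rate + s[["S1"]] * conc1 * psi1 + s[["S2"]] * conc2 * psi2)
}

#' Net growth rate and doubling time of a phenotype
#'
#' Net growth is division minus background death; the doubling time is
#' `log(2)` over the net growth rate (defined only when growth is positive).
#'
#' @inheritParams death_probability
#' @return Rate per hour, or hours for `doubling_time()`.
#' @export
#' @examples
#' doubling_time("DOUBLY_SENSITIVE", cell_params())  # 13.86 h
net_growth_rate <- function(type, params = cell_params()) {
  code <- if (is.character(type)) cell_type_code(type) else as.integer(type)
  params$division_rates[code] - params$death_rate
}

#' @rdname net_growth_rate
#' @export
doubling_time <- function(type, params = cell_params()) {
  g <- net_growth_rate(type, params)
  if (any(g <= 0)) stop("doubling time undefined for non-positive net growth")
  log(2) / g
}

#' In-bounds Moore neighborhood of a lattice site
#'
#' The up-to-8 surrounding sites; the lattice does not wrap, so edge and
#' corner sites have truncated neighborhoods.
#'
#' @param cells Integer lattice matrix (or anything with a `dim`).
#' @param site Integer vector `c(row, col)`, 1-based.
#' @return Two-column matrix of neighbor coordinates (row, col).
#' @export
moore_neighbors <- function(cells, site) {
  nr <- nrow(cells); nc <- ncol(cells)
  i <- site[1]; j <- site[2]
  if (i < 1 || i > nr || j < 1 || j > nc) stop("site out of lattice bounds")
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  ii <- i + off$di; jj <- j + off$dj
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  cbind(row = ii[ok], col = jj[ok])
}

#' Daughter phenotype at division
#'
#' Each permitted target phenotype is produced with probability `mu`; the
#' parent type is retained otherwise. When `allow_reverse = FALSE`, any
#' transition that would remove a resistance (including swaps between the
#' two singly resistant types) is forbidden and its probability mass folds
#' back into retention.
#'
#' @param parent_type Phenotype name.
#' @param mu Per-target mutation probability (requires `3 * mu <= 1`).
#' @param allow_reverse Permit resistance-removing transitions?
#' @param n Number of independent draws.
#' @return Character vector of `n` daughter phenotypes.
#' @export
mutate_daughter <- function(parent_type, mu, allow_reverse = TRUE, n = 1) {
  if (3 * mu > 1) stop("3*mu must be <= 1")
  types <- cell_types()
  parent <- cell_type_code(parent_type)
  targets <- setdiff(1:4, parent)
  if (!allow_reverse) {
    res <- function(code) c(as.integer(code %in% c(2L, 4L)), as.integer(code %in% c(3L, 4L)))
    p <- res(parent)
    targets <- targets[vapply(targets, function(t) all(res(t) >= p), logical(1))]
  }
  k <- length(targets)
  if (k == 0 || mu == 0) return(rep(types[parent], n))
  probs <- c(rep(mu, k), 1 - k * mu)
  draws <- sample(c(targets, parent), n, replace = TRUE, prob = probs)
  types[draws]
}

#' Seed a tumor disc at the lattice center
#'
#' Occupies every site whose squared Euclidean distance from the central site
#' is at most `radius^2`; each seeded cell's phenotype is drawn uniformly
#' from `types`. A radius of 10 yields 317 cells on the default grid.
#'
#' @param width,height Lattice dimensions in sites.
#' @param radius Disc radius in lattice units.
#' @param types Phenotypes to draw from (defaults to all four, equiprobable).
#' @return Integer lattice matrix (`height` rows, `width` columns).
#' @export
#' @examples
#' sum(seed_tumor(100, 100, 10) != 0)  # 317
seed_tumor <- function(width = 100, height = 100, radius = 10,
                       types = cell_types()) {
  if (radius < 0) stop("radius must be non-negative")
  ci <- floor((height + 1) / 2); cj <- floor((width + 1) / 2)
  if (ci - radius < 1 || ci + radius > height || cj - radius < 1 || cj + radius > width)
    stop("seeding disc exceeds lattice bounds")
  cells <- matrix(0L, nrow = height, ncol = width)
  d2 <- outer((seq_len(height) - ci)^2, (seq_len(width) - cj)^2, `+`)
  idx <- which(d2 <= radius^2)
  codes <- cell_type_code(types)
  cells[idx] <- if (length(codes) == 1L) codes else
    sample(codes, length(idx), replace = TRUE)
  cells
}

#' One division attempt of a cell (reference implementation)
#'
#' Draws the division Bernoulli for the cell at `site`; on success the
#' daughter is placed uniformly at random among empty Moore neighbors, or --
#' if the neighborhood is full -- replaces a uniformly chosen neighbor with
#' probability `replacement_prob`. This is the plain-R statement of the rule
#' used by the compiled engine.
#'
#' @param cells Integer lattice matrix.
#' @param site `c(row, col)` of an occupied site.
#' @param params A [cell_params()] object.
#' @return List with `outcome` (`"NO_DIVISION"`, `"PLACED"` or `"REPLACED"`),
#'   `site` (daughter coordinates or `NULL`) and `daughter_type` (phenotype
#'   name after mutation, or `NULL`).
#' @export
attempt_division <- function(cells, site, params = cell_params()) {
  code <- cells[site[1], site[2]]
  if (code == 0L) stop("cannot divide an empty site")
  no <- list(outcome = "NO_DIVISION", site = NULL, daughter_type = NULL)
  if (runif(1) >= params$division_rates[code]) return(no)
  nb <- moore_neighbors(cells, site)
  occ <- cells[nb] != 0L
  target <- NULL
  outcome <- "NO_DIVISION"
  if (any(!occ)) {
    empty <- nb[!occ, , drop = FALSE]
    target <- empty[sample.int(nrow(empty), 1L), ]
    outcome <- "PLACED"
  } else if (nrow(nb) > 0 && runif(1) < params$replacement_prob) {
    target <- nb[sample.int(nrow(nb), 1L), ]
    outcome <- "REPLACED"
  }
  if (is.null(target)) return(no)
  daughter <- mutate_daughter(cell_types()[code], params$mutation_rate,
                              params$allow_reverse)
  list(outcome = outcome, site = unname(target), daughter_type = daughter)
}
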