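#' Construct a single cell
#'
#' A cell is a particle with a 3D position, ellipsoid semi-axes `(a, a, c)`
#' (spherical, `a = c = r0`, for every state except corneocytes, whose volume
#' `a^2 c = r0^3` is conserved while they flatten), a lifecycle state, the
#' time spent in that state, an optional on-membrane anchor (stem cells only)
#' and an optional scalar calcium proxy in [0, 1].
#'
#' @param id integer cell id.
#' @param pos numeric 3-vector position (um).
#' @param state one of `"STEM"`, `"PROLIF"`, `"SPINOUS"`, `"GRANULAR"`,
#'   `"CORNEOCYTE"`.
#' @param r0_um intrinsic radius (um).
#' @param a,c ellipsoid semi-axes (um); default spherical.
#' @param age_in_state time in the current state (h).
#' @param anchor lattice anchor `c(x, y)` (required for stem cells, forbidden
#'   otherwise).
#' @param ca calcium proxy in [0, 1].
#' @return a list of class `epiderm_cell`.
#' @export
new_cell <- function(id, pos, state = "PROLIF", r0_um = 5,
                     a = r0_um, c = r0_um, age_in_state = 0,
                     anchor = NULL, ca = 0) {
  state <- match.arg(state, STATE_LEVELS)
  if (state == "STEM" && is.null(anchor))
    stop("STEM cells must carry an anchor")
  if (state != "STEM" && !is.null(anchor))
    stop("only STEM cells carry an anchor")
  if (a <= 0 || c <= 0) stop("semi-axes must be > 0")
  if (state != "CORNEOCYTE" && (a != c || abs(a - r0_um) > 1e-12))
    stop("non-corneocytes must be spherical with a = c = r0")
  if (abs(a^2 * c - r0_um^3) / r0_um^3 > 1e-8)
    stop("cell volume a^2 c must equal r0^3")
  structure(list(id = as.integer(id), pos = as.numeric(pos),
                 r0 = as.numeric(r0_um), a = as.numeric(a), c = as.numeric(c),
                 state = state, age_in_state = as.numeric(age_in_state),
                 anchor = anchor, ca = as.numeric(ca), alive = TRUE),
            class = "epiderm_cell")
}

# probability that a memoryless clock of the given rate fires within dt
clock_fires_prob <- function(rate, dt) 1 - exp(-rate * dt)

#' Attempt a stem-cell division
#'
#' Stem divisions are exponential-clock events with mean interval
#' `division_period_h` (optionally rate-jittered), suppressed entirely while
#' the local neighbour count within one cell diameter exceeds the crowding
#' cap. On firing, a spherical proliferative daughter is returned, placed at
#' `daughter_offset_um` in a uniformly random upward-hemisphere direction;
#' the stem keeps its anchor and resets its clock.
#'
#' @param cell an `epiderm_cell` in state `"STEM"`.
#' @param dt timestep (h).
#' @param local_density neighbour count within `2 * r0` of the stem.
#' @param lp a [lifecycle_params()] object.
#' @param new_id id to give the daughter if division fires.
#' @return the daughter `epiderm_cell`, or `NULL` if no division occurred.
#' @export
attempt_division <- function(cell, dt, local_density, lp, new_id = cell$id + 1L) {
  if (!inherits(cell, "epiderm_cell") || cell$state != "STEM")
    stop("attempt_division requires a STEM cell")
  rate <- 1 / lp$division_period_h
  if (lp$division_jitter > 0)
    rate <- rate / (1 + lp$division_jitter * runif(1, -1, 1))
  u <- runif(1)
  if (u >= clock_fires_prob(rate, dt)) return(NULL)
  if (local_density > lp$crowding_cap) return(NULL)
  uz <- runif(1)
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(max(0, 1 - uz^2))
  dir <- c(s * cos(phi), s * sin(phi), uz)
  new_cell(new_id, cell$pos + lp$daughter_offset_um * dir,
           state = "PROLIF", r0_um = lp$r0_um)
}

# vectorised state-machine advance shared by update_state() and the
# constant-influx occupancy driver: states/ages/ca are parallel vectors
advance_states <- function(state, age, gap, ca, dt, lp) {
  n <- length(state)
  u <- runif(n)
  new_state <- state
  new_age <- age + dt
  if (lp$calcium_on) {
    target <- pmin(1, pmax(0, gap / (lp$diff_height_um + 2 * lp$r0_um)))
    ca <- ca + (target - ca) * (1 - exp(-dt / lp$ca_tau_h))
  }
  prolif <- state == "PROLIF" & gap > lp$diff_height_um
  new_state[prolif] <- "SPINOUS"
  sp_rate <- rep(1 / lp$spinous_dur_h, n)
  if (lp$calcium_on) sp_rate <- sp_rate * ca
  spin <- state == "SPINOUS" & u < clock_fires_prob(sp_rate, dt)
  new_state[spin] <- "GRANULAR"
  gran <- state == "GRANULAR" & u < clock_fires_prob(1 / lp$granular_dur_h, dt)
  new_state[gran] <- "CORNEOCYTE"
  transitioned <- new_state != state
  new_age[transitioned] <- 0
  list(state = new_state, age = new_age, ca = ca)
}

#' Advance a cell's lifecycle state over one timestep
#'
#' Applies the positional differentiation rule (proliferative cells become
#' spinous once their membrane clearance exceeds `diff_height_um`) and the
#' exponential spinous and granular residence clocks. Stem cells never
#' transition; corneocyte shedding is handled by the stepping loop, which
#' knows about surface exposure. `age_in_state` resets on every transition.
#'
#' @param cell an `epiderm_cell`.
#' @param gap vertical membrane clearance at the cell position (um).
#' @param dt timestep (h), must be positive.
#' @param lp a [lifecycle_params()] object.
#' @return the updated `epiderm_cell`.
#' @export
update_state <- function(cell, gap, dt, lp) {
  stopifnot(inherits(cell, "epiderm_cell"))
  if (dt < 0) stop("dt must be non-negative")
  if (cell$state %in% c("STEM", "CORNEOCYTE")) {
    cell$age_in_state <- cell$age_in_state + dt
    return(cell)
  }
  adv <- advance_states(cell$state, cell$age_in_state, gap, cell$ca, dt, lp)
  cell$state <- adv$state
  cell$age_in_state <- adv$age
  cell$ca <- adv$ca
  cell
}

#' Relax a corneocyte toward its flattened shape
#'
#' The aspect ratio q = c/a decays exponentially toward `target_aspect` with
#' time constant `flatten_tau_h`; the semi-axes are recomputed from q so the
#' volume `a^2 c = r0^3` is preserved exactly at every step.
#'
#' @param cell an `epiderm_cell` in state `"CORNEOCYTE"`.
#' @param dt timestep (h).
#' @param lp a [lifecycle_params()] object.
#' @return the updated `epiderm_cell`.
#' @export
update_flattening <- function(cell, dt, lp) {
  if (!inherits(cell, "epiderm_cell") || cell$state != "CORNEOCYTE")
    stop("update_flattening requires a CORNEOCYTE cell")
  if (dt == 0) return(cell)
  q <- cell$c / cell$a
  q <- lp$target_aspect + (q - lp$target_aspect) * exp(-dt / lp$flatten_tau_h)
  cell$a <- cell$r0 * q^(-1 / 3)
  cell$c <- cell$r0 * q^(2 / 3)
  cell
}

#' Relax the scalar calcium proxy (optional feature)
#'
#' The per-cell calcium level relaxes toward a height-dependent target — 0 at
#' the membrane, 1 above the differentiation height plus one cell diameter —
#' with time constant `ca_tau_h`, clamped to [0, 1]. When the calcium feature
#' is enabled, the spinous-to-granular clock rate is multiplied by this level.
#'
#' @param cell an `epiderm_cell`.
#' @param gap vertical membrane clearance at the cell position (um).
#' @param dt timestep (h).
#' @param lp a [lifecycle_params()] object with `calcium_on = TRUE`.
#' @return the updated `epiderm_cell`.
#' @export
update_calcium <- function(cell, gap, dt, lp) {
  stopifnot(inherits(cell, "epiderm_cell"))
  if (!lp$calcium_on) stop("calcium feature is disabled in these parameters")
  target <- min(1, max(0, gap / (lp$diff_height_um + 2 * lp$r0_um)))
  cell$ca <- cell$ca + (target - cell$ca) * (1 - exp(-dt / lp$ca_tau_h))
  cell$ca <- min(1, max(0, cell$ca))
  cell
}

#' Stationary occupancy of a lifecycle compartment under constant influx
#'
#' Drives the package's state-machine advance with a constant Poisson influx
#' of proliferative cells placed above the differentiation height (so they
#' enter the spinous compartment immediately) and records the number of
#' spinous occupants over time. At stationarity this is an M/M/infinity
#' queue whose mean occupancy is influx rate x mean spinous residence.
#'
#' @param influx_per_h mean arrivals per hour.
#' @param lp a [lifecycle_params()] object.
#' @param t_total_h simulated time (h).
#' @param dt_h timestep (h).
#' @param burnin_h initial span excluded from the occupancy average.
#' @return list with `mean_occupancy` (time-averaged spinous count after
#'   burn-in) and `trace` (per-step occupancy).
#' @export
simulate_influx_occupancy <- function(influx_per_h, lp, t_total_h = 2000,
                                      dt_h = 0.25, burnin_h = 200) {
  n_steps <- ceiling(t_total_h / dt_h)
  state <- character(0)
  age <- numeric(0)
  occ <- integer(n_steps)
  gap_above <- lp$diff_height_um + 10 * lp$r0_um
  for (k in seq_len(n_steps)) {
    arrivals <- stats::rpois(1, influx_per_h * dt_h)
    if (arrivals > 0) {
      state <- c(state, rep("PROLIF", arrivals))
      age <- c(age, numeric(arrivals))
    }
    if (length(state)) {
      adv <- advance_states(state, age, rep(gap_above, length(state)),
                            numeric(length(state)), dt_h, lp)
      keep <- adv$state %in% c("PROLIF", "SPINOUS")   # departures leave
      state <- adv$state[keep]
      age <- adv$age[keep]
    }
    occ[k] <- sum(state == "SPINOUS")
  }
  keep_from <- ceiling(burnin_h / dt_h) + 1
  list(mean_occupancy = mean(occ[keep_from:n_steps]), trace = occ)
}
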