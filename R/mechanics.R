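#' Pairwise contact force between two cells
#'
#' Linear repulsion below contact and linear adhesion up to the adhesion
#' cutoff beyond contact, along the center line, with minimum-image periodic
#' wrapping in x and y. The contact distance is the sum of the two cells'
#' direction-dependent ellipsoid radii along the center line, so flattened
#' corneocytes present a thin profile vertically and a wide one laterally.
#' The force is antisymmetric by construction; coincident centers are
#' resolved by a deterministic hash-seeded direction and never produce NaN.
#'
#' @param ci,cj `epiderm_cell` objects (see [new_cell()]).
#' @param fp a [force_params()] object.
#' @param spec a `membrane_spec` (supplies the periodic domain extents).
#' @return the force on `ci` exerted by `cj`, as a numeric 3-vector.
#' @export
pairwise_force <- function(ci, cj, fp, spec) {
  stopifnot(inherits(ci, "epiderm_cell"), inherits(cj, "epiderm_cell"))
  if (ci$id == cj$id) stop("pairwise_force requires two distinct cells")
  cpp_pairwise_force(ci$pos, cj$pos, ci$a, ci$c, cj$a, cj$c,
                     ci$id, cj$id, unclass(fp),
                     spec$domain_x_um, spec$domain_y_um)
}

#' Membrane contact and anchoring force on a cell
#'
#' Cells closer to the membrane surface than their vertical semi-axis feel a
#' linear repulsion along the outward surface normal. Stem cells are attached
#' to the membrane: instead of surface repulsion they feel a linear spring
#' pinning them to their on-surface anchor point, so an undisturbed stem
#' rests exactly at its anchor.
#'
#' @param cell an `epiderm_cell`.
#' @param spec a `membrane_spec`.
#' @param fp a [force_params()] object.
#' @return numeric 3-vector force.
#' @export
membrane_force <- function(cell, spec, fp) {
  stopifnot(inherits(cell, "epiderm_cell"))
  mg <- membrane_gap(spec, cell$pos)
  f <- c(0, 0, 0)
  if (cell$state != "STEM" && mg$gap < cell$c)
    f <- f + fp$k_mem * (cell$c - mg$gap) * mg$normal[1, ]
  if (cell$state == "STEM") {
    az <- membrane_height(spec, cell$anchor[1], cell$anchor[2])
    dx <- c(wrap_diff(cell$pos[1] - cell$anchor[1], spec$domain_x_um),
            wrap_diff(cell$pos[2] - cell$anchor[2], spec$domain_y_um),
            cell$pos[3] - az)
    f <- f - fp$k_anchor * dx
  }
  f
}

wrap_diff <- function(d, L) d - L * round(d / L)

#' Grid-accelerated total forces on every cell
#'
#' Total mechanical force (pairwise contact + membrane contact + stem
#' anchoring) on each cell of a configuration, computed with the same
#' spatial-hash neighbour search the stepping loop uses.
#'
#' @param state a `sim_state`.
#' @param spec a `membrane_spec`.
#' @param fp a [force_params()] object.
#' @param lp a [lifecycle_params()] object (supplies the cell radius used to
#'   size the grid).
#' @return an n x 3 matrix of forces.
#' @export
total_forces <- function(state, spec, fp, lp = lifecycle_params()) {
  v <- state_vectors(state)
  cpp_total_forces(v$x, v$y, v$z, v$a, v$c, v$state, v$ax, v$ay, v$id,
                   unclass(spec), unclass(fp), unclass(lp))
}

#' Advance a simulation state by explicit overdamped steps
#'
#' Each step applies one explicit Euler-Maruyama update of the overdamped
#' dynamics (forces divided by drag, plus thermal noise for proliferative,
#' spinous and granular cells), followed by the lifecycle updates: stem
#' division, positional differentiation, the exponential residence clocks,
#' volume-preserving corneocyte flattening, exposure-gated desquamation and
#' periodic wrapping. Cells are processed in id order and all randomness
#' flows through R's RNG, so results are reproducible under [set.seed()].
#'
#' @param state a `sim_state`.
#' @param spec a `membrane_spec`.
#' @param fp a [force_params()] object (`fp$dt_h` is the timestep).
#' @param lp a [lifecycle_params()] object.
#' @param n_steps number of timesteps to take.
#' @return the advanced `sim_state`.
#' @export
step_state <- function(state, spec, fp, lp, n_steps = 1) {
  stopifnot(inherits(state, "sim_state"))
  if (n_steps < 1) return(state)
  v <- state_vectors(state)
  res <- cpp_run(v$x, v$y, v$z, v$a, v$c, v$state, v$age, v$ax, v$ay, v$ca,
                 v$id, unclass(spec), unclass(fp), unclass(lp),
                 as.integer(n_steps), 0L,
                 state$t, state$births, state$removals, -1L)
  snapshot_to_state(res$final)
}

#' Run an epidermal homeostasis simulation
#'
#' Seeds stem cells on the membrane, then integrates the center-based model
#' for `T_total_h` simulated hours, recording a snapshot every
#' `snapshot_every_h` hours (the initial state is always included).
#'
#' @param spec a `membrane_spec`.
#' @param lp a [lifecycle_params()] object.
#' @param fp a [force_params()] object.
#' @param T_total_h total simulated time (h).
#' @param snapshot_every_h snapshot interval (h); must be a multiple of the
#'   timestep.
#' @param seed integer RNG seed; the whole trajectory is reproducible from
#'   the arguments plus this seed.
#' @param stem_spacing_um stem-cell lattice spacing (um).
#' @param init optional `sim_state` to continue from instead of seeding
#'   stems.
#' @return an object of class `epiderm_trajectory`: a list with `snapshots`
#'   (list of `sim_state`), `counters` (data.frame with one row per snapshot:
#'   t, n, per-state counts, births, removals), and the run configuration.
#' @export
simulate_epidermis <- function(spec, lp = lifecycle_params(),
                               fp = force_params(), T_total_h = 500,
                               snapshot_every_h = 25, seed = 1,
                               stem_spacing_um = 10, init = NULL) {
  stopifnot(inherits(spec, "membrane_spec"))
  if (T_total_h < 0) stop("T_total_h must be >= 0")
  set.seed(seed)
  if (is.null(init)) {
    stems <- place_stem_cells(spec, spacing_um = stem_spacing_um,
                              r0_um = lp$r0_um)
    cells <- data.frame(id = seq_len(nrow(stems)) - 1L,
                        x = stems$x, y = stems$y, z = stems$z,
                        a = lp$r0_um, c = lp$r0_um, state = "STEM",
                        age_in_state = 0,
                        anchor_x = stems$x, anchor_y = stems$y, ca = 0)
    state <- sim_state(cells, r0_um = lp$r0_um)
  } else {
    state <- init
  }
  n_steps <- round(T_total_h / fp$dt_h)
  rec <- max(1L, round(snapshot_every_h / fp$dt_h))
  snapshots <- list(state)
  if (n_steps > 0) {
    v <- state_vectors(state)
    res <- cpp_run(v$x, v$y, v$z, v$a, v$c, v$state, v$age, v$ax, v$ay, v$ca,
                   v$id, unclass(spec), unclass(fp), unclass(lp),
                   as.integer(n_steps), as.integer(rec),
                   state$t, state$births, state$removals, -1L)
    snapshots <- c(snapshots, lapply(res$snapshots, snapshot_to_state))
    if (n_steps %% rec != 0)
      snapshots <- c(snapshots, list(snapshot_to_state(res$final)))
  }
  counters <- do.call(rbind, lapply(snapshots, function(s) {
    tab <- table(factor(s$cells$state, levels = STATE_LEVELS))
    data.frame(t = s$t, n = nrow(s$cells), as.list(tab),
               births = s$births, removals = s$removals,
               check.names = FALSE)
  }))
  structure(list(snapshots = snapshots, counters = counters,
                 spec = spec, lp = lp, fp = fp, seed = seed,
                 stem_spacing_um = stem_spacing_um),
            class = "epiderm_trajectory")
}

#' @export
print.epiderm_trajectory <- function(x, ...) {
  last <- x$counters[nrow(x$counters), ]
  cat(sprintf(paste0("<epiderm_trajectory> %s membrane, %d snapshots to ",
                     "t = %.0f h\n  final: %d cells (%d cornified), ",
                     "births %d, removals %d\n"),
              x$spec$kind, nrow(x$counters), last$t, last$n,
              last$CORNEOCYTE, last$births, last$removals))
  invisible(x)
}

#' Final snapshot of a trajectory
#' @param traj an `epiderm_trajectory`.
#' @return the last `sim_state`.
#' @export
final_state <- function(traj) traj$snapshots[[length(traj$snapshots)]]
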